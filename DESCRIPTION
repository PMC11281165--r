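Package: handassess
Title: Hand Function Assessment from 3D Keypoints and Knowledge-Graph
    Question Answering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes clinical hand-function measures from sequences of 21
    three-dimensional hand landmarks produced by monocular pose estimators:
    per-joint flexion angles via the dot-product formula, range of motion,
    the thumb-opposition test, thumb active range of motion, a functional
    scoring rubric with normal-range classification, and a surface-normal
    consistency metric for comparing predicted and reference poses. A
    forward-kinematic generator synthesises landmark sequences with
    programmed joint angles for validation. A companion module loads
    hand-disease records into an in-memory knowledge graph (diseases,
    departments, drugs, foods, producers) and answers natural-language
    questions through dictionary-automaton entity matching, intent
    classification and template queries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
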