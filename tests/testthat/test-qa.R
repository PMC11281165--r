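g_fix <- fixture_graph()
dict_fix <- build_dictionary(g_fix)

test_that("dictionary construction requires a nonempty graph", {
  expect_error(build_dictionary(kg_build(list())),
               class = "hand_error_empty_graph")
  expect_equal(nrow(dict_fix$entities), nrow(g_fix$entities))
})

test_that("entity matching keeps the longest occurrence and preserves order", {
  g <- kg_build(list(
    make_record("tendon sheath cyst"),
    make_record("cyst"),
    make_record("tenosynovitis")
  ))
  d <- build_dictionary(g)

  m <- match_entities("what causes tendon sheath cyst", d)
  expect_equal(m$entity_name, "tendon sheath cyst")
  expect_equal(m$surface, "tendon sheath cyst")
  expect_equal(substr("what causes tendon sheath cyst", m$start, m$end),
               m$surface)

  two <- match_entities("is a cyst worse than tenosynovitis?", d)
  expect_equal(two$entity_name, c("cyst", "tenosynovitis"))
  expect_true(all(diff(two$start) > 0))

  expect_equal(nrow(match_entities("no entities here", d)), 0)
  # case-insensitive matching reports the original surface
  up <- match_entities("What causes TENOSYNOVITIS?", d)
  expect_equal(up$entity_name, "tenosynovitis")
  expect_equal(up$surface, "TENOSYNOVITIS")
})

test_that("matching completeness: automaton hits equal naive search pre-resolution", {
  lower_names <- stringr::str_to_lower(dict_fix$entities$key)
  questions <- c(
    "does tendon sheath cyst accompany tenosynovitis or trigger finger",
    "tell me about achilles tendinitis and distal radius fracture",
    "renault's disease thallium poisoning hand flexor tendon injury"
  )
  for (q in questions) {
    expect_identical(sort_matches(ac_find(dict_fix$automaton, q)),
                     naive_find_all(lower_names, q))
  }
})

test_that("question classification follows the trigger table", {
  classify <- function(q) {
    m <- match_entities(q, dict_fix)
    classify_question(q, m, dict_fix)$intent
  }
  expect_equal(classify("What causes tenosynovitis?"), "cause")
  expect_setequal(
    classify("What should tenosynovitis patients eat and what drugs help?"),
    c("food_recommend", "drug_recommend"))
  expect_equal(classify("Tell me about tendon sheath cyst"), "desc")
  expect_equal(classify("What should tenosynovitis patients not eat?"),
               "food_avoid")
  expect_equal(classify("What is the cure rate of tendon sheath cyst?"),
               "cured_probe")
  expect_setequal(classify("How long does tendon sheath cyst treatment take?"),
                  "cure_lasttime")
  expect_equal(classify("Which department treats trigger finger?"),
               c("department", "cure_way"))
  expect_equal(classify("hello there"), character(0))
})

test_that("query templates map intents onto schema primitives", {
  p <- build_query("cause", "tenosynovitis")
  expect_equal(p$op, "attribute")
  expect_equal(p$arg, "cause")

  p <- build_query("complication", "tenosynovitis")
  expect_equal(p$op, "neighbors")
  expect_equal(p$arg, "acompany_with")
  expect_equal(p$direction, "out")

  p <- build_query("food_recommend", "tenosynovitis")
  expect_equal(p$arg, c("do_eat", "recommand_eat"))

  p <- build_query("drug_producer", "Ganlu Renqing Mangjue", "Drug")
  expect_equal(p$arg, "drugs_of")
  expect_equal(p$direction, "in")

  expect_error(build_query("sing_a_song", "x"),
               class = "hand_error_unsupported_intent")
})

test_that("query execution delegates to the graph and tolerates unknowns", {
  res <- execute_query(build_query("complication", "tenosynovitis"), g_fix)
  expect_equal(res$item, "purulent dactylitis")
  expect_equal(res$item, kg_neighbors(g_fix, "tenosynovitis", "acompany_with"))

  none <- execute_query(build_query("complication", "trigger finger"), g_fix)
  expect_equal(nrow(none), 0)

  expect_warning(
    res_unknown <- execute_query(build_query("cause", "never heard of it"), g_fix),
    "unknown entity")
  expect_equal(nrow(res_unknown), 0)
})

test_that("end-to-end answers carry the fixture facts", {
  a1 <- answer("What are the complications of tenosynovitis?", g_fix, dict_fix)
  expect_match(a1$rendered_text, "purulent dactylitis")
  expect_false(a1$empty_flag)

  a2 <- answer("How long does tendon sheath cyst treatment take?", g_fix, dict_fix)
  expect_match(a2$rendered_text, "1–3 weeks")

  a3 <- answer("hello", g_fix, dict_fix)
  expect_true(a3$empty_flag)
  expect_match(a3$rendered_text, "could not identify")

  a4 <- answer("What is the cure rate of tendon sheath cyst?", g_fix, dict_fix)
  expect_match(a4$rendered_text, "80%")
})

test_that("answers are deterministic and sound against the graph", {
  questions <- c(
    "What are the complications of tenosynovitis?",
    "What should tenosynovitis patients eat and what drugs help?",
    "Which department treats Renault's disease?",
    "What foods should Achilles tendinitis patients not eat?"
  )
  for (q in questions) {
    r1 <- answer(q, g_fix, dict_fix)
    r2 <- answer(q, g_fix, dict_fix)
    expect_identical(r1$rendered_text, r2$rendered_text)

    # provenance soundness: every neighbor item is a graph entity reachable
    # from the matched entity by the recorded relation
    prov <- tidy(r1)
    nb <- prov[prov$op == "neighbors", ]
    if (nrow(nb) > 0) {
      expect_true(all(nb$item %in% g_fix$entities$name))
      for (i in seq_len(nrow(nb))) {
        expect_true(nb$item[i] %in%
                      kg_neighbors(g_fix, nb$entity[i], nb$arg[i], nb$direction[i]))
      }
    }
  }
})

test_that("the degenerate ranking returns every retrieved entity", {
  a <- answer("What should distal radius fracture patients eat?", g_fix, dict_fix)
  retrieved <- sort(unique(c(
    kg_neighbors(g_fix, "distal radius fracture", "do_eat"),
    kg_neighbors(g_fix, "distal radius fracture", "recommand_eat")
  )))
  expect_setequal(tidy(a)$item, retrieved)
  for (item in retrieved) expect_match(a$rendered_text, item, fixed = TRUE)
})
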