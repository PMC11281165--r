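#' Question intents and their trigger keywords
#'
#' The question classifier recognises a closed set of 14 intents, induced by
#' the knowledge-graph schema: one per disease attribute (`desc`, `cause`,
#' `prevention`, `cure_way`, `cure_lasttime`, `cured_probe`, `easy_get`,
#' `symptom`) and one per askable relation (`complication`, `department`,
#' `food_recommend`, `food_avoid`, `drug_recommend`, `drug_producer`). Each
#' intent except `desc` has a list of English trigger phrases; `desc` is the
#' default when a question names an entity but contains no trigger. The
#' shipped table is an English reconstruction and can be replaced wholesale
#' for other locales (any tibble with columns `intent` and `trigger`).
#'
#' Trigger occurrences are found with the same dictionary automaton as
#' entity names, must fall on word boundaries, and overlapping occurrences
#' are resolved longest-first (so "cure rate" beats "cure", and "not eat"
#' beats "eat").
#'
#' @return A tibble with columns `intent` and `trigger`.
#' @export
qa_keyword_table <- function() {
  triggers <- list(
    cause = c("cause", "causes", "caused", "why", "etiology", "reason", "reasons"),
    prevention = c("prevent", "prevention", "preventive", "avoid getting",
                   "how to avoid"),
    cure_way = c("treatment", "treatments", "treat", "treats", "treated",
                 "therapy", "cure", "cured", "remedy", "how to fix"),
    cure_lasttime = c("how long", "duration", "treatment take",
                      "treatment period", "treatment cycle", "recovery time"),
    cured_probe = c("cure rate", "cured rate", "prognosis",
                    "chance of recovery", "probability of being cured",
                    "likelihood of cure", "curable"),
    easy_get = c("who gets", "susceptible", "prone to", "at risk",
                 "who is likely", "affected population"),
    symptom = c("symptom", "symptoms", "signs", "manifestation",
                "manifestations"),
    complication = c("complication", "complications", "comorbid",
                     "comorbidities", "accompany", "accompanied"),
    department = c("department", "departments", "which doctor", "what doctor",
                   "specialist", "clinic"),
    food_recommend = c("eat", "food", "foods", "diet", "dietary", "recipe",
                       "recipes", "nutrition"),
    food_avoid = c("not eat", "avoid eating", "avoid food", "shouldn't eat",
                   "should not eat", "cannot eat", "can't eat", "abstain",
                   "forbidden food", "avoid"),
    drug_recommend = c("drug", "drugs", "medication", "medications",
                       "medicine", "medicines", "prescribe", "prescription"),
    drug_producer = c("producer", "producers", "manufacturer", "manufacturers",
                      "who makes", "who sells", "brand", "on sale")
  )
  purrr::imap_dfr(triggers, function(tr, intent) {
    tibble::tibble(intent = intent, trigger = tr)
  })
}

qa_intents <- function() {
  c("desc", "cause", "prevention", "cure_way", "cure_lasttime", "cured_probe",
    "easy_get", "symptom", "complication", "department", "food_recommend",
    "food_avoid", "drug_recommend", "drug_producer")
}

#' Build the matching dictionary for a knowledge graph
#'
#' Constructs the entity-name automaton and the intent trigger automaton used
#' by [match_entities()] and [classify_question()]. Matching is
#' case-insensitive: dictionary and question are case-folded; reported
#' surfaces are taken from the original question text.
#'
#' @param g A `knowledge_graph` with at least one entity.
#' @param keyword_table Trigger table, by default [qa_keyword_table()].
#' @return An object of class `qa_dictionary`.
#' @export
build_dictionary <- function(g, keyword_table = qa_keyword_table()) {
  stopifnot(inherits(g, "knowledge_graph"))
  if (nrow(g$entities) == 0) {
    rlang::abort("cannot build a dictionary for an empty graph",
                 class = "hand_error_empty_graph")
  }
  entities <- dplyr::mutate(g$entities, key = stringr::str_to_lower(.data$name))
  # two entities that collide after case folding resolve to the first by name
  entities <- dplyr::distinct(entities, .data$key, .keep_all = TRUE)
  structure(
    list(
      entities = entities,
      automaton = ac_build(entities$key),
      keyword_table = keyword_table,
      trigger_automaton = ac_build(stringr::str_to_lower(keyword_table$trigger))
    ),
    class = "qa_dictionary"
  )
}

#' @export
print.qa_dictionary <- function(x, ...) {
  cat("<qa_dictionary>: ", nrow(x$entities), " entity names, ",
      nrow(x$keyword_table), " intent triggers\n", sep = "")
  invisible(x)
}

# keep matches whose flanks are not alphanumeric (word-boundary filter)
on_word_boundary <- function(text, start, end) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_word <- function(ch) grepl("[[:alnum:]]", ch)
  ok_left <- start == 1 | !vapply(chars[pmax(start - 1, 1)], is_word, logical(1))
  ok_right <- end == length(chars) |
    !vapply(chars[pmin(end + 1, length(chars))], is_word, logical(1))
  ok_left & ok_right
}

#' Match knowledge-graph entities in a question
#'
#' Finds every dictionary occurrence with the Aho-Corasick automaton, then
#' resolves overlaps to the longest match (ties: leftmost). Retained matches
#' are non-overlapping and ordered by position.
#'
#' @param question Question text.
#' @param dict A [build_dictionary()] object.
#' @return A tibble with columns `surface` (substring of `question`),
#'   `entity_name`, `entity_type`, `start`, `end` (1-based inclusive
#'   character positions).
#' @export
match_entities <- function(question, dict) {
  stopifnot(inherits(dict, "qa_dictionary"))
  lower <- stringr::str_to_lower(question)
  hits <- ac_find(dict$automaton, lower)
  hits <- resolve_overlaps(hits)
  if (nrow(hits) == 0) {
    return(tibble::tibble(surface = character(0), entity_name = character(0),
                          entity_type = character(0), start = integer(0),
                          end = integer(0)))
  }
  idx <- match(hits$pattern, dict$entities$key)
  tibble::tibble(
    surface = stringr::str_sub(question, hits$start, hits$end),
    entity_name = dict$entities$name[idx],
    entity_type = dict$entities$type[idx],
    start = hits$start,
    end = hits$end
  )
}

#' Classify a question into intents
#'
#' Applies the trigger table: every triggered keyword group contributes one
#' intent, ordered by first trigger position. A question that names an entity
#' but contains no trigger defaults to the `desc` intent; a question with no
#' matched entity yields no intents (the answering layer then asks for
#' clarification). Trigger occurrences inside a matched entity span are
#' ignored.
#'
#' @param question Question text.
#' @param matches Entity matches from [match_entities()].
#' @param dict A [build_dictionary()] object.
#' @return A tibble with one row per intent, column `intent`.
#' @export
classify_question <- function(question, matches, dict) {
  stopifnot(inherits(dict, "qa_dictionary"))
  if (nrow(matches) == 0) return(tibble::tibble(intent = character(0)))
  lower <- stringr::str_to_lower(question)
  hits <- ac_find(dict$trigger_automaton, lower)
  if (nrow(hits) > 0) {
    hits <- hits[on_word_boundary(lower, hits$start, hits$end), ]
  }
  if (nrow(hits) > 0) { # drop triggers inside an entity mention
    inside <- purrr::map2_lgl(hits$start, hits$end, function(s, e) {
      any(s >= matches$start & e <= matches$end)
    })
    hits <- hits[!inside, ]
  }
  hits <- resolve_overlaps(hits)
  if (nrow(hits) == 0) return(tibble::tibble(intent = "desc"))
  kt <- dict$keyword_table
  intents <- kt$intent[match(hits$pattern, stringr::str_to_lower(kt$trigger))]
  tibble::tibble(intent = unique(intents))
}

#' Build a query plan for an intent
#'
#' Each intent maps to a fixed template of primitive retrievals: an attribute
#' lookup on a disease, or a one-hop neighbor lookup along a typed relation.
#'
#' @param intent Intent name (see [qa_keyword_table()]).
#' @param entity_name Matched entity the intent applies to.
#' @param entity_type Entity type (`"Disease"`, `"Drug"`, ...).
#' @return A tibble with columns `op` (`"attribute"` or `"neighbors"`),
#'   `entity`, `arg` (attribute name or relation type), `direction`.
#' @export
build_query <- function(intent, entity_name, entity_type = "Disease") {
  attr_map <- c(desc = "desc", cause = "cause", prevention = "prevention",
                cure_way = "cure_way", cure_lasttime = "cure_lasttime",
                cured_probe = "cured_probe", easy_get = "easy_get",
                symptom = "symptoms")
  plan <- function(op, arg, direction = NA_character_) {
    tibble::tibble(op = op, entity = entity_name, arg = arg,
                   direction = direction)
  }
  if (intent %in% names(attr_map)) return(plan("attribute", attr_map[[intent]]))
  switch(intent,
    complication   = plan("neighbors", "acompany_with", "out"),
    department     = plan("neighbors", "belongs_to", "out"),
    food_recommend = dplyr::bind_rows(plan("neighbors", "do_eat", "out"),
                                      plan("neighbors", "recommand_eat", "out")),
    food_avoid     = plan("neighbors", "no_eat", "out"),
    drug_recommend = plan("neighbors", "recommand_drug", "out"),
    drug_producer  = if (identical(entity_type, "Drug")) {
      plan("neighbors", "drugs_of", "in")
    } else {
      plan("neighbors", "recommand_drug", "out")
    },
    rlang::abort(paste0("unsupported intent '", intent, "'"),
                 class = "hand_error_unsupported_intent")
  )
}

#' Execute a query plan against the graph
#'
#' Runs each primitive, deduplicates and sorts results per primitive, and
#' keeps provenance (which primitive produced each item). An unknown entity
#' yields an empty result with a warning rather than an error.
#'
#' @param plan A [build_query()] plan.
#' @param g A `knowledge_graph`.
#' @return A tibble with columns `op`, `entity`, `arg`, `direction`, `item`.
#' @export
execute_query <- function(plan, g) {
  stopifnot(inherits(g, "knowledge_graph"))
  purrr::pmap_dfr(plan, function(op, entity, arg, direction) {
    items <- tryCatch({
      if (op == "attribute") {
        v <- kg_attribute(g, entity, arg)
        if (all(is.na(v))) character(0) else v
      } else {
        kg_neighbors(g, entity, arg, direction)
      }
    }, hand_error_unknown_entity = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      character(0)
    })
    if (length(items) == 0) return(tibble::tibble())
    tibble::tibble(op = op, entity = entity, arg = arg,
                   direction = direction, item = items)
  })
}

qa_templates <- function() {
  c(desc = "About %s: %s",
    cause = "Causes of %s: %s",
    prevention = "Prevention of %s: %s",
    cure_way = "Treatment methods for %s: %s",
    cure_lasttime = "Typical treatment duration for %s: %s",
    cured_probe = "Cure rate of %s: %s",
    easy_get = "Susceptible population of %s: %s",
    symptom = "Symptoms of %s: %s",
    complication = "Known complications of %s: %s",
    department = "%s is treated by: %s",
    food_recommend = "Recommended foods for %s: %s",
    food_avoid = "Foods to avoid with %s: %s",
    drug_recommend = "Recommended drugs for %s: %s",
    drug_producer = "Producers associated with %s: %s")
}

#' Answer a natural-language question from the knowledge graph
#'
#' The full single-step retrieve-and-render pipeline: entity matching with
#' the dictionary automaton, intent classification via the trigger table, a
#' fixed query template per intent, one-hop retrieval, and one rendered
#' sentence per (intent, entity) pair. All retrieved items are kept (the
#' degenerate ranking: every candidate scores 1 against a threshold of 0).
#' The pipeline is deterministic: identical question and graph give
#' byte-identical output.
#'
#' @param question Question text.
#' @param g A `knowledge_graph`.
#' @param dict Optional prebuilt [build_dictionary()]; built on the fly when
#'   omitted.
#' @return An object of class `qa_answer`: a list with `question`,
#'   `matches`, `intents`, `results` (retrieval provenance), `rendered_text`
#'   and `empty_flag` (`TRUE` iff every retrieval came back empty).
#' @examples
#' g <- kg_build(read_disease_records(
#'   system.file("extdata", "hand_diseases.jsonl", package = "handassess")))
#' answer("What are the complications of tenosynovitis?", g)
#' @export
answer <- function(question, g, dict = NULL) {
  stopifnot(is.character(question), length(question) == 1)
  if (!nzchar(trimws(question))) {
    rlang::abort("question is empty", class = "hand_error_empty_question")
  }
  if (is.null(dict)) dict <- build_dictionary(g)
  matches <- match_entities(question, dict)
  intents <- classify_question(question, matches, dict)

  if (nrow(intents) == 0) {
    return(structure(
      list(question = question, matches = matches, intents = intents,
           results = tibble::tibble(),
           rendered_text = paste(
             "Sorry, I could not identify a disease, food or drug in your",
             "question. Please name one explicitly."),
           empty_flag = TRUE),
      class = "qa_answer"
    ))
  }

  templates <- qa_templates()
  sentences <- character(0)
  results <- list()
  for (intent in intents$intent) {
    # answer every matched disease; drug entities only for producer lookups
    targets <- if (intent == "drug_producer" && any(matches$entity_type == "Drug")) {
      matches[matches$entity_type == "Drug", ]
    } else {
      matches[matches$entity_type == "Disease", ]
    }
    if (nrow(targets) == 0) next
    for (t in seq_len(nrow(targets))) {
      ename <- targets$entity_name[t]
      plan <- build_query(intent, ename, targets$entity_type[t])
      res <- execute_query(plan, g)
      if (nrow(res) > 0) {
        res <- dplyr::mutate(res, intent = intent, .before = 1)
        results[[length(results) + 1]] <- res
        # producer questions about a disease fall back to its drug list
        tmpl_key <- if (intent == "drug_producer" &&
                        targets$entity_type[t] != "Drug") "drug_recommend" else intent
        sentences <- c(sentences,
                       sprintf(templates[[tmpl_key]], ename,
                               paste(res$item, collapse = "; ")))
      } else {
        sentences <- c(sentences,
                       sprintf("No %s information found for %s.",
                               gsub("_", " ", intent), ename))
      }
    }
  }
  results <- if (length(results) > 0) dplyr::bind_rows(results) else tibble::tibble()
  if (length(sentences) == 0) {
    sentences <- paste("Sorry, I could not relate your question to a disease",
                       "in the knowledge graph.")
  }
  structure(
    list(question = question, matches = matches, intents = intents,
         results = results,
         rendered_text = paste(sentences, collapse = "\n"),
         empty_flag = nrow(results) == 0),
    class = "qa_answer"
  )
}

#' @export
print.qa_answer <- function(x, ...) {
  cat("Q:", x$question, "\n")
  cat(x$rendered_text, "\n")
  invisible(x)
}

#' @rdname answer
#' @param x A `qa_answer`.
#' @param ... Unused.
#' @return `tidy.qa_answer()`: the provenance tibble (`intent`, `op`,
#'   `entity`, `arg`, `direction`, `item`).
#' @export
tidy.qa_answer <- function(x, ...) {
  if (nrow(x$results) == 0) {
    return(tibble::tibble(intent = character(0), op = character(0),
                          entity = character(0), arg = character(0),
                          direction = character(0), item = character(0)))
  }
  x$results
}
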