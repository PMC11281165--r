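test_that("relation bookkeeping matches the record fields", {
  g <- kg_build(list(make_record(
    "disease A",
    recommended_foods = list("food 1", "food 2"),
    complications = list("disease B")
  )))
  expect_equal(sum(g$relations$rel == "do_eat"), 2)
  expect_equal(sum(g$relations$rel == "acompany_with"), 1)
  expect_setequal(g$entities$type, c("Disease", "Food"))

  empty <- kg_build(list())
  expect_equal(nrow(empty$entities), 0)
  expect_equal(nrow(empty$relations), 0)
  s <- kg_stats(empty)
  expect_equal(s$n_entities, 0)
  expect_equal(s$n_relations, 0)
})

test_that("shared names deduplicate into a single entity", {
  g <- kg_build(list(
    make_record("disease A", recommended_foods = list("shared food")),
    make_record("disease B", recommended_foods = list("shared food"))
  ))
  expect_equal(sum(g$entities$name == "shared food"), 1)
  expect_equal(sum(g$relations$tail == "shared food"), 2)
})

test_that("duplicate disease names and schema violations are rejected", {
  recs <- list(make_record("dup"), make_record("dup"))
  expect_error(kg_build(recs), class = "hand_error_duplicate_disease")
  expect_error(kg_build(list(list(name = "  "))), class = "hand_error_schema")
  expect_error(kg_build(list(make_record("x", drug_producers = list(list("only one"))))),
               class = "hand_error_schema")
})

test_that("loading is order-invariant, idempotent and referentially intact", {
  recs <- read_disease_records(
    system.file("extdata", "hand_diseases.jsonl", package = "handassess"))
  g1 <- kg_build(recs)
  expect_identical(g1, kg_build(recs)) # idempotent on identical input

  set.seed(31)
  for (i in 1:5) {
    g2 <- kg_build(sample(recs))
    expect_identical(g1$entities, g2$entities)
    expect_identical(g1$relations, g2$relations)
    expect_identical(dplyr::arrange(g1$attributes, disease, attr),
                     dplyr::arrange(g2$attributes, disease, attr))
  }

  endpoints <- unique(c(g1$relations$head, g1$relations$tail))
  expect_true(all(endpoints %in% g1$entities$name))
})

test_that("neighbors agree with a linear scan of the relation set", {
  g <- fixture_graph()
  expect_equal(kg_neighbors(g, "tenosynovitis", "acompany_with"),
               "purulent dactylitis")
  expect_equal(kg_neighbors(g, "Renault's disease", "belongs_to"),
               "rheumatic immune disease")
  expect_equal(kg_neighbors(g, "hand flexor tendon injury", "do_eat"), "cashew")
  expect_equal(kg_neighbors(g, "Achilles tendinitis", "no_eat"), "chicken wings")
  expect_equal(kg_neighbors(g, "distal radius fracture", "recommand_eat"),
               "fried eggplant with egg")
  expect_equal(kg_neighbors(g, "Ganlu Renqing Mangjue", "drugs_of", "in"),
               "Renqing Mangjue")
  expect_equal(kg_neighbors(g, "tendon sheath cyst", "acompany_with"),
               character(0))
  expect_error(kg_neighbors(g, "nonexistent", "do_eat"),
               class = "hand_error_unknown_entity")

  # oracle: brute-force scan over all (entity, rel, direction) combinations
  for (ent in sample(g$entities$name, 10)) {
    for (rel in unique(g$relations$rel)) {
      scan_out <- sort(unique(g$relations$tail[
        g$relations$head == ent & g$relations$rel == rel]))
      scan_in <- sort(unique(g$relations$head[
        g$relations$tail == ent & g$relations$rel == rel]))
      expect_equal(kg_neighbors(g, ent, rel, "out"), scan_out)
      expect_equal(kg_neighbors(g, ent, rel, "in"), scan_in)
    }
  }
})

test_that("disease attributes store the documented example values", {
  g <- fixture_graph()
  expect_equal(kg_attribute(g, "tendon sheath cyst", "cure_lasttime"),
               "1–3 weeks")
  expect_equal(kg_attribute(g, "tendon sheath cyst", "cured_probe"), "80%")
  expect_match(kg_attribute(g, "tendon sheath cyst", "easy_get"),
               "young and middle-aged")
  expect_length(kg_attribute(g, "tendon sheath cyst", "cure_way"), 3)
  expect_true(is.na(kg_attribute(g, "Renault's disease", "cure_lasttime")))
  expect_error(kg_attribute(g, "tendon sheath cyst", "favourite_colour"),
               class = "hand_error_unknown_attribute")
})

test_that("graph statistics count entities and relations by type", {
  g <- fixture_graph()
  s <- kg_stats(g)
  expect_equal(sum(s$entities$n), s$n_entities)
  expect_equal(sum(s$relations$n), s$n_relations)
  expect_true(all(c("Department", "Disease", "Drug", "Food", "Producer") %in%
                    s$entities$type))
  expect_setequal(s$relations$rel,
                  c("acompany_with", "belongs_to", "do_eat", "drugs_of",
                    "no_eat", "recommand_drug", "recommand_eat"))
})

test_that("Cypher export emits one statement per entity and relation", {
  g <- fixture_graph()
  lines <- kg_export_cypher(g)
  expect_length(lines, nrow(g$entities) + nrow(g$relations))
  expect_true(any(grepl("CREATE \\(:Disease \\{name: 'tenosynovitis'\\}\\);", lines)))
  expect_true(any(grepl("\\[:acompany_with\\]", lines)))
  f <- withr::local_tempfile()
  kg_export_cypher(g, f)
  expect_identical(readLines(f, encoding = "UTF-8"), lines)
})
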