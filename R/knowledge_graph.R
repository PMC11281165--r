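#' Load hand-disease records into an in-memory knowledge graph
#'
#' Records follow a fixed per-disease schema: eight scalar attributes
#' (`desc`, `cause`, `prevention`, `cure_lasttime`, `cure_way`,
#' `cured_probe`, `easy_get`, plus the disease `name`), a list of symptom
#' phrases, and list fields that become typed relations:
#'
#' | record field         | relation        | head -> tail        |
#' |----------------------|-----------------|---------------------|
#' | `complications`      | `acompany_with` | Disease -> Disease  |
#' | `departments`        | `belongs_to`    | Disease -> Department |
#' | `recommended_foods`  | `do_eat`        | Disease -> Food     |
#' | `avoided_foods`      | `no_eat`        | Disease -> Food     |
#' | `recommended_recipes`| `recommand_eat` | Disease -> Food     |
#' | `recommended_drugs`  | `recommand_drug`| Disease -> Drug     |
#' | `drug_producers`     | `drugs_of`      | Producer -> Drug    |
#'
#' Symptoms are stored as a disease attribute (a list of phrases), not as
#' entities. Entity names are matched exactly after whitespace trimming and
#' whitespace normalization; names shared across records are deduplicated
#' into a single entity. Relations are a set: loading is idempotent and
#' independent of record order.
#'
#' @param records A list of disease records (named lists), or a data frame
#'   with one row per disease and list-columns for the list fields. See
#'   [read_disease_records()] for the line-delimited JSON file format.
#' @return An object of class `knowledge_graph` with tibble components
#'   `entities` (`name`, `type`), `relations` (`head`, `rel`, `tail`) and
#'   `attributes` (`disease`, `attr`, `value`).
#' @examples
#' g <- kg_build(list(
#'   list(name = "tenosynovitis", complications = list("purulent dactylitis"))
#' ))
#' kg_neighbors(g, "tenosynovitis", "acompany_with")
#' @export
kg_build <- function(records) {
  if (is.data.frame(records)) {
    records <- purrr::transpose(as.list(records))
  }
  norm <- function(x) stringr::str_squish(as.character(x))
  scalar_attrs <- c("desc", "cause", "prevention", "cure_lasttime",
                    "cured_probe", "easy_get")
  list_attrs <- c("cure_way", "symptoms")
  rel_fields <- tibble::tribble(
    ~field,                ~rel,             ~tail_type,
    "complications",       "acompany_with",  "Disease",
    "departments",         "belongs_to",     "Department",
    "recommended_foods",   "do_eat",         "Food",
    "avoided_foods",       "no_eat",         "Food",
    "recommended_recipes", "recommand_eat",  "Food",
    "recommended_drugs",   "recommand_drug", "Drug"
  )

  entities <- tibble::tibble(name = character(0), type = character(0))
  relations <- tibble::tibble(head = character(0), rel = character(0),
                              tail = character(0))
  attributes <- tibble::tibble(disease = character(0), attr = character(0),
                               value = list())

  add_entity <- function(name, type) {
    tibble::tibble(name = name, type = type)
  }

  seen <- character(0)
  ent_acc <- list()
  rel_acc <- list()
  attr_acc <- list()
  for (rec in records) {
    if (is.null(rec$name) || !nzchar(norm(rec$name))) {
      rlang::abort("every disease record needs a nonempty 'name'",
                   class = "hand_error_schema")
    }
    dname <- norm(rec$name)
    if (dname %in% seen) {
      rlang::abort(paste0("duplicate disease name '", dname, "'"),
                   class = "hand_error_duplicate_disease")
    }
    seen <- c(seen, dname)
    ent_acc[[length(ent_acc) + 1]] <- add_entity(dname, "Disease")

    for (a in scalar_attrs) {
      if (!is.null(rec[[a]]) && nzchar(norm(rec[[a]])[1])) {
        attr_acc[[length(attr_acc) + 1]] <-
          tibble::tibble(disease = dname, attr = a, value = list(norm(rec[[a]])[1]))
      }
    }
    for (a in list_attrs) {
      vals <- norm(unlist(rec[[a]]))
      vals <- vals[nzchar(vals)]
      if (length(vals) > 0) {
        attr_acc[[length(attr_acc) + 1]] <-
          tibble::tibble(disease = dname, attr = a, value = list(vals))
      }
    }
    for (r in seq_len(nrow(rel_fields))) {
      vals <- norm(unlist(rec[[rel_fields$field[r]]]))
      vals <- vals[nzchar(vals)]
      if (length(vals) > 0) {
        ent_acc[[length(ent_acc) + 1]] <- add_entity(vals, rel_fields$tail_type[r])
        rel_acc[[length(rel_acc) + 1]] <-
          tibble::tibble(head = dname, rel = rel_fields$rel[r], tail = vals)
      }
    }
    # drug_producers: list of (producer, drug) pairs -> Producer -drugs_of-> Drug
    if (!is.null(rec$drug_producers)) {
      pairs <- rec$drug_producers
      if (is.data.frame(pairs)) pairs <- purrr::transpose(as.list(pairs))
      if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
      if (is.character(pairs) && length(pairs) == 2) pairs <- list(pairs)
      for (p in pairs) {
        p <- unlist(p)
        if (length(p) != 2) {
          rlang::abort("drug_producers entries must be (producer, drug) pairs",
                       class = "hand_error_schema")
        }
        producer <- norm(p[1]); drug <- norm(p[2])
        ent_acc[[length(ent_acc) + 1]] <- add_entity(producer, "Producer")
        ent_acc[[length(ent_acc) + 1]] <- add_entity(drug, "Drug")
        rel_acc[[length(rel_acc) + 1]] <-
          tibble::tibble(head = producer, rel = "drugs_of", tail = drug)
      }
    }
  }

  entities <- dplyr::distinct(dplyr::bind_rows(entities, ent_acc))
  relations <- dplyr::distinct(dplyr::bind_rows(relations, rel_acc))
  attributes <- dplyr::bind_rows(attributes, attr_acc)

  dup <- entities$name[duplicated(entities$name)]
  if (length(dup) > 0) {
    rlang::abort(
      paste0("entity name(s) used with conflicting types: ",
             paste(unique(dup), collapse = ", ")),
      class = "hand_error_schema"
    )
  }
  entities <- dplyr::arrange(entities, .data$type, .data$name)
  relations <- dplyr::arrange(relations, .data$rel, .data$head, .data$tail)
  attributes <- dplyr::arrange(attributes, .data$disease, .data$attr)

  structure(list(entities = entities, relations = relations,
                 attributes = attributes),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph>: ", nrow(x$entities), " entities, ",
      nrow(x$relations), " relations, ",
      nrow(x$attributes), " attribute entries\n", sep = "")
  invisible(x)
}

#' Read line-delimited disease records
#'
#' One JSON object per line, UTF-8, with the field names documented in
#' [kg_build()].
#'
#' @param path Path to a `.jsonl` file.
#' @return A list of records suitable for [kg_build()].
#' @examples
#' path <- system.file("extdata", "hand_diseases.jsonl", package = "handassess")
#' g <- kg_build(read_disease_records(path))
#' kg_stats(g)
#' @export
read_disease_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  purrr::imap(lines, function(l, i) {
    tryCatch(
      jsonlite::fromJSON(l, simplifyVector = TRUE, simplifyDataFrame = FALSE),
      error = function(e) rlang::abort(
        paste0("line ", i, " of '", path, "' is not valid JSON: ",
               conditionMessage(e)),
        class = "hand_error_parse"
      )
    )
  })
}

check_entity <- function(g, name) {
  if (!name %in% g$entities$name) {
    rlang::abort(paste0("unknown entity '", name, "'"),
                 class = "hand_error_unknown_entity")
  }
  invisible(name)
}

#' One-hop neighbors of an entity
#'
#' @param g A `knowledge_graph`.
#' @param entity Entity name (exact, whitespace-normalized form).
#' @param rel Relation type, one of `acompany_with`, `belongs_to`, `do_eat`,
#'   `drugs_of`, `no_eat`, `recommand_drug`, `recommand_eat`.
#' @param direction `"out"` (entity is the head) or `"in"` (entity is the
#'   tail).
#' @return Sorted, deduplicated character vector of neighbor names.
#' @export
kg_neighbors <- function(g, entity, rel,
                         direction = c("out", "in")) {
  stopifnot(inherits(g, "knowledge_graph"))
  direction <- match.arg(direction)
  check_entity(g, entity)
  rels <- g$relations[g$relations$rel == rel, ]
  res <- if (direction == "out") rels$tail[rels$head == entity]
         else rels$head[rels$tail == entity]
  sort(unique(res))
}

#' Look up a disease attribute
#'
#' @param g A `knowledge_graph`.
#' @param disease Disease name.
#' @param attr One of `desc`, `cause`, `prevention`, `cure_lasttime`,
#'   `cure_way`, `cured_probe`, `easy_get`, `symptoms`.
#' @return The stored value (character vector; scalar attributes have length
#'   1), or `NA_character_` when the disease has no such attribute.
#' @export
kg_attribute <- function(g, disease, attr) {
  stopifnot(inherits(g, "knowledge_graph"))
  valid <- c("desc", "cause", "prevention", "cure_lasttime", "cure_way",
             "cured_probe", "easy_get", "symptoms")
  if (!attr %in% valid) {
    rlang::abort(paste0("unknown attribute '", attr, "'"),
                 class = "hand_error_unknown_attribute")
  }
  check_entity(g, disease)
  hit <- g$attributes[g$attributes$disease == disease & g$attributes$attr == attr, ]
  if (nrow(hit) == 0) return(NA_character_)
  hit$value[[1]]
}

#' Entity and relation counts
#'
#' @param g A `knowledge_graph`.
#' @return A list with tibbles `entities` (`type`, `n`), `relations`
#'   (`rel`, `n`) and scalar totals `n_entities`, `n_relations`.
#' @export
kg_stats <- function(g) {
  stopifnot(inherits(g, "knowledge_graph"))
  ent <- dplyr::count(g$entities, .data$type, name = "n")
  rel <- dplyr::count(g$relations, .data$rel, name = "n")
  list(entities = ent, relations = rel,
       n_entities = nrow(g$entities), n_relations = nrow(g$relations))
}

#' Export the graph as Cypher CREATE statements
#'
#' Write-only convenience for users who maintain a graph database; the text
#' is never parsed back by this package.
#'
#' @param g A `knowledge_graph`.
#' @param path Output file, or `NULL` to return the lines invisibly.
#' @return Character vector of Cypher statements, invisibly.
#' @export
kg_export_cypher <- function(g, path = NULL) {
  stopifnot(inherits(g, "knowledge_graph"))
  esc <- function(x) gsub("'", "\\\\'", x)
  ent_lines <- sprintf("CREATE (:%s {name: '%s'});",
                       g$entities$type, esc(g$entities$name))
  rel_lines <- sprintf(
    "MATCH (a {name: '%s'}), (b {name: '%s'}) CREATE (a)-[:%s]->(b);",
    esc(g$relations$head), esc(g$relations$tail), g$relations$rel
  )
  lines <- c(ent_lines, rel_lines)
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}
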