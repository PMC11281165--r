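#' Aho-Corasick multi-pattern string matching
#'
#' Builds a dictionary automaton (a character trie with breadth-first failure
#' links and merged output sets) that locates every occurrence of every
#' dictionary pattern in a text in a single left-to-right pass. This is the
#' matching engine behind entity linking in the question-answering pipeline,
#' where many disease, food and drug names must be searched simultaneously.
#'
#' Matching is case-sensitive at this level; callers wanting case-insensitive
#' behaviour fold both dictionary and text (see [build_dictionary()]).
#' Patterns are treated as plain character sequences (UTF-8 safe, no regex).
#'
#' @param patterns Character vector of nonempty dictionary patterns
#'   (duplicates are collapsed).
#' @return An object of class `ac_automaton`.
#' @examples
#' ac <- ac_build(c("he", "she", "his", "hers"))
#' ac_find(ac, "ushers")
#' @export
ac_build <- function(patterns) {
  patterns <- unique(as.character(patterns))
  if (length(patterns) == 0 || any(!nzchar(patterns))) {
    rlang::abort("patterns must be a nonempty set of nonempty strings",
                 class = "hand_error_empty_dictionary")
  }
  # nodes: children (named int vectors), fail links, output pattern ids
  children <- list(integer(0))
  fail <- 1L
  output <- list(integer(0))

  for (pi in seq_along(patterns)) {
    chars <- strsplit(patterns[pi], "", fixed = TRUE)[[1]]
    node <- 1L
    for (ch in chars) {
      nxt <- children[[node]][ch]
      if (is.na(nxt)) {
        children[[length(children) + 1L]] <- integer(0)
        output[[length(output) + 1L]] <- integer(0)
        fail[length(children)] <- 1L
        nxt <- length(children)
        children[[node]][ch] <- nxt
      }
      node <- as.integer(nxt)
    }
    output[[node]] <- c(output[[node]], pi)
  }

  # BFS to set failure links and merge outputs
  queue <- as.integer(children[[1L]])
  fail[queue] <- 1L
  head <- 1L
  while (head <= length(queue)) {
    node <- queue[head]; head <- head + 1L
    kids <- children[[node]]
    for (k in seq_along(kids)) {
      ch <- names(kids)[k]
      child <- as.integer(kids[k])
      f <- fail[node]
      while (f != 1L && is.na(children[[f]][ch])) f <- fail[f]
      cand <- children[[f]][ch]
      fail[child] <- if (!is.na(cand) && as.integer(cand) != child)
        as.integer(cand) else 1L
      output[[child]] <- c(output[[child]], output[[fail[child]]])
      queue <- c(queue, child)
    }
  }

  structure(
    list(patterns = patterns, children = children, fail = fail, output = output,
         pattern_nchar = nchar(patterns)),
    class = "ac_automaton"
  )
}

#' @export
print.ac_automaton <- function(x, ...) {
  cat("<ac_automaton>: ", length(x$patterns), " patterns, ",
      length(x$children), " states\n", sep = "")
  invisible(x)
}

#' Find all dictionary occurrences in a text
#'
#' @param ac An [ac_build()] automaton.
#' @param text A single string.
#' @return A tibble with one row per occurrence (all matches, overlaps
#'   included), columns `start`, `end` (1-based inclusive character
#'   positions) and `pattern`; ordered by `start`, then longest first.
#' @export
ac_find <- function(ac, text) {
  stopifnot(inherits(ac, "ac_automaton"), is.character(text), length(text) == 1)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  hits_start <- integer(0)
  hits_end <- integer(0)
  hits_pat <- integer(0)
  node <- 1L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    repeat {
      nxt <- ac$children[[node]][ch]
      if (!is.na(nxt)) { node <- as.integer(nxt); break }
      if (node == 1L) break
      node <- ac$fail[node]
    }
    out <- ac$output[[node]]
    if (length(out) > 0) {
      lens <- ac$pattern_nchar[out]
      hits_start <- c(hits_start, i - lens + 1L)
      hits_end <- c(hits_end, rep(i, length(out)))
      hits_pat <- c(hits_pat, out)
    }
  }
  res <- tibble::tibble(start = hits_start, end = hits_end,
                        pattern = ac$patterns[hits_pat])
  dplyr::arrange(res, .data$start, dplyr::desc(.data$end - .data$start))
}

# overlap resolution shared by entity and trigger matching: keep the longest
# match, break ties leftmost, drop anything overlapping a kept match
resolve_overlaps <- function(matches) {
  if (nrow(matches) == 0) return(matches)
  ord <- order(-(matches$end - matches$start), matches$start)
  kept <- matches[0, ]
  for (i in ord) {
    m <- matches[i, ]
    if (nrow(kept) == 0 ||
        all(m$end < kept$start | m$start > kept$end)) {
      kept <- dplyr::bind_rows(kept, m)
    }
  }
  dplyr::arrange(kept, .data$start)
}
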