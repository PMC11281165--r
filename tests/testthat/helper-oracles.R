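# Independent oracles and small generators shared across tests.

# vertex angle from pairwise distances only (law of cosines): the interior
# triangle angle at v is acos((a^2+b^2-c^2)/(2ab)); the flexion angle between
# bone vectors p->v and v->d is its supplement.
loc_angle_deg <- function(p, v, d) {
  a <- sqrt(sum((v - p)^2))
  b <- sqrt(sum((d - v)^2))
  cc <- sqrt(sum((d - p)^2))
  interior <- acos(min(1, max(-1, (a^2 + b^2 - cc^2) / (2 * a * b))))
  180 - interior * 180 / pi
}

# random proper rotation matrix (Haar-ish via QR)
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a random non-degenerate 21-landmark frame
random_frame <- function(scale = 100) {
  tibble::tibble(landmark = 0:20,
                 x = stats::runif(21, -scale, scale),
                 y = stats::runif(21, -scale, scale),
                 z = stats::runif(21, -scale, scale))
}

# apply rigid motion (+ optional scaling) to a frame or sequence tibble
transform_points <- function(df, rot = diag(3), shift = c(0, 0, 0), scale = 1) {
  m <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot) * scale
  df$x <- m[, 1] + shift[1]
  df$y <- m[, 2] + shift[2]
  df$z <- m[, 3] + shift[3]
  df
}

# all occurrences (overlaps included) of each pattern by brute-force scan
naive_find_all <- function(patterns, text) {
  n <- nchar(text)
  res <- list()
  for (p in patterns) {
    l <- nchar(p)
    if (l > n) next
    for (s in seq_len(n - l + 1)) {
      if (substr(text, s, s + l - 1) == p) {
        res[[length(res) + 1]] <- tibble::tibble(start = s, end = s + l - 1L,
                                                 pattern = p)
      }
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          pattern = character(0)))
  }
  dplyr::arrange(dplyr::bind_rows(res), start, end, pattern)
}

sort_matches <- function(df) dplyr::arrange(df, start, end, pattern)

# minimal disease record factory
make_record <- function(name, ...) c(list(name = name), list(...))

fixture_graph <- function() {
  kg_build(read_disease_records(
    system.file("extdata", "hand_diseases.jsonl", package = "handassess")
  ))
}

# place landmarks of an otherwise random frame at given positions
with_landmarks <- function(frame, idx, coords) {
  for (i in seq_along(idx)) {
    frame[frame$landmark == idx[i], c("x", "y", "z")] <- as.list(coords[[i]])
  }
  frame
}
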