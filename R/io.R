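#' Read and write keypoint sequence files
#'
#' Two plain-text interchange formats are supported for 21-landmark motion
#' sequences, both in millimetres:
#'
#' * JSON: an object `{"frame_rate": <Hz or null>, "frames": [[[x,y,z] x 21],
#'   ...]}`, landmarks ordered by index 0..20.
#' * CSV: long format with columns `frame`, `landmark`, `x`, `y`, `z`.
#'
#' Round-tripping a sequence through either format preserves coordinates to
#' at least 1e-9 mm (full double precision is written).
#'
#' @param path File path.
#' @param seq A motion-sequence tibble (columns `frame`, `landmark`, `x`,
#'   `y`, `z`).
#' @param frame_rate Optional sampling rate in Hz, stored in the JSON header.
#' @return `read_keypoints_*` return a motion-sequence tibble; the frame rate
#'   (JSON only) is attached as attribute `frame_rate`. Writers return `path`
#'   invisibly.
#' @examples
#' seq <- generate_motion(hand_geometry(),
#'   trajectory_spec(ramp_profile("index_MCP", 90, 5), n_frames = 5))
#' f <- tempfile(fileext = ".json")
#' write_keypoints_json(seq, f)
#' seq2 <- read_keypoints_json(f)
#' max(abs(seq$x - seq2$x)) < 1e-9
#' @name keypoint_io
NULL

#' @rdname keypoint_io
#' @export
write_keypoints_json <- function(seq, path, frame_rate = NULL) {
  seq <- validate_sequence(seq)
  frames <- lapply(split(seq, seq$frame), function(fr) {
    fr <- dplyr::arrange(fr, .data$landmark)
    unname(as.matrix(fr[, c("x", "y", "z")]))
  })
  obj <- list(frame_rate = frame_rate, frames = unname(frames))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname keypoint_io
#' @export
read_keypoints_json <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) rlang::abort(
      paste0("cannot parse keypoint JSON '", path, "': ", conditionMessage(e)),
      class = "hand_error_parse"
    )
  )
  if (is.null(obj$frames)) {
    rlang::abort("keypoint JSON lacks a 'frames' field", class = "hand_error_parse")
  }
  frames <- obj$frames
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
  }
  seq <- purrr::imap_dfr(frames, function(m, i) {
    m <- as.matrix(m)
    if (!is.numeric(m) || nrow(m) != 21 || ncol(m) != 3) {
      rlang::abort(paste0("frame ", i, " is not a 21x3 coordinate array"),
                   class = "hand_error_parse")
    }
    tibble::tibble(frame = as.integer(i), landmark = 0:20,
                   x = m[, 1], y = m[, 2], z = m[, 3])
  })
  seq <- validate_sequence(seq)
  attr(seq, "frame_rate") <- obj$frame_rate
  seq
}

#' @rdname keypoint_io
#' @export
write_keypoints_csv <- function(seq, path) {
  seq <- validate_sequence(seq)
  out <- dplyr::mutate(
    seq[, c("frame", "landmark", "x", "y", "z")],
    dplyr::across(c("x", "y", "z"), ~ sprintf("%.17g", .x))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname keypoint_io
#' @export
read_keypoints_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = c(frame = "integer", landmark = "integer",
                                         x = "numeric", y = "numeric", z = "numeric")),
    error = function(e) rlang::abort(
      paste0("cannot parse keypoint CSV '", path, "': ", conditionMessage(e)),
      class = "hand_error_parse"
    )
  )
  validate_sequence(tibble::as_tibble(df))
}
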