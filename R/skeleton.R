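#' The 21-landmark hand skeleton
#'
#' The hand is modelled as 21 named landmarks: one wrist/carpal node plus four
#' nodes per finger (the fingertip included). Landmark indexing follows the
#' convention used by common monocular hand-pose estimators:
#'
#' | index | landmark      | index | landmark      |
#' |-------|---------------|-------|---------------|
#' | 0     | `wrist`       | 11    | `middle_dip`  |
#' | 1     | `thumb_cmc`   | 12    | `middle_tip`  |
#' | 2     | `thumb_mcp`   | 13    | `ring_mcp`    |
#' | 3     | `thumb_ip`    | 14    | `ring_pip`    |
#' | 4     | `thumb_tip`   | 15    | `ring_dip`    |
#' | 5     | `index_mcp`   | 16    | `ring_tip`    |
#' | 6     | `index_pip`   | 17    | `little_mcp`  |
#' | 7     | `index_dip`   | 18    | `little_pip`  |
#' | 8     | `index_tip`   | 19    | `little_dip`  |
#' | 9     | `middle_mcp`  | 20    | `little_tip`  |
#' | 10    | `middle_pip`  |       |               |
#'
#' Fourteen hinge joints are measured: MCP, PIP and DIP for the index, middle,
#' ring and little fingers, plus the thumb MCP and the thumb interphalangeal
#' joint. The thumb lacks a middle phalanx, so it contributes two measured
#' joints rather than three; its single interphalangeal joint is reported as
#' `thumb_DIP` (alias `thumb_IP`). Each joint is an index triplet
#' (proximal, vertex, distal); the flexion angle is measured at the vertex.
#'
#' The triangular face set used by [normal_consistency()] is the 14 joint
#' triplets themselves: every three consecutively connected landmarks form one
#' joint surface.
#'
#' @return A list of class `hand_topology` with components:
#'   \describe{
#'     \item{landmarks}{tibble with columns `index` (0-based) and `name`.}
#'     \item{joints}{tibble with columns `joint`, `joint_class`
#'       (`"MCP"`, `"PIP"` or `"DIP"`), `proximal`, `vertex`, `distal`
#'       (0-based landmark indices).}
#'     \item{edges}{tibble of skeleton bones, columns `from`, `to`.}
#'     \item{faces}{tibble of triangular joint surfaces, columns `i`, `j`, `k`.}
#'   }
#' @examples
#' topo <- hand_topology()
#' nrow(topo$landmarks) # 21
#' nrow(topo$joints)    # 14
#' @export
hand_topology <- function() {
  fingers <- c("thumb", "index", "middle", "ring", "little")
  landmark_names <- c(
    "wrist",
    paste0("thumb_", c("cmc", "mcp", "ip", "tip")),
    unlist(lapply(fingers[-1], function(f) paste0(f, "_", c("mcp", "pip", "dip", "tip"))))
  )
  landmarks <- tibble::tibble(index = 0:20, name = landmark_names)

  # thumb: two measured joints; its IP joint is reported as thumb_DIP
  joints <- tibble::tibble(
    joint = c(
      "thumb_MCP", "thumb_DIP",
      paste0(rep(fingers[-1], each = 3), "_", rep(c("MCP", "PIP", "DIP"), 4))
    ),
    joint_class = c("MCP", "DIP", rep(c("MCP", "PIP", "DIP"), 4)),
    proximal = c(1L, 2L, unlist(lapply(0:3, function(f) c(0L, 5L + 4L * f, 6L + 4L * f)))),
    vertex   = c(2L, 3L, unlist(lapply(0:3, function(f) c(5L, 6L, 7L) + 4L * f))),
    distal   = c(3L, 4L, unlist(lapply(0:3, function(f) c(6L, 7L, 8L) + 4L * f)))
  )

  chains <- lapply(0:4, function(f) {
    base <- 1L + 4L * f
    cbind(c(0L, base, base + 1L, base + 2L), c(base, base + 1L, base + 2L, base + 3L))
  })
  edge_mat <- do.call(rbind, chains)
  edges <- tibble::tibble(from = edge_mat[, 1], to = edge_mat[, 2])

  faces <- tibble::tibble(i = joints$proximal, j = joints$vertex, k = joints$distal)

  structure(
    list(landmarks = landmarks, joints = joints, edges = edges, faces = faces),
    class = "hand_topology"
  )
}

#' @export
print.hand_topology <- function(x, ...) {
  cat("<hand_topology>: 21 landmarks, ", nrow(x$joints), " measured joints, ",
      nrow(x$edges), " bones, ", nrow(x$faces), " joint surfaces\n", sep = "")
  invisible(x)
}

#' Validate a single landmark frame
#'
#' A landmark frame is a data frame with one row per landmark and columns
#' `landmark` (0-based index 0..20), `x`, `y`, `z` in millimetres. A motion
#' sequence adds a `frame` column; [validate_sequence()] checks every frame.
#'
#' @param frame A data frame with columns `landmark`, `x`, `y`, `z`.
#' @return The validated frame, invisibly unchanged, as a tibble.
#' @examples
#' pose <- generate_pose(hand_geometry())
#' validate_frame(pose)
#' @export
validate_frame <- function(frame) {
  frame <- tibble::as_tibble(frame)
  required <- c("landmark", "x", "y", "z")
  missing_cols <- setdiff(required, names(frame))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("frame is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "hand_error_bad_frame"
    )
  }
  if (nrow(frame) != 21 || !setequal(frame$landmark, 0:20)) {
    rlang::abort(
      paste0("a landmark frame must contain exactly the 21 landmarks 0..20, got ",
             nrow(frame), " rows"),
      class = "hand_error_wrong_landmark_count"
    )
  }
  coords <- as.matrix(frame[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    rlang::abort("all landmark coordinates must be finite",
                 class = "hand_error_nonfinite")
  }
  frame
}

#' Validate a motion sequence
#'
#' @param seq A data frame with columns `frame`, `landmark`, `x`, `y`, `z`;
#'   each frame must hold the full 21-landmark layout with finite coordinates.
#' @param min_frames Minimum number of frames required (default 1).
#' @return The validated sequence as a tibble, frames ordered.
#' @export
validate_sequence <- function(seq, min_frames = 1) {
  seq <- tibble::as_tibble(seq)
  required <- c("frame", "landmark", "x", "y", "z")
  missing_cols <- setdiff(required, names(seq))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("sequence is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "hand_error_bad_frame"
    )
  }
  frame_ids <- sort(unique(seq$frame))
  if (length(frame_ids) < min_frames) {
    rlang::abort(
      paste0("sequence has ", length(frame_ids), " frame(s); at least ",
             min_frames, " required"),
      class = "hand_error_too_few_frames"
    )
  }
  for (fi in frame_ids) {
    fr <- seq[seq$frame == fi, c("landmark", "x", "y", "z")]
    tryCatch(validate_frame(fr), error = function(e) {
      rlang::abort(paste0("frame ", fi, ": ", conditionMessage(e)),
                   class = class(e)[1], parent = e)
    })
  }
  dplyr::arrange(seq, .data$frame, .data$landmark)
}

# 21 x 3 coordinate matrix ordered by landmark index; rownames are indices
frame_matrix <- function(frame) {
  frame <- validate_frame(frame)
  frame <- dplyr::arrange(frame, .data$landmark)
  m <- as.matrix(frame[, c("x", "y", "z")])
  rownames(m) <- frame$landmark
  m
}
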