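#' @importFrom rlang .data
NULL

# angle at vertex v between segments v->p and v->... measured as the angle
# between bone vectors p->v and v->d: 0 deg = collinear (fully extended),
# 180 deg = folded back. Inputs are length-3 numeric vectors (mm).
vertex_angle_deg <- function(p, v, d, context = "") {
  u1 <- v - p
  u2 <- d - v
  n1 <- sqrt(sum(u1^2))
  n2 <- sqrt(sum(u2^2))
  if (n1 <= 1e-9 || n2 <= 1e-9) {
    rlang::abort(
      paste0("degenerate bone segment (norm <= 1e-9 mm)",
             if (nzchar(context)) paste0(" at ", context) else ""),
      class = "hand_error_degenerate_segment"
    )
  }
  # atan2(|u1 x u2|, u1.u2) realizes arccos of the normalized dot product
  # with full precision near 0 and 180 degrees (no clamping needed)
  cr <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  atan2(sqrt(sum(cr^2)), sum(u1 * u2)) * 180 / pi
}

#' Flexion angle of one joint in a single frame
#'
#' The angle at joint vertex Y between the proximal bone vector XY and the
#' distal bone vector YZ, `arccos((XY . YZ) / (|XY||YZ|))`, reported in
#' degrees. Under this convention 0 deg is a fully extended (collinear)
#' segment chain and the value grows monotonically with flexion up to
#' 180 deg.
#'
#' @param frame A landmark frame (see [validate_frame()]).
#' @param joint A joint name from `hand_topology()$joints$joint`
#'   (e.g. `"index_MCP"`); `"thumb_IP"` is accepted as an alias for
#'   `"thumb_DIP"`.
#' @param topo A [hand_topology()] object.
#' @return Angle in degrees, a single number in \[0, 180\].
#' @examples
#' pose <- generate_pose(hand_geometry(), c(index_MCP = 30))
#' joint_angle(pose, "index_MCP") # 30
#' @export
joint_angle <- function(frame, joint, topo = hand_topology()) {
  js <- lookup_joint(joint, topo)
  m <- frame_matrix(frame)
  vertex_angle_deg(m[as.character(js$proximal), ],
                   m[as.character(js$vertex), ],
                   m[as.character(js$distal), ],
                   context = js$joint)
}

lookup_joint <- function(joint, topo) {
  if (is.data.frame(joint)) return(joint[1, , drop = FALSE])
  name <- as.character(joint)
  if (identical(name, "thumb_IP")) name <- "thumb_DIP"
  js <- topo$joints[topo$joints$joint == name, , drop = FALSE]
  if (nrow(js) != 1) {
    rlang::abort(paste0("unknown joint '", joint, "'"),
                 class = "hand_error_unknown_joint")
  }
  js
}

#' All 14 joint angles of a single frame
#'
#' @inheritParams joint_angle
#' @return A tibble with columns `joint`, `joint_class`, `angle_deg`.
#' @export
joint_angles <- function(frame, topo = hand_topology()) {
  m <- frame_matrix(frame)
  angles <- vapply(seq_len(nrow(topo$joints)), function(r) {
    vertex_angle_deg(m[topo$joints$proximal[r] + 1, ],
                     m[topo$joints$vertex[r] + 1, ],
                     m[topo$joints$distal[r] + 1, ],
                     context = topo$joints$joint[r])
  }, numeric(1))
  tibble::tibble(
    joint = topo$joints$joint,
    joint_class = topo$joints$joint_class,
    angle_deg = angles
  )
}

#' Per-frame angle trajectories for all measured joints
#'
#' @param seq A motion-sequence tibble (columns `frame`, `landmark`,
#'   `x`, `y`, `z`).
#' @param topo A [hand_topology()] object.
#' @return A tibble of class `hand_trajectories` with columns `frame`,
#'   `joint`, `joint_class`, `angle_deg`, ordered by frame. Degenerate bone
#'   segments abort with the offending frame index in the message.
#' @examples
#' seq <- generate_motion(hand_geometry(),
#'   trajectory_spec(ramp_profile("index_MCP", 90, 10), n_frames = 10))
#' traj <- joint_trajectories(seq)
#' range_of_motion(traj)
#' @export
joint_trajectories <- function(seq, topo = hand_topology()) {
  seq <- validate_sequence(seq)
  out <- dplyr::bind_rows(lapply(split(seq, seq$frame), function(fr) {
    fi <- fr$frame[1]
    ang <- tryCatch(
      joint_angles(fr[, c("landmark", "x", "y", "z")], topo),
      error = function(e) rlang::abort(
        paste0("frame ", fi, ": ", conditionMessage(e)),
        class = class(e)[1], parent = e
      )
    )
    dplyr::mutate(ang, frame = fi, .before = 1)
  }))
  out <- dplyr::arrange(out, .data$frame, match(.data$joint, topo$joints$joint))
  class(out) <- c("hand_trajectories", class(out))
  out
}

#' Range of motion
#'
#' ROM is the range between the maximum and minimum angle observed over a
#' sequence, `max - min`, in degrees. Multi-repetition sequences use the
#' global extrema, not per-repetition ranges.
#'
#' @param x Either a numeric vector of angles (degrees) for one joint, or a
#'   trajectory tibble as returned by [joint_trajectories()].
#' @param ... Unused.
#' @return For a numeric vector, a single nonnegative number. For a
#'   trajectory tibble, a tibble with one row per joint and columns `joint`,
#'   `joint_class`, `min_deg`, `max_deg`, `rom_deg`.
#' @examples
#' range_of_motion(c(10, 50, 30)) # 40
#' @export
range_of_motion <- function(x, ...) UseMethod("range_of_motion")

#' @export
range_of_motion.numeric <- function(x, ...) {
  if (length(x) < 2) {
    rlang::abort("range of motion needs at least 2 observations",
                 class = "hand_error_too_few_frames")
  }
  max(x) - min(x)
}

#' @export
range_of_motion.data.frame <- function(x, ...) {
  if (!all(c("joint", "angle_deg") %in% names(x))) {
    rlang::abort("expected a trajectory tibble with columns joint, angle_deg",
                 class = "hand_error_bad_frame")
  }
  if (min(table(x$joint)) < 2) {
    rlang::abort("range of motion needs at least 2 frames per joint",
                 class = "hand_error_too_few_frames")
  }
  if (!"joint_class" %in% names(x)) {
    x <- dplyr::left_join(tibble::as_tibble(x),
                          hand_topology()$joints[, c("joint", "joint_class")],
                          by = "joint")
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$joint, .data$joint_class),
    min_deg = min(.data$angle_deg),
    max_deg = max(.data$angle_deg),
    rom_deg = max(.data$angle_deg) - min(.data$angle_deg),
    .groups = "drop"
  )
  dplyr::arrange(out, match(.data$joint, hand_topology()$joints$joint))
}

#' Thumb-opposition distance and test
#'
#' Opposition is operationalised as the Euclidean distance between the thumb
#' tip (landmark 4) and the little-finger MCP joint (landmark 17). Over a
#' sequence, opposition is achieved when the minimum distance falls strictly
#' below the contact margin of 30 mm (3 cm); a distance of exactly 30 mm does
#' not count as achieved.
#'
#' @param frame A landmark frame.
#' @param seq A motion-sequence tibble.
#' @param threshold_mm Contact margin in millimetres (default 30).
#' @return `opposition_distance()`: a single distance in mm.
#'   `opposition_test()`: a one-row tibble with columns `outcome`
#'   (`"achieved"` or `"not_achieved"`), `min_distance_mm`, `threshold_mm`.
#' @examples
#' seq <- preset_fist_cycle(hand_geometry())
#' opposition_test(seq)
#' @export
opposition_distance <- function(frame) {
  m <- frame_matrix(frame)
  sqrt(sum((m["4", ] - m["17", ])^2))
}

#' @rdname opposition_distance
#' @export
opposition_test <- function(seq, threshold_mm = 30) {
  stopifnot(is.numeric(threshold_mm), threshold_mm > 0)
  seq <- validate_sequence(seq, min_frames = 1)
  d <- purrr::map_dbl(split(seq, seq$frame), function(fr) {
    opposition_distance(fr[, c("landmark", "x", "y", "z")])
  })
  dmin <- min(d)
  tibble::tibble(
    outcome = ifelse(dmin < threshold_mm, "achieved", "not_achieved"),
    min_distance_mm = dmin,
    threshold_mm = threshold_mm
  )
}

#' Thumb total active range of motion
#'
#' The sum of the ranges of motion of the thumb MCP joint and the thumb
#' interphalangeal joint over a sequence. A healthy thumb exceeds 90 degrees.
#'
#' @inheritParams joint_trajectories
#' @return Total AROM in degrees.
#' @export
thumb_total_arom <- function(seq, topo = hand_topology()) {
  traj <- joint_trajectories(seq, topo)
  thumb <- dplyr::filter(traj, .data$joint %in% c("thumb_MCP", "thumb_DIP"))
  roms <- range_of_motion(thumb)
  sum(roms$rom_deg)
}

#' Surface-normal consistency between a predicted and a reference pose
#'
#' Every joint triplet (three consecutively connected landmarks) defines a
#' triangular joint surface. For each surface whose reference (ground-truth)
#' vertices are not collinear, the metric accumulates, over the triangle's
#' three edges, the absolute dot product between the normalized predicted
#' edge vector and the unit normal of the reference face:
#' \deqn{L_n = \sum_{f} \sum_{(i,j) \subset f}
#'   \left| \frac{\hat V_i - \hat V_j}{\|\hat V_i - \hat V_j\|}
#'   \cdot n_f^{gt} \right|}
#' The value is 0 exactly when every evaluated predicted edge lies in its
#' reference face plane; it is invariant to translation and uniform positive
#' scaling of the prediction. Reference faces whose vertices are collinear
#' (e.g. a fully extended finger) have no defined normal and are skipped.
#'
#' @param pred Predicted landmark frame.
#' @param gt Reference (ground-truth) landmark frame.
#' @param topo A [hand_topology()] object supplying the face set.
#' @param collinear_tol Relative tolerance under which a reference face is
#'   treated as collinear and skipped.
#' @return A one-row tibble with columns `value`, `n_faces_evaluated`,
#'   `n_faces_skipped`.
#' @examples
#' geom <- hand_geometry()
#' gt <- generate_pose(geom, c(index_MCP = 45, index_PIP = 30))
#' normal_consistency(gt, gt)$value # 0
#' @export
normal_consistency <- function(pred, gt, topo = hand_topology(),
                               collinear_tol = 1e-8) {
  mp <- frame_matrix(pred)
  mg <- frame_matrix(gt)
  total <- 0
  n_eval <- 0L
  n_skip <- 0L
  for (r in seq_len(nrow(topo$faces))) {
    idx <- c(topo$faces$i[r], topo$faces$j[r], topo$faces$k[r]) + 1
    a <- mg[idx[1], ]; b <- mg[idx[2], ]; c3 <- mg[idx[3], ]
    nvec <- c(
      (b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
      (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
      (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1])
    )
    nn <- sqrt(sum(nvec^2))
    scale_ref <- max(sqrt(sum((b - a)^2)), sqrt(sum((c3 - a)^2)))
    if (nn <= collinear_tol * scale_ref^2 || scale_ref == 0) {
      n_skip <- n_skip + 1L
      next
    }
    nvec <- nvec / nn
    for (e in list(idx[c(1, 2)], idx[c(2, 3)], idx[c(3, 1)])) {
      ev <- mp[e[1], ] - mp[e[2], ]
      en <- sqrt(sum(ev^2))
      if (en <= 1e-9) {
        rlang::abort("zero-length predicted edge in face evaluation",
                     class = "hand_error_degenerate_segment")
      }
      total <- total + abs(sum(ev / en * nvec))
    }
    n_eval <- n_eval + 1L
  }
  if (n_eval == 0L) {
    rlang::abort("no evaluable faces: all reference faces are collinear",
                 class = "hand_error_no_evaluable_faces")
  }
  tibble::tibble(value = total, n_faces_evaluated = n_eval,
                 n_faces_skipped = n_skip)
}

#' Plot joint-angle trajectories
#'
#' @param object A `hand_trajectories` tibble from [joint_trajectories()].
#' @param ... Unused.
#' @return A ggplot object, one panel per joint class.
#' @export
autoplot.hand_trajectories <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$angle_deg,
                                       colour = .data$joint)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$joint_class)) +
    ggplot2::labs(x = "frame", y = "flexion angle (deg)",
                  title = "Joint-angle trajectories") +
    ggplot2::theme_minimal()
}
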