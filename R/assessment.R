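#' Functional scoring bands for flexion-extension range of motion
#'
#' The clinical rubric grades each joint's ROM into four bands per joint
#' class, each band mapping to a score range out of 10:
#'
#' * MCP: 70-90 deg -> 7.5~10; 50-69 -> 5~7.5; 30-49 -> 2.5~5; <30 -> 0~2.5
#' * PIP: 80-100 -> 7.5~10; 60-79 -> 5~7.5; 30-59 -> 2.5~5; <30 -> 0~2.5
#' * DIP: 30-45 -> 7.5~10; 20-29 -> 5~7.5; 15-19 -> 2.5~5; <15 -> 0~2.5
#'
#' The printed bands leave unit gaps (e.g. 69 to 70); they are implemented as
#' contiguous half-open intervals so every real-valued ROM falls in exactly
#' one band, and the score is interpolated linearly from the band's lower
#' edge to its printed upper endpoint. ROM above the top band's upper
#' endpoint is clamped to the maximum score of 10.
#'
#' @return A tibble with columns `joint_class`, `rom_low`, `rom_high`,
#'   `score_low`, `score_high`; bands per class are disjoint, ordered and
#'   contiguous.
#' @examples
#' score_bands()
#' @export
score_bands <- function() {
  tibble::tribble(
    ~joint_class, ~rom_low, ~rom_high, ~score_low, ~score_high,
    "MCP", 0,  30,  0,   2.5,
    "MCP", 30, 50,  2.5, 5,
    "MCP", 50, 70,  5,   7.5,
    "MCP", 70, 90,  7.5, 10,
    "PIP", 0,  30,  0,   2.5,
    "PIP", 30, 60,  2.5, 5,
    "PIP", 60, 80,  5,   7.5,
    "PIP", 80, 100, 7.5, 10,
    "DIP", 0,  15,  0,   2.5,
    "DIP", 15, 20,  2.5, 5,
    "DIP", 20, 30,  5,   7.5,
    "DIP", 30, 45,  7.5, 10
  )
}

# normal flexion-extension ROM per joint class (degrees)
normal_ranges <- function() {
  tibble::tribble(
    ~joint_class, ~normal_low, ~normal_high,
    "MCP", 70, 90,
    "PIP", 80, 100,
    "DIP", 30, 45
  )
}

check_joint_class <- function(joint_class) {
  if (length(joint_class) != 1 || !joint_class %in% c("MCP", "PIP", "DIP")) {
    rlang::abort(paste0("unknown joint class '", joint_class,
                        "' (expected MCP, PIP or DIP)"),
                 class = "hand_error_unknown_joint_class")
  }
  joint_class
}

#' Score a joint's range of motion
#'
#' Locates the scoring band containing `rom` (see [score_bands()]) and maps
#' the ROM linearly from the band's ROM interval onto its score interval.
#' ROM above the top band scores the maximum 10 points.
#'
#' @param joint_class `"MCP"`, `"PIP"` or `"DIP"`.
#' @param rom Range of motion in degrees (vectorised, each >= 0).
#' @return Score(s) in \[0, 10\], nondecreasing in `rom`.
#' @examples
#' score_joint_rom("MCP", 90) # 10
#' score_joint_rom("MCP", 80) # 8.75
#' @export
score_joint_rom <- function(joint_class, rom) {
  check_joint_class(joint_class)
  stopifnot(is.numeric(rom), all(is.finite(rom)), all(rom >= 0))
  bands <- score_bands()
  bands <- bands[bands$joint_class == joint_class, ]
  vapply(rom, function(r) {
    if (r >= bands$rom_high[nrow(bands)]) return(bands$score_high[nrow(bands)])
    b <- bands[r >= bands$rom_low & r < bands$rom_high, ]
    b$score_low + (r - b$rom_low) / (b$rom_high - b$rom_low) *
      (b$score_high - b$score_low)
  }, numeric(1))
}

#' Score the thumb-opposition outcome
#'
#' Opposition achievable scores 10, achievable with difficulty 5, not
#' achievable 0.
#'
#' @param outcome `"achieved"`, `"hard"` or `"not_achieved"`.
#' @return Score in \{0, 5, 10\}.
#' @examples
#' score_opposition("achieved")
#' @export
score_opposition <- function(outcome) {
  scores <- c(achieved = 10, hard = 5, not_achieved = 0)
  if (length(outcome) != 1 || !outcome %in% names(scores)) {
    rlang::abort(paste0("unknown opposition outcome '", outcome, "'"),
                 class = "hand_error_unknown_outcome")
  }
  unname(scores[outcome])
}

#' Score the thumb total active range of motion
#'
#' Total thumb MCP + interphalangeal ROM above 90 degrees scores 10; a
#' measurable but smaller AROM scores 5; no measurable motion (stiffness)
#' scores 0.
#'
#' @param arom Total thumb AROM in degrees (>= 0).
#' @return Score in \{0, 5, 10\}.
#' @examples
#' score_thumb_arom(120) # 10
#' @export
score_thumb_arom <- function(arom) {
  stopifnot(is.numeric(arom), length(arom) == 1, is.finite(arom), arom >= 0)
  if (arom > 90) 10 else if (arom > 0) 5 else 0
}

#' Classify a ROM against the normal reference interval
#'
#' Normal flexion-extension ROM is 70-90 degrees for MCP joints, 80-100 for
#' PIP and 30-45 for DIP. ROM below the interval is `"reduced"`; ROM at or
#' above the lower bound is `"normal"` (hypermobility above the upper bound
#' is still classified normal but can be recognised via the
#' `above_reference` flag in [assess_sequence()] reports).
#'
#' @inheritParams score_joint_rom
#' @return `"normal"` or `"reduced"` (vectorised over `rom`).
#' @examples
#' classify_normal_range("PIP", 85) # "normal"
#' @export
classify_normal_range <- function(joint_class, rom) {
  check_joint_class(joint_class)
  stopifnot(is.numeric(rom), all(rom >= 0))
  nr <- normal_ranges()
  lo <- nr$normal_low[nr$joint_class == joint_class]
  ifelse(rom >= lo, "normal", "reduced")
}

#' Assess a full motion sequence
#'
#' Runs the complete kinematic assessment: all 14 joint-angle trajectories,
#' per-joint ROM, rubric scores and normal-range flags, the thumb-opposition
#' test, thumb total AROM, and the total score (sum of the 14 joint scores,
#' the opposition score and the thumb-AROM score).
#'
#' @param seq A motion-sequence tibble with at least 2 frames.
#' @param topo A [hand_topology()].
#' @param opposition_threshold_mm Contact margin for the opposition test
#'   (default 30 mm).
#' @param hard_threshold_mm Optional second margin: a minimum distance at or
#'   above `opposition_threshold_mm` but strictly below this value is graded
#'   `"hard"` (opposition achievable with difficulty). `NULL` (default)
#'   disables the intermediate grade.
#' @return An object of class `hand_assessment`; see [tidy.hand_assessment()]
#'   and [glance.hand_assessment()] for tabular views.
#' @examples
#' report <- assess_sequence(preset_fist_cycle(hand_geometry()))
#' glance(report)
#' @export
assess_sequence <- function(seq, topo = hand_topology(),
                            opposition_threshold_mm = 30,
                            hard_threshold_mm = NULL) {
  seq <- validate_sequence(seq, min_frames = 2)
  traj <- joint_trajectories(seq, topo)
  roms <- range_of_motion(traj)
  joints <- dplyr::mutate(
    roms,
    score = purrr::map2_dbl(.data$joint_class, .data$rom_deg, score_joint_rom),
    normal_flag = purrr::map2_chr(.data$joint_class, .data$rom_deg,
                                  classify_normal_range),
    above_reference = .data$rom_deg > normal_ranges()$normal_high[
      match(.data$joint_class, normal_ranges()$joint_class)]
  )

  opp <- opposition_test(seq, threshold_mm = opposition_threshold_mm)
  outcome <- opp$outcome
  if (!is.null(hard_threshold_mm) && outcome == "not_achieved" &&
      opp$min_distance_mm < hard_threshold_mm) {
    outcome <- "hard"
  }
  opposition <- tibble::tibble(
    outcome = outcome,
    min_distance_mm = opp$min_distance_mm,
    threshold_mm = opp$threshold_mm,
    score = score_opposition(outcome)
  )

  arom <- thumb_total_arom(seq, topo)
  thumb_arom <- tibble::tibble(value_deg = arom, score = score_thumb_arom(arom))

  structure(
    list(
      joints = joints,
      opposition = opposition,
      thumb_arom = thumb_arom,
      total_score = sum(joints$score) + opposition$score + thumb_arom$score,
      n_frames = length(unique(seq$frame)),
      trajectories = traj
    ),
    class = "hand_assessment"
  )
}

#' @export
print.hand_assessment <- function(x, ...) {
  cat("Hand function assessment (", x$n_frames, " frames)\n\n", sep = "")
  df <- as.data.frame(x$joints[, c("joint", "joint_class", "min_deg", "max_deg",
                                   "rom_deg", "score", "normal_flag")])
  df$min_deg <- round(df$min_deg, 1)
  df$max_deg <- round(df$max_deg, 1)
  df$rom_deg <- round(df$rom_deg, 1)
  df$score <- round(df$score, 2)
  print(df, row.names = FALSE)
  cat("\nThumb opposition: ", x$opposition$outcome,
      " (min distance ", round(x$opposition$min_distance_mm, 1), " mm, margin ",
      x$opposition$threshold_mm, " mm) -> score ", x$opposition$score, "\n",
      sep = "")
  cat("Thumb total AROM: ", round(x$thumb_arom$value_deg, 1),
      " deg -> score ", x$thumb_arom$score, "\n", sep = "")
  cat("Total score: ", round(x$total_score, 2), " / ",
      nrow(x$joints) * 10 + 20, "\n", sep = "")
  invisible(x)
}

#' Tidy a hand assessment into a per-component tibble
#'
#' @param x A `hand_assessment` object.
#' @param ... Unused.
#' @return One row per scored component (14 joints, opposition, thumb AROM)
#'   with columns `component`, `joint_class`, `measure`, `value`, `score`,
#'   `normal_flag`.
#' @export
tidy.hand_assessment <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      component = x$joints$joint,
      joint_class = x$joints$joint_class,
      measure = "rom_deg",
      value = x$joints$rom_deg,
      score = x$joints$score,
      normal_flag = x$joints$normal_flag
    ),
    tibble::tibble(
      component = "thumb_opposition", joint_class = NA_character_,
      measure = "min_distance_mm", value = x$opposition$min_distance_mm,
      score = x$opposition$score, normal_flag = x$opposition$outcome
    ),
    tibble::tibble(
      component = "thumb_AROM", joint_class = NA_character_,
      measure = "arom_deg", value = x$thumb_arom$value_deg,
      score = x$thumb_arom$score,
      normal_flag = ifelse(x$thumb_arom$value_deg > 90, "normal", "reduced")
    )
  )
}

#' One-row summary of a hand assessment
#'
#' @param x A `hand_assessment` object.
#' @param ... Unused.
#' @return A one-row tibble with `total_score`, `max_score`, `n_joints_normal`,
#'   `opposition_outcome`, `thumb_arom_deg`, `n_frames`.
#' @export
glance.hand_assessment <- function(x, ...) {
  tibble::tibble(
    total_score = x$total_score,
    max_score = nrow(x$joints) * 10 + 20,
    n_joints_normal = sum(x$joints$normal_flag == "normal"),
    opposition_outcome = x$opposition$outcome,
    thumb_arom_deg = x$thumb_arom$value_deg,
    n_frames = x$n_frames
  )
}

#' Plot per-component assessment scores
#'
#' @param object A `hand_assessment` object.
#' @param ... Unused.
#' @return A ggplot bar chart of component scores.
#' @export
autoplot.hand_assessment <- function(object, ...) {
  td <- tidy(object)
  td$component <- factor(td$component, levels = rev(td$component))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$score, y = .data$component,
                                   fill = .data$normal_flag)) +
    ggplot2::geom_col() +
    ggplot2::xlim(0, 10) +
    ggplot2::labs(x = "score (points)", y = NULL,
                  title = "Hand joint functional activity scores") +
    ggplot2::theme_minimal()
}

#' Serialize an assessment report
#'
#' Writes the report as JSON (full structure) and optionally a per-joint CSV
#' table with columns `joint`, `min_deg`, `max_deg`, `rom_deg`.
#'
#' @param report A `hand_assessment` object.
#' @param json_path Path for the JSON report, or `NULL` to skip.
#' @param csv_path Path for the per-joint CSV table, or `NULL` to skip.
#' @return The report, invisibly.
#' @export
write_assessment <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "hand_assessment"))
  if (!is.null(json_path)) {
    obj <- list(
      joints = report$joints,
      opposition = report$opposition,
      thumb_arom = report$thumb_arom,
      total_score = report$total_score,
      n_frames = report$n_frames
    )
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(
      as.data.frame(report$joints[, c("joint", "min_deg", "max_deg", "rom_deg")]),
      csv_path, row.names = FALSE, quote = FALSE
    )
  }
  invisible(report)
}
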