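#' Synthetic hand geometry
#'
#' Bone-segment lengths and palm layout for the forward-kinematic generator.
#' Defaults are rounded adult-hand magnitudes in millimetres; they are
#' implementation fixtures chosen for realism, not measured reference values.
#' Each finger is a chain of four segments from the wrist: for the four
#' fingers metacarpal, proximal, middle and distal phalanx; the thumb lacks a
#' middle phalanx, so its chain is wrist-to-CMC, metacarpal, proximal and
#' distal phalanx. `base_angle_deg` fans the fingers in the palm plane
#' (0 = straight ahead, negative toward the thumb side) and
#' `plane_tilt_deg` tilts a finger's flexion plane across the palm: 0 bends
#' straight toward the palm, larger values sweep the finger toward the ulnar
#' side, which lets the thumb oppose the little-finger MCP.
#'
#' @param segments Optional tibble overriding the default layout; columns
#'   `finger`, `base_angle_deg`, `plane_tilt_deg`, `l1`..`l4` (segment
#'   lengths in mm, proximal to distal).
#' @return An object of class `hand_geometry`.
#' @examples
#' hand_geometry()
#' @export
hand_geometry <- function(segments = NULL) {
  if (is.null(segments)) {
    segments <- tibble::tribble(
      ~finger,  ~base_angle_deg, ~plane_tilt_deg, ~l1, ~l2, ~l3, ~l4,
      "thumb",  -60,             75,              35,  45,  35,  30,
      "index",  -15,             0,               70,  40,  25,  22,
      "middle", 0,               0,               65,  45,  28,  23,
      "ring",   12,              0,               60,  42,  27,  23,
      "little", 25,              0,               55,  33,  20,  20
    )
  }
  segments <- tibble::as_tibble(segments)
  required <- c("finger", "base_angle_deg", "plane_tilt_deg", paste0("l", 1:4))
  if (!all(required %in% names(segments)) ||
      !setequal(segments$finger, c("thumb", "index", "middle", "ring", "little"))) {
    rlang::abort("geometry needs one row per finger with base angle, tilt and l1..l4",
                 class = "hand_error_invalid_spec")
  }
  lens <- as.matrix(segments[, paste0("l", 1:4)])
  if (!all(is.finite(lens)) || any(lens <= 0)) {
    rlang::abort("all segment lengths must be positive and finite",
                 class = "hand_error_invalid_spec")
  }
  structure(list(segments = segments), class = "hand_geometry")
}

#' @export
print.hand_geometry <- function(x, ...) {
  cat("<hand_geometry> segment lengths (mm):\n")
  print(x$segments)
  invisible(x)
}

# generator joint names: the 14 measured joints plus the thumb CMC,
# which positions the thumb but is not itself scored
generator_joints <- function() {
  c("thumb_CMC", hand_topology()$joints$joint)
}

#' Generate a single pose by forward kinematics
#'
#' Places the 21 landmarks by chaining bone vectors. Each hinge joint bends in
#' its finger's flexion plane by exactly the requested angle, so
#' [joint_angle()] recovers the programmed values; bone lengths are preserved.
#' All unspecified joints stay at 0 degrees (fully extended).
#'
#' @param geom A [hand_geometry()].
#' @param angles Named numeric vector of flexion angles in degrees, each in
#'   \[0, 180\]. Valid names are the 14 measured joints (e.g. `"index_MCP"`)
#'   plus `"thumb_CMC"`; `"thumb_IP"` is accepted for `"thumb_DIP"`.
#' @return A landmark-frame tibble (columns `landmark`, `x`, `y`, `z`).
#' @examples
#' pose <- generate_pose(hand_geometry(), c(index_MCP = 30))
#' joint_angle(pose, "index_MCP")
#' @export
generate_pose <- function(geom, angles = numeric(0)) {
  stopifnot(inherits(geom, "hand_geometry"))
  if (length(angles) > 0) {
    if (is.null(names(angles)) || any(!nzchar(names(angles)))) {
      rlang::abort("angles must be a named vector", class = "hand_error_invalid_spec")
    }
    names(angles)[names(angles) == "thumb_IP"] <- "thumb_DIP"
    unknown <- setdiff(names(angles), generator_joints())
    if (length(unknown) > 0) {
      rlang::abort(paste0("unknown joint(s): ", paste(unknown, collapse = ", ")),
                   class = "hand_error_invalid_spec")
    }
    if (any(!is.finite(angles)) || any(angles < 0) || any(angles > 180)) {
      rlang::abort("all angles must lie in [0, 180] degrees",
                   class = "hand_error_invalid_angle")
    }
  }
  ang <- stats::setNames(rep(0, length(generator_joints())), generator_joints())
  ang[names(angles)] <- angles

  coords <- matrix(0, nrow = 21, ncol = 3)
  for (r in seq_len(nrow(geom$segments))) {
    finger <- geom$segments$finger[r]
    a <- geom$segments$base_angle_deg[r] * pi / 180
    beta <- geom$segments$plane_tilt_deg[r] * pi / 180
    u <- c(sin(a), cos(a), 0)
    v <- c(u[2], -u[1], 0)                  # in-plane perpendicular, ulnar side
    w <- sin(beta) * v + cos(beta) * c(0, 0, -1)  # flexion direction
    lens <- as.numeric(geom$segments[r, paste0("l", 1:4)])
    bend <- if (finger == "thumb") {
      c(ang["thumb_CMC"], ang["thumb_MCP"], ang["thumb_DIP"])
    } else {
      ang[paste0(finger, c("_MCP", "_PIP", "_DIP"))]
    }
    phi <- cumsum(c(0, bend)) * pi / 180    # cumulative flexion per segment
    base_idx <- 1L + 4L * (r - 1L)          # first landmark of the finger chain
    pos <- c(0, 0, 0)
    for (s in 1:4) {
      pos <- pos + lens[s] * (cos(phi[s]) * u + sin(phi[s]) * w)
      coords[base_idx + s, ] <- pos
    }
  }
  # reorder rows: geometry rows are thumb..little matching landmark blocks 1-4,
  # 5-8, ... only if segments are in canonical order; enforce that order
  tibble::tibble(landmark = 0:20, x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

#' Specify a programmed joint-angle trajectory
#'
#' A trajectory is a set of per-joint breakpoints `(frame, angle_deg)` that
#' are linearly interpolated over `n_frames` frames; joints without a profile
#' stay extended. Optional isotropic Gaussian landmark noise emulates pose-
#' estimator jitter.
#'
#' @param profiles Tibble with columns `joint`, `frame`, `angle_deg` listing
#'   the breakpoints (frames outside the breakpoint range hold the nearest
#'   breakpoint value).
#' @param n_frames Number of frames to generate (>= 2).
#' @param noise_sd_mm Standard deviation of isotropic Gaussian noise added to
#'   every coordinate, in millimetres (default 0 = noise-free).
#' @param seed Integer seed; required when `noise_sd_mm > 0` so generated
#'   files are reproducible.
#' @return An object of class `trajectory_spec`.
#' @examples
#' trajectory_spec(ramp_profile("index_MCP", 90, 20), n_frames = 20)
#' @export
trajectory_spec <- function(profiles, n_frames, noise_sd_mm = 0, seed = NULL) {
  profiles <- tibble::as_tibble(profiles)
  if (!all(c("joint", "frame", "angle_deg") %in% names(profiles)) ||
      nrow(profiles) == 0) {
    rlang::abort("profiles needs columns joint, frame, angle_deg",
                 class = "hand_error_invalid_spec")
  }
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2) {
    rlang::abort("n_frames must be an integer >= 2", class = "hand_error_invalid_spec")
  }
  profiles$joint[profiles$joint == "thumb_IP"] <- "thumb_DIP"
  unknown <- setdiff(unique(profiles$joint), generator_joints())
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown joint(s): ", paste(unknown, collapse = ", ")),
                 class = "hand_error_invalid_spec")
  }
  if (any(!is.finite(profiles$angle_deg)) ||
      any(profiles$angle_deg < 0) || any(profiles$angle_deg > 180)) {
    rlang::abort("breakpoint angles must lie in [0, 180]",
                 class = "hand_error_invalid_angle")
  }
  if (!is.numeric(noise_sd_mm) || noise_sd_mm < 0) {
    rlang::abort("noise_sd_mm must be >= 0", class = "hand_error_invalid_spec")
  }
  if (noise_sd_mm > 0 && is.null(seed)) {
    rlang::abort("a seed is required when noise_sd_mm > 0",
                 class = "hand_error_invalid_spec")
  }
  profiles <- dplyr::arrange(profiles, .data$joint, .data$frame)
  structure(
    list(profiles = profiles, n_frames = n_frames,
         noise_sd_mm = noise_sd_mm, seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "trajectory_spec"
  )
}

#' @rdname trajectory_spec
#' @param joint Joint name for the ramp.
#' @param peak_deg Angle reached at the final frame.
#' @param n_frames Number of frames spanned by the ramp.
#' @param start_deg Angle at the first frame (default 0).
#' @export
ramp_profile <- function(joint, peak_deg, n_frames, start_deg = 0) {
  tibble::tibble(joint = joint, frame = c(1L, as.integer(n_frames)),
                 angle_deg = c(start_deg, peak_deg))
}

# interpolated angle matrix: n_frames x joints with programmed profiles
interpolate_profiles <- function(spec) {
  joints <- unique(spec$profiles$joint)
  sapply(joints, function(j) {
    bp <- spec$profiles[spec$profiles$joint == j, ]
    if (nrow(bp) == 1) return(rep(bp$angle_deg, spec$n_frames))
    stats::approx(bp$frame, bp$angle_deg, xout = seq_len(spec$n_frames),
                  rule = 2, ties = "ordered")$y
  })
}

#' Generate a motion sequence by forward kinematics
#'
#' Applies [generate_pose()] to the interpolated per-frame angles of a
#' [trajectory_spec()], optionally adding seeded isotropic Gaussian noise.
#' Output is deterministic given the spec (including its seed); the caller's
#' RNG state is left untouched.
#'
#' @param geom A [hand_geometry()].
#' @param spec A [trajectory_spec()].
#' @return A motion-sequence tibble (columns `frame`, `landmark`, `x`, `y`,
#'   `z`).
#' @examples
#' seq <- generate_motion(hand_geometry(),
#'   trajectory_spec(ramp_profile("index_MCP", 90, 10), n_frames = 10))
#' range_of_motion(joint_trajectories(seq))
#' @export
generate_motion <- function(geom, spec) {
  stopifnot(inherits(geom, "hand_geometry"))
  if (!inherits(spec, "trajectory_spec")) {
    rlang::abort("spec must be a trajectory_spec", class = "hand_error_invalid_spec")
  }
  ang_mat <- interpolate_profiles(spec)
  frames <- purrr::map_dfr(seq_len(spec$n_frames), function(f) {
    angles <- stats::setNames(as.numeric(ang_mat[f, ]), colnames(ang_mat))
    pose <- generate_pose(geom, angles)
    dplyr::mutate(pose, frame = f, .before = 1)
  })
  if (spec$noise_sd_mm > 0) {
    noise <- local_rng(spec$seed, function() {
      stats::rnorm(nrow(frames) * 3, sd = spec$noise_sd_mm)
    })
    frames$x <- frames$x + noise[seq_len(nrow(frames))]
    frames$y <- frames$y + noise[nrow(frames) + seq_len(nrow(frames))]
    frames$z <- frames$z + noise[2 * nrow(frames) + seq_len(nrow(frames))]
  }
  frames
}

# run fn under a private RNG stream, restoring the caller's state
local_rng <- function(seed, fn) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Preset open-palm-to-fist assessment cycle
#'
#' Emulates the standard assessment protocol: several repetitions of a
#' continuous movement from an open palm to a clenched fist. Every measured
#' joint flexes periodically from 0 to the top of its scoring band (finger
#' MCP 90, PIP 100, DIP 45 degrees; thumb CMC 45, MCP 90, IP 45), and the
#' thumb's tilted flexion plane carries its tip to within the 30 mm contact
#' margin of the little-finger MCP at each mid-cycle, so the opposition test
#' succeeds.
#'
#' Peak angles are hit exactly when `n_frames - 1` is divisible by
#' `2 * n_repetitions`; the default 121 frames satisfies this for 3 and 4
#' repetitions.
#'
#' @param geom A [hand_geometry()].
#' @param n_repetitions Number of open-to-fist repetitions (default 3).
#' @param n_frames Total frames (default 121).
#' @param noise_sd_mm,seed Optional landmark noise, as in [trajectory_spec()].
#' @return A motion-sequence tibble.
#' @examples
#' seq <- preset_fist_cycle(hand_geometry())
#' opposition_test(seq)$outcome
#' @export
preset_fist_cycle <- function(geom, n_repetitions = 3, n_frames = 121,
                              noise_sd_mm = 0, seed = NULL) {
  if (n_repetitions < 1) {
    rlang::abort("n_repetitions must be >= 1", class = "hand_error_invalid_spec")
  }
  peaks <- c(
    thumb_CMC = 45, thumb_MCP = 90, thumb_DIP = 45,
    index_MCP = 90, index_PIP = 100, index_DIP = 45,
    middle_MCP = 90, middle_PIP = 100, middle_DIP = 45,
    ring_MCP = 90, ring_PIP = 100, ring_DIP = 45,
    little_MCP = 90, little_PIP = 100, little_DIP = 45
  )
  # triangular wave breakpoints: open at rep boundaries, fist at midpoints
  rep_len <- (n_frames - 1) / n_repetitions
  bp_frames <- sort(unique(c(
    1 + rep_len * (0:n_repetitions),
    1 + rep_len * (0:(n_repetitions - 1)) + rep_len / 2
  )))
  at_peak <- !(bp_frames %in% (1 + rep_len * (0:n_repetitions)))
  profiles <- purrr::imap_dfr(peaks, function(peak, joint) {
    tibble::tibble(joint = joint, frame = bp_frames,
                   angle_deg = ifelse(at_peak, peak, 0))
  })
  spec <- trajectory_spec(profiles, n_frames = n_frames,
                          noise_sd_mm = noise_sd_mm, seed = seed)
  generate_motion(geom, spec)
}
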