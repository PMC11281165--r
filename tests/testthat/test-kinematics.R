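test_that("joint angle matches the textbook cases", {
  fr <- with_landmarks(random_frame(), c(0, 5, 6), list(
    c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)
  ))
  expect_equal(joint_angle(fr, "index_MCP"), 0) # collinear = fully extended

  fr <- with_landmarks(fr, 6, list(c(10, 10, 0)))
  expect_equal(joint_angle(fr, "index_MCP"), 90)

  fr <- with_landmarks(fr, 6, list(c(0, 1e-3, 0)))
  expect_gt(joint_angle(fr, "index_MCP"), 170) # folded back

  # degenerate bone vector
  fr <- with_landmarks(fr, 6, list(c(10, 0, 0)))
  expect_error(joint_angle(fr, "index_MCP"),
               class = "hand_error_degenerate_segment")
})

test_that("joint angle equals the law-of-cosines oracle on random poses", {
  set.seed(41)
  topo <- hand_topology()
  for (i in 1:200) {
    fr <- random_frame()
    m <- as.matrix(dplyr::arrange(fr, landmark)[, c("x", "y", "z")])
    j <- topo$joints[sample(nrow(topo$joints), 1), ]
    expect_equal(joint_angle(fr, j$joint),
                 loc_angle_deg(m[j$proximal + 1, ], m[j$vertex + 1, ],
                               m[j$distal + 1, ]),
                 tolerance = 1e-9)
  }
})

test_that("joint angle is symmetric in chain direction and rigid/scale invariant", {
  set.seed(42)
  topo <- hand_topology()
  for (i in 1:50) {
    fr <- random_frame()
    j <- topo$joints[sample(nrow(topo$joints), 1), ]
    reversed <- j
    reversed$proximal <- j$distal
    reversed$distal <- j$proximal
    expect_equal(joint_angle(fr, j), joint_angle(fr, reversed), tolerance = 1e-9)

    moved <- transform_points(fr, random_rotation(), stats::rnorm(3, sd = 50),
                              scale = stats::runif(1, 0.1, 5))
    expect_equal(joint_angle(fr, j), joint_angle(moved, j), tolerance = 1e-9)
  }
})

test_that("trajectories preserve order and propagate frame context on errors", {
  geom <- hand_geometry()
  pose <- generate_pose(geom, c(index_MCP = 40))
  one <- dplyr::mutate(pose, frame = 1, .before = 1)
  traj1 <- joint_trajectories(one)
  expect_equal(nrow(traj1), 14)

  five <- dplyr::bind_rows(lapply(1:5, function(f) dplyr::mutate(pose, frame = f)))
  traj5 <- joint_trajectories(five)
  expect_equal(unique(table(traj5$joint)), 5L)
  expect_equal(length(unique(traj5$angle_deg[traj5$joint == "index_MCP"])), 1)

  broken <- five
  broken[broken$frame == 3 & broken$landmark == 6, c("x", "y", "z")] <-
    broken[broken$frame == 3 & broken$landmark == 5, c("x", "y", "z")]
  err <- tryCatch(joint_trajectories(broken), error = identity)
  expect_s3_class(err, "hand_error_degenerate_segment")
  expect_match(conditionMessage(err), "frame 3")
})

test_that("range of motion is max minus min with the expected invariances", {
  expect_equal(range_of_motion(c(10, 50, 30)), 40)
  expect_equal(range_of_motion(rep(12.5, 6)), 0)
  expect_error(range_of_motion(5), class = "hand_error_too_few_frames")

  set.seed(43)
  vals <- stats::runif(50, 0, 150)
  sorted_oracle <- function(x) { s <- sort(x); s[length(s)] - s[1] }
  for (i in 1:20) {
    perm <- sample(vals)
    expect_equal(range_of_motion(perm), sorted_oracle(vals))
  }
  # adding a frame never decreases ROM
  rom_before <- range_of_motion(vals)
  expect_gte(range_of_motion(c(vals, stats::runif(1, 0, 150))), rom_before)
})

test_that("opposition distance and test follow the strict 30 mm margin", {
  fr <- random_frame()
  fr <- with_landmarks(fr, c(4, 17), list(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(opposition_distance(fr), 0)

  for (d in c(29, 30, 31)) {
    fr_d <- with_landmarks(fr, 4, list(c(5 + d, 5, 5)))
    expect_equal(opposition_distance(fr_d), d)
    seq <- dplyr::bind_rows(
      dplyr::mutate(fr_d, frame = 1, .before = 1),
      dplyr::mutate(fr_d, frame = 2, .before = 1)
    )
    res <- opposition_test(seq)
    expect_equal(res$min_distance_mm, d)
    expect_equal(res$outcome, if (d < 30) "achieved" else "not_achieved")
  }

  # random frame equals the sqrt-of-squared-differences oracle
  set.seed(44)
  rf <- random_frame()
  m <- as.matrix(dplyr::arrange(rf, landmark)[, c("x", "y", "z")])
  expect_equal(opposition_distance(rf), sqrt(sum((m[5, ] - m[18, ])^2)),
               tolerance = 1e-12)
})

test_that("thumb total AROM is the sum of thumb MCP and IP ranges", {
  geom <- hand_geometry()
  static <- generate_motion(geom, trajectory_spec(
    tibble::tibble(joint = "index_MCP", frame = c(1, 5), angle_deg = c(10, 60)),
    n_frames = 5
  ))
  expect_equal(thumb_total_arom(static), 0)

  sweep <- generate_motion(geom, trajectory_spec(
    dplyr::bind_rows(ramp_profile("thumb_MCP", 50, 10),
                     ramp_profile("thumb_DIP", 50, 10)),
    n_frames = 10
  ))
  expect_equal(thumb_total_arom(sweep), 100, tolerance = 1e-6)

  # definitional decomposition on an arbitrary sequence
  traj <- joint_trajectories(sweep)
  roms <- range_of_motion(traj)
  expect_equal(thumb_total_arom(sweep),
               sum(roms$rom_deg[roms$joint %in% c("thumb_MCP", "thumb_DIP")]))
})

test_that("normal consistency is zero on identity and translation, positive under perturbation", {
  geom <- hand_geometry()
  gt <- generate_pose(geom, c(
    thumb_CMC = 20, thumb_MCP = 30, thumb_DIP = 25,
    index_MCP = 40, index_PIP = 35, index_DIP = 20,
    middle_MCP = 45, middle_PIP = 30, middle_DIP = 25,
    ring_MCP = 35, ring_PIP = 40, ring_DIP = 20,
    little_MCP = 30, little_PIP = 35, little_DIP = 15
  ))
  res <- normal_consistency(gt, gt)
  expect_equal(res$value, 0, tolerance = 1e-12)
  expect_equal(res$n_faces_evaluated, 14)

  shifted <- transform_points(gt, shift = c(11, -4, 7))
  expect_equal(normal_consistency(shifted, gt)$value, 0, tolerance = 1e-12)
  scaled <- transform_points(gt, scale = 3.7)
  expect_equal(normal_consistency(scaled, gt)$value, 0, tolerance = 1e-12)
})

test_that("normal consistency matches a brute-force oracle under normal displacement", {
  geom <- hand_geometry()
  topo <- hand_topology()
  gt <- generate_pose(geom, c(index_MCP = 50, index_PIP = 40, index_DIP = 30,
                              middle_MCP = 45, middle_PIP = 35, middle_DIP = 25,
                              ring_MCP = 40, ring_PIP = 30, ring_DIP = 20,
                              little_MCP = 35, little_PIP = 25, little_DIP = 15,
                              thumb_CMC = 10, thumb_MCP = 20, thumb_DIP = 15))
  mg <- as.matrix(dplyr::arrange(gt, landmark)[, c("x", "y", "z")])

  # displace the index PIP landmark along the normal of its MCP face
  face <- topo$faces[3, ] # index MCP triplet (0, 5, 6)
  a <- mg[face$i + 1, ]; b <- mg[face$j + 1, ]; c3 <- mg[face$k + 1, ]
  nrm <- pracma::cross(b - a, c3 - a)
  nrm <- nrm / sqrt(sum(nrm^2))
  pred <- gt
  pred[pred$landmark == 6, c("x", "y", "z")] <-
    as.list(mg[7, ] + 8 * nrm)

  res <- normal_consistency(pred, gt)
  expect_gt(res$value, 0)

  # independent per-edge accumulation
  mp <- as.matrix(dplyr::arrange(pred, landmark)[, c("x", "y", "z")])
  oracle <- 0
  for (r in seq_len(nrow(topo$faces))) {
    idx <- c(topo$faces$i[r], topo$faces$j[r], topo$faces$k[r]) + 1
    nf <- pracma::cross(mg[idx[2], ] - mg[idx[1], ], mg[idx[3], ] - mg[idx[1], ])
    if (sqrt(sum(nf^2)) < 1e-6) next
    nf <- nf / sqrt(sum(nf^2))
    for (e in list(idx[c(1, 2)], idx[c(2, 3)], idx[c(3, 1)])) {
      ev <- mp[e[1], ] - mp[e[2], ]
      oracle <- oracle + abs(sum(ev / sqrt(sum(ev^2)) * nf))
    }
  }
  expect_equal(res$value, oracle, tolerance = 1e-9)
})

test_that("collinear reference faces are excluded, fully extended hand has none", {
  geom <- hand_geometry()
  # one finger flexed, the rest extended: only the two index faces with a bend
  gt <- generate_pose(geom, c(index_PIP = 45))
  pred <- transform_points(gt, shift = c(1, 2, 3))
  res <- normal_consistency(pred, gt)
  expect_lt(res$n_faces_evaluated, 14)
  expect_equal(res$n_faces_evaluated + res$n_faces_skipped, 14)

  flat <- generate_pose(geom) # all joints extended: every face collinear
  expect_error(normal_consistency(flat, flat),
               class = "hand_error_no_evaluable_faces")
})
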