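test_that("zero anthropometric offsets reproduce the source markers", {
  sim <- simulate_recording(bowing_profile("expert", seed = 2), n_cycles = 1)
  rec <- sim$recording
  jc <- estimate_joint_centers(rec, anthropometrics(0, 0, 0))
  expect_equal(
    bowkin:::center_xyz(jc, "shoulder"),
    bowkin:::marker_xyz(rec, "acromion")
  )
  expect_equal(
    bowkin:::center_xyz(jc, "elbow"),
    bowkin:::marker_xyz(rec, "elbow_lat")
  )
  expect_equal(
    bowkin:::center_xyz(jc, "finger"),
    bowkin:::marker_xyz(rec, "hand_mcp1")
  )
})

test_that("elbow centre offsets half the elbow width along the flexion axis", {
  sim <- simulate_recording(bowing_profile("expert", noise_sd = 0,
    dropout_rate = 0), n_cycles = 1)
  rec <- sim$recording
  jc <- estimate_joint_centers(rec, anthropometrics(0, 60, 0))
  el_marker <- bowkin:::marker_xyz(rec, "elbow_lat")
  el_center <- bowkin:::center_xyz(jc, "elbow")
  d <- sqrt(rowSums((el_center - el_marker)^2))
  expect_equal(d, rep(30, length(d)), tolerance = 1e-9)
  # displacement is perpendicular to both adjacent segments
  sh <- bowkin:::center_xyz(jc, "shoulder")
  wr <- bowkin:::marker_xyz(rec, "wrist")
  off <- el_center - el_marker
  expect_lt(max(abs(rowSums(off * (sh - el_marker)))), 1e-6 * 30 * 300)
  expect_lt(max(abs(rowSums(off * (wr - el_marker)))), 1e-6 * 30 * 300)
})

test_that("a missing anthropometric entry is a named hard error", {
  sim <- simulate_recording(bowing_profile("expert"), n_cycles = 1,
    subject_id = "SUBJ7")
  a <- anthropometrics()
  a$elbow_width_mm <- NULL
  expect_error(
    estimate_joint_centers(sim$recording, a),
    "elbow_width_mm.*SUBJ7"
  )
})

test_that("the cello frame transform is an isometry and undoes rigid motion", {
  sim <- simulate_recording(
    bowing_profile("expert", noise_sd = 0, dropout_rate = 0),
    n_cycles = 1
  )
  rec <- sim$recording
  cf <- to_cello_frame(rec)

  # identity when the scene is already cello-aligned
  cf2 <- to_cello_frame(cf)
  expect_equal(cf2$x, cf$x, tolerance = 1e-9)
  expect_equal(cf2$y, cf$y, tolerance = 1e-9)

  # rigid motion of the whole scene cancels
  set.seed(4)
  R <- random_rotation()
  moved <- transform_rec(rec, R, rnorm(3, 0, 500))
  cf3 <- to_cello_frame(moved)
  expect_equal(cf3$x, cf$x, tolerance = 1e-6)
  expect_equal(cf3$z, cf$z, tolerance = 1e-6)

  # pairwise distances preserved
  p1 <- bowkin:::marker_xyz(rec, "bow_tip") -
    bowkin:::marker_xyz(rec, "wrist")
  p2 <- bowkin:::marker_xyz(cf, "bow_tip") -
    bowkin:::marker_xyz(cf, "wrist")
  expect_equal(sqrt(rowSums(p1^2)), sqrt(rowSums(p2^2)), tolerance = 1e-9)
})

test_that("joint angles read 0 for a straight chain and 90 for a right angle", {
  n <- 5
  mk <- function(p) matrix(p, n, 3, byrow = TRUE)
  straight <- joint_angles_from_points(
    shoulder = mk(c(0, 0, 0)), elbow = mk(c(300, 0, 0)),
    wrist = mk(c(560, 0, 0)), hand = mk(c(650, 0, 0)),
    finger2 = mk(c(710, 0, 0)), trunk_up = c(0, 0, 1)
  )
  expect_equal(straight$elbow_flexion, rep(0, n), tolerance = 1e-9)
  expect_equal(straight$wrist_flexion, rep(0, n), tolerance = 1e-9)
  expect_equal(straight$finger_flexion, rep(0, n), tolerance = 1e-9)
  expect_equal(straight$shoulder_abduction, rep(90, n), tolerance = 1e-9)

  bent <- joint_angles_from_points(
    shoulder = mk(c(0, 0, 0)), elbow = mk(c(300, 0, 0)),
    wrist = mk(c(300, 260, 0)), hand = mk(c(300, 350, 0)),
    finger2 = mk(c(300, 410, 0)), trunk_up = c(0, 0, 1)
  )
  expect_equal(bent$elbow_flexion, rep(90, n), tolerance = 1e-9)
})

test_that("a prescribed planar elbow angle is recovered exactly", {
  # forward kinematics of a planar 2-link chain with a known elbow angle
  fs <- 60
  t <- (0:299) / fs
  theta <- 40 + 20 * sin(2 * pi * t / 1.5) # elbow flexion, degrees
  l1 <- 300
  l2 <- 260
  shoulder <- cbind(0, 0, 0)[rep(1, length(t)), ]
  elbow <- cbind(l1, 0, 0)[rep(1, length(t)), ]
  phi <- (180 - theta) * pi / 180 # interior angle at the elbow
  wrist <- cbind(l1 + l2 * cos(pi - phi), l2 * sin(pi - phi), 0)
  hand <- wrist + 90 * cbind(cos(pi - phi), sin(pi - phi), 0)
  fing <- hand + 60 * cbind(cos(pi - phi), sin(pi - phi), 0)
  ang <- joint_angles_from_points(shoulder, elbow, wrist, hand, fing,
    trunk_up = c(0, 0, 1)
  )
  expect_equal(ang$elbow_flexion, theta, tolerance = 1e-6)
  expect_equal(ang$wrist_flexion, rep(0, length(t)), tolerance = 1e-6)
})

test_that("joint angles are invariant under rigid transforms of the scene", {
  sim <- simulate_recording(
    bowing_profile("novice", noise_sd = 0, dropout_rate = 0, seed = 6),
    n_cycles = 1
  )
  rec <- sim$recording
  jc <- estimate_joint_centers(rec, anthropometrics(0, 0, 0))
  ang <- compute_joint_angles(rec, jc)
  set.seed(99)
  for (i in 1:3) {
    moved <- transform_rec(rec, random_rotation(), rnorm(3, 0, 300))
    jc2 <- estimate_joint_centers(moved, anthropometrics(0, 0, 0))
    ang2 <- compute_joint_angles(moved, jc2)
    expect_equal(ang2$angle_deg, ang$angle_deg, tolerance = 1e-6)
  }
})
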