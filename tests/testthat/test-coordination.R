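test_that("marker acceleration magnitude matches closed forms", {
  fs <- 60
  t <- (0:239) / fs
  # uniform linear motion: zero acceleration
  p_lin <- cbind(10 * t, 5 * t, -2 * t)
  a_lin <- marker_acc_norm(p_lin, fs)
  expect_equal(a_lin[3:238], rep(0, 236), tolerance = 1e-9)

  # quadratic: |x''| = 1 exactly at interior samples
  p_quad <- cbind(t^2 / 2, 0, 0)
  a_quad <- marker_acc_norm(p_quad, fs)
  expect_equal(a_quad[3:238], rep(1, 236), tolerance = 1e-9)

  # circular motion radius r, rate w: centripetal acceleration r w^2
  r <- 500
  w <- 2 * pi * 0.8
  p_circ <- cbind(r * cos(w * t), r * sin(w * t), 0)
  a_circ <- marker_acc_norm(p_circ, fs)
  expect_equal(
    a_circ[3:238], rep(r * w^2, 236),
    tolerance = 0.02 * r * w^2
  )
})

test_that("shoulder normalization divides by the instantaneous distance", {
  n <- 10
  acc <- rep(2000, n)
  p <- matrix(c(1000, 0, 0), n, 3, byrow = TRUE)
  sh <- matrix(0, n, 3)
  expect_equal(normalize_to_shoulder(acc, p, sh), rep(2, n))
  # doubling the lever arm halves the normalized value
  expect_equal(normalize_to_shoulder(acc, 2 * p, sh), rep(1, n))
  # sub-millimetre distances are masked
  tiny <- matrix(c(0.5, 0, 0), n, 3, byrow = TRUE)
  expect_true(all(is.na(normalize_to_shoulder(acc, tiny, sh))))
})

test_that("rigid rotation about the shoulder equalizes normalized profiles", {
  fs <- 120
  t <- (0:479) / fs
  phi <- 0.3 * sin(2 * pi * t / 1.5) # whole-chain rotation angle
  sh <- matrix(0, length(t), 3)
  norm_of <- function(r) {
    p <- cbind(r * cos(phi), r * sin(phi), 0)
    normalize_to_shoulder(marker_acc_norm(p, fs), p, sh)
  }
  n1 <- norm_of(300)
  n2 <- norm_of(700)
  interior <- 3:(length(t) - 2)
  expect_equal(n1[interior], n2[interior], tolerance = 0.01)
})

test_that("markers sharing one pulse have identical peak times", {
  sim <- simulate_recording(
    bowing_profile("expert",
      noise_sd = 0, dropout_rate = 0,
      proximal_distal_lag = 0, peak_time_offset_sd = 0
    ),
    n_cycles = 3
  )
  an <- suppressWarnings(analyze_recording(sim$recording))
  spread <- dplyr::summarise(
    dplyr::group_by(an$marker_features, .data$event),
    spread = diff(range(.data$t_peak_acc))
  )
  expect_lt(max(spread$spread), 2 / 60)
})

test_that("generator timing lags are recovered from marker features", {
  lag <- 0.030
  sim <- simulate_recording(
    bowing_profile("expert",
      noise_sd = 0, dropout_rate = 0,
      proximal_distal_lag = lag, peak_time_offset_sd = 0
    ),
    n_cycles = 4
  )
  an <- suppressWarnings(analyze_recording(sim$recording))
  means <- dplyr::summarise(
    dplyr::group_by(an$marker_features, .data$marker),
    t_peak = mean(.data$t_peak_acc)
  )
  steps <- diff(means$t_peak[match(
    c("elbow", "wrist", "hand", "bow"),
    means$marker
  )])
  expect_lt(max(abs(steps - lag)), 1 / 60)
})

test_that("amplitude gain makes normalized amplitude grow along the chain", {
  sim <- simulate_recording(
    bowing_profile("expert",
      noise_sd = 0, dropout_rate = 0,
      proximal_distal_amp_gain = 2.0
    ),
    n_cycles = 3
  )
  an <- suppressWarnings(analyze_recording(sim$recording))
  means <- dplyr::summarise(
    dplyr::group_by(an$marker_features, .data$marker),
    a = mean(.data$a_at_rev)
  )
  a <- means$a[match(c("elbow", "wrist", "hand", "bow"), means$marker)]
  expect_true(all(diff(a) > 0))
})

test_that("joint reversal timing handles aligned, lagged and monotone angles", {
  fs <- 60
  t <- (0:299) / fs
  mk_angles <- function(values) {
    joints <- c("shoulder", "elbow", "wrist", "finger")
    out <- purrr::map_dfr(joints, function(j) {
      tibble::tibble(
        frame = seq_along(t), time = t, joint = j,
        angle_deg = values, present = TRUE
      )
    })
    out$joint <- factor(out$joint, levels = joints)
    structure(out, fs = fs)
  }
  events <- tibble::tibble(event = 1L, t_rev = 1.875, direction = "up_down")

  # angle peaking exactly at the bow reversal: relative time 0
  aligned <- mk_angles(30 + 10 * sin(2 * pi * t / 1.5))
  jr <- joint_reversal_time(events, aligned)
  expect_equal(jr$t_joint_rev, rep(0, 4), tolerance = 1 / fs)

  # angle peaking 40 ms earlier: recovered with sub-sample precision
  lagged <- mk_angles(30 + 10 * sin(2 * pi * (t + 0.040) / 1.5))
  jr2 <- joint_reversal_time(events, lagged)
  expect_equal(jr2$t_joint_rev, rep(-0.040, 4), tolerance = 1 / fs)

  # monotone angle: no reversal in the window
  mono <- mk_angles(10 + 5 * t)
  jr3 <- joint_reversal_time(events, mono)
  expect_true(all(is.na(jr3$t_joint_rev)))

  # polarity: a down_up event needs a minus-to-plus angular velocity change
  events_du <- tibble::tibble(event = 1L, t_rev = 1.875,
    direction = "down_up")
  jr4 <- joint_reversal_time(events_du, aligned)
  # nearest qualifying crossing is the angle minimum 0.75 s away - outside
  expect_true(all(is.na(jr4$t_joint_rev)))
})
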