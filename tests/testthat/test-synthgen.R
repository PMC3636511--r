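test_that("profile validation enforces the stated invariants", {
  expect_error(bowing_profile("expert", tempo_bpm = 0), "tempo")
  expect_error(bowing_profile("expert", stroke_amplitude = -1), "amplitude")
  expect_error(bowing_profile("novice", n_accel_peaks = 0), "n_accel_peaks")
  expect_error(bowing_profile("expert", dropout_rate = 1), "dropout")
  expect_error(
    bowing_profile("expert", reversal_duration_50 = 0.8),
    "stroke period"
  )
  expect_error(chain_geometry(seg_forearm = 0), "positive")
  expect_error(
    chain_geometry(cello_body = c(575, 0, 0)),
    "non-collinear"
  )
})

test_that("an expert trial has one reversal per stroke, 0.75 s apart", {
  sim <- simulate_recording(
    bowing_profile("expert", noise_sd = 0, dropout_rate = 0),
    n_cycles = 2, fs = 60
  )
  rev <- sim$truth$reversals
  expect_equal(nrow(rev), 4)
  expect_equal(diff(rev$t_rev), rep(0.75, 3), tolerance = 1e-6)
  expect_equal(rev$direction, c("up_down", "down_up", "up_down", "down_up"))
  expect_true(all(rev$n_peaks == 1))
})

test_that("no dropout means an all-true mask; dropout thins it", {
  sim <- simulate_recording(bowing_profile("expert", dropout_rate = 0),
    n_cycles = 1
  )
  expect_true(all(sim$recording$present))
  sim2 <- simulate_recording(
    bowing_profile("expert", dropout_rate = 0.05, seed = 2),
    n_cycles = 1
  )
  expect_lt(mean(sim2$recording$present), 1)
  expect_gt(mean(sim2$recording$present), 0.9)
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_recording(bowing_profile("novice", seed = 42), n_cycles = 1)
  b <- simulate_recording(bowing_profile("novice", seed = 42), n_cycles = 1)
  expect_identical(a$recording$x, b$recording$x)
  expect_identical(a$truth$reversals, b$truth$reversals)
  c_ <- simulate_recording(bowing_profile("novice", seed = 43), n_cycles = 1)
  expect_false(identical(a$recording$x, c_$recording$x))
})

test_that("the proximal-distal lag appears exactly in the marker ground truth", {
  lag <- 0.030
  sim <- simulate_recording(
    bowing_profile("expert",
      noise_sd = 0, dropout_rate = 0,
      proximal_distal_lag = lag, peak_time_offset_sd = 0
    ),
    n_cycles = 2
  )
  mf <- sim$truth$marker_features
  wide <- tidyr::pivot_wider(mf[, c("event", "marker", "t_peak")],
    names_from = "marker", values_from = "t_peak"
  )
  expect_equal(wide$hand - wide$bow, rep(-lag, nrow(wide)), tolerance = 1e-9)
  expect_equal(wide$wrist - wide$hand, rep(-lag, nrow(wide)), tolerance = 1e-9)
  expect_equal(wide$elbow - wide$wrist, rep(-lag, nrow(wide)),
    tolerance = 1e-9
  )
})

test_that("ground-truth reversal directions strictly alternate", {
  for (preset in c("expert", "novice")) {
    sim <- simulate_recording(bowing_profile(preset, seed = 7), n_cycles = 3)
    d <- sim$truth$reversals$direction
    expect_true(all(d[-1] != d[-length(d)]))
  }
})

test_that("longer requested switch times produce longer measured switch times", {
  measured <- vapply(c(0.10, 0.18, 0.30), function(dur) {
    sim <- simulate_recording(
      bowing_profile("expert",
        noise_sd = 0, dropout_rate = 0,
        reversal_duration_50 = dur, peak_time_offset_mean = 0,
        peak_time_offset_sd = 0
      ),
      n_cycles = 3
    )
    an <- suppressWarnings(analyze_recording(sim$recording))
    mean(an$bow_metrics$dur_50)
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
  # at short switch times the local-peak reference equals the stroke
  # plateau, so the requested and measured durations coincide
  expect_lt(abs(measured[1] - 0.10), 0.02)
})

test_that("noise-free pipelines recover every ground truth within a sample", {
  dt <- 1 / 60
  for (preset in c("expert", "novice")) {
    sim <- simulate_recording(
      bowing_profile(preset, noise_sd = 0, dropout_rate = 0, seed = 8),
      n_cycles = 6
    )
    an <- suppressWarnings(analyze_recording(sim$recording))
    tr <- sim$truth

    # every analyzed reversal matches a true reversal within one sample
    ev_map <- vapply(an$events$t_rev, function(t) {
      which.min(abs(tr$reversals$t_rev - t))
    }, integer(1))
    expect_lt(max(abs(an$events$t_rev - tr$reversals$t_rev[ev_map])), dt)
    expect_equal(
      an$events$direction, tr$reversals$direction[ev_map]
    )

    # per-marker peak-acceleration times within one sample
    mf <- dplyr::inner_join(
      dplyr::mutate(an$marker_features,
        truth_event = ev_map[match(event, an$events$event)],
        marker = as.character(marker)
      ),
      dplyr::mutate(tr$marker_features, marker = as.character(marker)),
      by = c("truth_event" = "event", "marker"), suffix = c("", ".t")
    )
    expect_lt(max(abs(mf$t_peak_acc - mf$t_peak)), dt)
    expect_lt(max(abs(mf$a_at_rev - mf$a_at_rev.t) / mf$a_at_rev.t), 0.05)

    # joint reversal times within one sample
    jt <- dplyr::mutate(tr$joint_reversals,
      joint = sub("_(abduction|flexion)$", "", joint)
    )
    jf <- dplyr::mutate(an$joint_features,
      joint = as.character(joint),
      truth_event = ev_map[match(event, an$events$event)]
    )
    jj <- dplyr::inner_join(jt, jf, by = c("event" = "truth_event", "joint"))
    expect_false(any(is.na(jj$t_joint_rev.y)))
    expect_lt(max(abs(jj$t_joint_rev.y - jj$t_joint_rev.x)), dt)
  }
})

test_that("cohorts are reproducible and carry the design labels", {
  co <- simulate_cohort(
    n_experts = 2, n_novices = 2, n_cycles = 1,
    base_seed = 5
  )
  expect_length(co, 4)
  s <- cohort_subjects(co)
  expect_equal(s$group, c("expert", "expert", "novice", "novice"))
  expect_true(all(s$lab %in% c("A", "B")))
  co2 <- simulate_cohort(
    n_experts = 2, n_novices = 2, n_cycles = 1,
    base_seed = 5
  )
  expect_identical(co[[1]]$recording$x, co2[[1]]$recording$x)
  expect_identical(co[[4]]$truth$reversals, co2[[4]]$truth$reversals)
})
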