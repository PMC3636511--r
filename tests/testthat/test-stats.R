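test_that("lab-effect removal matches hand arithmetic and is minimal", {
  df <- data.frame(
    lab = rep(c("A", "B"), each = 3),
    y = c(1, 2, 3, 11, 12, 13)
  )
  out <- remove_lab_effect(df, y)
  expect_equal(out$y, c(6, 7, 8, 6, 7, 8))

  # single lab / equal lab means: unchanged
  one <- data.frame(lab = "A", y = c(4, 5, 6))
  expect_equal(remove_lab_effect(one, y)$y, c(4, 5, 6))
  eq <- data.frame(lab = rep(c("A", "B"), each = 2), y = c(1, 3, 0, 4))
  expect_equal(remove_lab_effect(eq, y)$y, eq$y)

  # within-lab contrasts exactly preserved; grand mean preserved
  set.seed(2)
  big <- data.frame(
    lab = sample(c("A", "B"), 30, replace = TRUE),
    y = rnorm(30)
  )
  adj <- remove_lab_effect(big, y)
  for (l in c("A", "B")) {
    expect_equal(
      diff(adj$y[big$lab == l]), diff(big$y[big$lab == l]),
      tolerance = 1e-12
    )
  }
  expect_equal(mean(adj$y), mean(big$y), tolerance = 1e-12)
})

test_that("the mixed ANOVA matches explicit sums-of-squares arithmetic", {
  set.seed(31)
  for (rep_ in 1:5) {
    n <- 8
    d <- expand.grid(
      subject_id = sprintf("S%02d", 1:(2 * n)),
      direction = c("up_down", "down_up"),
      stringsAsFactors = FALSE
    )
    d$group <- ifelse(as.integer(sub("S", "", d$subject_id)) <= n,
      "expert", "novice"
    )
    d$y <- rnorm(nrow(d)) +
      2 * (d$group == "expert") + 0.5 * (d$direction == "up_down")
    fit <- rm_anova(d, "y")
    tab <- tidy(fit)
    oracle <- mixed_anova_oracle(d$y, d$group, d$subject_id, d$direction)
    expect_equal(
      tab$statistic[tab$effect == "group"], oracle$F_group,
      tolerance = 1e-6
    )
    expect_equal(
      tab$statistic[tab$effect == "direction"], oracle$F_within,
      tolerance = 1e-6
    )
    expect_equal(
      tab$statistic[tab$effect == "group:direction"], oracle$F_inter,
      tolerance = 1e-6
    )
    expect_equal(tab$df_den[tab$effect == "group"], 2 * (n - 1))
  }
})

test_that("identical cells give vanishing F statistics", {
  d <- expand.grid(
    subject_id = sprintf("S%02d", 1:8),
    direction = c("up_down", "down_up"), stringsAsFactors = FALSE
  )
  d$group <- rep(c("expert", "novice"), each = 2)[
    as.integer(sub("S", "", d$subject_id)) %% 4 + 1
  ]
  d$group <- ifelse(as.integer(sub("S", "", d$subject_id)) <= 4,
    "expert", "novice"
  )
  set.seed(9)
  d$y <- 5 + rnorm(nrow(d), 0, 1e-8) # essentially constant
  tab <- tidy(rm_anova(d, "y"))
  expect_true(all(tab$statistic < 10)) # no spurious structure
  expect_true(all(tab$p.value > 1e-4))
})

test_that("a realistic group effect on switch time is reliably detected", {
  set.seed(77)
  hits <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    d <- expand.grid(
      subject_id = sprintf("S%02d", 1:20),
      direction = c("up_down", "down_up"), stringsAsFactors = FALSE
    )
    d$group <- ifelse(as.integer(sub("S", "", d$subject_id)) <= 10,
      "expert", "novice"
    )
    subj_eff <- rnorm(20, 0, 0.03)
    names(subj_eff) <- sprintf("S%02d", 1:20)
    d$y <- ifelse(d$group == "expert", 0.15, 0.30) +
      subj_eff[d$subject_id] + rnorm(nrow(d), 0, 0.02)
    tab <- tidy(rm_anova(d, "y"))
    if (tab$p.value[tab$effect == "group"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("polynomial trends decompose an ordered factor correctly", {
  base <- expand.grid(
    subject_id = sprintf("S%02d", 1:10),
    direction = c("up_down", "down_up"),
    marker = c("elbow", "wrist", "hand", "bow"),
    stringsAsFactors = FALSE
  )
  base$marker <- factor(base$marker,
    levels = c("elbow", "wrist", "hand", "bow")
  )
  set.seed(13)
  noise <- rnorm(nrow(base), 0, 0.05)

  # exactly linear cell means: the linear contrast carries all the SS
  d1 <- base
  d1$y <- as.integer(d1$marker) + noise
  fit1 <- bowkin:::within_anova(d1, "y",
    within = c("direction", "marker"),
    ordered = "marker"
  )
  tr1 <- trend_contrasts(fit1, "marker")
  m1 <- tr1[tr1$effect == "marker", ]
  f_marker <- tidy(fit1)$statistic[tidy(fit1)$effect == "marker"]
  expect_equal(unname(m1$statistic[m1$trend == "linear"]), 3 * f_marker,
    tolerance = 1e-3
  )
  expect_gt(m1$p.value[m1$trend == "quadratic"], 0.01)
  expect_gt(m1$p.value[m1$trend == "cubic"], 0.01)

  # alternating means [1, -1, 1, -1]: SS splits linear:cubic = 1:4,
  # from the normalized contrast values (-4/sqrt(20)) and (-8/sqrt(20))
  d2 <- base
  d2$y <- c(1, -1, 1, -1)[as.integer(d2$marker)] + noise
  fit2 <- bowkin:::within_anova(d2, "y",
    within = c("direction", "marker"),
    ordered = "marker"
  )
  tr2 <- trend_contrasts(fit2, "marker")
  m2 <- tr2[tr2$effect == "marker", ]
  expect_equal(
    unname(m2$statistic[m2$trend == "cubic"] /
      m2$statistic[m2$trend == "linear"]), 4,
    tolerance = 0.2
  )
  expect_gt(m2$p.value[m2$trend == "quadratic"], 0.01)

  expect_error(trend_contrasts(fit2, "direction"), "ordered")
})

test_that("Holm adjustment matches step-down enumeration and is monotone", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p, "holm"), c(0.03, 0.04, 0.04))
  expect_equal(p.adjust(p, "holm"), holm_oracle(p))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- p.adjust(p, "holm")
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p)) # order-preserving
  }
})

test_that("post-hoc t-tests pair correctly and adjust within the family", {
  set.seed(8)
  d <- expand.grid(
    subject_id = sprintf("S%02d", 1:12),
    marker = c("elbow", "wrist", "hand"), stringsAsFactors = FALSE
  )
  d$y <- rnorm(nrow(d)) + c(0, 0.5, 2)[match(d$marker, c(
    "elbow", "wrist",
    "hand"
  ))]
  ph <- posthoc_t(d, "y", "marker")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p.adjusted, p.adjust(ph$p.value, "holm"))
  # a single comparison is unadjusted
  ph2 <- posthoc_t(d[d$marker != "hand", ], "y", "marker")
  expect_equal(ph2$p.adjusted, ph2$p.value)
  # cross-check one comparison against t.test directly
  x <- d$y[d$marker == "elbow"]
  y <- d$y[d$marker == "wrist"]
  tt <- t.test(x, y, paired = TRUE)
  row <- ph[ph$level1 == "elbow" & ph$level2 == "wrist", ]
  expect_equal(row$statistic, unname(tt$statistic))
  expect_equal(row$p.value, tt$p.value)
})

test_that("one-sample tests against zero behave at the boundaries", {
  set.seed(4)
  strong <- -1 + rnorm(10, 0, 0.01)
  res <- one_sample_vs_zero(strong)
  expect_lt(res$p.value, 0.01)
  expect_lt(res$estimate, 0)

  # closed-form check at n = 2: t = mean / (sd / sqrt(2))
  res2 <- one_sample_vs_zero(c(1, 3))
  expect_equal(res2$statistic, 2 / (sqrt(2) / sqrt(2)), tolerance = 1e-12)
  expect_equal(res2$df, 1)

  expect_warning(res3 <- one_sample_vs_zero(c(2, 2, 2)), "zero variance")
  expect_equal(res3$p.value, 0)
  expect_warning(res4 <- one_sample_vs_zero(c(0, 0, 0)), "zero variance")
  expect_equal(res4$p.value, 1)
  expect_error(one_sample_vs_zero(c(1)), "n >= 2")
})

test_that("one-sample p-values are calibrated under the null", {
  set.seed(55)
  n_rep <- 2000
  rej <- 0
  for (i in seq_len(n_rep)) {
    if (one_sample_vs_zero(rnorm(10))$p.value < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.02)
})
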