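# fixtures built in code: small recordings and kinematics series

# a bow_kinematics tibble from a velocity series (acceleration by
# three-point differentiation, as in the pipeline)
make_bk <- function(v, fs) {
  tb <- tibble::tibble(
    frame = seq_along(v),
    time = (seq_along(v) - 1) / fs,
    velocity = v,
    acceleration = three_point_diff(v, fs),
    present = !is.na(v)
  )
  structure(tb, fs = fs, class = c("bow_kinematics", class(tb)))
}

# a full recording in which the bow markers follow a prescribed tip
# trajectory and everything else is static in an arm-like layout
make_bow_rec <- function(tip_xyz, fs, mid_offset = c(0, 490, 0)) {
  n <- nrow(tip_xyz)
  anchors <- chain_geometry()$anchors
  long <- purrr::map_dfr(rownames(anchors), function(m) {
    p <- if (m == "bow_tip") {
      tip_xyz
    } else if (m == "bow_mid") {
      sweep(tip_xyz, 2, mid_offset, "-") # axis tip - mid == +mid_offset
    } else {
      matrix(anchors[m, ], n, 3, byrow = TRUE)
    }
    tibble::tibble(
      frame = seq_len(n), marker = m,
      x = p[, 1], y = p[, 2], z = p[, 3], present = TRUE
    )
  })
  bow_recording(long, fs = fs, subject_id = "FIX", group = "expert",
    lab = "A")
}

# random rotation matrix
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid transform to a recording
transform_rec <- function(rec, R, tvec) {
  parts <- bowkin:::rec_split(rec)
  for (m in parts$markers) {
    parts$pos[[m]] <- sweep(parts$pos[[m]] %*% t(R), 2, tvec, "+")
  }
  bowkin:::rec_rebuild(rec, parts$pos, parts$present)
}

# quadrature amplitude of a sinusoid at frequency f in series y
sine_amplitude <- function(y, t, f) {
  s <- sin(2 * pi * f * t)
  c_ <- cos(2 * pi * f * t)
  2 * sqrt(mean(y * s)^2 + mean(y * c_)^2)
}

# brute-force oracle for the peak-count rule: enumerate every pairwise
# separated subset of candidate maxima (in one dimension, pairwise
# separation equals consecutive separation in time order, so a depth-first
# enumeration over time-ordered candidates visits exactly the valid
# subsets), pick the amplitude-lexicographically maximal one, then apply
# the 50% threshold. Independent of the greedy implementation.
brute_force_peaks <- function(a_abs, t, peak_frac = 0.5, min_sep = 0.1) {
  n <- length(a_abs)
  interior <- 2:(n - 1)
  cand <- interior[a_abs[interior] > a_abs[interior - 1] &
    a_abs[interior] > a_abs[interior + 1]]
  gmax <- max(a_abs)
  if (length(cand) == 0) {
    return(1L)
  }
  cand <- cand[order(t[cand])]
  m <- length(cand)
  best_key <- NULL
  best_set <- integer(0)
  dfs <- function(pos, chosen) {
    if (pos > m) {
      key <- sort(a_abs[chosen], decreasing = TRUE)
      if (is.null(best_key) || lex_greater(key, best_key)) {
        best_key <<- key
        best_set <<- chosen
      }
      return(invisible())
    }
    i <- cand[pos]
    ok <- length(chosen) == 0 ||
      (t[i] - t[chosen[length(chosen)]]) >= min_sep - 1e-12
    if (ok) dfs(pos + 1, c(chosen, i))
    dfs(pos + 1, chosen)
  }
  dfs(1, integer(0))
  max(1L, sum(a_abs[best_set] > peak_frac * gmax))
}

lex_greater <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) {
    for (i in seq_len(k)) {
      if (a[i] > b[i]) {
        return(TRUE)
      }
      if (a[i] < b[i]) {
        return(FALSE)
      }
    }
  }
  length(a) > length(b)
}

# independent mixed-ANOVA oracle for a balanced 2 (between) x 2 (within)
# design: explicit sums-of-squares arithmetic
mixed_anova_oracle <- function(y, group, subject, within) {
  M <- mean(y)
  gl <- unique(group)
  wl <- unique(within)
  n <- length(unique(subject[group == gl[1]]))
  Mg <- tapply(y, group, mean)
  Mw <- tapply(y, within, mean)
  Ms <- tapply(y, subject, mean)
  Mgw <- tapply(y, list(group, within), mean)
  sub_group <- tapply(group, subject, function(g) g[1])

  ss_group <- 2 * n * sum((Mg - M)^2)
  ss_sub <- 2 * sum((Ms - Mg[sub_group])^2)
  ss_w <- 2 * n * sum((Mw - M)^2)
  ss_gw <- n * sum(sweep(
    sweep(Mgw - M, 1, Mg - M), 2, Mw - M
  )^2)
  fitted <- Mgw[cbind(group, within)] + Ms[subject] - Mg[group]
  ss_err <- sum((y - fitted)^2)
  df_sub <- 2 * (n - 1)
  list(
    F_group = (ss_group / 1) / (ss_sub / df_sub),
    F_within = (ss_w / 1) / (ss_err / df_sub),
    F_inter = (ss_gw / 1) / (ss_err / df_sub),
    df = c(1, df_sub)
  )
}

# Holm step-down adjustment by direct enumeration
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}
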