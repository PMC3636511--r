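# Analytic bow-motion synthesis.
#
# Each bow reversal is realised as one or more Gaussian acceleration pulses
# (optionally skewed: different left/right widths). Velocity and position
# then have closed forms in erf, so ground-truth reversal times (velocity
# zero crossings) and pulse peak times are available to numerical precision
# rather than at grid resolution.

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfinv_ <- function(y) stats::qnorm((y + 1) / 2) / sqrt(2)

# unit-amplitude skewed Gaussian pulse: widths sl (left of c), sr (right)
pulse_acc1 <- function(t, c, sl, sr) {
  u <- t - c
  s <- ifelse(u < 0, sl, sr)
  exp(-u^2 / (2 * s^2))
}

# cumulative integral of pulse_acc1 from -Inf
pulse_cum1 <- function(t, c, sl, sr) {
  u <- t - c
  k <- sqrt(pi / 2)
  ifelse(
    u < 0,
    k * sl * (1 + erf_(u / (sqrt(2) * sl))),
    k * (sl + sr * erf_(u / (sqrt(2) * sr)))
  )
}

# integral of pulse_cum1 from -Inf (used for closed-form position)
pulse_J1 <- function(t, c, sl, sr) {
  u <- t - c
  k <- sqrt(pi / 2)
  left <- k * sl * (u * (1 + erf_(u / (sqrt(2) * sl))) +
    sl * sqrt(2 / pi) * exp(-u^2 / (2 * sl^2)))
  right <- sl^2 + k * (sl * u +
    sr * (u * erf_(u / (sqrt(2) * sr)) +
      sr * sqrt(2 / pi) * (exp(-u^2 / (2 * sr^2)) - 1)))
  ifelse(u < 0, left, right)
}

# inverse of the unit pulse's cumulative area fraction (frac in (0,1))
pulse_cum_inv1 <- function(frac, sl, sr) {
  tot <- sl + sr
  if (frac <= sl / tot) {
    sqrt(2) * sl * erfinv_(frac * tot / sl - 1)
  } else {
    sqrt(2) * sr * erfinv_((frac * tot - sl) / sr)
  }
}

# +-50% switch duration and reversal shift of a unit-sigma pulse, skew g
skew_dur50_unit <- function(g) {
  pulse_cum_inv1(0.75, 1 - g, 1 + g) - pulse_cum_inv1(0.25, 1 - g, 1 + g)
}
skew_revshift_unit <- function(g) pulse_cum_inv1(0.5, 1 - g, 1 + g)

# solve the skew that puts the acceleration peak `ratio` switch-durations
# before the velocity zero crossing (ratio = offset / dur50, negative =
# peak first)
solve_skew <- function(ratio) {
  f <- function(g) -skew_revshift_unit(g) / skew_dur50_unit(g) - ratio
  lim <- 0.92
  ratio_min <- -skew_revshift_unit(lim) / skew_dur50_unit(lim)
  ratio_max <- -skew_revshift_unit(-lim) / skew_dur50_unit(-lim)
  ratio <- min(max(ratio, ratio_min), ratio_max)
  if (abs(ratio) < 1e-12) {
    return(0)
  }
  uniroot(function(g) {
    -skew_revshift_unit(g) / skew_dur50_unit(g) - ratio
  }, c(-lim, lim), tol = 1e-12)$root
}

# measured -50% -> +50% switch duration of a symmetric n-pulse group with
# side weight 0.7 (unit velocity change), used to calibrate the group
multi_group_dur50 <- function(n_pk, delta, sig) {
  centres <- (seq_len(n_pk) - (n_pk + 1) / 2) * delta
  w <- rep(0.7, n_pk)
  w[ceiling(n_pk / 2)] <- 1
  area <- sqrt(2 * pi) * sig * sum(w)
  vfun <- function(t) {
    v <- -area / 2
    for (j in seq_len(n_pk)) {
      v <- v + w[j] * pulse_cum1(t, centres[j], sig, sig)
    }
    v
  }
  span <- (n_pk - 1) / 2 * delta + 6 * sig
  lo <- uniroot(function(t) vfun(t) + area / 4, c(-span, span),
    tol = 1e-10)$root
  hi <- uniroot(function(t) vfun(t) - area / 4, c(-span, span),
    tol = 1e-10)$root
  hi - lo
}

# build the pulse table and analytic motion functions for one trial
make_bow_motion <- function(profile, n_cycles) {
  T_stroke <- 60 / profile$tempo_bpm
  n_strokes <- 2L * n_cycles
  A <- profile$stroke_amplitude
  V <- A / T_stroke
  dur50 <- profile$reversal_duration_50
  n_pk <- profile$n_accel_peaks
  bell <- profile$velocity_shape == "bell_shaped"

  pulses <- list()
  events <- list()
  for (k in seq_len(n_strokes)) {
    t_k <- k * T_stroke
    sgn <- (-1)^k # first stroke is a down-bow (positive velocity)
    o_k <- rnorm(1, profile$peak_time_offset_mean, profile$peak_time_offset_sd)
    if (n_pk == 1) {
      g <- solve_skew(o_k / dur50)
      sig <- dur50 / skew_dur50_unit(g)
      sl <- sig * (1 - g)
      sr <- sig * (1 + g)
      centre <- t_k - sig * skew_revshift_unit(g)
      P <- 2 * V / (sqrt(pi / 2) * (sl + sr))
      tab <- tibble::tibble(
        event = k, center = centre, P = P, sl = sl, sr = sr, sign = sgn,
        main = TRUE
      )
    } else {
      delta <- max(0.12, dur50 / 2)
      sig <- min(dur50 / 6, delta / 3)
      if (bell) sig <- min(sig * 1.25, delta / 2.8)
      # calibrate the pulse group by exact time dilation so the measured
      # -50% -> +50% switch time of the group equals the requested value
      scale_k <- dur50 / multi_group_dur50(n_pk, delta, sig)
      delta <- delta * scale_k
      sig <- min(sig * scale_k, delta / 2.8)
      centres <- t_k + (seq_len(n_pk) - (n_pk + 1) / 2) * delta
      main_j <- which.min(abs(centres - (t_k + o_k)))
      w <- rep(0.7, n_pk)
      w[main_j] <- 1
      P <- 2 * V / (sqrt(2 * pi) * sig * sum(w))
      tab <- tibble::tibble(
        event = k, center = centres, P = P * w, sl = sig, sr = sig,
        sign = sgn, main = seq_len(n_pk) == main_j
      )
    }
    pulses[[k]] <- tab
    # sgn < 0: velocity drops from + (down-bow) to - (up-bow): "up_down"
    # under the signed-velocity labelling convention
    events[[k]] <- tibble::tibble(
      event = k, t_nominal = t_k,
      direction = if (sgn < 0) "up_down" else "down_up"
    )
  }
  pulses <- dplyr::bind_rows(pulses)
  events <- dplyr::bind_rows(events)

  acc <- function(t) {
    out <- numeric(length(t))
    for (i in seq_len(nrow(pulses))) {
      out <- out + pulses$sign[i] * pulses$P[i] *
        pulse_acc1(t, pulses$center[i], pulses$sl[i], pulses$sr[i])
    }
    out
  }
  vel <- function(t) {
    out <- rep(V, length(t))
    for (i in seq_len(nrow(pulses))) {
      out <- out + pulses$sign[i] * pulses$P[i] *
        pulse_cum1(t, pulses$center[i], pulses$sl[i], pulses$sr[i])
    }
    out
  }
  pos <- function(t) {
    out <- V * t
    for (i in seq_len(nrow(pulses))) {
      out <- out + pulses$sign[i] * pulses$P[i] *
        (pulse_J1(t, pulses$center[i], pulses$sl[i], pulses$sr[i]) -
          pulse_J1(0, pulses$center[i], pulses$sl[i], pulses$sr[i]))
    }
    out
  }

  # exact reversal and peak times per event
  half <- 0.45 * T_stroke
  events$t_rev <- vapply(events$event, function(k) {
    uniroot(vel, c(k * T_stroke - half, k * T_stroke + half), tol = 1e-10)$root
  }, numeric(1))
  main_centres <- pulses$center[pulses$main]
  span <- if (n_pk == 1) {
    max(pulses$sl, pulses$sr)
  } else {
    max(0.12, dur50 / 2) / 2
  }
  pk <- t(vapply(seq_len(nrow(events)), function(i) {
    opt <- optimize(function(t) abs(acc(t)),
      lower = main_centres[i] - span, upper = main_centres[i] + span,
      maximum = TRUE, tol = 1e-10
    )
    c(opt$maximum, opt$objective)
  }, numeric(2)))
  events$t_peak <- pk[, 1] - events$t_rev
  events$a_peak <- pk[, 2]
  events$a_at_rev <- abs(acc(events$t_rev))
  events$n_peaks <- n_pk

  list(
    events = events, pulses = pulses, acc = acc, vel = vel, pos = pos,
    T_stroke = T_stroke, n_strokes = n_strokes, V = V, A = A,
    duration = n_strokes * T_stroke + 0.5 * T_stroke
  )
}
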