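# Acceleration peak counting.
#
# Candidates are strict interior local maxima of the magnitude profile
# within the reversal window. The >=`min_sep` separation is enforced
# greedily in descending amplitude order (with distinct amplitudes this is
# exactly the amplitude-lexicographically maximal pairwise-separated
# subset), and the >50%-of-global-maximum threshold is applied last.
count_accel_peaks <- function(a_abs, t, peak_frac = 0.5, min_sep = 0.1) {
  n <- length(a_abs)
  if (n < 3 || all(is.na(a_abs))) {
    return(NA_integer_)
  }
  interior <- 2:(n - 1)
  cand <- interior[a_abs[interior] > a_abs[interior - 1] &
    a_abs[interior] > a_abs[interior + 1]]
  gmax <- max(a_abs, na.rm = TRUE)
  # the window's global maximum is always a peak, even when it sits on the
  # window edge with no interior-maximum shape
  if (length(cand) == 0) {
    return(1L)
  }
  ord <- cand[order(-a_abs[cand], t[cand])]
  kept <- numeric(0)
  kept_amp <- numeric(0)
  for (i in ord) {
    if (all(abs(t[i] - kept) >= min_sep - 1e-12)) {
      kept <- c(kept, t[i])
      kept_amp <- c(kept_amp, a_abs[i])
    }
  }
  max(1L, sum(kept_amp > peak_frac * gmax))
}

# last upward crossing of `level` before index set / first after, by linear
# interpolation on (t, y); returns NA when no crossing exists
interp_crossings <- function(t, y, level) {
  dy <- y - level
  idx <- which(dy[-length(dy)] * dy[-1] < 0 | dy[-length(dy)] == 0)
  if (length(idx) == 0 && length(dy) > 0 && dy[length(dy)] == 0) {
    idx <- length(dy) - 1
  }
  vapply(idx, function(i) {
    if (dy[i] == 0) {
      return(t[i])
    }
    t[i] + (t[i + 1] - t[i]) * dy[i] / (dy[i] - dy[i + 1])
  }, numeric(1))
}

#' Bow-level dependent variables of one or more reversals
#'
#' For every retained event, kinematic data are time-locked to the reversal
#' in a +-`window` s window (realised inclusively: all samples within
#' `window` plus half a sample period). Within the window:
#'
#' * the acceleration sign is oriented per event so the reversal impulse is
#'   positive (the mean acceleration over +-50 ms around the reversal is
#'   made positive), letting up-down and down-up reversals share one
#'   definition;
#' * `a_peak` is the maximum oriented acceleration and `t_peak_acc` its
#'   time relative to the reversal;
#' * `a_at_rev` is the oriented acceleration at the reversal time
#'   (linearly interpolated);
#' * `dur_50` / `dur_10` are the times taken to switch between -f and +f of
#'   the local peak velocities (f = 0.5 / 0.1), where the reference peaks
#'   are the extreme velocities within the pre- and post-reversal
#'   half-windows: the last crossing of -f|v_peak_pre| before and the first
#'   crossing of +f|v_peak_post| after the reversal;
#' * `n_peaks` counts local maxima of the acceleration magnitude above 50%
#'   of the window maximum, at least `peak_sep` s apart.
#'
#' Events whose window is truncated by the recording edge or touches masked
#' samples are dropped (column `ok = FALSE`).
#'
#' @param events Retained events ([select_reversals()] output).
#' @param bk The matching [bow_kinematics()].
#' @param window Half-width of the reversal window, s.
#' @param dur_fracs Velocity fractions for the switch durations.
#' @param peak_frac,peak_sep Peak-counting threshold (fraction of window
#'   maximum) and minimum separation (s).
#' @return A `bow_reversal_metrics` tibble, one row per event: `event`,
#'   `t_rev`, `direction`, `t_peak_acc`, `a_peak`, `a_at_rev`, `dur_50`,
#'   `dur_10`, `n_peaks`, `ok`.
#' @export
reversal_metrics <- function(events, bk, window = 0.375,
                             dur_fracs = c(0.1, 0.5),
                             peak_frac = 0.5, peak_sep = 0.1) {
  fs <- rec_fs(bk)
  half_dt <- 0.5 / fs
  t <- bk$time
  v <- bk$velocity
  a <- bk$acceleration

  one <- function(t_rev, direction) {
    na_row <- tibble::tibble(
      t_peak_acc = NA_real_, a_peak = NA_real_, a_at_rev = NA_real_,
      dur_50 = NA_real_, dur_10 = NA_real_, n_peaks = NA_integer_,
      ok = FALSE
    )
    idx <- which(abs(t - t_rev) <= window + half_dt)
    if (length(idx) == 0) {
      return(na_row)
    }
    if (t[min(idx)] > t_rev - window + half_dt ||
      t[max(idx)] < t_rev + window - half_dt) {
      return(na_row) # truncated by the recording edge
    }
    if (any(is.na(a[idx])) || any(is.na(v[idx]))) {
      return(na_row)
    }
    tw <- t[idx]
    vw <- v[idx]
    aw <- a[idx]

    near <- abs(tw - t_rev) <= 0.05 + half_dt
    orient <- sign(mean(aw[near]))
    if (is.na(orient) || orient == 0) orient <- 1
    ao <- orient * aw
    # the signed velocity oriented so the pre-reversal side is negative
    vo <- if (direction == "up_down") -vw else vw

    ipk <- which.max(ao)
    a_peak <- ao[ipk]
    t_peak_acc <- tw[ipk] - t_rev
    a_at_rev <- approx(tw, ao, xout = t_rev)$y

    # the reversal itself is a known zero of the velocity; closing each
    # half-window with it lets threshold crossings that fall between the
    # last sample and the reversal be interpolated rather than lost
    pre <- c(vo[tw < t_rev], 0)
    tpre <- c(tw[tw < t_rev], t_rev)
    post <- c(0, vo[tw > t_rev])
    tpost <- c(t_rev, tw[tw > t_rev])
    v_pre <- max(abs(pre))
    v_post <- max(abs(post))
    durs <- vapply(dur_fracs, function(f) {
      lo <- interp_crossings(tpre, pre, -f * v_pre)
      hi <- interp_crossings(tpost, post, f * v_post)
      lo <- lo[lo < t_rev]
      hi <- hi[hi > t_rev]
      if (length(lo) == 0 || length(hi) == 0) {
        return(NA_real_)
      }
      min(hi) - max(lo)
    }, numeric(1))

    tibble::tibble(
      t_peak_acc = t_peak_acc, a_peak = a_peak, a_at_rev = a_at_rev,
      dur_50 = durs[match(0.5, dur_fracs)],
      dur_10 = durs[match(0.1, dur_fracs)],
      n_peaks = count_accel_peaks(abs(aw), tw, peak_frac, peak_sep),
      ok = TRUE
    )
  }

  res <- purrr::map2_dfr(events$t_rev, events$direction, one)
  out <- dplyr::bind_cols(
    events[, c("event", "t_rev", "direction")], res
  )
  n_drop <- sum(!out$ok)
  if (n_drop > 0) {
    warn(sprintf(
      "reversal_metrics: dropped %d event(s) with truncated or masked windows",
      n_drop
    ))
  }
  structure(out, fs = fs, class = c("bow_reversal_metrics", class(out)))
}

#' Aggregate bow-level metrics per subject and direction
#'
#' Means over retained events per subject x direction cell for every
#' metric, plus the across-event SD of the peak-acceleration time (the
#' timing-variability dependent variable). Cells with a single event have
#' no SD and are flagged (`ok = FALSE`); downstream ANOVAs exclude them
#' with a warning.
#'
#' @param metrics A `bow_reversal_metrics` (rows with `ok = FALSE` are
#'   ignored).
#' @param meta One-row metadata tibble ([rec_meta()]) or a data frame with
#'   `subject_id`, `group`, `lab`.
#' @return Tibble with one row per subject x direction: metric means,
#'   `t_peak_acc_sd`, `n_events`, `ok`.
#' @export
aggregate_bow_metrics <- function(metrics, meta) {
  dat <- dplyr::filter(metrics, .data$ok)
  out <- dplyr::summarise(
    dplyr::group_by(dat, .data$direction),
    t_peak_acc_sd = sd(.data$t_peak_acc),
    t_peak_acc = mean(.data$t_peak_acc),
    a_peak = mean(.data$a_peak),
    a_at_rev = mean(.data$a_at_rev),
    dur_50 = mean(.data$dur_50, na.rm = TRUE),
    dur_10 = mean(.data$dur_10, na.rm = TRUE),
    n_peaks = mean(.data$n_peaks),
    n_events = dplyr::n(),
    .groups = "drop"
  )
  out$ok <- out$n_events >= 2
  dplyr::bind_cols(
    meta[rep(1, nrow(out)), c("subject_id", "group", "lab")],
    out
  )
}
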