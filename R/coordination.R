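#' Acceleration magnitude of a point trajectory
#'
#' Twice-applied three-point differentiation of each coordinate followed by
#' the Euclidean vector norm. Two differentiations cost two samples at each
#' segment boundary, so at least 5 contiguous present samples are needed for
#' any output.
#'
#' @param p An n x 3 position matrix (mm), `NA` marking absent samples.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of acceleration magnitudes, mm/s^2.
#' @export
marker_acc_norm <- function(p, fs) {
  vel <- apply(p, 2, three_point_diff, fs = fs)
  acc <- apply(vel, 2, three_point_diff, fs = fs)
  sqrt(rowSums(acc^2))
}

#' Normalize acceleration to the shoulder
#'
#' Divides an acceleration-magnitude series by the distance between the
#' marker and the right shoulder joint centre, yielding an
#' angular-acceleration-like quantity (1/s^2) that is comparable along the
#' kinematic chain: under a rigid rotation about the shoulder every point
#' of the chain has the same normalized value. By default the instantaneous
#' per-sample distance is used; `distance = "window_mean"` uses the mean
#' distance over the present samples instead.
#'
#' @param acc_norm Acceleration magnitudes, mm/s^2.
#' @param p Marker positions, n x 3 (mm).
#' @param shoulder Shoulder-centre positions, n x 3 (mm).
#' @param distance `"instantaneous"` or `"window_mean"`.
#' @param min_dist Distances below this (mm) mask the sample.
#' @return Normalized acceleration series, 1/s^2.
#' @export
normalize_to_shoulder <- function(acc_norm, p, shoulder,
                                  distance = c("instantaneous", "window_mean"),
                                  min_dist = 1) {
  distance <- match.arg(distance)
  d <- sqrt(rowSums((p - shoulder)^2))
  if (distance == "window_mean") {
    d <- rep(mean(d, na.rm = TRUE), length(d))
  }
  d[!is.na(d) & d < min_dist] <- NA_real_
  acc_norm / d
}

# normalized acceleration series for the four chain markers
# (elbow, wrist, hand = joint centres; bow = proximal bow marker)
chain_acc_series <- function(rec, jc, distance = "instantaneous") {
  fs <- rec_fs(rec)
  shoulder <- center_xyz(jc, "shoulder")
  src <- list(
    elbow = center_xyz(jc, "elbow"),
    wrist = center_xyz(jc, "wrist"),
    hand = center_xyz(jc, "finger"),
    bow = marker_xyz(rec, "bow_mid")
  )
  rows <- rec$marker == "bow_mid"
  time <- rec$time[rows]
  out <- purrr::imap_dfr(src, function(p, m) {
    acc <- marker_acc_norm(p, fs)
    tibble::tibble(
      time = time, marker = m,
      acc_norm = normalize_to_shoulder(acc, p, shoulder,
        distance = distance
      )
    )
  })
  out$marker <- factor(out$marker, levels = c("elbow", "wrist", "hand", "bow"))
  structure(out, fs = fs, class = c("bow_chain_acc", class(out)))
}

#' Per-marker reversal features along the kinematic chain
#'
#' For each retained reversal and each chain marker (elbow, wrist and hand
#' joint centres and the proximal bow marker, ordered proximal to distal),
#' extracts from the shoulder-normalized acceleration magnitude within the
#' +-`window` s event window: the time of peak acceleration relative to the
#' reversal, and the (interpolated) normalized amplitude at the reversal
#' time. A marker whose window contains masked samples yields `NA`s for
#' that event.
#'
#' @param events Retained events ([select_reversals()] output).
#' @param rec The preprocessed `bow_recording`.
#' @param jc Matching [estimate_joint_centers()].
#' @param window Half-width of the event window, s.
#' @param distance Passed to [normalize_to_shoulder()].
#' @return Tibble: `event`, `direction`, `marker` (ordered factor),
#'   `chain_pos` (1-4), `t_peak_acc`, `a_at_rev` (1/s^2).
#' @export
marker_reversal_features <- function(events, rec, jc, window = 0.375,
                                     distance = "instantaneous") {
  series <- chain_acc_series(rec, jc, distance = distance)
  fs <- rec_fs(rec)
  half_dt <- 0.5 / fs
  out <- purrr::map_dfr(levels(series$marker), function(m) {
    s <- series[series$marker == m, ]
    purrr::map2_dfr(events$t_rev, events$direction, function(t_rev, dirn) {
      idx <- which(abs(s$time - t_rev) <= window + half_dt)
      acc <- s$acc_norm[idx]
      tt <- s$time[idx]
      if (length(idx) == 0 || any(is.na(acc)) ||
        tt[1] > t_rev - window + half_dt ||
        tt[length(tt)] < t_rev + window - half_dt) {
        return(tibble::tibble(
          t_rev = t_rev, direction = dirn, marker = m,
          t_peak_acc = NA_real_, a_at_rev = NA_real_
        ))
      }
      ipk <- which.max(acc)
      tibble::tibble(
        t_rev = t_rev, direction = dirn, marker = m,
        t_peak_acc = tt[ipk] - t_rev,
        a_at_rev = approx(tt, acc, xout = t_rev)$y
      )
    })
  })
  out$marker <- factor(out$marker, levels = levels(series$marker))
  out$chain_pos <- as.integer(out$marker)
  out <- dplyr::left_join(
    out, events[, c("t_rev", "event")],
    by = "t_rev"
  )
  out[, c(
    "event", "direction", "marker", "chain_pos", "t_peak_acc",
    "a_at_rev"
  )]
}

#' Joint reversal times relative to the bow reversal
#'
#' The time, relative to the bow reversal, at which each joint angle
#' reverses: for up-down bow reversals the angular velocity changes from
#' positive to negative (flexion to extension; abduction to adduction for
#' the shoulder), and vice versa for down-up reversals. The search is
#' restricted to the +-`window` s event window; among multiple qualifying
#' sign changes the one nearest the bow reversal is taken, with sub-sample
#' interpolation of the crossing. Events without a qualifying sign change
#' yield `NA`.
#'
#' @param events Retained events.
#' @param angles [compute_joint_angles()] output.
#' @param window Half-width of the search window, s.
#' @return Tibble: `event`, `direction`, `joint` (ordered factor,
#'   proximal to distal), `chain_pos`, `t_joint_rev` (s, negative = joint
#'   reverses before the bow).
#' @export
joint_reversal_time <- function(events, angles, window = 0.375) {
  fs <- rec_fs(angles)
  half_dt <- 0.5 / fs
  joints <- levels(angles$joint)
  out <- purrr::map_dfr(joints, function(j) {
    s <- angles[angles$joint == j, ]
    omega <- three_point_diff(
      ifelse(s$present, s$angle_deg, NA_real_), fs
    )
    tt <- s$time
    purrr::map2_dfr(events$t_rev, events$direction, function(t_rev, dirn) {
      idx <- which(abs(tt - t_rev) <= window + half_dt)
      om <- omega[idx]
      tw <- tt[idx]
      res <- NA_real_
      if (length(idx) >= 2) {
        want <- if (dirn == "up_down") -1 else 1
        # sign changes between consecutive non-zero samples; exact zeros
        # (e.g. a perfectly symmetric extremum) mark the crossing
        # themselves, a run of zeros its midpoint
        nz <- which(!is.na(om) & om != 0)
        t_cross <- numeric(0)
        if (length(nz) >= 2) {
          for (kk in seq_len(length(nz) - 1)) {
            i1 <- nz[kk]
            i2 <- nz[kk + 1]
            if (sign(om[i1]) != sign(om[i2]) && sign(om[i2]) == want &&
              !anyNA(om[i1:i2])) {
              t_cross <- c(t_cross, if (i2 == i1 + 1) {
                tw[i1] + (tw[i2] - tw[i1]) * om[i1] / (om[i1] - om[i2])
              } else {
                (tw[i1 + 1] + tw[i2 - 1]) / 2
              })
            }
          }
        }
        if (length(t_cross) > 0) {
          res <- t_cross[which.min(abs(t_cross - t_rev))] - t_rev
        }
      }
      tibble::tibble(
        t_rev = t_rev, direction = dirn, joint = j, t_joint_rev = res
      )
    })
  })
  out$joint <- factor(out$joint, levels = joints)
  out$chain_pos <- as.integer(out$joint)
  out <- dplyr::left_join(out, events[, c("t_rev", "event")], by = "t_rev")
  out[, c("event", "direction", "joint", "chain_pos", "t_joint_rev")]
}
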