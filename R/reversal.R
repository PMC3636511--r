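#' Detect bow-direction reversals
#'
#' Reversals are zero crossings of the signed bowing velocity. The crossing
#' time is sub-sample, linearly interpolated between the two straddling
#' samples; an exact-zero sample counts as the crossing point, and a run of
#' zeros contributes its midpoint. Crossings are only scored between
#' adjacent present samples (a crossing hidden inside a masked gap is not
#' invented). Direction labels follow the signed-velocity convention
#' (positive = down-bow): `up_down` when velocity goes + to -, `down_up`
#' when it goes - to +.
#'
#' @param bk A [bow_kinematics()] tibble.
#' @return A `bow_reversals` tibble: `event`, `t_rev` (s), `direction`.
#' @export
detect_reversals <- function(bk) {
  v <- bk$velocity
  t <- bk$time
  n <- length(v)
  events <- list()
  i <- 1
  while (i < n) {
    if (is.na(v[i])) {
      i <- i + 1
      next
    }
    if (v[i] == 0) {
      # run of exact zeros: midpoint is the crossing if the signs flip
      j <- i
      while (j < n && !is.na(v[j + 1]) && v[j + 1] == 0) j <- j + 1
      prev <- if (i > 1 && !is.na(v[i - 1])) v[i - 1] else NA_real_
      nxt <- if (j < n && !is.na(v[j + 1])) v[j + 1] else NA_real_
      if (!is.na(prev) && !is.na(nxt) && prev * nxt < 0) {
        events[[length(events) + 1]] <- list(
          t_rev = (t[i] + t[j]) / 2,
          direction = if (prev > 0) "up_down" else "down_up"
        )
      }
      i <- j + 1
      next
    }
    if (!is.na(v[i + 1]) && v[i + 1] != 0 && v[i] * v[i + 1] < 0) {
      frac <- v[i] / (v[i] - v[i + 1])
      events[[length(events) + 1]] <- list(
        t_rev = t[i] + frac * (t[i + 1] - t[i]),
        direction = if (v[i] > 0) "up_down" else "down_up"
      )
    }
    i <- i + 1
  }
  out <- if (length(events) == 0) {
    tibble::tibble(
      event = integer(), t_rev = numeric(),
      direction = character()
    )
  } else {
    tibble::tibble(
      event = seq_along(events),
      t_rev = vapply(events, `[[`, numeric(1), "t_rev"),
      direction = vapply(events, `[[`, character(1), "direction")
    )
  }
  structure(out,
    fs = rec_fs(bk),
    class = c("bow_reversals", class(out))
  )
}

#' Score bowing movements and flag analyzable reversals
#'
#' A movement is the interval between two consecutive reversals. It is
#' valid iff its duration lies within `[min_dur, max_dur]` (the instructed
#' stroke takes 0.75 s) *and* it contains no masked sample of the bow
#' kinematics or of any analysed joint angle. A reversal is analyzable iff
#' both flanking movements are valid; the first and last reversal of a
#' trial have only one flanking movement and are never analyzable.
#'
#' @param events [detect_reversals()] output.
#' @param bk The matching [bow_kinematics()].
#' @param angles Optional [compute_joint_angles()] output included in the
#'   missing-data rule.
#' @param min_dur,max_dur Validity bounds on movement duration, s.
#' @return The events tibble with logical columns `prev_valid`,
#'   `next_valid`, `analyzable`; the per-movement table (with exclusion
#'   reasons) is attached as attribute `movements`.
#' @export
segment_movements <- function(events, bk, angles = NULL,
                              min_dur = 0.5, max_dur = 1.0) {
  n_ev <- nrow(events)
  if (n_ev < 2) {
    events$prev_valid <- rep(FALSE, n_ev)
    events$next_valid <- rep(FALSE, n_ev)
    events$analyzable <- rep(FALSE, n_ev)
    attr(events, "movements") <- tibble::tibble(
      start_t = numeric(), end_t = numeric(), duration = numeric(),
      valid = logical(), reason = character()
    )
    return(events)
  }
  t <- bk$time
  bad_t <- t[!bk$present]
  if (!is.null(angles)) {
    bad_t <- c(bad_t, unique(angles$time[!angles$present]))
  }
  movements <- tibble::tibble(
    start_t = events$t_rev[-n_ev],
    end_t = events$t_rev[-1]
  )
  movements$duration <- movements$end_t - movements$start_t
  dur_ok <- movements$duration >= min_dur & movements$duration <= max_dur
  gap_ok <- vapply(seq_len(nrow(movements)), function(i) {
    !any(bad_t > movements$start_t[i] & bad_t < movements$end_t[i])
  }, logical(1))
  movements$valid <- dur_ok & gap_ok
  movements$reason <- dplyr::case_when(
    !dur_ok ~ "duration",
    !gap_ok ~ "missing",
    TRUE ~ "valid"
  )
  events$prev_valid <- c(FALSE, movements$valid)
  events$next_valid <- c(movements$valid, FALSE)
  events$analyzable <- events$prev_valid & events$next_valid
  attr(events, "movements") <- movements
  events
}

#' Select the first reversals per direction
#'
#' To balance the number of events entering the statistics across subjects,
#' only the earliest `max_per_direction` analyzable reversals of each
#' direction are retained. A shortfall is kept (with a warning).
#'
#' @param events [segment_movements()] output.
#' @param max_per_direction Maximum retained events per direction.
#' @return The retained events, time-ordered.
#' @export
select_reversals <- function(events, max_per_direction = 10) {
  sel <- events[which(events$analyzable), , drop = FALSE]
  sel <- dplyr::slice_head(
    dplyr::group_by(dplyr::arrange(sel, .data$t_rev), .data$direction),
    n = max_per_direction
  )
  sel <- dplyr::arrange(dplyr::ungroup(sel), .data$t_rev)
  counts <- table(factor(sel$direction, c("up_down", "down_up")))
  short <- counts[counts < max_per_direction]
  if (length(short) > 0) {
    warn(sprintf(
      "select_reversals: only %s analyzable event(s) for direction(s) %s",
      paste(short, collapse = ", "), paste(names(short), collapse = ", ")
    ))
  }
  sel
}
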