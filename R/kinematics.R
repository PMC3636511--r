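#' Three-point numerical differentiation
#'
#' Central difference `(x[i+1] - x[i-1]) * fs / 2` at interior samples of
#' each contiguous present segment. No one-sided estimate is used: a
#' derivative sample requires both neighbours, so segment endpoints (and
#' both neighbours of every gap) come out `NA`. The rule is exact for
#' quadratic trajectories sampled uniformly.
#'
#' @param x Numeric vector, `NA` marking absent samples.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of the same length.
#' @examples
#' three_point_diff(c(0, 1, 4, 9, 16), fs = 1) # derivative of i^2
#' @export
three_point_diff <- function(x, fs) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 3) {
    return(out)
  }
  out[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  out[is.na(x)] <- NA_real_ # no estimate at a masked sample itself
  out
}

#' Bow kinematics: signed bowing velocity and acceleration
#'
#' The bow-tip velocity vector is obtained by three-point differentiation of
#' the bow-tip position; *bowing velocity* is its inner product with the
#' unit bow axis (the line through the two bow markers), i.e. the signed
#' velocity component along the bow's long axis, which is what moves the bow
#' hair across the string. *Bow acceleration* is the three-point derivative
#' of bowing velocity.
#'
#' Sign convention: positive velocity = down-bow. Since the axis orientation
#' from two markers is ambiguous, `orient = "auto"` flips the overall sign,
#' if needed, so that the first substantial stroke of the trial is positive
#' (a down-bow).
#'
#' @param rec A (preferably filtered, cello-frame) `bow_recording`.
#' @param tip,mid Names of the distal and proximal bow markers.
#' @param orient `"auto"` (first stroke positive), `"none"`, or `"flip"`.
#' @return A `bow_kinematics` tibble with columns `frame`, `time`,
#'   `velocity` (mm/s), `acceleration` (mm/s^2), `present`; `fs` attached as
#'   an attribute.
#' @export
bow_kinematics <- function(rec, tip = "bow_tip", mid = "bow_mid",
                           orient = c("auto", "none", "flip")) {
  orient <- match.arg(orient)
  fs <- rec_fs(rec)
  ptip <- marker_xyz(rec, tip)
  pmid <- marker_xyz(rec, mid)
  vel <- apply(ptip, 2, three_point_diff, fs = fs)
  axis <- ptip - pmid
  nrm <- sqrt(rowSums(axis^2))
  nrm[nrm < 1e-9] <- NA_real_
  axis <- axis / nrm
  v <- rowSums(vel * axis)
  if (orient == "auto") {
    lead <- head(v[!is.na(v)], round(0.5 * fs))
    if (length(lead) > 0 && mean(lead) < 0) v <- -v
  } else if (orient == "flip") {
    v <- -v
  }
  a <- three_point_diff(v, fs)
  rows <- rec$marker == tip
  out <- tibble::tibble(
    frame = rec$frame[rows],
    time = rec$time[rows],
    velocity = v,
    acceleration = a,
    present = !is.na(v)
  )
  structure(out, fs = fs, class = c("bow_kinematics", class(out)))
}
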