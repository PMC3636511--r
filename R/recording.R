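#' Build a bowing recording from marker positions
#'
#' A recording is a long tibble with one row per frame and marker, carrying
#' the 3D position in millimetres and a `present` flag. Masked-out samples
#' (`present == FALSE`) hold `NA` positions and are never consumed by numeric
#' operations downstream; the flag is the single source of truth for
#' missingness. Sampling metadata travel as attributes.
#'
#' @param positions Long data frame with columns `frame`, `marker`, `x`, `y`,
#'   `z` (mm) and optionally `present`. Every marker must appear on every
#'   frame.
#' @param fs Sampling rate in Hz (typically 60 or 120).
#' @param subject_id Subject identifier string.
#' @param group `"expert"` or `"novice"` (or `NA`).
#' @param lab `"A"` or `"B"` (or `NA`).
#' @param registry A [marker_registry()]; positions must cover its markers.
#' @return A `bow_recording` tibble with columns `frame`, `time`, `marker`,
#'   `x`, `y`, `z`, `present`.
#' @export
bow_recording <- function(positions, fs, subject_id = NA_character_,
                          group = NA_character_, lab = NA_character_,
                          registry = marker_registry()) {
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  pos <- tibble::as_tibble(positions)
  needed <- c("frame", "marker", "x", "y", "z")
  if (!all(needed %in% names(pos))) {
    abort(paste0(
      "positions must have columns ",
      paste(needed, collapse = ", ")
    ))
  }
  unknown <- setdiff(unique(pos$marker), registry$name)
  if (length(unknown) > 0) {
    abort(paste0("unknown marker(s): ", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(registry$name, unique(pos$marker))
  if (length(missing) > 0) {
    abort(paste0(
      "recording lacks required marker(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (!"present" %in% names(pos)) {
    pos$present <- TRUE
  }
  pos$present <- pos$present & !is.na(pos$x) & !is.na(pos$y) & !is.na(pos$z)
  pos$x[!pos$present] <- NA_real_
  pos$y[!pos$present] <- NA_real_
  pos$z[!pos$present] <- NA_real_
  pos$marker <- factor(pos$marker, levels = registry$name)
  pos <- dplyr::arrange(pos, .data$marker, .data$frame)
  frames_per_marker <- table(pos$marker)
  if (length(unique(frames_per_marker)) != 1) {
    abort("every marker must be sampled on every frame")
  }
  pos$time <- (pos$frame - min(pos$frame)) / fs
  pos <- pos[, c("frame", "time", "marker", "x", "y", "z", "present")]
  structure(
    pos,
    fs = fs,
    subject_id = subject_id,
    group = group,
    lab = lab,
    registry = registry,
    class = c("bow_recording", class(tibble::tibble()))
  )
}

#' Sampling rate of a recording or derived series
#' @param x A `bow_recording` or derived object carrying an `fs` attribute.
#' @return Sampling rate in Hz.
#' @export
rec_fs <- function(x) attr(x, "fs")

#' Subject metadata of a recording
#' @param x A `bow_recording`.
#' @return A one-row tibble with `subject_id`, `group`, `lab`, `fs`.
#' @export
rec_meta <- function(x) {
  tibble::tibble(
    subject_id = attr(x, "subject_id"),
    group = attr(x, "group"),
    lab = attr(x, "lab"),
    fs = attr(x, "fs")
  )
}

#' @export
print.bow_recording <- function(x, ...) {
  m <- rec_meta(x)
  n_frames <- length(unique(x$frame))
  cat(sprintf(
    "<bow_recording> subject=%s group=%s lab=%s | %d frames x %d markers @ %g Hz (%.1f s), %.2f%% present\n",
    m$subject_id, m$group, m$lab, n_frames, length(levels(x$marker)),
    m$fs, n_frames / m$fs, 100 * mean(x$present)
  ))
  NextMethod()
}

# internal: recording -> list of per-marker frame x 3 matrices + mask
rec_split <- function(rec) {
  markers <- levels(rec$marker)
  n <- length(unique(rec$frame))
  pos <- lapply(markers, function(m) {
    rows <- rec$marker == m
    cbind(x = rec$x[rows], y = rec$y[rows], z = rec$z[rows])
  })
  names(pos) <- markers
  present <- vapply(markers, function(m) rec$present[rec$marker == m],
    logical(n)
  )
  time <- rec$time[rec$marker == markers[1]]
  list(pos = pos, present = present, time = time, markers = markers)
}

# internal: rebuild a recording from rec_split-style parts, keeping metadata
rec_rebuild <- function(rec, pos, present) {
  markers <- levels(rec$marker)
  frames <- unique(rec$frame)
  out <- rec
  for (m in markers) {
    rows <- which(out$marker == m)
    p <- pos[[m]]
    ok <- present[, m] & !is.na(p[, 1]) & !is.na(p[, 2]) & !is.na(p[, 3])
    p[!ok, ] <- NA_real_
    out$x[rows] <- p[, 1]
    out$y[rows] <- p[, 2]
    out$z[rows] <- p[, 3]
    out$present[rows] <- ok
  }
  out
}

# internal: positions of one marker as a frame x 3 matrix (NA where absent)
marker_xyz <- function(rec, marker) {
  rows <- rec$marker == marker
  cbind(rec$x[rows], rec$y[rows], rec$z[rows])
}

#' Decimate a recording to a lower sampling rate
#'
#' Keeps every k-th frame, where k = `fs / target_fs` must be an integer.
#' No extra anti-alias stage is applied: the standard preprocessing order is
#' [lowpass_filter()] at the native rate (whose 20 Hz cutoff sits below the
#' 30 Hz Nyquist frequency of the 60 Hz target) followed by decimation. The
#' mask is decimated consistently.
#'
#' @param rec A `bow_recording`.
#' @param target_fs Target sampling rate in Hz.
#' @return A `bow_recording` at `target_fs`.
#' @export
downsample_recording <- function(rec, target_fs) {
  fs <- rec_fs(rec)
  if (target_fs <= 0) abort("target_fs must be positive")
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort(sprintf(
      "fs (%g Hz) must be an integer multiple of target_fs (%g Hz)",
      fs, target_fs
    ))
  }
  ratio <- round(ratio)
  if (ratio == 1) {
    return(rec)
  }
  frames <- sort(unique(rec$frame))
  keep_frames <- frames[seq(1, length(frames), by = ratio)]
  out <- rec[rec$frame %in% keep_frames, ]
  out$frame <- match(out$frame, keep_frames)
  out$time <- (out$frame - 1) / target_fs
  attr(out, "fs") <- target_fs
  out
}
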