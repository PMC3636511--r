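#' Read a marker table into a recording
#'
#' The primary on-disk dialect is a tab-separated table with a `frame` (or
#' `time`) column and one `<marker>_x`, `<marker>_y`, `<marker>_z` triple per
#' marker; empty cells mark missing samples. Metadata (sampling rate,
#' subject, group, lab) live in a YAML sidecar, by default
#' `<path-without-extension>.yaml`; `fs` may instead be supplied directly.
#'
#' A frame where any of a marker's three coordinates is absent is masked out
#' entirely for that marker. A `time` column must be uniform to within 1e-6 s
#' or the reader stops with an error.
#'
#' @param path Path to the TSV marker table.
#' @param registry Expected [marker_registry()].
#' @param sidecar Path to the YAML sidecar; `NULL` uses the default path.
#' @param fs Sampling rate override in Hz (otherwise taken from the sidecar
#'   or inferred from a `time` column).
#' @return A `bow_recording`.
#' @seealso [write_marker_table()]
#' @export
read_marker_table <- function(path, registry = marker_registry(),
                              sidecar = NULL, fs = NULL) {
  if (is.null(sidecar)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
  }
  meta <- list()
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cols <- names(tab)

  time <- NULL
  if ("time" %in% cols) {
    time <- tab$time
    dt <- diff(time)
    if (length(dt) > 0 && (max(dt) - min(dt)) > 1e-6) {
      abort("non-uniform time stamps (tolerance 1e-6 s)")
    }
  }
  if (is.null(fs)) fs <- meta$fs
  if (is.null(fs) && !is.null(time)) fs <- 1 / mean(diff(time))
  if (is.null(fs)) abort("sampling rate not found: supply `fs` or a sidecar")

  n <- nrow(tab)
  frame <- if ("frame" %in% cols) tab$frame else seq_len(n)

  suffixes <- c("_x", "_y", "_z")
  for (m in registry$name) {
    want <- paste0(m, suffixes)
    if (!all(want %in% cols)) {
      abort(sprintf("marker table lacks required marker '%s'", m))
    }
  }
  long <- purrr::map_dfr(registry$name, function(m) {
    tibble::tibble(
      frame = frame,
      marker = m,
      x = as.numeric(tab[[paste0(m, "_x")]]),
      y = as.numeric(tab[[paste0(m, "_y")]]),
      z = as.numeric(tab[[paste0(m, "_z")]])
    )
  })
  bow_recording(
    long,
    fs = fs,
    subject_id = meta$subject_id %||% NA_character_,
    group = meta$group %||% NA_character_,
    lab = meta$lab %||% NA_character_,
    registry = registry
  )
}

#' Write a recording as a marker table
#'
#' Inverse of [read_marker_table()]: writes the wide TSV dialect plus (by
#' default) a YAML sidecar with `fs`, `subject_id`, `group` and `lab`.
#' Masked samples become empty cells, so `read(write(rec))` reproduces the
#' recording up to float formatting.
#'
#' @param rec A `bow_recording`.
#' @param path Output TSV path.
#' @param sidecar `TRUE` (default path), `FALSE`, or an explicit path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(rec, path, sidecar = TRUE) {
  wide <- tidyr::pivot_wider(
    dplyr::select(rec, "frame", "marker", "x", "y", "z"),
    names_from = "marker", values_from = c("x", "y", "z"),
    names_glue = "{marker}_{.value}"
  )
  ord <- c("frame", paste0(
    rep(levels(rec$marker), each = 3), c("_x", "_y", "_z")
  ))
  wide <- wide[, ord]
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  if (!isFALSE(sidecar)) {
    sc <- if (isTRUE(sidecar)) {
      paste0(tools::file_path_sans_ext(path), ".yaml")
    } else {
      sidecar
    }
    m <- rec_meta(rec)
    yaml::write_yaml(
      list(
        fs = m$fs, subject_id = m$subject_id,
        group = m$group, lab = m$lab
      ),
      sc
    )
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
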