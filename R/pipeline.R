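#' Analysis configuration
#'
#' Bundles every tunable parameter of the analysis with the standard
#' defaults: 20 Hz / 5th-order bidirectional Butterworth filtering, 60 Hz
#' working rate, movement-duration validity bounds 0.5-1 s, +-375 ms
#' reversal windows, +-10%/+-50% switch thresholds, 50%-of-maximum peak
#' threshold with >=100 ms separation, and at most 10 retained reversals
#' per direction.
#'
#' @param cutoff_hz,filter_order Low-pass filter parameters.
#' @param target_fs_hz Working sampling rate (recordings at an integer
#'   multiple are decimated after filtering).
#' @param min_movement_s,max_movement_s Movement-duration validity bounds.
#' @param window_s Reversal-window half-width.
#' @param dur_fracs Velocity fractions for switch durations.
#' @param peak_frac,peak_sep_s Acceleration peak-counting rule.
#' @param max_per_direction Retained reversals per direction.
#' @param anthropometrics Default [anthropometrics()] used when a recording
#'   has none of its own.
#' @param distance Shoulder-distance mode for normalization.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cutoff_hz = 20, filter_order = 5,
                            target_fs_hz = 60,
                            min_movement_s = 0.5, max_movement_s = 1.0,
                            window_s = 0.375,
                            dur_fracs = c(0.1, 0.5),
                            peak_frac = 0.5, peak_sep_s = 0.1,
                            max_per_direction = 10,
                            anthropometrics = bowkin::anthropometrics(
                              0, 0, 0
                            ),
                            distance = "instantaneous") {
  structure(
    list(
      cutoff_hz = cutoff_hz, filter_order = filter_order,
      target_fs_hz = target_fs_hz,
      min_movement_s = min_movement_s, max_movement_s = max_movement_s,
      window_s = window_s, dur_fracs = dur_fracs,
      peak_frac = peak_frac, peak_sep_s = peak_sep_s,
      max_per_direction = max_per_direction,
      anthropometrics = anthropometrics,
      distance = distance
    ),
    class = "pipeline_config"
  )
}

#' Analyse one recording end to end
#'
#' Runs the full single-subject chain: low-pass filtering, decimation to
#' the working rate, cello-frame transform, joint-centre estimation, joint
#' angles, bow kinematics, reversal detection, movement validity filtering,
#' event selection, bow-level metrics, and chain coordination features.
#'
#' @param rec A raw `bow_recording`.
#' @param config A [pipeline_config()].
#' @param anthro Optional subject [anthropometrics()] (otherwise
#'   `config$anthropometrics`).
#' @return A `bow_analysis` list: `meta`, `events` (selected),
#'   `bow_metrics`, `marker_features`, `joint_features`, `exclusions`,
#'   `kinematics`, `angles`.
#' @export
analyze_recording <- function(rec, config = pipeline_config(),
                              anthro = NULL) {
  anthro <- anthro %||% config$anthropometrics
  meta <- rec_meta(rec)

  rec <- lowpass_filter(rec,
    cutoff = config$cutoff_hz,
    order = config$filter_order
  )
  if (rec_fs(rec) > config$target_fs_hz) {
    rec <- downsample_recording(rec, config$target_fs_hz)
  }
  rec <- to_cello_frame(rec)
  jc <- estimate_joint_centers(rec, anthro)
  angles <- compute_joint_angles(rec, jc)
  bk <- bow_kinematics(rec)

  events <- detect_reversals(bk)
  events <- segment_movements(events, bk, angles,
    min_dur = config$min_movement_s, max_dur = config$max_movement_s
  )
  movements <- attr(events, "movements")
  selected <- select_reversals(events, config$max_per_direction)

  metrics <- reversal_metrics(selected, bk,
    window = config$window_s, dur_fracs = config$dur_fracs,
    peak_frac = config$peak_frac, peak_sep = config$peak_sep_s
  )
  kept <- selected[metrics$ok, , drop = FALSE]
  mf <- marker_reversal_features(kept, rec, jc,
    window = config$window_s,
    distance = config$distance
  )
  jf <- joint_reversal_time(kept, angles, window = config$window_s)

  exclusions <- tibble::tibble(
    subject_id = meta$subject_id,
    total_movements = nrow(movements),
    excluded_duration = sum(movements$reason == "duration"),
    excluded_missing = sum(movements$reason == "missing"),
    retained_movements = sum(movements$valid),
    analyzable_reversals = sum(events$analyzable),
    selected_reversals = nrow(kept)
  )

  structure(
    list(
      meta = meta, events = kept, bow_metrics = metrics,
      marker_features = mf, joint_features = jf, exclusions = exclusions,
      kinematics = bk, angles = angles
    ),
    class = "bow_analysis"
  )
}

#' Run the full group pipeline
#'
#' Applies [analyze_recording()] to every subject, aggregates dependent
#' variables per subject x direction (x marker / joint), removes lab main
#' effects from every dependent variable, and runs the inferential layer:
#' Group x Direction mixed ANOVAs for the bow-level variables; Group x
#' Direction x Marker (or Joint) ANOVAs with ordered chain factors plus
#' per-group Direction x Marker/Joint ANOVAs with polynomial trend
#' decomposition; pairwise group post-hoc t-tests (Holm); and one-sample
#' t-tests of the relative temporal measures against zero.
#'
#' @param recordings A `bow_cohort`, or a list of `bow_recording`s (each
#'   optionally wrapped in `list(recording = , truth = )`), or a directory
#'   path containing TSV+YAML marker tables.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, event-level and
#'   subject-level CSVs, ANOVA/post-hoc tables and a JSON run log are
#'   written there.
#' @return A `bow_pipeline_result` list: `subject_bow`, `event_bow`,
#'   `subject_markers`, `subject_joints`, `anova` (named list of
#'   `bow_anova`), `trends`, `posthoc`, `one_sample`, `exclusions`,
#'   `retention_pct`, `config`.
#' @export
run_pipeline <- function(recordings, config = pipeline_config(),
                         out_dir = NULL) {
  recs <- normalize_recordings(recordings)
  analyses <- purrr::map(recs, analyze_recording, config = config)

  event_bow <- purrr::map_dfr(analyses, function(a) {
    dplyr::bind_cols(
      a$meta[rep(1, nrow(a$bow_metrics)), c("subject_id", "group", "lab")],
      a$bow_metrics
    )
  })
  subject_bow <- purrr::map_dfr(
    analyses,
    function(a) aggregate_bow_metrics(a$bow_metrics, a$meta)
  )
  subject_markers <- purrr::map_dfr(analyses, function(a) {
    agg <- dplyr::summarise(
      dplyr::group_by(a$marker_features, .data$direction, .data$marker),
      t_peak_acc = mean(.data$t_peak_acc, na.rm = TRUE),
      a_at_rev = mean(.data$a_at_rev, na.rm = TRUE),
      .groups = "drop"
    )
    dplyr::bind_cols(
      a$meta[rep(1, nrow(agg)), c("subject_id", "group", "lab")], agg
    )
  })
  subject_joints <- purrr::map_dfr(analyses, function(a) {
    agg <- dplyr::summarise(
      dplyr::group_by(a$joint_features, .data$direction, .data$joint),
      t_joint_rev = mean(.data$t_joint_rev, na.rm = TRUE),
      .groups = "drop"
    )
    dplyr::bind_cols(
      a$meta[rep(1, nrow(agg)), c("subject_id", "group", "lab")], agg
    )
  })
  exclusions <- purrr::map_dfr(analyses, "exclusions")
  retention_pct <- 100 * sum(exclusions$retained_movements) /
    sum(exclusions$total_movements)

  # lab adjustment: exactly one per dependent variable, then ANOVAs
  bow_dvs <- c(
    "a_peak", "t_peak_acc", "t_peak_acc_sd", "a_at_rev", "dur_50",
    "dur_10", "n_peaks"
  )
  subject_bow_adj <- subject_bow
  for (dvn in bow_dvs) {
    subject_bow_adj <- remove_lab_effect(subject_bow_adj, !!rlang::sym(dvn))
  }
  subject_markers_adj <- subject_markers
  for (dvn in c("t_peak_acc", "a_at_rev")) {
    subject_markers_adj <- remove_lab_effect(
      subject_markers_adj, !!rlang::sym(dvn)
    )
  }
  subject_joints_adj <- remove_lab_effect(subject_joints, t_joint_rev)

  anovas <- list()
  for (dvn in bow_dvs) {
    anovas[[dvn]] <- rm_anova(subject_bow_adj, dvn, within = "direction")
  }
  for (dvn in c("t_peak_acc", "a_at_rev")) {
    anovas[[paste0("marker_", dvn)]] <- rm_anova(
      subject_markers_adj, dvn,
      within = c("direction", "marker"), ordered = "marker"
    )
  }
  anovas[["joint_t_rev"]] <- rm_anova(
    subject_joints_adj, "t_joint_rev",
    within = c("direction", "joint"), ordered = "joint"
  )

  # per-group chain ANOVAs with polynomial trends on the ordered factor
  trends <- purrr::map_dfr(unique(subject_markers_adj$group), function(g) {
    purrr::map_dfr(c("t_peak_acc", "a_at_rev"), function(dvn) {
      fit <- within_anova(
        subject_markers_adj[subject_markers_adj$group == g, ],
        dvn,
        within = c("direction", "marker"), ordered = "marker"
      )
      tr <- trend_contrasts(fit, "marker")
      tr$group <- g
      tr$dv <- dvn
      tr
    })
  })

  posthoc <- purrr::map_dfr(bow_dvs, function(dvn) {
    purrr::map_dfr(unique(subject_bow_adj$direction), function(d) {
      ph <- posthoc_t(
        subject_bow_adj[subject_bow_adj$direction == d, ],
        dvn, "group",
        paired = FALSE
      )
      if (nrow(ph) == 0) {
        return(NULL)
      }
      ph$dv <- dvn
      ph$direction <- d
      ph
    })
  })

  one_sample <- purrr::map_dfr(
    split(
      subject_joints_adj,
      list(
        subject_joints_adj$group, subject_joints_adj$direction,
        subject_joints_adj$joint
      )
    ),
    function(d) {
      if (nrow(d) < 2 || all(is.na(d$t_joint_rev))) {
        return(NULL)
      }
      res <- one_sample_vs_zero(d$t_joint_rev)
      dplyr::bind_cols(
        tibble::tibble(
          group = d$group[1], direction = d$direction[1],
          joint = d$joint[1]
        ),
        res
      )
    }
  )

  result <- structure(
    list(
      subject_bow = subject_bow, event_bow = event_bow,
      subject_markers = subject_markers, subject_joints = subject_joints,
      anova = anovas, trends = trends, posthoc = posthoc,
      one_sample = one_sample, exclusions = exclusions,
      retention_pct = retention_pct, config = config
    ),
    class = "bow_pipeline_result"
  )
  if (!is.null(out_dir)) {
    write_pipeline_result(result, out_dir)
  }
  result
}

normalize_recordings <- function(recordings) {
  if (inherits(recordings, "bow_recording")) {
    return(list(recordings))
  }
  if (is.character(recordings) && length(recordings) == 1) {
    paths <- sort(list.files(recordings, pattern = "\\.tsv$",
      full.names = TRUE))
    if (length(paths) == 0) {
      abort(sprintf("no .tsv marker tables found in '%s'", recordings))
    }
    return(purrr::map(paths, read_marker_table))
  }
  purrr::map(recordings, function(r) {
    if (inherits(r, "bow_recording")) r else r$recording
  })
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$event_bow, file.path(out_dir, "events_bow.csv"))
  readr::write_csv(result$subject_bow, file.path(out_dir, "subject_bow.csv"))
  readr::write_csv(
    result$subject_markers, file.path(out_dir, "subject_markers.csv")
  )
  readr::write_csv(
    result$subject_joints, file.path(out_dir, "subject_joints.csv")
  )
  anova_tab <- purrr::imap_dfr(result$anova, function(a, nm) {
    tab <- tidy(a)
    tab$dv <- nm
    tab
  })
  readr::write_csv(anova_tab, file.path(out_dir, "anova.csv"))
  readr::write_csv(result$trends, file.path(out_dir, "trends.csv"))
  readr::write_csv(result$posthoc, file.path(out_dir, "posthoc.csv"))
  readr::write_csv(result$one_sample, file.path(out_dir, "one_sample.csv"))
  readr::write_csv(result$exclusions, file.path(out_dir, "exclusions.csv"))
  log <- list(
    config = unclass(result$config),
    retention_pct = result$retention_pct,
    n_subjects = nrow(result$exclusions)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}

# within-subject-only ANOVA (single-group chain analyses)
within_anova <- function(data, dv, within, subject = "subject_id",
                         ordered = NULL) {
  dat <- tibble::as_tibble(data)
  dat <- dat[!is.na(dat[[dv]]), ]
  dat[[subject]] <- factor(dat[[subject]])
  for (w in within) {
    lv <- if (is.factor(dat[[w]])) levels(dat[[w]]) else unique(dat[[w]])
    dat[[w]] <- factor(dat[[w]], levels = lv, ordered = w %in% ordered)
  }
  n_cells <- prod(vapply(within, function(w) nlevels(dat[[w]]), numeric(1)))
  counts <- table(dat[[subject]])
  incomplete <- names(counts)[counts < n_cells]
  if (length(incomplete) > 0) {
    dat <- dat[!dat[[subject]] %in% incomplete, ]
    dat[[subject]] <- droplevels(dat[[subject]])
  }
  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(paste0(
    dv, " ~ ", rhs, " + Error(", subject, "/(", rhs, "))"
  ))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- aov(fml, data = dat)
  structure(
    list(
      table = anova_table_from_aov(fit), fit = fit, data = dat, dv = dv,
      between = NULL, within = within, subject = subject, ordered = ordered
    ),
    class = "bow_anova"
  )
}

#' @export
print.bow_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<bow_pipeline_result> %d subjects | movement retention %.1f%%\n",
    nrow(x$exclusions), x$retention_pct
  ))
  cat("ANOVA dependent variables:", paste(names(x$anova), collapse = ", "),
    "\n")
  invisible(x)
}
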