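# chain step of each marker, counted from the bow (0) toward the shoulder;
# static markers have no step
chain_steps <- c(
  bow_tip = 0, bow_mid = 0, hand_pip1 = 0.75, hand_mcp1 = 1,
  wrist = 2, forearm = 2.5, elbow_lat = 3
)

# drive sign per moving marker (relative to the bow displacement); the
# pattern matches the chain_geometry() directions so that all joint angles
# increase monotonically with bow displacement in both group regimes
marker_drive_signs <- c(
  bow_tip = 1, bow_mid = 1, hand_pip1 = -1, hand_mcp1 = -1,
  wrist = -1, forearm = -1, elbow_lat = 1
)

# chain labels used by the coordination analysis -> source markers
chain_marker_map <- c(
  elbow = "elbow_lat", wrist = "wrist", hand = "hand_mcp1", bow = "bow_mid"
)

#' Simulate one bowing recording with ground truth
#'
#' Synthesises marker trajectories for one subject bowing `n_cycles` full
#' cycles (one up- plus one down-stroke each) at the profile's tempo. The
#' bow displacement along the bowing (lateral) axis follows the profile's
#' analytic velocity shape; arm markers move along the same axis as
#' gain-scaled, time-advanced copies of the bow displacement, anchored in an
#' arm-like layout given by `geometry`, so the proximal-to-distal timing lag
#' and amplitude gain hold exactly by construction. The whole scene is then
#' rigidly displaced into a world frame, and measurement noise and dropout
#' are applied last.
#'
#' The returned ground truth contains, per reversal: the exact velocity
#' zero-crossing time, direction label, bow peak-acceleration time and
#' amplitude and true pulse count; per reversal and chain marker (elbow,
#' wrist, hand, bow): the true peak-acceleration time and shoulder-normalized
#' acceleration at the reversal; per reversal and joint (shoulder, elbow,
#' wrist, finger): the true joint-angle reversal time, found by root-finding
#' on the analytic marker geometry.
#'
#' @param profile A [bowing_profile()].
#' @param geometry A [chain_geometry()].
#' @param n_cycles Number of full bowing cycles (>= 1).
#' @param fs Sampling rate, Hz.
#' @param seed RNG seed; defaults to `profile$seed`. Output is deterministic
#'   given the seed.
#' @param subject_id,group,lab Metadata stored on the recording.
#' @return A list with elements `recording` (a `bow_recording`) and `truth`
#'   (a `bow_ground_truth` list of tibbles `reversals`, `marker_features`,
#'   `joint_reversals`).
#' @examples
#' sim <- simulate_recording(bowing_profile("expert", noise_sd = 0,
#'   dropout_rate = 0), n_cycles = 2)
#' sim$truth$reversals
#' @export
simulate_recording <- function(profile, geometry = chain_geometry(),
                               n_cycles = 20, fs = 60,
                               seed = profile$seed,
                               subject_id = "S01", group = profile$preset,
                               lab = "A") {
  stopifnot(n_cycles >= 1)
  set.seed(seed)
  motion <- make_bow_motion(profile, n_cycles)

  n_frames <- floor(motion$duration * fs) + 1L
  t <- (seq_len(n_frames) - 1) / fs
  rho <- geometry$structural_attenuation / profile$proximal_distal_amp_gain
  lag <- profile$proximal_distal_lag
  A <- motion$A

  anchors <- geometry$anchors
  markers <- rownames(anchors)
  # each arm marker carries the bow displacement profile, attenuated per
  # chain step and time-advanced by the proximal-distal lag; drive signs
  # keep all joint angles monotone increasing in bow displacement so the
  # flexion-to-extension polarity at reversals is consistent
  disp_fun <- function(step, sgn = 1) {
    if (is.na(step)) {
      function(tt) rep(0, length(tt))
    } else {
      gain <- sgn * rho^step
      adv <- step * lag
      function(tt) gain * (motion$pos(tt + adv) - A / 2)
    }
  }
  steps <- chain_steps[markers]
  names(steps) <- markers
  dsigns <- marker_drive_signs[markers]
  names(dsigns) <- markers

  # cello-frame positions (analytic), then a fixed rigid world embedding
  Rw <- rot_z(25 * pi / 180) %*% rot_x(-12 * pi / 180)
  tw <- c(800, -400, 300)
  pos_cello <- lapply(markers, function(m) {
    d <- disp_fun(steps[[m]], dsigns[[m]] %|NA|% 1)(t)
    sweep(cbind(0, d, 0), 2, anchors[m, ], "+")
  })
  names(pos_cello) <- markers

  long <- purrr::map_dfr(markers, function(m) {
    p <- pos_cello[[m]] %*% t(Rw)
    p <- sweep(p, 2, tw, "+")
    if (profile$noise_sd > 0) {
      p <- p + ar1_noise(n_frames, 3, profile$noise_sd, profile$noise_ar1)
    }
    present <- if (profile$dropout_rate > 0) {
      runif(n_frames) >= profile$dropout_rate
    } else {
      rep(TRUE, n_frames)
    }
    tibble::tibble(
      frame = seq_len(n_frames), marker = m,
      x = ifelse(present, p[, 1], NA_real_),
      y = ifelse(present, p[, 2], NA_real_),
      z = ifelse(present, p[, 3], NA_real_),
      present = present
    )
  })
  rec <- bow_recording(long,
    fs = fs, subject_id = subject_id, group = group,
    lab = lab
  )

  truth <- synth_ground_truth(motion, geometry, profile, steps, dsigns,
    disp_fun)
  truth$profile <- profile
  truth$fs <- fs
  truth$subject_id <- subject_id
  class(truth) <- "bow_ground_truth"
  list(recording = rec, truth = truth)
}

`%|NA|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# stationary AR(1) noise, n x k matrix with marginal SD `sd`
ar1_noise <- function(n, k, sd, phi) {
  innov <- matrix(rnorm(n * k), n, k)
  if (phi <= 0) {
    return(sd * innov)
  }
  innov <- innov * sqrt(1 - phi^2)
  innov[1, ] <- rnorm(k) # stationary start
  out <- apply(innov, 2, function(e) {
    as.numeric(stats::filter(e, phi, method = "recursive"))
  })
  sd * out
}

# ground-truth tables from the analytic motion
synth_ground_truth <- function(motion, geometry, profile, steps, dsigns,
                               disp_fun) {
  ev <- motion$events
  anchors <- geometry$anchors
  rho <- geometry$structural_attenuation / profile$proximal_distal_amp_gain
  lag <- profile$proximal_distal_lag
  sh <- anchors["acromion", ]

  # per chain marker: exact peak time and normalized amplitude at reversal
  mf <- purrr::map_dfr(names(chain_marker_map), function(lab) {
    src <- chain_marker_map[[lab]]
    k <- steps[[src]]
    d_at <- function(tt) {
      p <- disp_fun(k, dsigns[[src]])(tt)
      sqrt(sum((anchors[src, ] + c(0, p, 0) - sh)^2))
    }
    tibble::tibble(
      event = ev$event,
      marker = lab,
      chain_pos = match(lab, names(chain_marker_map)),
      t_peak = ev$t_peak - k * lag,
      a_at_rev = rho^k * abs(motion$acc(ev$t_rev + k * lag)) /
        vapply(ev$t_rev, d_at, numeric(1))
    )
  })
  mf$marker <- factor(mf$marker, levels = names(chain_marker_map))

  # joint reversal times from the analytic geometry evaluated once on a
  # whole-trial fine grid; sub-grid crossing times by linear interpolation
  # of the angular velocity (grid error ~ (1/600 s)^2, far below a sample)
  trunk_up <- anchors["c7", ] - anchors["sternum", ]
  trunk_up <- trunk_up / sqrt(sum(trunk_up^2))
  fs_fine <- 600
  tt <- seq(0, motion$duration, by = 1 / fs_fine)
  pos_of <- function(m) {
    p <- disp_fun(steps_or_na(steps, m), dsigns[[m]] %|NA|% 1)(tt)
    sweep(cbind(0, p, 0), 2, anchors[m, ], "+")
  }
  ang <- joint_angles_from_points(
    shoulder = pos_of("acromion"),
    elbow = pos_of("elbow_lat"),
    wrist = pos_of("wrist"),
    hand = pos_of("hand_mcp1"),
    finger2 = pos_of("hand_pip1"),
    trunk_up = trunk_up
  )
  joints <- c("shoulder_abduction", "elbow_flexion", "wrist_flexion",
    "finger_flexion")
  jr <- purrr::map_dfr(joints, function(j) {
    th <- ang[[j]]
    # angular velocity at grid midpoints, crossings interpolated linearly
    dth <- diff(th) * fs_fine
    tmid <- (tt[-1] + tt[-length(tt)]) / 2
    i2 <- seq_len(length(dth) - 1)
    sc <- which(dth[i2] * dth[i2 + 1] < 0)
    t_cross <- tmid[sc] + (tmid[sc + 1] - tmid[sc]) *
      dth[sc] / (dth[sc] - dth[sc + 1])
    pol <- ifelse(dth[sc] > 0, "pos_to_neg", "neg_to_pos")
    purrr::map_dfr(seq_len(nrow(ev)), function(i) {
      t0 <- ev$t_rev[i]
      near <- which(abs(t_cross - t0) <= 0.3)
      if (length(near) == 0) {
        return(tibble::tibble(
          event = ev$event[i], joint = j, t_joint_rev = NA_real_,
          polarity = NA_character_
        ))
      }
      best <- near[which.min(abs(t_cross[near] - t0))]
      tibble::tibble(
        event = ev$event[i], joint = j, t_joint_rev = t_cross[best] - t0,
        polarity = pol[best]
      )
    })
  })
  jr <- dplyr::arrange(jr, .data$event, match(.data$joint, joints))
  jr$joint <- factor(jr$joint, levels = joints)

  list(
    reversals = ev[, c(
      "event", "t_nominal", "t_rev", "direction", "t_peak",
      "a_peak", "a_at_rev", "n_peaks"
    )],
    marker_features = mf,
    joint_reversals = jr
  )
}

steps_or_na <- function(steps, m) {
  if (m %in% names(steps) && !is.na(steps[[m]])) steps[[m]] else NA_real_
}

#' Simulate a cohort of expert and novice bowing recordings
#'
#' Generates `n_experts + n_novices` subjects, each with a subject-specific
#' profile obtained by jittering the group profile (log-normal jitter on
#' amplitudes and durations, additive on timing offsets; SDs in `jitter`),
#' and simulates one recording per subject. Per-subject seeds are
#' `base_seed + subject index`, so a cohort is bit-reproducible from
#' `base_seed`.
#'
#' The default lab assignment mirrors a two-lab design in which group and
#' lab are confounded (most experts in lab B, most novices in lab A), which
#' is what the [remove_lab_effect()] adjustment exists for.
#'
#' @param n_experts,n_novices Group sizes.
#' @param expert_profile,novice_profile Group-level [bowing_profile()]s.
#' @param geometry A [chain_geometry()].
#' @param n_cycles Cycles per subject.
#' @param fs Sampling rate, Hz.
#' @param lab_assignment Optional character vector (values `"A"`/`"B"`) of
#'   length `n_experts + n_novices`, experts first.
#' @param base_seed Integer seed from which subject seeds derive.
#' @param jitter Named list of between-subject jitter SDs:
#'   `stroke_amplitude`, `reversal_duration_50`, `proximal_distal_amp_gain`
#'   (relative, log scale), `peak_time_offset_mean`, `proximal_distal_lag`
#'   (absolute, s).
#' @return A `bow_cohort` list of per-subject `list(recording, truth)`.
#' @export
simulate_cohort <- function(n_experts = 10, n_novices = 10,
                            expert_profile = bowing_profile("expert"),
                            novice_profile = bowing_profile("novice"),
                            geometry = chain_geometry(),
                            n_cycles = 20, fs = 60,
                            lab_assignment = NULL,
                            base_seed = 1L,
                            jitter = list(
                              stroke_amplitude = 0.05,
                              reversal_duration_50 = 0.08,
                              proximal_distal_amp_gain = 0.04,
                              peak_time_offset_mean = 0.005,
                              proximal_distal_lag = 0.003
                            )) {
  n_total <- n_experts + n_novices
  if (is.null(lab_assignment)) {
    lab_e <- rep(c("A", "B"), c(ceiling(n_experts * 0.2), 0))
    lab_e <- c(lab_e, rep("B", n_experts - length(lab_e)))
    lab_n <- rep(c("A", "B"), c(ceiling(n_novices * 0.6), 0))
    lab_n <- c(lab_n, rep("B", n_novices - length(lab_n)))
    lab_assignment <- c(lab_e, lab_n)
  }
  stopifnot(length(lab_assignment) == n_total)

  subjects <- tibble::tibble(
    subject_id = c(
      sprintf("E%02d", seq_len(n_experts)),
      sprintf("N%02d", seq_len(n_novices))
    ),
    group = rep(c("expert", "novice"), c(n_experts, n_novices)),
    lab = lab_assignment,
    seed = base_seed + seq_len(n_total)
  )

  out <- purrr::pmap(subjects, function(subject_id, group, lab, seed) {
    base <- if (group == "expert") expert_profile else novice_profile
    set.seed(seed * 2L + 1L)
    prof <- base
    prof$stroke_amplitude <- base$stroke_amplitude *
      exp(rnorm(1, 0, jitter$stroke_amplitude))
    prof$reversal_duration_50 <- min(
      base$reversal_duration_50 * exp(rnorm(1, 0, jitter$reversal_duration_50)),
      0.9 * 60 / base$tempo_bpm
    )
    prof$proximal_distal_amp_gain <- max(
      1, base$proximal_distal_amp_gain *
        exp(rnorm(1, 0, jitter$proximal_distal_amp_gain))
    )
    prof$peak_time_offset_mean <- base$peak_time_offset_mean +
      rnorm(1, 0, jitter$peak_time_offset_mean)
    prof$proximal_distal_lag <- max(
      0, base$proximal_distal_lag + rnorm(1, 0, jitter$proximal_distal_lag)
    )
    simulate_recording(
      prof, geometry,
      n_cycles = n_cycles, fs = fs, seed = seed,
      subject_id = subject_id, group = group, lab = lab
    )
  })
  names(out) <- subjects$subject_id
  structure(out, subjects = subjects, class = "bow_cohort")
}

#' Subject table of a simulated cohort
#' @param cohort A `bow_cohort`.
#' @return Tibble with `subject_id`, `group`, `lab`, `seed`.
#' @export
cohort_subjects <- function(cohort) attr(cohort, "subjects")

#' @export
print.bow_cohort <- function(x, ...) {
  s <- cohort_subjects(x)
  cat(sprintf(
    "<bow_cohort> %d subjects (%d expert, %d novice)\n",
    nrow(s), sum(s$group == "expert"), sum(s$group == "novice")
  ))
  invisible(x)
}
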