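#' Bowing profile for the synthetic generator
#'
#' A profile describes the statistical structure of one subject's bowing:
#' tempo, bow travel per stroke, the shape of the velocity transition at
#' each reversal, how many acceleration pulses realise it, reversal
#' sharpness, the timing of peak acceleration relative to the reversal, and
#' the proximal-to-distal structure of the arm (per-step timing lag and
#' acceleration-amplitude gain), plus measurement noise and dropout.
#'
#' The two presets encode the canonical contrast between skilled and
#' unskilled bowing at 80 bows/min:
#' * `"expert"`: flat stroke velocity with a single sharp, skewed
#'   acceleration impulse at the reversal (+-50% switch time ~0.15 s), peak
#'   acceleration ~30 ms *before* the reversal with small trial-to-trial
#'   variability, a 30 ms/step proximal-to-distal timing lag and a strong
#'   distal amplitude gain.
#' * `"novice"`: bell-shaped strokes whose reversals are spread over several
#'   smaller acceleration pulses (3 by default, each above 50% of the
#'   largest and >=120 ms apart, so the true peak count is known by
#'   construction), ~0.30 s switch time, no systematic peak-time offset but
#'   large variability, no timing lag and no distal gain. Novices are given
#'   less bow travel per stroke, which together with the distributed
#'   impulse yields the lower peak accelerations typical of beginners.
#'
#' @param preset `"expert"` or `"novice"`.
#' @param tempo_bpm Bows per minute (one stroke per beat).
#' @param stroke_amplitude Bow travel per stroke, mm.
#' @param velocity_shape `"flat_with_impulse_reversal"` or `"bell_shaped"`.
#' @param n_accel_peaks Number of acceleration pulses per reversal (>= 1).
#' @param reversal_duration_50 Target +-50% switch time, s.
#' @param peak_time_offset_mean,peak_time_offset_sd Mean and across-reversal
#'   SD of the time of peak acceleration relative to the reversal, s
#'   (negative = peak precedes reversal).
#' @param proximal_distal_lag Reversal-timing lag per kinematic-chain step,
#'   s (positive = proximal earlier).
#' @param proximal_distal_amp_gain Multiplicative acceleration-amplitude
#'   gain per chain step toward the bow (>= 1).
#' @param noise_sd Stationary measurement-noise RMS per coordinate, mm.
#'   Noise is generated as an AR(1) process (see `noise_ar1`): optical
#'   marker reconstruction error drifts smoothly rather than jumping
#'   frame-to-frame, and its high-frequency power — which double
#'   differentiation amplifies — is far below that of white noise of the
#'   same RMS.
#' @param noise_ar1 Lag-one autocorrelation of the noise process at the
#'   sampling rate (0 = white).
#' @param dropout_rate Probability per frame per marker of a missing sample.
#' @param seed Default RNG seed for [simulate_recording()].
#' @return A `bowing_profile` list.
#' @examples
#' bowing_profile("expert")
#' bowing_profile("novice", n_accel_peaks = 2)
#' @export
bowing_profile <- function(preset = c("expert", "novice"),
                           tempo_bpm = 80,
                           stroke_amplitude = NULL,
                           velocity_shape = NULL,
                           n_accel_peaks = NULL,
                           reversal_duration_50 = NULL,
                           peak_time_offset_mean = NULL,
                           peak_time_offset_sd = NULL,
                           proximal_distal_lag = NULL,
                           proximal_distal_amp_gain = NULL,
                           noise_sd = 0.2,
                           noise_ar1 = 0.9,
                           dropout_rate = 2e-4,
                           seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "expert") {
    list(
      stroke_amplitude = 450,
      velocity_shape = "flat_with_impulse_reversal",
      n_accel_peaks = 1L,
      reversal_duration_50 = 0.15,
      peak_time_offset_mean = -0.030,
      peak_time_offset_sd = 0.010,
      proximal_distal_lag = 0.030,
      proximal_distal_amp_gain = 2.0
    )
  } else {
    list(
      stroke_amplitude = 300,
      velocity_shape = "bell_shaped",
      n_accel_peaks = 3L,
      reversal_duration_50 = 0.30,
      peak_time_offset_mean = 0,
      peak_time_offset_sd = 0.10,
      proximal_distal_lag = 0,
      proximal_distal_amp_gain = 1.0
    )
  }
  p <- list(
    preset = preset,
    tempo_bpm = tempo_bpm,
    stroke_amplitude = stroke_amplitude %||% def$stroke_amplitude,
    velocity_shape = velocity_shape %||% def$velocity_shape,
    n_accel_peaks = as.integer(n_accel_peaks %||% def$n_accel_peaks),
    reversal_duration_50 = reversal_duration_50 %||% def$reversal_duration_50,
    peak_time_offset_mean = peak_time_offset_mean %||% def$peak_time_offset_mean,
    peak_time_offset_sd = peak_time_offset_sd %||% def$peak_time_offset_sd,
    proximal_distal_lag = proximal_distal_lag %||% def$proximal_distal_lag,
    proximal_distal_amp_gain =
      proximal_distal_amp_gain %||% def$proximal_distal_amp_gain,
    noise_sd = noise_sd,
    noise_ar1 = noise_ar1,
    dropout_rate = dropout_rate,
    seed = as.integer(seed)
  )
  p$velocity_shape <- match.arg(
    p$velocity_shape, c("flat_with_impulse_reversal", "bell_shaped")
  )
  if (p$tempo_bpm <= 0) abort("tempo_bpm must be positive")
  if (p$stroke_amplitude <= 0) abort("stroke_amplitude must be positive")
  if (p$n_accel_peaks < 1) abort("n_accel_peaks must be >= 1")
  if (p$dropout_rate < 0 || p$dropout_rate >= 1) {
    abort("dropout_rate must be in [0, 1)")
  }
  if (p$noise_ar1 < 0 || p$noise_ar1 >= 1) {
    abort("noise_ar1 must be in [0, 1)")
  }
  if (p$proximal_distal_amp_gain < 1) {
    abort("proximal_distal_amp_gain must be >= 1")
  }
  if (p$reversal_duration_50 >= 60 / p$tempo_bpm) {
    abort("reversal_duration_50 must be shorter than the stroke period")
  }
  structure(p, class = "bowing_profile")
}

#' @export
print.bowing_profile <- function(x, ...) {
  cat(sprintf(
    "<bowing_profile:%s> %g bpm, %g mm/stroke, %s, %d peak(s), dur50=%g s, lag=%g s/step, gain=%gx/step\n",
    x$preset, x$tempo_bpm, x$stroke_amplitude, x$velocity_shape,
    x$n_accel_peaks, x$reversal_duration_50, x$proximal_distal_lag,
    x$proximal_distal_amp_gain
  ))
  invisible(x)
}

#' Kinematic-chain geometry for the synthetic generator
#'
#' Defines the arm-and-instrument layout the generator embeds its motion in:
#' segment lengths of the chain shoulder -> elbow -> wrist -> hand -> bow,
#' the (static) shoulder anchor, and the cello marker positions that define
#' the string and lateral axes. All positions are in the cello-centred frame
#' (origin at the scroll marker, x = string axis scroll -> tailpiece,
#' y = lateral axis = bowing direction); the scene is rigidly displaced into
#' an arbitrary world frame at simulation time.
#'
#' `structural_attenuation` is the fixed fraction of a marker's displacement
#' amplitude transmitted one step proximally before the profile's
#' `proximal_distal_amp_gain` is applied; it keeps proximal excursions
#' anatomically small even for gain 1.
#'
#' @param seg_upper_arm,seg_forearm,seg_hand,seg_hand_bow,seg_bow Segment
#'   lengths, mm.
#' @param shoulder_anchor Shoulder anchor position, cello frame, mm.
#' @param cello_scroll,cello_tail,cello_body Cello marker positions, mm.
#' @param structural_attenuation Per-step displacement attenuation in (0, 1].
#' @return A `chain_geometry` list including derived static marker anchors.
#' @export
chain_geometry <- function(seg_upper_arm = 300, seg_forearm = 260,
                           seg_hand = 90, seg_hand_bow = 70, seg_bow = 490,
                           shoulder_anchor = c(350, 0, 520),
                           cello_scroll = c(0, 0, 0),
                           cello_tail = c(1150, 0, 0),
                           cello_body = c(600, 150, 0),
                           structural_attenuation = 0.8) {
  lens <- c(seg_upper_arm, seg_forearm, seg_hand, seg_hand_bow, seg_bow)
  if (any(lens <= 0)) abort("all segment lengths must be positive")
  if (structural_attenuation <= 0 || structural_attenuation > 1) {
    abort("structural_attenuation must be in (0, 1]")
  }
  # collinearity of the cello markers leaves the lateral axis undefined
  v1 <- cello_tail - cello_scroll
  v2 <- cello_body - cello_scroll
  cr <- c(
    v1[2] * v2[3] - v1[3] * v2[2],
    v1[3] * v2[1] - v1[1] * v2[3],
    v1[1] * v2[2] - v1[2] * v2[1]
  )
  if (sqrt(sum(cr^2)) < 1e-6) abort("cello markers must be non-collinear")

  unitv <- function(v) v / sqrt(sum(v^2))
  # directions chosen (together with the per-marker drive signs of the
  # generator) so that every joint angle is a monotone increasing function
  # of the bow displacement over the realistic amplitude range, which keeps
  # the flexion-to-extension polarity at reversals consistent across
  # expert-like and novice-like profiles
  d_upper <- unitv(c(0.2047, 0.9169, -0.3426))
  d_fore <- unitv(c(0.4845, 0.6136, -0.6235))
  d_hand <- unitv(c(0.7291, 0.6780, 0.0929))
  d_bowseg <- unitv(c(0.60, -0.30, -0.10))
  elbow <- shoulder_anchor + seg_upper_arm * d_upper
  wrist <- elbow + seg_forearm * d_fore
  mcp <- wrist + seg_hand * d_hand
  bow_mid <- mcp + seg_hand_bow * d_bowseg
  bow_tip <- bow_mid + c(0, seg_bow, 0) # bow long axis along the lateral axis
  pip <- mcp + 60 * unitv(c(0.5482, 0.7271, -0.4133))
  anchors <- rbind(
    sternum = c(250, 40, 380),
    c7 = c(230, 20, 530),
    acromion = shoulder_anchor,
    elbow_lat = elbow,
    forearm = (elbow + wrist) / 2 + c(10, 5, 0),
    wrist = wrist,
    hand_mcp1 = mcp,
    hand_pip1 = pip,
    cello_scroll = cello_scroll,
    cello_tail = cello_tail,
    cello_body = cello_body,
    bow_tip = bow_tip,
    bow_mid = bow_mid
  )
  structure(
    list(
      segment_lengths = c(
        upper_arm = seg_upper_arm, forearm = seg_forearm, hand = seg_hand,
        hand_bow = seg_hand_bow, bow = seg_bow
      ),
      shoulder_anchor = shoulder_anchor,
      anchors = anchors,
      structural_attenuation = structural_attenuation
    ),
    class = "chain_geometry"
  )
}
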