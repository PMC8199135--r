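# Parametric generator of per-foot gyro + pressure walking signals with
# ground-truth event times, for normal gait and a graded hemiplegic-gait
# preset (prolonged affected-side swing, attenuated swing peak, pressure
# onset leading the gyro heel-strike trough).
#
# Waveform family: each gait phase landmark is a raised-cosine (Hann) lobe
# - C1-smooth, with controllable extrema and an exactly flat mid-stance,
# which is what the rule-based mid-stance detector requires. Per stride of
# duration T with stance fraction c, the gyro is
#   -A_hs  at the opening heel strike  (width 0.4 c T, centred on HS)
#   -A_to  at toe-off                  (width 0.4 c T, centred on c T)
#   +A_msw at mid-swing                (centred on (1+c)/2 T, wide enough
#                                       to overlap the flanking troughs so
#                                       the swing has no spurious flats)
# and the pressure is a negative heel lobe rolling into a positive
# forefoot lobe confined to the stance interval, exactly zero in swing.
# A lead-in swing peak is prepended before the first heel strike so that
# the first planted stride is detectable, and a landing flat follows the
# last heel strike so the final stride can be closed; an n-stride record
# therefore carries n + 1 swing peaks.

#' Generator parameters
#'
#' Defaults describe a normal adult walk: 1.1 s strides at 100 Hz with a
#' 60/40 stance/swing split, a 250 deg/s mid-swing peak, 100 and 60 deg/s
#' heel-strike and toe-off troughs, unit-amplitude heel/forefoot pressure
#' lobes, 2% stride-duration jitter, 5% per-stride amplitude jitter and
#' 0.5 deg/s additive gyro noise.
#'
#' @param rate Sampling rate (Hz).
#' @param n_strides Number of complete heel-strike-to-heel-strike strides.
#' @param stride_duration Mean stride duration (s).
#' @param stride_jitter_sd Per-stride duration jitter sd (s).
#' @param stance_fraction Fraction of the cycle in stance, in (0, 1).
#' @param swing_peak_amplitude Mid-swing gyro peak (deg/s); must exceed
#'   the detection threshold.
#' @param hs_trough_amplitude,to_trough_amplitude Heel-strike and toe-off
#'   trough depths (deg/s, positive numbers).
#' @param heel_load_amplitude,forefoot_load_amplitude Pressure lobe
#'   amplitudes (a.u., positive numbers; heel is emitted negative).
#' @param pressure_lead Pressure onset time relative to the gyro
#'   heel-strike trough (s); 0 for normal gait, negative when the foot
#'   loads before the shank has finished rotating (hemiplegic signature).
#' @param noise_sd_gyro,noise_sd_pressure Additive Gaussian noise sd
#'   (deg/s and a.u.).
#' @param amp_jitter_sd Multiplicative per-stride amplitude jitter sd.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `gait_params` list.
#' @export
gait_params <- function(rate = 100,
                        n_strides = 10,
                        stride_duration = 1.1,
                        stride_jitter_sd = 0.02,
                        stance_fraction = 0.60,
                        swing_peak_amplitude = 250,
                        hs_trough_amplitude = 100,
                        to_trough_amplitude = 60,
                        heel_load_amplitude = 1,
                        forefoot_load_amplitude = 1,
                        pressure_lead = 0,
                        noise_sd_gyro = 0.5,
                        noise_sd_pressure = 0.01,
                        amp_jitter_sd = 0.05,
                        seed = NULL) {
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    stop_config("stance_fraction must lie in (0, 1)")
  }
  if (min(swing_peak_amplitude, hs_trough_amplitude, to_trough_amplitude,
          heel_load_amplitude, forefoot_load_amplitude) <= 0) {
    stop_config("amplitudes must be positive")
  }
  if (n_strides < 1) stop_config("n_strides must be >= 1")
  structure(as.list(environment()), class = "gait_params")
}

#' Hemiplegic-gait asymmetry preset
#'
#' A graded software analogue of restricting one ankle: at severity
#' `s = 1` the affected side's swing duration is multiplied by
#' `swing_prolongation` (stride period unchanged, so the stance fraction
#' shrinks), its swing peak by `peak_attenuation`, and its pressure onset
#' leads the gyro heel-strike trough by `pressure_lead` seconds. All three
#' interpolate linearly to the identity at `s = 0`.
#'
#' @param severity Severity in `[0, 1]`.
#' @param side Affected side, `"left"` or `"right"`.
#' @param swing_prolongation Swing-duration factor at full severity.
#' @param peak_attenuation Swing-peak factor at full severity.
#' @param pressure_lead Pressure onset lead (s, negative) at full severity.
#' @return An `asymmetry_preset` list.
#' @export
asymmetry_preset <- function(severity = 1,
                             side = c("right", "left"),
                             swing_prolongation = 1.3,
                             peak_attenuation = 0.6,
                             pressure_lead = -0.06) {
  side <- match.arg(side)
  if (severity < 0 || severity > 1) stop_config("severity must be in [0, 1]")
  structure(list(severity = severity, side = side,
                 swing_prolongation = swing_prolongation,
                 peak_attenuation = peak_attenuation,
                 pressure_lead = pressure_lead),
            class = "asymmetry_preset")
}

# evaluate the preset at its severity: per-stride modifiers for one foot
preset_modifiers <- function(params, preset, side) {
  s <- if (!is.null(preset) && preset$side == side) preset$severity else 0
  swing0 <- 1 - params$stance_fraction
  swing <- swing0 * (1 + s * (preset_or(preset, "swing_prolongation") - 1))
  if (swing >= 1) stop_config("swing_prolongation drives swing past 100% of cycle")
  list(
    stance_fraction = 1 - swing,
    peak_scale = 1 + s * (preset_or(preset, "peak_attenuation") - 1),
    lead = s * preset_or(preset, "pressure_lead")
  )
}

preset_or <- function(preset, field) {
  if (is.null(preset)) {
    c(swing_prolongation = 1, peak_attenuation = 1, pressure_lead = 0)[[field]]
  } else {
    preset[[field]]
  }
}

# add a Hann lobe amp * 0.5 * (1 + cos(2 pi (t - center) / width)) on its
# support into sig, given the uniform time grid
add_hann <- function(sig, t, center, width, amp) {
  lo <- which(t >= center - width / 2)[1]
  if (is.na(lo)) return(sig)
  hi <- length(t) - which(rev(t) <= center + width / 2)[1] + 1L
  if (is.na(hi) || hi < lo) return(sig)
  idx <- lo:hi
  sig[idx] <- sig[idx] + amp * 0.5 * (1 + cos(2 * pi * (t[idx] - center) / width))
  sig
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize one foot's recording with ground truth
#'
#' @param params A [gait_params()].
#' @param side `"left"` or `"right"`.
#' @param preset Optional [asymmetry_preset()]; applied only if its `side`
#'   matches.
#' @param start_offset Extra delay (s) before the first heel strike (used
#'   for the half-cycle inter-foot phase offset).
#' @param durations,amp_jitter Optional pre-drawn per-stride durations (s)
#'   and multiplicative amplitude factors, shared across feet by
#'   [synth_walk()]; drawn from `params` when `NULL`.
#' @param raw_voltage If `TRUE`, emit the pressure channel on the raw
#'   divider scale (`vin/2` offset still present, see
#'   [pressure_to_voltage()]) instead of offset-removed units.
#' @param vin Divider supply voltage for `raw_voltage`.
#' @return List with `recording` (a [foot_recording()]) and `truth`, a
#'   data.frame of planted per-stride times: `hs_time`, `next_hs_time`,
#'   `ms_time` (foot-flat onset), `to_time`, `msw_time`,
#'   `pressure_onset_time`, plus `stance_fraction`, `swing_duration` and
#'   `peak_amplitude`.
#' @export
#' @examples
#' foot <- synth_foot(gait_params(n_strides = 5, seed = 42))
#' foot$recording
#' head(foot$truth)
synth_foot <- function(params, side = c("left", "right"), preset = NULL,
                       start_offset = 0, durations = NULL, amp_jitter = NULL,
                       raw_voltage = FALSE, vin = 5) {
  side <- match.arg(side)
  stopifnot(inherits(params, "gait_params"))
  local_seed(params$seed, {
    K <- params$n_strides
    if (is.null(durations)) {
      durations <- params$stride_duration +
        rnorm(K, 0, params$stride_jitter_sd)
      durations <- pmax(durations, 0.5 * params$stride_duration)
    }
    if (is.null(amp_jitter)) {
      amp_jitter <- pmax(1 + rnorm(K, 0, params$amp_jitter_sd), 0.5)
    }
    mods <- preset_modifiers(params, preset, side)
    tbar <- mean(durations)
    pad <- 0.6 * tbar
    bounds <- pad + start_offset + cumsum(c(0, durations))  # S_1 .. S_(K+1)
    total <- bounds[K + 1] + 0.6 * tbar
    t <- seq(0, total, by = 1 / params$rate)
    gyro <- numeric(length(t))
    pressure <- numeric(length(t))

    c_k <- mods$stance_fraction
    msw_amp <- params$swing_peak_amplitude * mods$peak_scale
    w_msw <- function(T) (1.08 - 1.4 * c_k) * T

    # lead-in swing peak so the first heel strike is detectable
    gyro <- add_hann(gyro, t, bounds[1] - (1 - c_k) / 2 * durations[1],
                     w_msw(durations[1]), msw_amp * amp_jitter[1])
    for (k in seq_len(K)) {
      T_k <- durations[k]; S_k <- bounds[k]; aj <- amp_jitter[k]
      gyro <- add_hann(gyro, t, S_k, 0.4 * c_k * T_k,
                       -params$hs_trough_amplitude * aj)
      gyro <- add_hann(gyro, t, S_k + c_k * T_k, 0.4 * c_k * T_k,
                       -params$to_trough_amplitude * aj)
      gyro <- add_hann(gyro, t, S_k + (1 + c_k) / 2 * T_k, w_msw(T_k),
                       msw_amp * aj)
      lead <- params$pressure_lead + mods$lead
      pressure <- add_hann(pressure, t, S_k + 0.25 * c_k * T_k + lead,
                           0.5 * c_k * T_k, -params$heel_load_amplitude * aj)
      pressure <- add_hann(pressure, t, S_k + (2 / 3) * c_k * T_k + lead,
                           (2 / 3) * c_k * T_k,
                           params$forefoot_load_amplitude * aj)
    }
    # closing heel strike + landing flat
    gyro <- add_hann(gyro, t, bounds[K + 1], 0.4 * c_k * durations[K],
                     -params$hs_trough_amplitude * amp_jitter[K])

    if (params$noise_sd_gyro > 0) {
      gyro <- gyro + rnorm(length(t), 0, params$noise_sd_gyro)
    }
    if (params$noise_sd_pressure > 0) {
      pressure <- pressure + rnorm(length(t), 0, params$noise_sd_pressure)
    }
    if (raw_voltage) pressure <- pressure_to_voltage(pressure, vin)

    truth <- data.frame(
      stride = seq_len(K),
      hs_time = bounds[seq_len(K)],
      next_hs_time = bounds[seq_len(K) + 1],
      ms_time = bounds[seq_len(K)] + 0.2 * c_k * durations,
      to_time = bounds[seq_len(K)] + c_k * durations,
      msw_time = bounds[seq_len(K)] + (1 + c_k) / 2 * durations,
      pressure_onset_time = bounds[seq_len(K)] + params$pressure_lead + mods$lead,
      stance_fraction = c_k,
      swing_duration = (1 - c_k) * durations,
      peak_amplitude = msw_amp * amp_jitter
    )
    list(recording = foot_recording(t, gyro, pressure, side), truth = truth)
  })
}

#' Synthesize a two-foot walk
#'
#' Stride durations and per-stride amplitude factors are drawn once and
#' shared by both feet (cadence is common to both legs in steady walking);
#' measurement noise is drawn independently per foot. The right foot is
#' phase shifted by half a cycle. With `severity = 0` and all noise off
#' the two feet are identical up to that offset.
#'
#' @param params A [gait_params()].
#' @param preset Optional [asymmetry_preset()] applied to its affected
#'   side.
#' @param label Walk label; defaults to `"symmetric"` or `"asymmetric"`
#'   according to the preset.
#' @return A [walk_recording()] with attributes `truth_left` and
#'   `truth_right` (ground-truth tables as in [synth_foot()]).
#' @export
synth_walk <- function(params, preset = NULL, label = NULL) {
  stopifnot(inherits(params, "gait_params"))
  if (is.null(label)) {
    label <- if (is.null(preset) || preset$severity == 0) "symmetric" else "asymmetric"
  }
  local_seed(params$seed, {
    K <- params$n_strides
    durations <- pmax(params$stride_duration + rnorm(K, 0, params$stride_jitter_sd),
                      0.5 * params$stride_duration)
    amp_jitter <- pmax(1 + rnorm(K, 0, params$amp_jitter_sd), 0.5)
    inner <- params; inner$seed <- NULL
    left <- synth_foot(inner, "left", preset, start_offset = 0,
                       durations = durations, amp_jitter = amp_jitter)
    right <- synth_foot(inner, "right", preset,
                        start_offset = mean(durations) / 2,
                        durations = durations, amp_jitter = amp_jitter)
    walk <- walk_recording(left$recording, right$recording, label)
    attr(walk, "truth_left") <- left$truth
    attr(walk, "truth_right") <- right$truth
    walk
  })
}

#' Synthesize a cohort of independent walks
#'
#' @param n_walks Number of walks.
#' @param params A [gait_params()]; each walk uses seed
#'   `seed + walk index` when `seed` is given.
#' @param preset Optional [asymmetry_preset()].
#' @param seed Base seed for the cohort (overrides `params$seed`).
#' @return List of [walk_recording()]s.
#' @export
synth_cohort <- function(n_walks, params = gait_params(), preset = NULL,
                         seed = NULL) {
  if (n_walks < 1) stop_config("n_walks must be >= 1")
  if (is.null(seed)) seed <- params$seed
  lapply(seq_len(n_walks), function(w) {
    p <- params
    p$seed <- if (is.null(seed)) NULL else seed + w
    synth_walk(p, preset)
  })
}
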