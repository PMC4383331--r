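#' Standard 64-channel 10-20/10-10 montage labels
#'
#' The Biosemi-style 64-electrode layout used as the default montage by
#' the cohort generator.  The two EOG channels (`"VEOG"`, `"HEOG"`) are
#' appended separately by [cohort_spec()].
#'
#' @return character vector of 64 labels.
#' @export
montage64 <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
}

#' Specify a synthetic two-group ERP cohort
#'
#' Defines the study conditions a generated cohort emulates: two groups
#' of `n_per_group` subjects, a visual oddball-style block of
#' `n_stimuli_per_block` triangle stimuli (every third completing the
#' predictive left-up-right sequence and carrying code `"P"`), and a
#' group difference confined to beta-band Gabor bursts on
#' `effect_channels` inside `effect_windows`.
#'
#' Defaults mirror the clinical protocol the pipeline targets: 25
#' subjects per group, a 64-channel montage plus two EOG channels,
#' 512 Hz sampling, 78 stimuli of 150 ms at 1 s ISI, effects on the
#' frontal-central sites F2/FC3 in the 15-27.5 Hz band near 200-300 ms
#' and 900-950 ms post-stimulus, and evoked responses that habituate
#' over trials.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param channel_labels EEG montage labels (EOG labels are appended).
#' @param fs sampling rate, Hz; must exceed twice `effect_band[2]`.
#' @param n_stimuli_per_block stimuli per block.
#' @param stimulus_duration stimulus duration, ms.
#' @param isi inter-stimulus interval, ms.
#' @param effect_channels subset of `channel_labels` carrying the group
#'   difference.
#' @param effect_band `c(low, high)` Hz of the evoked bursts.
#' @param effect_windows list of `c(start, end)` ms post-stimulus; all
#'   within `[0, isi + stimulus_duration]`.
#' @param effect_size patient/healthy burst-amplitude ratio (1 = null).
#' @param evoked_amplitude healthy-group burst amplitude, microvolts.
#' @param erp_amplitude amplitude of the slow group-identical ERP wave
#'   present on all EEG channels, microvolts.
#' @param habituation_tau exponential decay constant of evoked
#'   amplitude over predictive-trial index, in trials.
#' @param latency_jitter `c(healthy =, patient =)` burst latency jitter
#'   s.d., ms.
#' @param artifact_rates `c(blink =, saccade =, miss =,
#'   large_amplitude =)` per-epoch probabilities in `[0, 1]`.
#' @param noise_model `list(exponent =, pink_sd =, white_sd =)`: 1/f
#'   power-law exponent, s.d. (uV) of the 1/f background, and s.d. (uV)
#'   of the white floor.
#' @param seed default integer seed for [generate_cohort()].
#' @return a validated list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = 25,
                        channel_labels = montage64(),
                        fs = 512,
                        n_stimuli_per_block = 78,
                        stimulus_duration = 150,
                        isi = 1000,
                        effect_channels = c("F2", "FC3"),
                        effect_band = c(15, 27.5),
                        effect_windows = list(c(200, 300), c(900, 950)),
                        effect_size = 0.5,
                        evoked_amplitude = 8,
                        erp_amplitude = 3,
                        habituation_tau = 5,
                        latency_jitter = c(healthy = 8, patient = 20),
                        artifact_rates = c(blink = 0.2, saccade = 0.05,
                                           miss = 0.1, large_amplitude = 0.05),
                        noise_model = list(exponent = 1, pink_sd = 4,
                                           white_sd = 1),
                        seed = 1L) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @export
validate_cohort_spec <- function(spec) {
  if (spec$n_per_group < 2)
    stop_config("cohort_spec: n_per_group must be >= 2 (got %d)",
                spec$n_per_group)
  if (spec$fs <= 2 * spec$effect_band[2])
    stop_config("cohort_spec: fs (%g) must exceed 2 x effect_band high (%g)",
                spec$fs, spec$effect_band[2])
  if (length(spec$effect_band) != 2 || spec$effect_band[1] >= spec$effect_band[2])
    stop_config("cohort_spec: effect_band must be c(low, high) with low < high")
  span <- spec$isi + spec$stimulus_duration
  for (w in spec$effect_windows) {
    if (length(w) != 2 || w[1] >= w[2] || w[1] < 0 || w[2] > span)
      stop_config("cohort_spec: effect_window [%g, %g] outside [0, %g] ms",
                  w[1], w[2], span)
  }
  rates <- spec$artifact_rates
  need <- c("blink", "saccade", "miss", "large_amplitude")
  if (!all(need %in% names(rates)))
    stop_config("cohort_spec: artifact_rates must name %s",
                paste(need, collapse = ", "))
  if (any(rates < 0 | rates > 1))
    stop_config("cohort_spec: artifact_rates must lie in [0, 1]")
  missing_ch <- setdiff(spec$effect_channels, spec$channel_labels)
  if (length(missing_ch))
    stop_config("cohort_spec: effect_channels not in montage: %s",
                paste(missing_ch, collapse = ", "))
  if (spec$effect_size < 0)
    stop_config("cohort_spec: effect_size must be >= 0")
  if (spec$habituation_tau <= 0)
    stop_config("cohort_spec: habituation_tau must be > 0")
  invisible(spec)
}

#' Specify the latent severity model for synthetic patients
#'
#' Maps each synthetic patient's latent severity u ~ Uniform(0, 1) to
#' clinical covariates (hospitalizations, medication load, SAPS/SANS
#' symptom counts) and to the attenuation of their evoked bursts, so
#' severity-regression recovery can be tested against a known ground
#' truth.
#'
#' @param hospitalization_lambda scale of the exponential hospitalization
#'   count model `1 + Poisson(lambda * (exp(2.8 u) - 1))`.
#' @param dose_range `c(min, max)` medication load, arbitrary units.
#' @param n_saps,n_sans `c(min, max)` symptom-count ranges.
#' @param severity_link monotone non-decreasing function from latent
#'   severity in `[0, 1]` to the burst-attenuation mixing weight.
#' @return a list of class `"severity_model"`.
#' @export
severity_model <- function(hospitalization_lambda = 1,
                           dose_range = c(50, 600),
                           n_saps = c(0, 20),
                           n_sans = c(0, 20),
                           severity_link = identity) {
  u <- seq(0, 1, length.out = 64)
  if (any(diff(severity_link(u)) < 0))
    stop_config("severity_model: severity_link must be monotone non-decreasing")
  structure(list(hospitalization_lambda = hospitalization_lambda,
                 dose_range = dose_range, n_saps = n_saps, n_sans = n_sans,
                 severity_link = severity_link),
            class = "severity_model")
}
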