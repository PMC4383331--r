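# Synthetic two-group ERP cohort generator.
#
# Signal model per EEG channel: an independent 1/f ("pink") Gaussian
# process plus a few spatially smooth shared pink sources (a cheap
# stand-in for volume conduction) plus a white floor; at each
# predictive ("P") stimulus a slow group-identical ERP wave on all EEG
# channels and, on the effect channels only, a stimulus-locked Gabor
# burst (carrier at the effect-band centre, Gaussian envelope inside
# each effect window).  The patient group's bursts are attenuated by
# effect_size (scaled further by each patient's latent severity) and
# carry larger latency jitter.  Evoked amplitude decays over trials as
# exp(-(i-1)/habituation_tau).  All randomness flows from one seeded
# stream; outputs are quantized to single precision so fixture round
# trips are bit-exact.

# Gaussian 1/f^exponent spectrum: complex-normal bins with s.d.
# k^(-exponent/2) (a stationary Gaussian process), Hermitian symmetric.
pink_spectrum <- function(n, exponent) {
  half <- floor((n - 1) / 2)
  amp <- seq_len(floor(n / 2))^(-exponent / 2)
  X <- complex(n)
  X[1 + seq_len(half)] <- amp[seq_len(half)] *
    complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) /
    sqrt(2)
  if (n %% 2 == 0)
    X[n / 2 + 1] <- amp[n / 2] * stats::rnorm(1)      # Nyquist bin is real
  X[n + 1 - seq_len(half)] <- Conj(X[1 + seq_len(half)])
  X
}

# Realize a spectrum as a real time series scaled so the s.d. of its
# realized in-band (band, Hz) content equals sd_target exactly.  The
# in-band normalization keeps per-channel analysis-band power fixed
# across subjects (so group contrasts stay confined to the injected
# effect) while within-band structure still varies naturally.
realize_spectrum <- function(X, fs, sd_target, band = c(0.5, 30)) {
  n <- length(X)
  if (sd_target <= 0) return(numeric(n))
  k <- seq_len(floor(n / 2))
  in_band <- k * fs / n >= band[1] & k * fs / n <= band[2]
  var_band <- 2 * sum(Mod(X[1 + k[in_band]])^2) / n^2
  Re(stats::fft(X, inverse = TRUE)) / n * (sd_target / sqrt(var_band))
}

# Convenience wrapper kept for spectral-contract checks.
pink_noise <- function(n, exponent, sd_target, fs = n) {
  realize_spectrum(pink_spectrum(n, exponent), fs, sd_target,
                   band = c(0, fs / 2))
}

# Gaussian-smoothed random topography over channel index, for the
# shared volume-conduction components.
smooth_topography <- function(n_ch) {
  centre <- stats::runif(1, 1, n_ch)
  width <- n_ch / 3
  exp(-((seq_len(n_ch) - centre)^2) / (2 * width^2))
}

# Blink spatial weight by 10-20 label prefix: strongest frontally.
blink_weight <- function(label) {
  if (label == "VEOG") return(1)
  if (label == "HEOG") return(0.1)
  if (grepl("^Fp", label)) return(0.4)
  if (grepl("^AF", label)) return(0.3)
  if (grepl("^FC", label)) return(0.1)
  if (grepl("^F", label)) return(0.22)
  0.03
}

# Event schedule for one block: stimuli every isi + duration ms, codes
# cycling L, U, P (the "P" completes the predictive triangle triple).
build_events <- function(spec, n_samples) {
  step <- ms_to_samples(spec$isi + spec$stimulus_duration, spec$fs)
  pre <- ms_to_samples(2000, spec$fs)
  onsets <- pre + (seq_len(spec$n_stimuli_per_block) - 1L) * step
  codes <- rep(c("L", "U", "P"), length.out = spec$n_stimuli_per_block)
  rt <- pmin(pmax(stats::rlnorm(length(onsets), log(0.45), 0.2), 0.2), 1.1)
  resp <- onsets + ms_to_samples(rt * 1000, spec$fs)
  data.frame(onset_sample = as.integer(onsets), code = codes,
             response_sample = as.integer(resp))
}

# Gabor burst: carrier at f_c Hz, Gaussian envelope with sigma_t =
# width/2.  Time-frequency uncertainty drives this choice: a burst
# squeezed entirely into a 100 ms window would have sigma_f ~ 6 Hz and
# put most of its energy outside a 5 Hz effect band, so the envelope
# is kept as wide as the window allows (~68% of the energy inside the
# nominal window, sigma_f ~ 3 Hz inside the nominal band).
add_burst <- function(x, fs, onset_sample, window_ms, f_c, amplitude,
                      jitter_ms) {
  t_c <- mean(window_ms) + jitter_ms
  sigma <- (window_ms[2] - window_ms[1]) / 2 / 1000      # s
  span <- ms_to_samples(4 * sigma * 1000, fs)
  centre <- onset_sample + ms_to_samples(t_c, fs)
  idx <- max(1L, centre - span):min(length(x), centre + span)
  tt <- (idx - 1 - (onset_sample - 1)) / fs - t_c / 1000 # s rel. centre
  x[idx] <- x[idx] +
    amplitude * cos(2 * pi * f_c * tt) * exp(-tt^2 / (2 * sigma^2))
  x
}

simulate_recording <- function(spec, subject_id, group, patient_ratio,
                               metadata, jitter_sd = NULL) {
  eeg_labels <- spec$channel_labels
  labels <- c(eeg_labels, "VEOG", "HEOG")
  n_eeg <- length(eeg_labels)
  step <- ms_to_samples(spec$isi + spec$stimulus_duration, spec$fs)
  n_samples <- ms_to_samples(2000, spec$fs) +
    spec$n_stimuli_per_block * step + ms_to_samples(1500, spec$fs)
  # pad the post-stimulus roll to a 2-3-5-smooth sample count so the
  # FFTs in noise synthesis and filtering stay O(n log n)
  n_samples <- stats::nextn(n_samples, factors = c(2, 3, 5))

  events <- build_events(spec, n_samples)
  nm <- spec$noise_model

  # background: independent random-phase 1/f spectrum per channel plus
  # three spatially smooth shared sources (volume-conduction stand-in),
  # assembled in the frequency domain and scaled so each channel's
  # 0.5-30 Hz s.d. equals pink_sd exactly
  n_shared <- 3L
  shared_spec <- vector("list", n_shared)
  topo <- matrix(0, n_eeg, n_shared)
  for (k in seq_len(n_shared)) {
    topo[, k] <- smooth_topography(n_eeg)
    shared_spec[[k]] <- pink_spectrum(n_samples, nm$exponent)
  }

  signal <- matrix(0, length(labels), n_samples,
                   dimnames = list(labels, NULL))
  for (ch in seq_len(n_eeg)) {
    spec_ch <- 0.75 * pink_spectrum(n_samples, nm$exponent)
    for (k in seq_len(n_shared))
      spec_ch <- spec_ch + 0.5 * topo[ch, k] * shared_spec[[k]]
    signal[ch, ] <- realize_spectrum(spec_ch, spec$fs, nm$pink_sd) +
      stats::rnorm(n_samples, 0, nm$white_sd)
  }
  for (lab in c("VEOG", "HEOG")) {
    signal[lab, ] <- realize_spectrum(pink_spectrum(n_samples, nm$exponent),
                                      spec$fs, nm$pink_sd * 1.5) +
      stats::rnorm(n_samples, 0, nm$white_sd)
  }

  # evoked content at predictive stimuli
  p_rows <- which(events$code == "P")
  jit_sd <- jitter_sd %||% unname(spec$latency_jitter[[group]])
  f_c <- mean(spec$effect_band)
  erp_t <- seq(0, ms_to_samples(700, spec$fs) - 1)
  erp_wave <- exp(-(((erp_t / spec$fs * 1000) - 300)^2) / (2 * 60^2))
  eff_idx <- match(spec$effect_channels, labels)
  for (i in seq_along(p_rows)) {
    onset <- events$onset_sample[p_rows[i]] + 1L  # 1-based sample
    hab <- exp(-(i - 1) / spec$habituation_tau)
    idx <- onset:min(n_samples, onset + length(erp_wave) - 1L)
    wave <- spec$erp_amplitude * hab * erp_wave[seq_along(idx)]
    signal[seq_len(n_eeg), idx] <-
      sweep(signal[seq_len(n_eeg), idx, drop = FALSE], 2, wave, `+`)
    amp <- spec$evoked_amplitude * hab *
      if (group == "patient") patient_ratio else 1
    for (w in spec$effect_windows) {
      jitter <- stats::rnorm(1, 0, jit_sd)
      for (ch in eff_idx) {
        signal[ch, ] <- add_burst(signal[ch, ], spec$fs, onset, w, f_c,
                                  amp, jitter)
      }
    }
  }

  recording(subject_id = subject_id, group = group,
            channel_labels = labels, fs = spec$fs, signal = signal,
            events = events, metadata = metadata)
}

# Draw clinical covariates for one patient from the severity model.
draw_severity_record <- function(model, u) {
  lam <- model$hospitalization_lambda * (exp(2.8 * u) - 1)
  hosp <- 1L + stats::rpois(1, lam)
  dose <- model$dose_range[1] +
    (model$dose_range[2] - model$dose_range[1]) *
    pmin(pmax(u + stats::rnorm(1, 0, 0.15), 0), 1)
  saps <- round(model$n_saps[1] +
                  (model$n_saps[2] - model$n_saps[1]) *
                  pmin(pmax(u + stats::rnorm(1, 0, 0.15), 0), 1))
  sans <- round(model$n_sans[1] +
                  (model$n_sans[2] - model$n_sans[1]) *
                  pmin(pmax(u + stats::rnorm(1, 0, 0.15), 0), 1))
  severity_record(hosp, dose, saps, sans)
}

#' Generate a synthetic two-group EEG cohort
#'
#' Produces `2 * n_per_group` continuous recordings (healthy subjects
#' `H01...`, patients `P01...`) under the conditions in `spec`, injects
#' artifacts at the configured rates, and attaches the ground-truth
#' artifact table for audit tests.  Deterministic given `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param severity optional [severity_model()]; when supplied, patients
#'   receive clinical metadata and burst attenuation tied to a latent
#'   severity, and the latent values are attached as attribute
#'   `"latent_severity"`.
#' @param seed integer seed; defaults to `spec$seed`.
#' @return list of [recording()] objects with attribute
#'   `"artifact_truth"` (a data frame: subject_id, p_index, event_row,
#'   type) and, with a severity model, `"latent_severity"`.
#' @export
generate_cohort <- function(spec, severity = NULL, seed = spec$seed) {
  validate_cohort_spec(spec)
  with_seed(seed, {
    recs <- vector("list", 2L * spec$n_per_group)
    truth <- list()
    latent <- numeric(0)
    idx <- 1L
    for (group in c("healthy", "patient")) {
      for (s in seq_len(spec$n_per_group)) {
        id <- sprintf("%s%02d", if (group == "healthy") "H" else "P", s)
        meta <- NULL
        ratio <- spec$effect_size
        jit <- NULL
        if (group == "patient" && !is.null(severity)) {
          u <- stats::runif(1)
          latent[id] <- u
          v <- severity$severity_link(u)
          # severity grades both burst attenuation and latency jitter
          # between a half-strength deficit (v = 0) and the full
          # effect (v = 1)
          ratio <- 1 - (1 - spec$effect_size) * (0.5 + 0.5 * v)
          jit <- spec$latency_jitter[["healthy"]] +
            (spec$latency_jitter[["patient"]] -
               spec$latency_jitter[["healthy"]]) * v
          meta <- draw_severity_record(severity, u)
        }
        rec <- simulate_recording(spec, id, group, ratio, meta,
                                  jitter_sd = jit)
        art <- inject_artifacts(rec, spec$artifact_rates, seed = NULL)
        rec <- art$recording
        rec$signal <- as_float32(rec$signal)
        recs[[idx]] <- rec
        if (nrow(art$truth)) truth[[length(truth) + 1L]] <- art$truth
        idx <- idx + 1L
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(subject_id = character(0), p_index = integer(0),
                 event_row = integer(0), type = character(0))
    structure(recs, artifact_truth = truth,
              latent_severity = if (length(latent)) latent else NULL)
  })
}

#' Inject artifacts into a recording with a ground-truth table
#'
#' Contaminates the predictive ("P") epochs independently per artifact
#' type: `blink` (300 ms raised-cosine deflection, 300 uV on VEOG,
#' scaled frontally on EEG channels — strong enough that a blink the
#' ICA stage fails to remove trips the 75 uV amplitude exclusion on
#' Fp/AF sites), `saccade` (smoothed ~55 uV step on HEOG), `miss`
#' (the button press is deleted), and `large_amplitude` (a 150 ms,
#' 120 uV bump on one random EEG channel).
#'
#' @param rec an [recording()].
#' @param rates named per-epoch probabilities
#'   `c(blink =, saccade =, miss =, large_amplitude =)`.
#' @param seed integer seed, or `NULL` to draw from the current stream
#'   (as [generate_cohort()] does).
#' @param eog_labels the two EOG channel labels.
#' @return `list(recording =, truth =)` where `truth` has one row per
#'   contamination: subject_id, p_index (ordinal among "P" events),
#'   event_row (row in the event table), type.
#' @export
inject_artifacts <- function(rec, rates, seed = NULL,
                             eog_labels = c("VEOG", "HEOG")) {
  validate_recording(rec)
  with_seed(seed, {
    fs <- rec$fs
    n <- ncol(rec$signal)
    p_rows <- which(rec$events$code == "P")
    eeg_idx <- which(!(rec$channel_labels %in% eog_labels))
    truth <- list()
    pre <- ms_to_samples(200, fs)
    ep_len <- ms_to_samples(1200, fs)
    for (i in seq_along(p_rows)) {
      onset <- rec$events$onset_sample[p_rows[i]] + 1L
      ep_start <- onset - pre
      hit <- stats::runif(4) < rates[c("blink", "saccade", "miss",
                                       "large_amplitude")]
      if (hit[1]) {  # blink
        len <- ms_to_samples(300, fs)
        at <- ep_start + sample.int(ep_len - len, 1)
        idx <- at:(at + len - 1)
        idx <- idx[idx >= 1 & idx <= n]
        wave <- 300 * 0.5 * (1 - cos(2 * pi * seq_along(idx) / len))
        for (ch in seq_along(rec$channel_labels)) {
          w <- blink_weight(rec$channel_labels[ch])
          if (w > 0) rec$signal[ch, idx] <- rec$signal[ch, idx] + w * wave
        }
        truth[[length(truth) + 1L]] <-
          data.frame(subject_id = rec$subject_id, p_index = i,
                     event_row = p_rows[i], type = "blink")
      }
      if (hit[2]) {  # saccade: smoothed step on HEOG
        at <- ep_start + sample.int(ep_len - ms_to_samples(500, fs), 1)
        trans <- ms_to_samples(40, fs)
        plateau <- ms_to_samples(400, fs)
        prof <- c(0.5 * (1 - cos(pi * seq_len(trans) / trans)),
                  rep(1, plateau),
                  0.5 * (1 + cos(pi * seq_len(trans) / trans)))
        idx <- at:(at + length(prof) - 1)
        keep <- idx >= 1 & idx <= n
        amp <- 55 * sample(c(-1, 1), 1)
        h <- match("HEOG", rec$channel_labels)
        rec$signal[h, idx[keep]] <- rec$signal[h, idx[keep]] +
          amp * prof[keep]
        truth[[length(truth) + 1L]] <-
          data.frame(subject_id = rec$subject_id, p_index = i,
                     event_row = p_rows[i], type = "saccade")
      }
      if (hit[3]) {  # miss
        rec$events$response_sample[p_rows[i]] <- NA_integer_
        truth[[length(truth) + 1L]] <-
          data.frame(subject_id = rec$subject_id, p_index = i,
                     event_row = p_rows[i], type = "miss")
      }
      if (hit[4]) {  # large amplitude
        len <- ms_to_samples(150, fs)
        at <- ep_start + sample.int(ep_len - len, 1)
        idx <- at:(at + len - 1)
        idx <- idx[idx >= 1 & idx <= n]
        ch <- sample(eeg_idx, 1)
        rec$signal[ch, idx] <- rec$signal[ch, idx] +
          120 * sin(pi * seq_along(idx) / length(idx))
        truth[[length(truth) + 1L]] <-
          data.frame(subject_id = rec$subject_id, p_index = i,
                     event_row = p_rows[i], type = "large_amplitude")
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(subject_id = character(0), p_index = integer(0),
                 event_row = integer(0), type = character(0))
    list(recording = rec, truth = truth)
  })
}
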