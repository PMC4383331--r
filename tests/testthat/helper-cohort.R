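# Shared fixture builders.  Everything is generated in code at test
# time; no stored data.

# Small cohort spec with artifacts off and a single effect window,
# overridable field by field.
quiet_spec <- function(...) {
  args <- list(
    n_per_group = 6,
    channel_labels = c("F2", "FC3", "Cz", "Pz"),
    effect_channels = c("F2", "FC3"),
    effect_band = c(15, 20),
    effect_windows = list(c(200, 300)),
    n_stimuli_per_block = 18,
    artifact_rates = c(blink = 0, saccade = 0, miss = 0,
                       large_amplitude = 0),
    seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_spec, args)
}

# Hand-built epoch_set: one EEG channel ("F2") plus EOG labels, with a
# Gaussian energy bump at the given peak latency (ms) per event.
# Gives the latency baselines and feature extraction a fully
# controlled input.
make_epoch_set <- function(subject_id, group, peaks_ms, fs = 256,
                           amplitude = 5, noise_sd = 0.01, width_ms = 40) {
  pre <- round(0.2 * fs)
  len <- round(1.2 * fs)
  t_ms <- (seq_len(len) - 1 - pre) / fs * 1000
  labs <- c("F2", "VEOG", "HEOG")
  data <- array(stats::rnorm(length(labs) * len * length(peaks_ms),
                             0, noise_sd),
                c(length(labs), len, length(peaks_ms)),
                dimnames = list(labs, NULL, NULL))
  for (j in seq_along(peaks_ms)) {
    data["F2", , j] <- data["F2", , j] +
      amplitude * exp(-(t_ms - peaks_ms[j])^2 / (2 * width_ms^2))
  }
  structure(
    list(subject_id = subject_id, group = group, channel_labels = labs,
         fs = fs, t_ms = t_ms, data = data,
         event_index = seq_along(peaks_ms),
         n_events_total = length(peaks_ms),
         exclusion_log = data.frame(subject_id = character(0),
                                    event_index = integer(0),
                                    reason = character(0))),
    class = "epoch_set")
}

# Exhaustive KNN-LOO reimplementation used as the classifier oracle:
# nested loops, explicit sort, independent of the package's vote code.
naive_loo <- function(X, labels, K) {
  n <- nrow(X)
  lab <- as.character(labels)
  pred <- character(n)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    d[i] <- Inf
    nn <- order(d)[seq_len(K)]
    n_pat <- 0
    for (m in nn) if (lab[m] == "patient") n_pat <- n_pat + 1
    pred[i] <- if (2 * n_pat > K) "patient"
      else if (2 * n_pat < K) "healthy"
      else lab[nn[1]]
  }
  pred
}

# Expected exclusion log from a generator truth table under the
# documented precedence miss -> saccade -> amplitude.
expected_exclusions <- function(truth) {
  prec <- c(miss = 1, saccade = 2, large_amplitude = 3)
  keep <- truth[truth$type %in% names(prec), , drop = FALSE]
  if (!nrow(keep))
    return(data.frame(subject_id = character(0), event_index = integer(0),
                      reason = character(0)))
  out <- do.call(rbind, lapply(
    split(keep, paste(keep$subject_id, keep$p_index)),
    function(d) d[which.min(prec[d$type]), ]))
  out$reason <- c(miss = "miss", saccade = "saccade",
                  large_amplitude = "amplitude")[out$type]
  out <- data.frame(subject_id = out$subject_id,
                    event_index = out$p_index, reason = out$reason)
  out[order(out$subject_id, out$event_index), ]
}
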