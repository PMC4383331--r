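# Cohort generator contracts.

test_that("cohort generation is deterministic and single-precision exact", {
  spec <- quiet_spec(n_per_group = 2, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(lapply(a, `[[`, "signal"), lapply(b, `[[`, "signal"))
  expect_identical(lapply(a, `[[`, "events"), lapply(b, `[[`, "events"))
  expect_identical(sapply(a, `[[`, "subject_id"),
                   c("H01", "H02", "P01", "P02"))
  expect_identical(sapply(a, `[[`, "group"),
                   rep(c("healthy", "patient"), each = 2))
  # signals are exactly representable in float32 (fixture precision)
  expect_identical(a[[1]]$signal, tffo:::as_float32(a[[1]]$signal))
})

test_that("artifact injection: identity, saturation, and miss recount", {
  rec <- generate_cohort(quiet_spec(n_per_group = 2, seed = 3))[[1]]
  zero <- c(blink = 0, saccade = 0, miss = 0, large_amplitude = 0)

  out0 <- inject_artifacts(rec, zero, seed = 5)
  expect_identical(out0$recording$signal, rec$signal)
  expect_identical(out0$recording$events, rec$events)
  expect_equal(nrow(out0$truth), 0)

  sat <- inject_artifacts(rec, c(blink = 0, saccade = 0, miss = 0,
                                 large_amplitude = 1), seed = 5)
  n_p <- sum(rec$events$code == "P")
  expect_equal(sum(sat$truth$type == "large_amplitude"), n_p)
  expect_setequal(sat$truth$p_index, seq_len(n_p))

  miss <- inject_artifacts(rec, c(blink = 0, saccade = 0, miss = 0.3,
                                  large_amplitude = 0), seed = 11)
  p_rows <- which(miss$recording$events$code == "P")
  n_removed <- sum(is.na(miss$recording$events$response_sample[p_rows])) -
    sum(is.na(rec$events$response_sample[p_rows]))
  expect_equal(n_removed, sum(miss$truth$type == "miss"))
})

test_that("injected group contrast matches the closed-form amplitude ratio", {
  # no jitter, no habituation, near-zero noise: the patient/healthy
  # ratio of mean Stockwell magnitude in the effect region equals
  # effect_size by linearity
  spec <- quiet_spec(n_per_group = 10, n_stimuli_per_block = 30,
                     effect_size = 0.4,
                     latency_jitter = c(healthy = 0, patient = 0),
                     habituation_tau = 1e9, erp_amplitude = 0,
                     noise_model = list(exponent = 1, pink_sd = 0.2,
                                        white_sd = 0.05),
                     seed = 21)
  coh <- generate_cohort(spec)
  grp <- vapply(coh, `[[`, "", "group")
  mags <- vapply(coh, function(rec) {
    es <- epoch_and_exclude(bandpass_normalize(rec, normalize = "none"))
    avg <- rowMeans(es$data[match("F2", es$channel_labels), , ], dims = 1)
    st <- stockwell(avg, rec$fs, t0_ms = -200, f_max = 31)
    mean(st$magnitudes[st$time_axis >= 200 & st$time_axis <= 300,
                       st$freq_axis >= 15 & st$freq_axis <= 20])
  }, 0)
  ratio <- mean(mags[grp == "patient"]) / mean(mags[grp == "healthy"])
  expect_lt(abs(ratio / 0.4 - 1), 0.10)
})

test_that("background spectrum follows the configured 1/f model", {
  spec <- quiet_spec(n_per_group = 2, n_stimuli_per_block = 78,
                     evoked_amplitude = 0, erp_amplitude = 0,
                     noise_model = list(exponent = 1, pink_sd = 4,
                                        white_sd = 0),
                     seed = 22)
  x <- generate_cohort(spec)[[1]]$signal[1, ]
  expect_gt(length(x) / 512, 60)  # >= 60 s of signal
  sp <- stats::spec.pgram(stats::ts(x, frequency = 512),
                          spans = c(31, 31), taper = 0.1, plot = FALSE)
  sel <- sp$freq >= 1 & sp$freq <= 30
  slope <- unname(stats::coef(stats::lm(log(sp$spec[sel]) ~
                                          log(sp$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("group difference is confined to effect channels, band and windows", {
  spec <- quiet_spec(n_per_group = 12, n_stimuli_per_block = 78,
                     effect_size = 0.4, seed = 1)
  coh <- generate_cohort(spec)
  grp <- vapply(coh, `[[`, "", "group")
  pows <- vapply(coh, function(rec) {
    es <- epoch_and_exclude(bandpass_normalize(rec, normalize = "none"))
    res <- c(off_channel = 0, off_band = 0, off_window = 0)
    nj <- dim(es$data)[3]
    for (j in seq_len(nj)) {
      stF <- stockwell(es$data[match("F2", es$channel_labels), , j],
                       es$fs, t0_ms = -200, f_max = 31)
      stC <- stockwell(es$data[match("Cz", es$channel_labels), , j],
                       es$fs, t0_ms = -200, f_max = 31)
      fa <- stF$freq_axis; ta <- stF$time_axis
      res <- res + c(
        mean(stC$magnitudes[, fa >= 1 & fa <= 30]^2),
        mean(stF$magnitudes[, (fa >= 1 & fa <= 13) |
                              (fa >= 22 & fa <= 30)]^2),
        mean(stF$magnitudes[ta <= 100 | ta >= 450,
                            fa >= 15 & fa <= 20]^2))
    }
    res / nj
  }, numeric(3))
  ratios <- rowMeans(pows[, grp == "patient"]) /
    rowMeans(pows[, grp == "healthy"])
  expect_true(all(abs(ratios - 1) < 0.05),
              info = paste(round(ratios, 4), collapse = " "))
})

test_that("evoked amplitude habituates at the configured rate", {
  spec <- quiet_spec(n_per_group = 2, n_stimuli_per_block = 30,
                     habituation_tau = 3,
                     latency_jitter = c(healthy = 0, patient = 0),
                     erp_amplitude = 0,
                     noise_model = list(exponent = 1, pink_sd = 0.1,
                                        white_sd = 0.02),
                     seed = 23)
  rec <- bandpass_normalize(generate_cohort(spec)[[1]], normalize = "none")
  es <- epoch_and_exclude(rec)
  tt <- which(es$t_ms >= 200 & es$t_ms <= 300)
  amps <- vapply(1:8, function(j)
    sqrt(mean(es$data[match("F2", es$channel_labels), tt, j]^2)), 0)
  tau_hat <- -1 / unname(stats::coef(stats::lm(log(amps) ~ seq_len(8)))[2])
  expect_lt(abs(tau_hat / 3 - 1), 0.25)
})

test_that("severity model yields valid, severity-linked patient metadata", {
  spec <- quiet_spec(n_per_group = 12, seed = 4)
  coh <- generate_cohort(spec, severity = severity_model())
  patients <- Filter(function(r) r$group == "patient", coh)
  latent <- attr(coh, "latent_severity")
  expect_length(latent, 12)
  hosp <- vapply(patients, function(r) r$metadata$hospitalizations, 0)
  sans <- vapply(patients, function(r) r$metadata$sans, 0)
  expect_true(all(hosp >= 1))
  expect_true(all(vapply(patients, function(r)
    all(unlist(r$metadata) >= 0), TRUE)))
  # covariates track the latent severity
  expect_gt(stats::cor(latent[vapply(patients, `[[`, "", "subject_id")],
                       sans, method = "spearman"), 0.5)
  # healthy subjects carry no metadata
  expect_true(all(vapply(Filter(function(r) r$group == "healthy", coh),
                         function(r) is.null(r$metadata), TRUE)))
})

test_that("invalid cohort specs are rejected with the violated invariant", {
  expect_error(quiet_spec(n_per_group = 1), "n_per_group")
  expect_error(quiet_spec(fs = 30), "fs")
  expect_error(quiet_spec(effect_windows = list(c(900, 1300))),
               "effect_window")
  expect_error(quiet_spec(artifact_rates = c(blink = 1.2, saccade = 0,
                                             miss = 0,
                                             large_amplitude = 0)),
               "artifact_rates")
  expect_error(quiet_spec(effect_channels = "XX"), "effect_channels")
})
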