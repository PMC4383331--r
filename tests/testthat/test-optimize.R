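# Grid search, marginals, argmax tie-breaks, early/late profiles.

grid_fixture <- function() {
  spec <- quiet_spec(n_per_group = 5, n_stimuli_per_block = 18,
                     effect_size = 0.4, seed = 41)
  preprocess_cohort(generate_cohort(spec))
}

test_that("a degenerate one-coordinate grid equals a direct loo_cv call", {
  eps <- grid_fixture()
  w <- window_spec(200, 300, 15, 20)
  gr <- run_grid(eps, electrodes = "F2", windows = list(w),
                 n_events = 4, K = 2)
  expect_equal(nrow(gr$cells), 1)
  fe <- extract_features(eps, w, "F2", 4)
  cv <- loo_cv(fe, 2)
  expect_equal(gr$cells$accuracy, cv$accuracy)
  expect_equal(gr$cells$specificity, cv$specificity)
  expect_equal(gr$cells$sensitivity, cv$sensitivity)
})

test_that("every cell of a 2x2x2x2 grid matches an independent recomputation", {
  eps <- grid_fixture()
  wins <- list(window_spec(150, 300, 14, 21), window_spec(500, 700, 2, 8))
  gr <- run_grid(eps, electrodes = c("F2", "Cz"), windows = wins,
                 n_events = c(4, 6), K = c(1, 2))
  expect_equal(nrow(gr$cells), 16)
  for (r in seq_len(nrow(gr$cells))) {
    cell <- gr$cells[r, ]
    w <- window_spec(cell$t_start, cell$t_end, cell$f_low, cell$f_high)
    fe <- extract_features(eps, w, cell$electrode, cell$n_events)
    cv <- loo_cv(fe, cell$K)
    expect_equal(cell$accuracy, cv$accuracy)
    expect_equal(cell$sensitivity, cv$sensitivity)
  }
})

test_that("grid cells are independent of evaluation order and K bounds hold", {
  eps <- grid_fixture()
  wins <- list(window_spec(150, 300, 14, 21), window_spec(500, 700, 2, 8))
  gr1 <- run_grid(eps, electrodes = c("F2", "Cz"), windows = wins,
                  n_events = c(4, 6), K = c(1, 2))
  gr2 <- run_grid(eps, electrodes = c("Cz", "F2"), windows = rev(wins),
                  n_events = c(6, 4), K = c(2, 1))
  key <- function(g) {
    d <- g$cells
    d <- d[order(d$electrode, d$t_start, d$f_low, d$n_events, d$K), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(gr1), key(gr2))
  # K beyond floor(n_events/2) is an invalid cell, not a wrong number
  gr3 <- run_grid(eps, electrodes = "F2", windows = wins[1],
                  n_events = 4, K = c(2, 3))
  expect_true(is.na(gr3$cells$accuracy[gr3$cells$K == 3]))
  expect_false(is.na(gr3$cells$accuracy[gr3$cells$K == 2]))
  expect_error(run_grid(eps, electrodes = "XX", windows = wins,
                        n_events = 4), "XX")
})

test_that("marginals aggregate correctly and conserve the global maximum", {
  eps <- grid_fixture()
  wins <- list(window_spec(150, 300, 14, 21), window_spec(500, 700, 2, 8))
  gr <- run_grid(eps, electrodes = c("F2", "Cz"), windows = wins,
                 n_events = c(4, 6), K = c(1, 2))
  for (dim_ in c("electrode", "time_window", "freq_band", "n_events",
                 "K")) {
    m <- marginal(gr, dim_)
    expect_equal(max(m$best_accuracy),
                 max(gr$cells$accuracy, na.rm = TRUE))
    expect_equal(sum(m$n_cells), sum(!is.na(gr$cells$accuracy)))
  }
  # constant-accuracy grid: all marginal means equal that constant
  gr_const <- gr
  gr_const$cells$accuracy <- 0.75
  m <- marginal(gr_const, "electrode")
  expect_true(all(m$mean_accuracy == 0.75))
  # single-cell grid: marginal equals the cell
  gr1 <- run_grid(eps, "F2", wins[1], 4, K = 1)
  m1 <- marginal(gr1, "n_events")
  expect_equal(m1$mean_accuracy, gr1$cells$accuracy)
  expect_error(marginal(gr, "voltage"), "arg")
})

test_that("argmax ties resolve by window start, band, events, K, electrode", {
  cells <- expand.grid(electrode = c("Cz", "F2"), t_start = c(100, 200),
                       f_low = c(5, 15), n_events = c(4, 8), K = c(1, 2),
                       stringsAsFactors = FALSE)
  cells$t_end <- cells$t_start + 100
  cells$f_high <- cells$f_low + 5
  cells$n_subjects <- 10
  cells$accuracy <- 0.9
  cells$specificity <- cells$sensitivity <- 0.9
  gr <- structure(list(cells = cells,
                       axes = list(electrodes = c("F2", "Cz"),
                                   windows = list(), n_events = c(4, 8),
                                   K = 1:2)),
                  class = "grid_result")
  top <- top_cell(gr)
  expect_equal(top$t_start, 100)
  expect_equal(top$f_low, 5)
  expect_equal(top$n_events, 4)
  expect_equal(top$K, 1)
  expect_equal(top$electrode, "F2")    # axis order breaks the last tie
})

test_that("early/late profiles expose habituation and its absence", {
  base <- list(n_per_group = 4, n_stimuli_per_block = 45,
               latency_jitter = c(healthy = 0, patient = 0),
               noise_model = list(exponent = 1, pink_sd = 0.05,
                                  white_sd = 0.01))
  # habituating cohort: late-trial evoked amplitude collapses
  eps_hab <- preprocess_cohort(generate_cohort(
    do.call(quiet_spec, c(base, list(habituation_tau = 3, seed = 51)))))
  prof <- early_late_profile(eps_hab, n_early = 5, n_late = 5,
                             electrode = "F2")
  peak <- function(p, grp, sub)
    max(abs(p$amplitude[p$group == grp & p$subset == sub &
                          p$t_ms > 0 & p$t_ms < 500]))
  expect_lt(peak(prof, "healthy", "late"),
            0.25 * peak(prof, "healthy", "early"))
  # no habituation: early and late responses are equivalent
  eps_flat <- preprocess_cohort(generate_cohort(
    do.call(quiet_spec, c(base, list(habituation_tau = 1e9, seed = 52)))))
  prof_flat <- early_late_profile(eps_flat, electrode = "F2")
  expect_lt(abs(peak(prof_flat, "healthy", "early") /
                  peak(prof_flat, "healthy", "late") - 1), 0.05)
  # deterministic under fixed inputs
  expect_identical(prof, early_late_profile(eps_hab, 5, 5, "F2"))
  expect_error(early_late_profile(eps_hab, n_early = 20, n_late = 20),
               "surviving trials")
})
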