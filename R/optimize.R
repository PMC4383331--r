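# Exhaustive enumeration of (electrode x time window x band x
# n_events x K) with LOO-KNN metrics per cell, plus the per-dimension
# marginal analyses (electrode ranking, event-count curve, window
# curve, band curve).

#' Populate the cross-validated parameter grid
#'
#' Computes a LOO-KNN [loo_cv()]-equivalent result for every coordinate
#' of the declared axes.  One Stockwell transform is computed per
#' (subject, electrode, n_events) and every window then slices the same
#' magnitude map, so cells are mutually independent and the result is
#' identical under any evaluation order.  Cells whose K exceeds the
#' legal bound `floor(n_events / 2)` (or `n - 1`) carry `NA` metrics.
#'
#' @param epoch_sets list of `"epoch_set"` objects.
#' @param electrodes channel labels to scan; all must be present.
#' @param windows list of [window_spec()] (e.g. [enumerate_windows()]).
#' @param n_events event counts to scan.
#' @param K neighbour counts to scan; default `1..floor(max(n_events)/2)`.
#' @param kernel,mode passed to [extract_features()].
#' @return an object of class `"grid_result"`: `cells` (one row per
#'   coordinate: electrode, t_start, t_end, f_low, f_high, n_events, K,
#'   n_subjects, accuracy, specificity, sensitivity) and `axes`.
#' @export
run_grid <- function(epoch_sets, electrodes, windows, n_events,
                     K = NULL, kernel = c("paper", "classic"),
                     mode = "average-then-transform") {
  kernel <- match.arg(kernel)
  if (!length(electrodes) || !length(windows) || !length(n_events))
    stop_config("run_grid: empty axis")
  for (es in epoch_sets) {
    missing_ch <- setdiff(electrodes, es$channel_labels)
    if (length(missing_ch))
      stop_config("run_grid: electrode(s) %s absent for subject %s",
                  paste(missing_ch, collapse = ", "), es$subject_id)
  }
  if (is.null(K)) K <- seq_len(max(1L, floor(max(n_events) / 2)))
  f_max <- max(vapply(windows, `[[`, 0, "f_high"))

  rows <- vector("list",
                 length(electrodes) * length(windows) * length(n_events) *
                   length(K))
  ri <- 1L
  for (el in electrodes) {
    for (ne in sort(n_events)) {
      have <- vapply(epoch_sets, function(es) dim(es$data)[3] >= ne, TRUE)
      sets <- epoch_sets[have]
      labels <- factor(vapply(sets, `[[`, "", "group"),
                       levels = c("healthy", "patient"))
      n <- length(sets)
      # one transform per subject; all windows slice this map
      maps <- vector("list", n)
      for (s in seq_len(n)) {
        es <- sets[[s]]
        ch <- match(el, es$channel_labels)
        if (mode == "average-then-transform") {
          avg <- rowMeans(es$data[ch, , seq_len(ne), drop = FALSE],
                          dims = 2)
          st <- stockwell(as.vector(avg), es$fs, t0_ms = es$t_ms[1],
                          kernel = kernel, f_max = f_max)
          maps[[s]] <- st$magnitudes
        } else {
          acc <- NULL
          for (j in seq_len(ne)) {
            st <- stockwell(es$data[ch, , j], es$fs, t0_ms = es$t_ms[1],
                            kernel = kernel, f_max = f_max)
            acc <- if (is.null(acc)) st$magnitudes else acc + st$magnitudes
          }
          maps[[s]] <- acc / ne
        }
        if (s == 1L) {
          time_axis <- st$time_axis
          freq_axis <- st$freq_axis
        }
      }
      n_t <- length(time_axis)
      big <- t(vapply(maps, as.vector, numeric(n_t * length(freq_axis))))
      k_max <- min(floor(ne / 2), n - 1L)
      classes_ok <- all(table(labels) >= 2)
      for (w in windows) {
        t_idx <- which(time_axis >= w$t_start & time_axis <= w$t_end)
        f_idx <- which(freq_axis >= w$f_low & freq_axis <= w$f_high)
        cols <- as.vector(outer(t_idx, (f_idx - 1L) * n_t, `+`))
        D <- as.matrix(stats::dist(big[, cols, drop = FALSE]))
        K_ok <- K[K >= 1 & K <= k_max]
        acc_v <- spec_v <- sens_v <- rep(NA_real_, length(K))
        if (length(K_ok) && classes_ok) {
          preds <- loo_predict_multi_k(D, labels, K_ok)
          for (j in seq_along(K_ok)) {
            pos <- match(K_ok[j], K)
            pred <- preds[, j]
            acc_v[pos] <- mean(pred == as.character(labels))
            spec_v[pos] <- sum(pred == "healthy" & labels == "healthy") /
              sum(labels == "healthy")
            sens_v[pos] <- sum(pred == "patient" & labels == "patient") /
              sum(labels == "patient")
          }
        }
        rows[[ri]] <- data.frame(
          electrode = el, t_start = w$t_start, t_end = w$t_end,
          f_low = w$f_low, f_high = w$f_high, n_events = ne, K = K,
          n_subjects = n, accuracy = acc_v, specificity = spec_v,
          sensitivity = sens_v)
        ri <- ri + 1L
      }
    }
  }
  structure(list(cells = do.call(rbind, rows),
                 axes = list(electrodes = electrodes, windows = windows,
                             n_events = sort(n_events), K = K)),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d cells over %d electrodes x %d windows x %d event counts x %d K\n",
              nrow(x$cells), length(x$axes$electrodes),
              length(x$axes$windows), length(x$axes$n_events),
              length(x$axes$K)))
  invisible(x)
}

#' Marginal accuracy along one grid dimension
#'
#' For every value of the chosen dimension, the mean and maximum
#' accuracy over all other dimensions (`NA` cells excluded) — the
#' electrode ranking, event-count curve, time-window curve and
#' frequency-band curve of the methodology.
#'
#' @param gr a `"grid_result"`.
#' @param dimension one of `"electrode"`, `"time_window"`,
#'   `"freq_band"`, `"n_events"`, `"K"`.
#' @return data frame of dimension value(s), `mean_accuracy`,
#'   `best_accuracy`, `n_cells`.
#' @export
marginal <- function(gr, dimension = c("electrode", "time_window",
                                       "freq_band", "n_events", "K")) {
  dimension <- match.arg(dimension)
  cells <- gr$cells[!is.na(gr$cells$accuracy), , drop = FALSE]
  key_cols <- switch(dimension,
                     electrode = "electrode",
                     time_window = c("t_start", "t_end"),
                     freq_band = c("f_low", "f_high"),
                     n_events = "n_events",
                     K = "K")
  key <- interaction(cells[key_cols], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(cells, key), function(d) {
    cbind(d[1, key_cols, drop = FALSE],
          data.frame(mean_accuracy = mean(d$accuracy),
                     best_accuracy = max(d$accuracy),
                     n_cells = nrow(d)))
  })
  out <- do.call(rbind, agg)
  ord <- do.call(order, out[key_cols])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-performing grid cell
#'
#' The maximum-accuracy cell; ties resolved deterministically by
#' earliest window start, lowest band, fewest events, smallest K, then
#' electrode axis order.
#'
#' @param gr a `"grid_result"`.
#' @return one-row data frame.
#' @export
top_cell <- function(gr) {
  cells <- gr$cells[!is.na(gr$cells$accuracy), , drop = FALSE]
  if (!nrow(cells)) stop_config("top_cell: no valid cells")
  el_rank <- match(cells$electrode, gr$axes$electrodes)
  ord <- order(-cells$accuracy, cells$t_start, cells$f_low,
               cells$n_events, cells$K, el_rank)
  cells[ord[1], , drop = FALSE]
}

#' Early/late trial response profile
#'
#' Group-averaged epoch waveforms over the first `n_early`, the last
#' `n_late`, and all surviving trials — the habituation picture behind
#' the event-count analysis.  Subjects with fewer than
#' `n_early + n_late` surviving trials are skipped and listed in
#' `attr(, "skipped")`.
#'
#' @param epoch_sets list of `"epoch_set"` objects.
#' @param n_early,n_late trial counts defining the early and late sets.
#' @param electrode channel label, or `NULL` to average over all
#'   non-EOG channels.
#' @return long data frame: group, subset (early/late/all), t_ms,
#'   amplitude (uV on the epoch scale).
#' @export
early_late_profile <- function(epoch_sets, n_early = 5, n_late = 5,
                               electrode = NULL) {
  acc <- list(); skipped <- character(0)
  for (es in epoch_sets) {
    n_avail <- dim(es$data)[3]
    if (n_avail < n_early + n_late) {
      skipped <- c(skipped, es$subject_id)
      next
    }
    ch <- if (is.null(electrode))
      which(!(es$channel_labels %in% c("VEOG", "HEOG")))
    else match(electrode, es$channel_labels)
    tr <- function(idx) {
      m <- es$data[ch, , idx, drop = FALSE]
      apply(m, 2, mean)
    }
    acc[[length(acc) + 1L]] <- data.frame(
      group = es$group, t_ms = rep(es$t_ms, 3),
      subset = rep(c("early", "late", "all"), each = length(es$t_ms)),
      amplitude = c(tr(seq_len(n_early)),
                    tr(seq(n_avail - n_late + 1, n_avail)),
                    tr(seq_len(n_avail))))
  }
  if (!length(acc))
    stop_config("early_late_profile: no subject has %d surviving trials",
                n_early + n_late)
  all_df <- do.call(rbind, acc)
  out <- stats::aggregate(amplitude ~ group + subset + t_ms, all_df, mean)
  out <- out[order(out$group, out$subset, out$t_ms), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
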