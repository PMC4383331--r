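# Latency-based comparison methods sharing the preprocessing and CV
# machinery: PE-Latency (k-means on mean peak-energy latency) and
# P300-RF-Latency (KNN-LOO on the histogram of peak-energy latencies
# in the P300 range).

# Per-event peak-energy latency (ms) within a search window at one
# electrode.  Energy is the squared band-passed amplitude; the peak is
# the argmax sample, ties to earliest.
peak_energy_latencies <- function(es, electrode, window = c(0, 1000)) {
  ch <- match(electrode, es$channel_labels)
  if (is.na(ch))
    stop_config("electrode '%s' absent for subject %s", electrode,
                es$subject_id)
  sel <- which(es$t_ms >= window[1] & es$t_ms <= window[2])
  n_ev <- dim(es$data)[3]
  vapply(seq_len(n_ev), function(j) {
    e <- es$data[ch, sel, j]^2
    es$t_ms[sel[which.max(e)]]
  }, 0)
}

#' PE-Latency baseline: k-means on mean peak-energy latency
#'
#' Each subject is summarized by the mean latency of peak instantaneous
#' energy over surviving events; subjects are split by 2-means
#' clustering and clusters mapped to group labels by majority.
#'
#' @param epoch_sets list of `"epoch_set"` objects.
#' @param electrode channel label.
#' @param window `c(start, end)` ms search window for the energy peak.
#' @param n_clusters number of clusters (2 for the two-group problem).
#' @param seed seed for the k-means start.
#' @return a `"tffo_cv"` result (accuracy, specificity, sensitivity);
#'   the distance score column holds each subject's distance to its
#'   cluster centre.
#' @export
pe_latency_classify <- function(epoch_sets, electrode,
                                window = c(0, 1000), n_clusters = 2,
                                seed = 1) {
  lat <- vapply(epoch_sets, function(es)
    mean(peak_energy_latencies(es, electrode, window)), 0)
  labels <- factor(vapply(epoch_sets, `[[`, "", "group"),
                   levels = c("healthy", "patient"))
  if (any(table(labels) < 2))
    stop_config("pe_latency_classify: each class needs >= 2 subjects")
  if (stats::var(lat) == 0)
    stop_config("pe_latency_classify: degenerate (all-equal) latencies")
  km <- with_seed(seed, stats::kmeans(matrix(lat, ncol = 1),
                                      centers = n_clusters, nstart = 10))
  # map clusters to labels by majority membership
  pred <- character(length(lat))
  for (cl in seq_len(n_clusters)) {
    members <- which(km$cluster == cl)
    tab <- table(labels[members])
    pred[members] <- names(tab)[which.max(tab)]
  }
  score <- abs(lat - km$centers[km$cluster])
  cv_result(labels, pred, score,
            vapply(epoch_sets, `[[`, "", "subject_id"), K = NA_integer_)
}

#' P300-RF-Latency baseline: KNN-LOO on latency histograms
#'
#' Replaces the time-frequency features with each subject's histogram
#' (10 fixed bins) of per-event peak-energy latencies inside the P300
#' window, then runs the identical [loo_cv()] pipeline.
#'
#' @param epoch_sets list of `"epoch_set"` objects.
#' @param electrode channel label.
#' @param p300_window `c(start, end)` ms; default 250-500 ms, the
#'   conventional P300 latency range.
#' @param K voting neighbours for [loo_cv()].
#' @param n_bins histogram bins over the window.
#' @return a `"tffo_cv"` result; the feature object is attached as
#'   `attr(, "features")`.
#' @export
p300_rf_latency_classify <- function(epoch_sets, electrode,
                                     p300_window = c(250, 500), K = 3,
                                     n_bins = 10) {
  breaks <- seq(p300_window[1], p300_window[2], length.out = n_bins + 1)
  rows <- t(vapply(epoch_sets, function(es) {
    lat <- peak_energy_latencies(es, electrode, p300_window)
    tabulate(findInterval(lat, breaks, rightmost.closed = TRUE),
             nbins = n_bins)
  }, numeric(n_bins)))
  feats <- list(features = rows,
                labels = factor(vapply(epoch_sets, `[[`, "", "group"),
                                levels = c("healthy", "patient")),
                subjects = vapply(epoch_sets, `[[`, "", "subject_id"))
  cv <- loo_cv(feats, K)
  attr(cv, "features") <- feats
  cv
}
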