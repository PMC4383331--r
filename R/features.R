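# Windowed time-frequency feature extraction.

#' Specify a time window x frequency band feature region
#'
#' @param t_start,t_end window edges, ms post-stimulus (`t_start <
#'   t_end`).
#' @param f_low,f_high band edges, Hz, within `[0, 30]`.
#' @return a list of class `"window_spec"`.
#' @export
window_spec <- function(t_start, t_end, f_low, f_high) {
  if (!(t_start < t_end))
    stop_config("window_spec: t_start must be < t_end")
  if (!(f_low < f_high))
    stop_config("window_spec: f_low must be < f_high")
  if (f_low < 0 || f_high > 30)
    stop_config("window_spec: band must lie within [0, 30] Hz")
  structure(list(t_start = t_start, t_end = t_end, f_low = f_low,
                 f_high = f_high), class = "window_spec")
}

#' Enumerate the sliding window x band grid
#'
#' Builds the full cross product of sliding time windows and sliding
#' frequency bands, each width paired with its step (defaults: 100 ms
#' windows stepped by 25 ms and 500 ms windows stepped by 50 ms; 5 Hz
#' bands stepped by 1 Hz and 10 Hz bands stepped by 2 Hz).  Ordering
#' is deterministic: time-major (all widths in the given order, starts
#' ascending), then frequency.
#'
#' @param t_range `c(start, end)` ms of the searchable epoch interval.
#' @param t_widths,t_steps paired time-window widths and steps, ms.
#' @param f_widths,f_steps paired band widths and steps, Hz.
#' @param f_range `c(low, high)` Hz of the searchable band interval.
#' @return list of [window_spec()] objects.
#' @export
enumerate_windows <- function(t_range = c(0, 1000),
                              t_widths = c(100, 500),
                              t_steps = c(25, 50),
                              f_widths = c(5, 10),
                              f_steps = c(1, 2),
                              f_range = c(0, 30)) {
  stopifnot(length(t_widths) == length(t_steps),
            length(f_widths) == length(f_steps))
  if (any(t_widths > diff(t_range)) || any(f_widths > diff(f_range)))
    stop_config("enumerate_windows: width exceeds the searchable span")
  tw <- list()
  for (i in seq_along(t_widths)) {
    for (s in seq(t_range[1], t_range[2] - t_widths[i], by = t_steps[i]))
      tw[[length(tw) + 1L]] <- c(s, s + t_widths[i])
  }
  fb <- list()
  for (i in seq_along(f_widths)) {
    for (s in seq(f_range[1], f_range[2] - f_widths[i], by = f_steps[i]))
      fb[[length(fb) + 1L]] <- c(s, s + f_widths[i])
  }
  out <- vector("list", length(tw) * length(fb))
  idx <- 1L
  for (t in tw) for (f in fb) {
    out[[idx]] <- window_spec(t[1], t[2], f[1], f[2])
    idx <- idx + 1L
  }
  out
}

# Indices of the st_map bins falling inside a window_spec (inclusive).
st_window_bins <- function(st, spec) {
  list(t = which(st$time_axis >= spec$t_start & st$time_axis <= spec$t_end),
       f = which(st$freq_axis >= spec$f_low & st$freq_axis <= spec$f_high))
}

# Restrict an st_map magnitude matrix to a window and flatten
# (time-major).
st_restrict <- function(st, spec) {
  b <- st_window_bins(st, spec)
  if (!length(b$t) || !length(b$f))
    stop_config("window [%g, %g] ms x [%g, %g] Hz selects no bins",
                spec$t_start, spec$t_end, spec$f_low, spec$f_high)
  as.vector(st$magnitudes[b$t, b$f, drop = FALSE])
}

#' Extract per-subject Stockwell feature vectors
#'
#' For each subject, takes the FIRST `n_events` surviving epochs in
#' trial order at `electrode`, averages them (default mode), applies
#' [stockwell()], restricts the magnitude map to `spec`, and flattens.
#' Subjects with fewer than `n_events` surviving epochs are dropped and
#' listed in `skipped`.
#'
#' @param epoch_sets list of `"epoch_set"` objects (see
#'   [preprocess_cohort()]).
#' @param spec a [window_spec()].
#' @param electrode channel label.
#' @param n_events number of surviving epochs used per subject.
#' @param mode `"average-then-transform"` (default) or
#'   `"transform-then-average"` (magnitudes averaged across single-trial
#'   transforms).
#' @param kernel passed to [stockwell()].
#' @return a list of class `"tffo_features"`: `features` (subjects x
#'   dims matrix), `labels` (factor healthy/patient), `subjects`,
#'   `skipped`, and provenance fields.
#' @export
extract_features <- function(epoch_sets, spec, electrode, n_events,
                             mode = c("average-then-transform",
                                      "transform-then-average"),
                             kernel = c("paper", "classic")) {
  mode <- match.arg(mode)
  kernel <- match.arg(kernel)
  rows <- list(); labs <- character(0); subj <- character(0)
  skipped <- character(0)
  for (es in epoch_sets) {
    ch <- match(electrode, es$channel_labels)
    if (is.na(ch))
      stop_config("extract_features: electrode '%s' absent for subject %s",
                  electrode, es$subject_id)
    n_avail <- dim(es$data)[3]
    if (n_avail < n_events) {
      skipped <- c(skipped, es$subject_id)
      next
    }
    t0 <- es$t_ms[1]
    if (mode == "average-then-transform") {
      avg <- rowMeans(es$data[ch, , seq_len(n_events), drop = FALSE],
                      dims = 2)
      st <- stockwell(as.vector(avg), es$fs, t0_ms = t0, kernel = kernel,
                      f_max = spec$f_high + 1)
      v <- st_restrict(st, spec)
    } else {
      acc <- NULL
      for (j in seq_len(n_events)) {
        st <- stockwell(es$data[ch, , j], es$fs, t0_ms = t0,
                        kernel = kernel, f_max = spec$f_high + 1)
        vj <- st_restrict(st, spec)
        acc <- if (is.null(acc)) vj else acc + vj
      }
      v <- acc / n_events
    }
    rows[[length(rows) + 1L]] <- v
    labs <- c(labs, es$group)
    subj <- c(subj, es$subject_id)
  }
  if (!length(rows))
    stop_config("extract_features: no subject has %d surviving epochs",
                n_events)
  features <- do.call(rbind, rows)
  rownames(features) <- subj
  structure(list(features = features,
                 labels = factor(labs, levels = c("healthy", "patient")),
                 subjects = subj, skipped = skipped,
                 electrode = electrode, window = spec,
                 n_events = n_events, mode = mode, kernel = kernel),
            class = "tffo_features")
}
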