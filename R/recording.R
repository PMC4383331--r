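#' Construct a continuous EEG recording
#'
#' The core data container: one subject's continuous multi-channel EEG
#' in microvolts, a stimulus/response event table, and optional clinical
#' metadata.  Channel access everywhere in the package is by 10-20
#' label, never by row index.
#'
#' @param subject_id character scalar.
#' @param group one of `"healthy"`, `"patient"`, `"unknown"`.
#' @param channel_labels character vector of montage labels (may include
#'   the EOG channels `"VEOG"`, `"HEOG"`).
#' @param fs sampling rate in Hz.
#' @param signal numeric matrix, channels x samples, in microvolts; row
#'   order matches `channel_labels`.
#' @param events event table: a `data.frame` with columns
#'   `onset_sample` (0-based sample index, strictly increasing), `code`
#'   (opaque stimulus code string; predictive-sequence epochs carry
#'   `"P"`), and `response_sample` (0-based button-press sample or `NA`).
#' @param metadata optional [severity_record()] list (patients) or `NULL`.
#' @param norm_factor internal scale factor applied to the signal by
#'   [bandpass_normalize()]; physical microvolts are `signal / norm_factor`.
#' @return an object of class `"eeg_recording"`.
#' @export
recording <- function(subject_id, group = c("unknown", "healthy", "patient"),
                      channel_labels, fs, signal,
                      events = empty_events(), metadata = NULL,
                      norm_factor = 1) {
  group <- match.arg(group)
  rec <- structure(
    list(subject_id = as.character(subject_id), group = group,
         channel_labels = as.character(channel_labels), fs = fs,
         signal = signal, events = events, metadata = metadata,
         norm_factor = norm_factor),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

#' @rdname recording
#' @export
empty_events <- function() {
  data.frame(onset_sample = integer(0), code = character(0),
             response_sample = integer(0))
}

#' Validate an eeg_recording object
#'
#' Checks the container invariants: label/row agreement, positive
#' sampling rate, event onsets strictly increasing and within the
#' signal, responses after their onsets.
#'
#' @param rec an `"eeg_recording"`.
#' @return `rec`, invisibly; errors name the violated field.
#' @export
validate_recording <- function(rec) {
  if (!is.matrix(rec$signal))
    stop_config("recording '%s': signal must be a channels x samples matrix",
                rec$subject_id)
  if (nrow(rec$signal) != length(rec$channel_labels))
    stop_config("recording '%s': signal has %d rows but %d channel_labels",
                rec$subject_id, nrow(rec$signal), length(rec$channel_labels))
  if (anyDuplicated(rec$channel_labels))
    stop_config("recording '%s': duplicated channel_labels", rec$subject_id)
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0)
    stop_config("recording '%s': fs must be a positive scalar", rec$subject_id)
  ev <- rec$events
  need <- c("onset_sample", "code", "response_sample")
  if (!all(need %in% names(ev)))
    stop_config("recording '%s': events must have columns %s",
                rec$subject_id, paste(need, collapse = ", "))
  n <- ncol(rec$signal)
  if (nrow(ev)) {
    if (any(ev$onset_sample < 0 | ev$onset_sample >= n))
      stop_config("recording '%s': field onset_sample out of range [0, %d)",
                  rec$subject_id, n)
    if (any(diff(ev$onset_sample) <= 0))
      stop_config("recording '%s': field onset_sample not strictly increasing",
                  rec$subject_id)
    resp <- ev$response_sample
    ok <- is.na(resp) | (resp > ev$onset_sample & resp < n)
    if (!all(ok))
      stop_config("recording '%s': field response_sample must be NA or in (onset, n_samples)",
                  rec$subject_id)
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s): %d channels x %d samples @ %g Hz, %d events\n",
              x$subject_id, x$group, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Clinical severity metadata for one patient
#'
#' @param hospitalizations documented hospitalization count (>= 0;
#'   patients by definition have >= 1).
#' @param dose_load medication load, arbitrary units (>= 0).
#' @param saps positive-symptom count (SAPS scale, >= 0).
#' @param sans negative-symptom count (SANS scale, >= 0).
#' @return a named list of class `"severity_record"`.
#' @export
severity_record <- function(hospitalizations, dose_load, saps, sans) {
  vals <- c(hospitalizations = hospitalizations, dose_load = dose_load,
            saps = saps, sans = sans)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_config("severity_record fields must be finite and >= 0")
  structure(list(hospitalizations = hospitalizations, dose_load = dose_load,
                 saps = saps, sans = sans), class = "severity_record")
}

# Fetch one channel (by label) as a numeric vector.
channel_vec <- function(rec, label) {
  i <- match(label, rec$channel_labels)
  if (is.na(i))
    stop_config("channel '%s' not present in recording '%s'", label,
                rec$subject_id)
  rec$signal[i, ]
}
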