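# Recording I/O.
#
# Fixture format (lossless for single-precision data): <base>.dat holds
# the channels x samples matrix as little-endian float32, column-major;
# <base>.json is the sidecar (labels, fs, subject, group, metadata);
# <base>.events.tsv is the event table.  EDF (16-bit) and BDF (24-bit)
# are written with a single data record spanning the whole signal;
# their integer quantization is the documented loss, and events /
# metadata ride in the same sidecar files next to the EDF/BDF.

fixture_paths <- function(path) {
  base <- sub("\\.(dat|json|edf|bdf)$", "", path)
  list(dat = paste0(base, ".dat"), json = paste0(base, ".json"),
       events = paste0(base, ".events.tsv"))
}

write_events_tsv <- function(events, path) {
  ev <- events
  ev$response_sample <- ifelse(is.na(ev$response_sample), "NA",
                               as.character(ev$response_sample))
  utils::write.table(ev, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character",
                                         "character"))
  ev$response_sample <- suppressWarnings(as.integer(ev$response_sample))
  ev
}

#' Write a recording to disk
#'
#' @param rec an [recording()].
#' @param path output basename (extension is added/replaced per format).
#' @param format `"fixture"` (float32 + JSON + TSV, lossless at single
#'   precision), `"edf"` (16-bit) or `"bdf"` (24-bit).
#' @return the main file path, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, format = c("fixture", "edf", "bdf")) {
  format <- match.arg(format)
  validate_recording(rec)
  p <- fixture_paths(path)
  meta <- list(subject_id = rec$subject_id, group = rec$group,
               channel_labels = rec$channel_labels, fs = rec$fs,
               n_samples = ncol(rec$signal), norm_factor = rec$norm_factor,
               metadata = if (is.null(rec$metadata)) NULL else
                 unclass(rec$metadata))
  jsonlite::write_json(meta, p$json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  write_events_tsv(rec$events, p$events)
  if (format == "fixture") {
    con <- file(p$dat, "wb")
    on.exit(close(con))
    writeBin(as.vector(rec$signal), con, size = 4, endian = "little")
    invisible(p$dat)
  } else {
    main <- paste0(sub("\\.(dat|json|edf|bdf)$", "", path), ".", format)
    write_edf_like(rec, main, bits = if (format == "edf") 16L else 24L)
    invisible(main)
  }
}

#' Read a recording from disk
#'
#' Inverse of [write_recording()].  The fixture round trip is bit-exact
#' (signals are stored as float32; the generator emits float32-exact
#' data); EDF/BDF round trips are exact up to one integer quantization
#' step of the stored physical range.
#'
#' @param path path to the `.dat`/`.edf`/`.bdf` file or its basename.
#' @param format `"fixture"`, `"edf"` or `"bdf"`.
#' @return an [recording()].
#' @export
read_recording <- function(path, format = c("fixture", "edf", "bdf")) {
  format <- match.arg(format)
  p <- fixture_paths(path)
  if (!file.exists(p$json))
    stop_config("read_recording: sidecar '%s' not found", p$json)
  meta <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  events <- if (file.exists(p$events)) read_events_tsv(p$events) else
    empty_events()
  if (format == "fixture") {
    if (!file.exists(p$dat))
      stop_config("read_recording: file '%s' not found", p$dat)
    n_ch <- length(meta$channel_labels)
    con <- file(p$dat, "rb")
    on.exit(close(con))
    x <- readBin(con, "double", n = n_ch * meta$n_samples, size = 4,
                 endian = "little")
    if (length(x) != n_ch * meta$n_samples)
      stop_config("read_recording: '%s' truncated (field signal)", p$dat)
    signal <- matrix(x, nrow = n_ch,
                     dimnames = list(meta$channel_labels, NULL))
  } else {
    main <- paste0(sub("\\.(dat|json|edf|bdf)$", "", path), ".", format)
    got <- read_edf_like(main, bits = if (format == "edf") 16L else 24L)
    if (!identical(got$labels, as.character(meta$channel_labels)))
      stop_config("read_recording: '%s' channel labels disagree with sidecar",
                  main)
    signal <- got$signal
    rownames(signal) <- meta$channel_labels
  }
  md <- meta$metadata
  if (!is.null(md) && length(md))
    md <- severity_record(md$hospitalizations, md$dose_load, md$saps,
                          md$sans)
  else md <- NULL
  recording(subject_id = meta$subject_id, group = meta$group,
            channel_labels = meta$channel_labels, fs = meta$fs,
            signal = signal, events = events, metadata = md,
            norm_factor = meta$norm_factor %||% 1)
}

# ---- EDF/BDF (one data record spanning the signal) -------------------

pad_field <- function(x, width) {
  s <- substr(format(x, trim = TRUE, scientific = FALSE), 1, width)
  formatC(s, width = width, flag = "-")
}

write_edf_like <- function(rec, path, bits) {
  n_ch <- nrow(rec$signal)
  n_samp <- ncol(rec$signal)
  dig_max <- if (bits == 16L) 32767 else 8388607
  dig_min <- -dig_max - 1
  # pre-round so the written 8-char header field and the scaling agree;
  # round UP at the 6th significant digit so no sample is clipped
  m <- max(1e-6, max(abs(rec$signal)))
  k <- 5 - floor(log10(m))
  phys_max <- ceiling(m * 10^k) / 10^k
  con <- file(path, "wb")
  on.exit(close(con))
  version <- if (bits == 16L) charToRaw(pad_field("0", 8)) else
    c(as.raw(255), charToRaw(pad_field("BIOSEMI", 7)))
  writeBin(version, con)
  writeBin(charToRaw(pad_field(rec$subject_id, 80)), con)
  writeBin(charToRaw(pad_field("recording", 80)), con)
  writeBin(charToRaw("01.01.0001.00.00"), con)  # start date+time, 16 bytes
  writeBin(charToRaw(pad_field(256 * (n_ch + 1), 8)), con)
  writeBin(charToRaw(pad_field("", 44)), con)
  writeBin(charToRaw(pad_field(1, 8)), con)                   # n records
  writeBin(charToRaw(pad_field(n_samp / rec$fs, 8)), con)     # duration s
  writeBin(charToRaw(pad_field(n_ch, 4)), con)
  put <- function(vals, width)
    writeBin(charToRaw(paste0(vapply(vals, pad_field, "", width = width),
                              collapse = "")), con)
  put(rec$channel_labels, 16)                    # label
  put(rep("", n_ch), 80)                         # transducer
  put(rep("uV", n_ch), 8)                        # physical dimension
  put(rep(-phys_max, n_ch), 8)                   # physical minimum
  put(rep(phys_max, n_ch), 8)                    # physical maximum
  put(rep(dig_min, n_ch), 8)                     # digital minimum
  put(rep(dig_max, n_ch), 8)                     # digital maximum
  put(rep("", n_ch), 80)                         # prefiltering
  put(rep(n_samp, n_ch), 8)                      # samples per record
  put(rep("", n_ch), 32)                         # reserved
  scale <- (dig_max - dig_min) / (2 * phys_max)
  for (ch in seq_len(n_ch)) {
    dig <- round((rec$signal[ch, ] + phys_max) * scale) + dig_min
    dig <- as.integer(pmin(pmax(dig, dig_min), dig_max))
    if (bits == 16L) {
      writeBin(dig, con, size = 2, endian = "little")
    } else {
      u <- ifelse(dig < 0, dig + 16777216, dig)  # two's complement, 24 bit
      b <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
      writeBin(as.raw(b), con)
    }
  }
  invisible(path)
}

read_edf_like <- function(path, bits) {
  if (!file.exists(path))
    stop_config("read_recording: file '%s' not found", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 8)                          # version
  readBin(con, "raw", 80 + 80 + 16)               # ids, date/time
  header_bytes <- as.integer(rawToChar(readBin(con, "raw", 8)))
  readBin(con, "raw", 44)
  n_rec <- as.integer(rawToChar(readBin(con, "raw", 8)))
  dur <- as.numeric(rawToChar(readBin(con, "raw", 8)))
  n_ch <- as.integer(rawToChar(readBin(con, "raw", 4)))
  if (is.na(n_ch) || n_ch < 1)
    stop_config("read_recording: '%s' malformed header (field n_channels)",
                path)
  grab <- function(width) {
    raw <- readBin(con, "raw", width * n_ch)
    vapply(seq_len(n_ch), function(i)
      trimws(rawToChar(raw[((i - 1) * width + 1):(i * width)])), "")
  }
  labels <- grab(16); grab(80); grab(8)
  phys_min <- as.numeric(grab(8)); phys_max <- as.numeric(grab(8))
  dig_min <- as.numeric(grab(8)); dig_max <- as.numeric(grab(8))
  grab(80)
  n_samp <- as.integer(grab(8))
  grab(32)
  signal <- matrix(0, n_ch, n_samp[1])
  for (ch in seq_len(n_ch)) {
    if (bits == 16L) {
      dig <- readBin(con, "integer", n_samp[ch], size = 2,
                     endian = "little")
    } else {
      b <- readBin(con, "raw", 3L * n_samp[ch])
      m <- matrix(as.integer(b), nrow = 3)
      u <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      dig <- ifelse(u > 8388607, u - 16777216, u)
    }
    signal[ch, ] <- phys_min[ch] +
      (dig - dig_min[ch]) * (phys_max[ch] - phys_min[ch]) /
      (dig_max[ch] - dig_min[ch])
  }
  list(labels = as.character(labels), signal = signal,
       fs = n_samp[1] / dur)
}

#' Read / write per-subject metadata tables
#'
#' TSV with columns subject_id, group, hospitalizations, dose_load,
#' saps, sans (clinical columns `NA` for healthy subjects).
#'
#' @param recs list of recordings.
#' @param path TSV path.
#' @return `write_metadata_tsv`: the path, invisibly;
#'   `read_metadata_tsv`: a data frame.
#' @export
write_metadata_tsv <- function(recs, path) {
  rows <- lapply(recs, function(r) {
    m <- r$metadata
    data.frame(subject_id = r$subject_id, group = r$group,
               hospitalizations = if (is.null(m)) NA else m$hospitalizations,
               dose_load = if (is.null(m)) NA else m$dose_load,
               saps = if (is.null(m)) NA else m$saps,
               sans = if (is.null(m)) NA else m$sans)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
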