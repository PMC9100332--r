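# Readers and writers for the two on-disk recording formats: a minimal WFDB
# subset (single-signal format-16 .hea/.dat pairs, enough to round-trip
# PhysioNet-style records) and plain one-sample-per-line text with a JSON
# sidecar carrying the sampling rate and labels.

#' Write a recording as a WFDB record
#'
#' Writes `<name>.hea` and `<name>.dat` (format 16, little-endian int16, one
#' signal). Amplitudes are scaled by an automatically chosen integer gain.
#' Identity, database and session start are preserved in header comment lines.
#'
#' @param recording an [ecg_recording()].
#' @param dir output directory.
#' @param name record name; defaults to the identity id.
#' @return the record path prefix (without extension), invisibly.
#' @export
write_wfdb <- function(recording, dir, name = recording$identity_id) {
  x <- recording$samples
  amax <- max(abs(x), 1e-6)
  gain <- max(1, floor(32000 / amax))
  adc <- as.integer(round(x * gain))
  prefix <- file.path(dir, name)
  hea <- c(
    sprintf("%s 1 %g %d", name, recording$sampling_rate, length(x)),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 ECG", name, gain, adc[1]),
    sprintf("# identity_id %s", recording$identity_id),
    sprintf("# database_id %s", recording$database_id),
    sprintf("# session_start %g", recording$session_start)
  )
  writeLines(hea, paste0(prefix, ".hea"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2L, endian = "little")
  invisible(prefix)
}

#' Read a WFDB record
#'
#' Reads the first signal of a format-16 WFDB record written by [write_wfdb()]
#' or any compatible single-segment header.
#'
#' @param prefix record path prefix (no extension).
#' @return an [ecg_recording()].
#' @export
read_wfdb <- function(prefix) {
  hea_path <- paste0(prefix, ".hea")
  if (!file.exists(hea_path)) stop("no header file: ", hea_path)
  lines <- readLines(hea_path)
  meta <- list(identity_id = basename(prefix), database_id = "wfdb", session_start = 0)
  for (ln in grep("^#", lines, value = TRUE)) {
    parts <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]
    if (length(parts) >= 2 && parts[1] %in% names(meta)) {
      meta[[parts[1]]] <- if (parts[1] == "session_start") as.numeric(parts[2]) else parts[2]
    }
  }
  lines <- lines[!grepl("^#", lines)]
  rec_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  fs <- as.numeric(rec_fields[3])
  nsamp <- as.integer(rec_fields[4])
  sig_fields <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  fmt <- sig_fields[2]
  if (fmt != "16") stop("only WFDB format 16 is supported (got ", fmt, ")")
  gain_spec <- sig_fields[3]
  gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_spec)))
  baseline <- if (grepl("\\(", gain_spec))
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec)) else 0
  if (is.na(gain) || gain == 0) gain <- 200
  dat_path <- paste0(prefix, ".dat")
  con <- file(dat_path, "rb")
  on.exit(close(con))
  adc <- readBin(con, "integer", n = nsamp, size = 2L, endian = "little", signed = TRUE)
  ecg_recording((adc - baseline) / gain, fs, meta$identity_id, meta$database_id,
                meta$session_start)
}

#' Write / read a recording as plain text
#'
#' One sample per line; sampling rate and labels live in a `<path>.json`
#' sidecar.
#'
#' @param recording an [ecg_recording()].
#' @param path text file path.
#' @return `write_ecg_text` returns `path` invisibly; `read_ecg_text` an
#'   [ecg_recording()].
#' @export
write_ecg_text <- function(recording, path) {
  writeLines(format(recording$samples, digits = 10, trim = TRUE, scientific = FALSE),
             path)
  jsonlite::write_json(list(sampling_rate = recording$sampling_rate,
                            identity_id = recording$identity_id,
                            database_id = recording$database_id,
                            session_start = recording$session_start),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ecg_text
#' @export
read_ecg_text <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar config: ", side)
  cfg <- jsonlite::read_json(side, simplifyVector = TRUE)
  x <- scan(path, what = numeric(), quiet = TRUE)
  ecg_recording(x, cfg$sampling_rate, cfg$identity_id, cfg$database_id,
                cfg$session_start %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
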