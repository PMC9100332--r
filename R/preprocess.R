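#' ECG recording container
#'
#' A labeled raw single-lead ECG trace. Amplitude units are arbitrary;
#' `session_start` (seconds since epoch) is bookkeeping for time-separation
#' experiments and morphology drift.
#'
#' @param samples numeric vector of ECG samples.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param identity_id non-empty identity label.
#' @param database_id database label.
#' @param session_start recording start time, seconds since epoch.
#' @return an `ecg_recording` object.
#' @export
ecg_recording <- function(samples, sampling_rate, identity_id,
                          database_id = "db", session_start = 0) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar")
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("samples must be non-empty")
  if (!nzchar(identity_id)) stop("identity_id must be non-empty")
  structure(list(samples = samples, sampling_rate = as.numeric(sampling_rate),
                 identity_id = as.character(identity_id),
                 database_id = as.character(database_id),
                 session_start = as.numeric(session_start)),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %s/%s: %d samples @ %g Hz (%.1f s), session_start=%g\n",
              x$database_id, x$identity_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$session_start))
  invisible(x)
}

.as_segment <- function(values, identity = NA_character_, offset = NA_integer_,
                        standardized = FALSE) {
  structure(as.numeric(values), class = "ecg_segment",
            identity = identity, offset = offset, standardized = standardized)
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment> %d samples, identity=%s, offset=%s, standardized=%s\n",
              length(x), attr(x, "identity"), attr(x, "offset"),
              attr(x, "standardized")))
  invisible(x)
}

#' Bandpass filter specification
#'
#' Fifth-order Butterworth bandpass with critical frequencies expressed as
#' fractions of the 64 Hz Nyquist frequency of 128 Hz data: the default
#' passband is 0.01 * 64 = 0.64 Hz to 0.7 * 64 = 44.8 Hz.
#'
#' @param order filter order.
#' @param low_frac,high_frac critical frequencies as fractions of `nyquist_hz`.
#' @param nyquist_hz Nyquist frequency in Hz.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(order = 5L, low_frac = 0.01, high_frac = 0.7,
                        nyquist_hz = 64) {
  if (!(low_frac > 0 && low_frac < high_frac && high_frac < 1))
    stop("need 0 < low_frac < high_frac < 1")
  structure(list(order = as.integer(order), low_frac = low_frac,
                 high_frac = high_frac, nyquist_hz = nyquist_hz),
            class = "filter_spec")
}

#' Resample a recording
#'
#' Polyphase rational resampling (anti-aliased FIR) to the model's operating
#' rate. A recording already at the target rate is returned unchanged.
#'
#' @param recording an [ecg_recording()].
#' @param target_rate target sampling rate in Hz.
#' @return an `ecg_recording` at `target_rate`.
#' @export
resample_recording <- function(recording, target_rate = 128) {
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("target_rate must be positive")
  fs <- recording$sampling_rate
  if (isTRUE(all.equal(fs, target_rate))) return(recording)
  # reduce target/fs to a small rational p/q
  scale <- 1000
  p <- round(target_rate * scale); q <- round(fs * scale)
  g <- .gcd(p, q)
  y <- signal::resample(recording$samples, p / g, q / g)
  ecg_recording(y, target_rate, recording$identity_id, recording$database_id,
                recording$session_start)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Blind segmentation
#'
#' Cuts exactly 384 consecutive samples (3 s at 128 Hz) starting at a 0-based
#' sample offset. No fiducial points or peak detection of any kind: the window
#' depends only on the offset, never on signal content.
#'
#' @param recording an [ecg_recording()] at 128 Hz.
#' @param start_offset 0-based sample offset; the window is
#'   `[start_offset, start_offset + 384)`.
#' @param seg_len segment length in samples.
#' @return a raw (unstandardized) `ecg_segment`.
#' @export
blind_segment <- function(recording, start_offset, seg_len = 384L) {
  if (!isTRUE(all.equal(recording$sampling_rate, 128)))
    stop("blind segmentation expects a 128 Hz recording; resample first")
  start_offset <- as.integer(start_offset)
  if (start_offset < 0L) stop("start_offset must be >= 0")
  if (start_offset + seg_len > length(recording$samples))
    stop("segment window [", start_offset, ", ", start_offset + seg_len,
         ") exceeds recording length ", length(recording$samples))
  .as_segment(recording$samples[(start_offset + 1L):(start_offset + seg_len)],
              identity = recording$identity_id, offset = start_offset,
              standardized = FALSE)
}

.design_butter <- function(spec) {
  signal::butter(spec$order, c(spec$low_frac, spec$high_frac), type = "pass")
}

# Zero-phase forward-backward IIR filtering with odd-reflection end padding and
# steady-state initial conditions (the response to a held constant input), so
# a DC input maps to (numerically) zero and end transients stay small.
.zero_phase_filter <- function(bf, x) {
  b <- bf$b; a <- bf$a
  n <- length(x)
  pad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 2L)
  xe <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  h1 <- sum(b) / sum(a)     # DC gain
  run <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1L),
                              init.y = rep(h1 * z[1], length(a) - 1L)))
  }
  y <- run(xe)
  y <- rev(run(rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Bandpass filter a segment
#'
#' Applies the Butterworth bandpass to a single already-cut segment (always
#' after segmentation, so edge distortion stays inside the classification
#' window). Zero-phase forward-backward application is the default; set
#' `zero_phase = FALSE` for a causal single pass.
#'
#' @param segment raw `ecg_segment` (length 384).
#' @param spec a [filter_spec()].
#' @param zero_phase logical; forward-backward (`signal::filtfilt`) vs causal.
#' @return filtered raw `ecg_segment`.
#' @export
bandpass_filter <- function(segment, spec = filter_spec(), zero_phase = TRUE) {
  x <- as.numeric(segment)
  bf <- .design_butter(spec)
  y <- if (zero_phase) .zero_phase_filter(bf, x)
       else as.numeric(signal::filter(bf, x))
  .as_segment(y, identity = attr(segment, "identity"),
              offset = attr(segment, "offset"), standardized = FALSE)
}

#' Standardize a segment (z-score)
#'
#' Standard-score normalization g' = (g - mu) / sigma applied to every scope
#' and query segment; sigma is the population (divide-by-N) standard deviation.
#' A flat segment (sigma = 0) is a degenerate input and raises an error.
#'
#' @param segment raw `ecg_segment`.
#' @return standardized `ecg_segment` (mean 0, sd 1).
#' @export
standardize <- function(segment) {
  x <- as.numeric(segment)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma < 1e-12)
    stop("degenerate segment: zero standard deviation (flat signal)")
  .as_segment((x - mu) / sigma, identity = attr(segment, "identity"),
              offset = attr(segment, "offset"), standardized = TRUE)
}

#' Full preprocessing pipeline
#'
#' Resample to 128 Hz, blind-segment at the given offsets, bandpass filter each
#' segment, then standardize — in that exact order (filtering is per-segment,
#' never applied to the whole recording).
#'
#' @param recording an [ecg_recording()] at any rate.
#' @param offsets integer vector of 0-based offsets at 128 Hz.
#' @param target_rate operating rate (Hz).
#' @param spec a [filter_spec()].
#' @param zero_phase see [bandpass_filter()].
#' @return list of standardized `ecg_segment`s (one per offset).
#' @export
preprocess_pipeline <- function(recording, offsets, target_rate = 128,
                                spec = filter_spec(), zero_phase = TRUE) {
  rec <- resample_recording(recording, target_rate)
  lapply(offsets, function(o) {
    standardize(bandpass_filter(blind_segment(rec, o), spec, zero_phase))
  })
}

# Fast path used by the dataset builder / evaluation: filter + standardize many
# raw 384-sample windows held as rows of a matrix.
.prep_segments <- function(segmat, spec = filter_spec(), zero_phase = TRUE) {
  bf <- .design_butter(spec)
  out <- t(apply(segmat, 1L, function(x) {
    y <- if (zero_phase) .zero_phase_filter(bf, x)
         else as.numeric(signal::filter(bf, x))
    mu <- mean(y)
    s <- sqrt(mean((y - mu)^2))
    if (s < 1e-12) stop("degenerate segment: zero standard deviation")
    (y - mu) / s
  }))
  out
}
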