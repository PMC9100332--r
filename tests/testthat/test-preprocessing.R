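test_that("resampling preserves duration, rate and spectral content", {
  expect_error(resample_recording(sine_recording(5, 500), -1), "positive")

  # halving the rate halves the count for a 3 s signal
  rec <- ecg_recording(rnorm(768), 256, "a")
  out <- resample_recording(rec, 128)
  expect_equal(out$sampling_rate, 128)
  expect_equal(length(out$samples), 384L)

  # identity case: already at 128 Hz -> sample-identical
  rec128 <- ecg_recording(rnorm(500), 128, "a")
  expect_identical(resample_recording(rec128, 128)$samples, rec128$samples)

  # FFT-peak oracle: a 5 Hz sinusoid resampled 500 -> 128 Hz keeps its peak
  rec <- sine_recording(5, 500, dur = 4)
  out <- resample_recording(rec, 128)
  peak_hz <- function(x, fs) {
    sp <- Mod(fft(x))[seq_len(floor(length(x) / 2))]
    (which.max(sp) - 1) * fs / length(x)
  }
  expect_lt(abs(peak_hz(out$samples, 128) - 5), 128 / length(out$samples) + 1e-9)
})

test_that("blind segmentation is content-blind windowing with strict bounds", {
  rec <- ecg_recording(seq_len(400), 128, "a")
  seg <- blind_segment(rec, 0)
  expect_length(as.numeric(seg), 384L)
  expect_equal(as.numeric(seg), as.numeric(1:384))
  # offset window must fit: 17 + 384 > 400
  expect_error(blind_segment(rec, 17), "exceeds")
  expect_error(blind_segment(rec, -1), ">= 0")
  # 3 s at 128 Hz = 384 points; a 384-sample recording is one whole window
  rec384 <- ecg_recording(rnorm(384), 128, "a")
  expect_equal(as.numeric(blind_segment(rec384, 0)), rec384$samples)
  # identical window boundaries for any two equal-length recordings
  rec2 <- ecg_recording(rnorm(400), 128, "b")
  s1 <- blind_segment(rec, 10); s2 <- blind_segment(rec2, 10)
  expect_equal(attr(s1, "offset"), attr(s2, "offset"))
})

test_that("bandpass filter kills DC, keeps 10 Hz, attenuates 60 Hz", {
  # constant (DC) component: output RMS far below the DC amplitude
  seg_dc <- blind_segment(ecg_recording(rep(1, 500), 128, "a"), 0)
  out_dc <- bandpass_filter(seg_dc)
  expect_lt(sqrt(mean(as.numeric(out_dc)^2)), 0.01)

  # oracle: analytic magnitude response of the designed filter, applied twice
  # (forward-backward); gain measured as an RMS ratio away from the edges
  bf <- ecgscope:::.design_butter(filter_spec())
  hmag2 <- function(freq) {
    z <- exp(-1i * 2 * pi * freq / 128)
    h <- sum(bf$b * z^(seq_along(bf$b) - 1)) / sum(bf$a * z^(seq_along(bf$a) - 1))
    Mod(h)^2
  }
  gain_after <- function(freq) {
    tt <- (0:383) / 128
    seg <- blind_segment(ecg_recording(sin(2 * pi * freq * tt), 128, "a"), 0)
    out <- as.numeric(bandpass_filter(seg))
    sqrt(mean(out[100:284]^2) / mean(as.numeric(seg)[100:284]^2))
  }
  expect_lt(abs(gain_after(10) - hmag2(10)), 0.05)
  expect_gt(gain_after(10), 0.95)
  expect_lt(gain_after(60), gain_after(10))
  expect_lt(abs(gain_after(60) - hmag2(60)), 0.05)
})

test_that("standardization is an exact z-score with degenerate-input error", {
  seg <- blind_segment(ecg_recording(as.numeric(1:500), 128, "a"), 0)
  out <- standardize(seg)
  x <- as.numeric(out)
  expect_lt(abs(mean(x)), 1e-9)
  expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-9)
  expect_true(attr(out, "standardized"))
  # sigma = 0 -> degenerate input
  flat <- blind_segment(ecg_recording(rep(3, 400), 128, "a"), 0)
  expect_error(standardize(flat), "degenerate")
  # idempotence
  expect_equal(as.numeric(standardize(out)), x, tolerance = 1e-6)
})

test_that("pipeline equals the manually staged path and removes gain", {
  rec <- synth_recording(sample_identity(5), noise_spec_easy(), 10, 256, seed = 2)
  offs <- c(0L, 384L, 500L)
  segs <- preprocess_pipeline(rec, offs)
  expect_length(segs, 3L)
  expect_length(preprocess_pipeline(rec, integer(0)), 0L)
  # manual staging oracle
  rec128 <- resample_recording(rec, 128)
  manual <- standardize(bandpass_filter(blind_segment(rec128, 384L)))
  expect_equal(as.numeric(segs[[2]]), as.numeric(manual), tolerance = 1e-12)
  # gain invariance: pipeline(c * x) == pipeline(x)
  rec_scaled <- rec; rec_scaled$samples <- rec$samples * 37.5
  segs2 <- preprocess_pipeline(rec_scaled, offs)
  expect_equal(as.numeric(segs2[[1]]), as.numeric(segs[[1]]), tolerance = 1e-6)
  # per-segment filtering: a segment's output depends only on its own window
  short <- ecg_recording(rec128$samples[501:1000], 128, "a")
  seg_short <- preprocess_pipeline(short, 0L)[[1]]
  seg_long <- preprocess_pipeline(rec128, 500L)[[1]]
  expect_equal(as.numeric(seg_short), as.numeric(seg_long), tolerance = 1e-12)
})

test_that("wfdb and text round-trips preserve signal and metadata", {
  dir <- withr::local_tempdir()
  rec <- synth_recording(sample_identity(9), noise_spec(), 5, 128, seed = 3,
                         session_start = 1234)
  rec$identity_id <- "someone"
  prefix <- write_wfdb(rec, dir)
  back <- read_wfdb(prefix)
  expect_equal(back$samples, rec$samples, tolerance = 1e-3)
  expect_equal(back$sampling_rate, 128)
  expect_equal(back$identity_id, "someone")
  expect_equal(back$session_start, 1234)

  path <- file.path(dir, "trace.txt")
  write_ecg_text(rec, path)
  back2 <- read_ecg_text(path)
  expect_equal(back2$samples, rec$samples, tolerance = 1e-7)
  expect_equal(back2$sampling_rate, 128)
})
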