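test_that("identity sampling is deterministic, distinct and matches its priors", {
  m1 <- sample_identity(42)
  m2 <- sample_identity(42)
  expect_identical(m1, m2)
  expect_gt(abs(m1$bump_amplitudes[3]), max(abs(m1$bump_amplitudes[-3])))

  ms <- lapply(1:100, sample_identity)
  pm <- sapply(ms, function(m) c(m$bump_amplitudes, m$bump_widths, m$mean_rr))
  d <- as.matrix(dist(t(pm)))
  expect_true(all(d[upper.tri(d)] > 0))

  # Monte-Carlo check of the documented RR prior mean
  rr <- vapply(1:10000, function(s) sample_identity(s)$mean_rr, numeric(1))
  expect_lt(abs(mean(rr) - morphology_priors()$rr_prior_mean) /
              morphology_priors()$rr_prior_mean, 0.05)
})

test_that("noise-free jitter-free recordings are periodic with period mean_rr", {
  m <- sample_identity(7)
  m$mean_rr <- 0.75            # 96 samples at 128 Hz: integer period
  m$rr_jitter_sd <- 0
  rec <- synth_recording(m, noise_spec(0, 0, 0.25), 12, 128, seed = 1)
  expect_length(rec$samples, 12 * 128)
  x <- rec$samples
  p <- 96L
  core <- 200:(length(x) - 200)
  expect_lt(max(abs(x[core + p] - x[core])), 1e-8)
  expect_error(synth_recording(m, noise_spec(), 2, 128), "at least 3")
  expect_error(synth_recording(m, noise_spec(), 10, 32), "64")
})

test_that("mean inter-peak spacing matches mean_rr (argmax oracle)", {
  m <- sample_identity(11)
  rec <- synth_recording(m, noise_spec(0, 0, 0.25), 30, 128, seed = 4)
  x <- rec$samples
  # simple argmax peak finder on the noise-free signal
  thr <- 0.6 * max(x)
  peaks <- which(x > thr &
                   x >= c(-Inf, x[-length(x)]) & x > c(x[-1], -Inf))
  spacing <- diff(peaks) / 128
  spacing <- spacing[spacing > 0.4 * m$mean_rr]   # guard double-detections
  expect_lt(abs(mean(spacing) - m$mean_rr) / m$mean_rr, 0.03)
})

test_that("session-time drift lowers beat-template correlation", {
  m <- sample_identity(13, drift_rate = 0.5)
  rec0a <- synth_recording(m, noise_spec(0, 0, 0.25), 20, 128,
                           session_start = 0, seed = 5)
  rec0b <- synth_recording(m, noise_spec(0, 0, 0.25), 20, 128,
                           session_start = 60, seed = 6)       # same session-ish
  rec1 <- synth_recording(m, noise_spec(0, 0, 0.25), 20, 128,
                          session_start = 30 * 24 * 3600, seed = 7)  # +30 days
  template <- function(rec) {
    # average beat-aligned window via argmax peaks
    x <- rec$samples
    pk <- which(x > 0.6 * max(x) & x >= c(-Inf, x[-length(x)]) & x > c(x[-1], -Inf))
    pk <- pk[pk > 64 & pk < length(x) - 64]
    rowMeans(sapply(pk, function(p) x[(p - 50):(p + 50)]))
  }
  t0a <- template(rec0a); t0b <- template(rec0b); t1 <- template(rec1)
  expect_gt(cor(t0a, t0b), cor(t0a, t1))
})

test_that("registries are deterministic, correctly sized and writable", {
  reg <- synth_registry(2L, c(40L, 10L), rates = c(128, 250), seed = 3,
                        duration_s = 10)
  expect_length(registry_identities(reg), 50L)
  reg2 <- synth_registry(2L, c(40L, 10L), rates = c(128, 250), seed = 3,
                         duration_s = 10)
  expect_identical(reg$databases[[2]]$identities[[5]][[1]]$samples,
                   reg2$databases[[2]]$identities[[5]][[1]]$samples)
  # distinct seeds differ
  reg3 <- synth_registry(2L, c(40L, 10L), rates = c(128, 250), seed = 4,
                         duration_s = 10)
  expect_false(identical(reg$databases[[1]]$identities[[1]][[1]]$samples,
                         reg3$databases[[1]]$identities[[1]][[1]]$samples))

  dir <- withr::local_tempdir()
  write_registry(reg, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  rec <- read_wfdb(file.path(dir, "db01", "db01_id001_r1"))
  expect_equal(rec$samples, reg$databases[[1]]$identities[[1]][[1]]$samples,
               tolerance = 1e-3)
})

test_that("easy regime is separable: nearest-template identification is perfect", {
  # the oracle for the "easy" study condition: with near-zero noise and no
  # drift, correlation against per-identity beat templates classifies segments
  # with 100% accuracy
  n_id <- 8L
  morphs <- lapply(1:n_id, function(s) sample_identity(s * 11L))
  recs <- lapply(morphs, function(m)
    synth_recording(m, noise_spec_easy(), 30, 128, seed = m$seed + 1L))
  template <- function(rec) {
    x <- rec$samples
    pk <- which(x > 0.6 * max(x) & x >= c(-Inf, x[-length(x)]) & x > c(x[-1], -Inf))
    pk <- pk[pk > 80 & pk < length(x) - 80]
    rowMeans(sapply(pk, function(p) x[(p - 60):(p + 60)]))
  }
  temps <- lapply(recs, template)
  classify <- function(seg) {
    # matched filter: best correlation over all alignments, per identity
    best <- vapply(temps, function(tp) {
      L <- length(tp)
      max(vapply(seq_len(length(seg) - L + 1L), function(l) {
        suppressWarnings(cor(seg[l:(l + L - 1L)], tp))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    which.max(best)
  }
  set.seed(99)
  correct <- 0L; total <- 0L
  for (i in seq_len(n_id)) {
    for (rep in 1:5) {
      off <- sample(0:(30 * 128 - 384), 1)
      seg <- recs[[i]]$samples[(off + 1):(off + 384)]
      total <- total + 1L
      if (classify(seg) == i) correct <- correct + 1L
    }
  }
  expect_equal(correct, total)
})
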