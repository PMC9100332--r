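# Synthetic multi-identity ECG corpus generator. Each identity is a stable
# waveform morphology: one heartbeat is a sum of five Gaussian bumps standing
# in for the P, Q, R, S and T waves, placed at jittered RR intervals. Noise,
# baseline wander and slow per-identity morphology drift (driven by absolute
# session time) emulate the nuisance factors of real recordings. Realism is a
# non-goal; controllable identity separability and full determinism are.

#' Priors for identity morphology sampling
#'
#' Documented population priors from which [sample_identity()] draws. Bump
#' order is (P, Q, R, S, T); amplitudes are in arbitrary mV-like units, widths
#' and latencies in seconds. The RR-interval prior is lognormal;
#' `rr_prior_mean` is its analytic mean.
#'
#' @return named list of prior parameters.
#' @export
morphology_priors <- function() {
  rr_meanlog <- log(0.85); rr_sdlog <- 0.12
  list(amp_mean = c(0.12, -0.15, 1.00, -0.25, 0.30),
       amp_sd = c(0.03, 0.05, 0.12, 0.07, 0.08),
       width_mean = c(0.040, 0.010, 0.012, 0.010, 0.060),
       width_sdlog = 0.15,
       lat_mean = c(-0.200, -0.025, 0.000, 0.025, 0.220),
       lat_sd = c(0.015, 0.004, 0.000, 0.004, 0.020),
       rr_meanlog = rr_meanlog, rr_sdlog = rr_sdlog,
       rr_prior_mean = exp(rr_meanlog + rr_sdlog^2 / 2),
       jitter_mean = 0.020, jitter_sd = 0.008, jitter_min = 0.002)
}

#' Sample an identity morphology
#'
#' Deterministic given the seed. The R-like bump is kept strictly largest in
#' magnitude. `drift_rate` is the fractional morphology change per hour of
#' absolute session time; the (unit) drift direction over the 15 shape
#' parameters is part of the identity, so drift is slow and consistent.
#'
#' @param seed integer seed.
#' @param drift_rate fractional morphology change per hour (>= 0).
#' @param priors see [morphology_priors()].
#' @return an `identity_morphology` list.
#' @export
sample_identity <- function(seed, drift_rate = 0, priors = morphology_priors()) {
  .with_seed(seed, {
    amps <- stats::rnorm(5L, priors$amp_mean, priors$amp_sd)
    widths <- priors$width_mean * exp(stats::rnorm(5L, 0, priors$width_sdlog))
    lats <- stats::rnorm(5L, priors$lat_mean, priors$lat_sd)
    lats[3L] <- 0
    # the R-like bump must dominate
    other <- max(abs(amps[-3L]))
    if (abs(amps[3L]) <= other) amps[3L] <- sign(amps[3L] + 1e-12) * other * 1.3
    mean_rr <- exp(stats::rnorm(1L, priors$rr_meanlog, priors$rr_sdlog))
    jit <- max(priors$jitter_min,
               stats::rnorm(1L, priors$jitter_mean, priors$jitter_sd))
    dir <- stats::rnorm(15L)
    dir <- dir / sqrt(sum(dir^2))
    structure(list(bump_amplitudes = amps, bump_widths = widths,
                   bump_latencies = lats, mean_rr = mean_rr,
                   rr_jitter_sd = jit, drift_rate = drift_rate,
                   drift_dir = dir, seed = as.integer(seed)),
              class = "identity_morphology")
  })
}

# Morphology at an absolute time (seconds since epoch): linear drift of
# amplitudes, log-linear of widths, additive shift of latencies.
.morph_at <- function(morph, abs_time_s) {
  s <- morph$drift_rate * abs_time_s / 3600
  if (s == 0) return(morph)
  d <- morph$drift_dir
  morph$bump_amplitudes <- morph$bump_amplitudes * (1 + s * d[1:5])
  morph$bump_widths <- morph$bump_widths * exp(s * d[6:10])
  morph$bump_latencies <- morph$bump_latencies + s * d[11:15] * 0.03
  morph
}

#' Noise specification
#'
#' Additive white Gaussian noise plus sinusoidal baseline wander (random phase).
#' The defaults are the study conditions for "realistic" synthetic recordings;
#' [noise_spec_easy()] is the near-noiseless easy regime used when a cleanly
#' separable corpus is required.
#'
#' @param white_sd white noise standard deviation (amplitude units).
#' @param baseline_wander_amp baseline wander amplitude.
#' @param baseline_wander_hz baseline wander frequency (< 0.5 Hz).
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(white_sd = 0.02, baseline_wander_amp = 0.05,
                       baseline_wander_hz = 0.25) {
  if (any(c(white_sd, baseline_wander_amp, baseline_wander_hz) < 0))
    stop("noise parameters must be >= 0")
  if (baseline_wander_hz >= 0.5) stop("baseline wander must be below 0.5 Hz")
  structure(list(white_sd = white_sd, baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_hz = baseline_wander_hz), class = "noise_spec")
}

#' @rdname noise_spec
#' @export
noise_spec_easy <- function() noise_spec(0.002, 0, 0.25)

#' Synthesize an ECG recording
#'
#' Places one five-bump beat per RR interval (mean `mean_rr`, Gaussian jitter),
#' applies per-beat morphology drift at the beat's absolute time
#' (`session_start` + offset), and adds noise per the spec. Fully deterministic
#' given `seed`.
#'
#' @param morph an [sample_identity()] morphology.
#' @param noise a [noise_spec()].
#' @param duration_s duration in seconds (>= 3).
#' @param rate_hz sampling rate (>= 64).
#' @param session_start recording start, seconds since epoch.
#' @param seed integer seed for jitter/noise draws.
#' @param database_id database label attached to the recording.
#' @return an [ecg_recording()].
#' @export
synth_recording <- function(morph, noise = noise_spec(), duration_s, rate_hz = 128,
                            session_start = 0, seed = 1L, database_id = "synth") {
  if (duration_s < 3) stop("duration_s must be at least 3 s (one segment)")
  if (rate_hz < 64) stop("rate_hz must be at least 64 Hz")
  n <- round(duration_s * rate_hz)
  .with_seed(seed, {
    # beat centers
    centers <- numeric(0)
    tcur <- morph$mean_rr / 2
    while (tcur < duration_s + 0.5) {
      centers <- c(centers, tcur)
      rr <- morph$mean_rr
      if (morph$rr_jitter_sd > 0)
        rr <- max(0.3 * morph$mean_rr, rr + stats::rnorm(1L, 0, morph$rr_jitter_sd))
      tcur <- tcur + rr
    }
    x <- numeric(n)
    tv <- (seq_len(n) - 1L) / rate_hz
    for (ct in centers) {
      m <- .morph_at(morph, session_start + ct)
      for (j in 1:5) {
        w <- m$bump_widths[j]
        c_j <- ct + m$bump_latencies[j]
        lo <- max(1L, ceiling((c_j - 4 * w) * rate_hz) + 1L)
        hi <- min(n, floor((c_j + 4 * w) * rate_hz) + 1L)
        if (lo <= hi) {
          tt <- tv[lo:hi]
          x[lo:hi] <- x[lo:hi] + m$bump_amplitudes[j] * exp(-(tt - c_j)^2 / (2 * w^2))
        }
      }
    }
    if (noise$baseline_wander_amp > 0) {
      phase <- stats::runif(1L, 0, 2 * pi)
      x <- x + noise$baseline_wander_amp *
        sin(2 * pi * noise$baseline_wander_hz * tv + phase)
    }
    if (noise$white_sd > 0) x <- x + stats::rnorm(n, 0, noise$white_sd)
    ecg_recording(x, rate_hz, identity_id = paste0("id", morph$seed),
                  database_id = database_id, session_start = session_start)
  })
}

#' Build a synthetic multi-database registry
#'
#' Emulates a multi-database corpus: each database has its own sampling rate
#' and identities, each identity one long recording plus a train/validation
#' split, so the training dataset generator can mix databases exactly as with
#' real corpora.
#'
#' @param n_databases number of databases.
#' @param identities_per_db integer vector (length `n_databases`).
#' @param rates per-database sampling rates in Hz.
#' @param seed root seed; all identity morphologies and recordings derive from
#'   it deterministically.
#' @param duration_s recording length per identity (seconds).
#' @param noise a [noise_spec()] shared by all databases.
#' @param drift_rate per-identity morphology drift (fraction/hour).
#' @param split list of `c(train, validation)` identity counts per database, or
#'   `NULL` for a default 60/40 split.
#' @param session_start recording start time(s), recycled across databases.
#' @return an `ecg_registry`.
#' @export
synth_registry <- function(n_databases, identities_per_db, rates, seed = 1L,
                           duration_s = 60, noise = noise_spec(), drift_rate = 0,
                           split = NULL, session_start = 0) {
  stopifnot(length(identities_per_db) == n_databases, length(rates) == n_databases)
  session_start <- rep_len(session_start, n_databases)
  total <- sum(identities_per_db)
  seeds <- .spawn_seeds(seed, 2L * total)
  dbs <- vector("list", n_databases)
  k <- 0L
  for (d in seq_len(n_databases)) {
    db_id <- sprintf("db%02d", d)
    n_id <- identities_per_db[d]
    ids <- sprintf("%s_id%03d", db_id, seq_len(n_id))
    recs <- vector("list", n_id); names(recs) <- ids
    morphs <- vector("list", n_id); names(morphs) <- ids
    for (i in seq_len(n_id)) {
      k <- k + 1L
      morph <- sample_identity(seeds[2L * k - 1L], drift_rate = drift_rate)
      rec <- synth_recording(morph, noise, duration_s, rates[d],
                             session_start = session_start[d],
                             seed = seeds[2L * k], database_id = db_id)
      rec$identity_id <- ids[i]
      morphs[[i]] <- morph
      recs[[i]] <- list(rec)
    }
    if (is.null(split)) {
      n_tr <- max(1L, floor(0.6 * n_id))
      sp <- c(n_tr, n_id - n_tr)
    } else sp <- split[[d]]
    if (sum(sp) > n_id) stop("split counts exceed identity count in ", db_id)
    dbs[[d]] <- list(database_id = db_id, rate = rates[d],
                     identities = recs, morphologies = morphs,
                     split = list(train = ids[seq_len(sp[1])],
                                  validation = if (sp[2] > 0)
                                    ids[(sp[1] + 1L):(sp[1] + sp[2])] else character(0)))
  }
  structure(list(databases = dbs, seed = as.integer(seed), resampled = FALSE),
            class = "ecg_registry")
}

#' @export
print.ecg_registry <- function(x, ...) {
  n_id <- vapply(x$databases, function(d) length(d$identities), integer(1))
  cat(sprintf("<ecg_registry> %d database(s), %d identities (%s)%s\n",
              length(x$databases), sum(n_id), paste(n_id, collapse = "+"),
              if (x$resampled) ", resampled to 128 Hz" else ""))
  invisible(x)
}

#' List all identity ids in a registry
#' @param registry an `ecg_registry`.
#' @return character vector of identity ids (globally unique).
#' @export
registry_identities <- function(registry) {
  unlist(lapply(registry$databases, function(d) names(d$identities)),
         use.names = FALSE)
}

#' Resample every recording in a registry to 128 Hz
#'
#' The dataset generator and evaluation protocol operate at 128 Hz; this caches
#' the resampled recordings once.
#'
#' @param registry an `ecg_registry`.
#' @param target_rate operating rate in Hz.
#' @return the registry with all recordings at `target_rate`.
#' @export
resample_registry <- function(registry, target_rate = 128) {
  if (registry$resampled) return(registry)
  registry$databases <- lapply(registry$databases, function(db) {
    db$identities <- lapply(db$identities, function(recs) {
      lapply(recs, resample_recording, target_rate = target_rate)
    })
    db
  })
  registry$resampled <- TRUE
  registry
}

#' Write a registry to disk
#'
#' One WFDB record per recording plus a JSON manifest of identities, seeds and
#' session times.
#'
#' @param registry an `ecg_registry`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = registry$seed, databases = list())
  for (db in registry$databases) {
    dbdir <- file.path(dir, db$database_id)
    dir.create(dbdir, showWarnings = FALSE)
    entries <- list()
    for (id in names(db$identities)) {
      for (i in seq_along(db$identities[[id]])) {
        rec <- db$identities[[id]][[i]]
        nm <- sprintf("%s_r%d", id, i)
        write_wfdb(rec, dbdir, nm)
        entries[[length(entries) + 1L]] <-
          list(identity_id = id, record = nm, session_start = rec$session_start)
      }
    }
    manifest$databases[[db$database_id]] <-
      list(rate = db$rate, split = db$split, records = entries)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
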