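# Training/validation example generation over a multi-database registry.
# One classification example = h enrolled segments (the scope), one query
# segment, and the scope position of the query's true identity. The scope is
# first drawn from one uniformly chosen database and topped up one identity at
# a time from uniformly chosen databases, so every database has an equal chance
# of appearing regardless of its size.

#' Split a registry into training and validation partitions
#'
#' Identities in each database are partitioned according to the per-database
#' `c(train, validation)` counts (the registry's stored split by default).
#' Partitions are disjoint and their union is the original identity set when
#' the counts are exhaustive.
#'
#' @param registry an `ecg_registry`.
#' @param ratios optional list of `c(train, validation)` counts per database.
#' @return list with `train` and `validation` registries.
#' @export
split_registry <- function(registry, ratios = NULL) {
  take <- function(db, ids) {
    db$identities <- db$identities[ids]
    db$morphologies <- db$morphologies[ids]
    db$split <- list(train = ids, validation = character(0))
    db
  }
  out <- list(train = registry, validation = registry)
  for (d in seq_along(registry$databases)) {
    db <- registry$databases[[d]]
    if (!is.null(ratios)) {
      r <- ratios[[d]]
      n_id <- length(db$identities)
      if (sum(r) > n_id)
        stop("split ratio ", paste(r, collapse = ":"), " exceeds ", n_id,
             " identities in ", db$database_id)
      ids <- names(db$identities)
      tr <- ids[seq_len(r[1])]
      va <- if (r[2] > 0) ids[(r[1] + 1L):(r[1] + r[2])] else character(0)
    } else {
      tr <- db$split$train; va <- db$split$validation
    }
    out$train$databases[[d]] <- take(db, tr)
    out$validation$databases[[d]] <- take(db, va)
  }
  # drop databases left empty by the split
  for (g in c("train", "validation")) {
    keep <- vapply(out[[g]]$databases, function(db) length(db$identities) > 0,
                   logical(1))
    out[[g]]$databases <- out[[g]]$databases[keep]
  }
  out
}

# internal: flat view of a (128 Hz) registry for fast sampling
.registry_view <- function(registry) {
  dbs <- lapply(registry$databases, function(db) {
    list(ids = names(db$identities),
         recs = db$identities)
  })
  names(dbs) <- vapply(registry$databases, `[[`, "", "database_id")
  dbs
}

#' Generate one classification example
#'
#' The single-example generator: draw `scope_size` identities starting from one
#' uniformly chosen database (topping up from other uniformly chosen databases
#' while skipping duplicates), pick the query identity q uniformly from the
#' scope, cut one blind segment per enrolled identity — two non-overlapping
#' windows (|offset difference| >= 384) from one recording for the query
#' identity — then bandpass filter and standardize all h + 1 segments.
#'
#' Uses the caller's RNG stream; seed upstream for reproducibility.
#'
#' @param registry an `ecg_registry` already resampled to 128 Hz (it will be
#'   resampled on the fly otherwise).
#' @param scope_size number of enrolled identities per example (training
#'   default 32).
#' @param seg_len segment length in samples.
#' @param segments if `FALSE`, skip filtering/standardizing and return only
#'   provenance (identities and offsets) — used for statistical audits of the
#'   generator itself.
#' @param spec,zero_phase filtering options, see [bandpass_filter()].
#' @return list with `scope_ids`, `J` (h x 384 matrix of standardized segments,
#'   unless `segments = FALSE`), `query` (length-384 segment), `label` (scope
#'   position of the true identity), and a `provenance` data.frame.
#' @export
single_example <- function(registry, scope_size = 32L, seg_len = 384L,
                           segments = TRUE, spec = filter_spec(),
                           zero_phase = TRUE) {
  if (!registry$resampled) registry <- resample_registry(registry)
  view <- .registry_view(registry)
  total <- sum(vapply(view, function(d) length(d$ids), integer(1)))
  if (total < scope_size)
    stop("registry holds ", total, " identities; scope requires ", scope_size)
  n_db <- length(view)
  # step 1: scope_size identities from one random database
  first_db <- sample.int(n_db, 1L)
  ids0 <- view[[first_db]]$ids
  scope <- if (length(ids0) <= scope_size) {
    sample(ids0, length(ids0))
  } else sample(ids0, scope_size)
  scope_db <- rep(names(view)[first_db], length(scope))
  # steps 2-6: fill up from random databases, skipping duplicates
  while (length(scope) < scope_size) {
    d <- sample.int(n_db, 1L)
    k <- sample(view[[d]]$ids, 1L)
    if (!(k %in% scope)) {
      scope <- c(scope, k)
      scope_db <- c(scope_db, names(view)[d])
    }
  }
  h <- length(scope)
  q_pos <- sample.int(h, 1L)
  segmat <- if (segments) matrix(0, h + 1L, seg_len)
  offs <- integer(h)
  recs_used <- integer(h)
  q_off <- NA_integer_
  for (k in seq_len(h)) {
    recs <- view[[scope_db[k]]]$recs[[scope[k]]]
    ri <- sample.int(length(recs), 1L)
    rec <- recs[[ri]]
    n <- length(rec$samples)
    if (k == q_pos) {
      ok <- FALSE
      for (try in 1:3) {
        if (n >= 2L * seg_len) {
          for (attempt in 1:1000) {
            o <- sample.int(n - seg_len + 1L, 2L, replace = TRUE) - 1L
            if (abs(o[1] - o[2]) >= seg_len) { ok <- TRUE; break }
          }
        }
        if (ok) break
        ri <- sample.int(length(recs), 1L)
        rec <- recs[[ri]]
        n <- length(rec$samples)
      }
      if (!ok) stop("recording for ", scope[k],
                    " too short for two non-overlapping windows")
      offs[k] <- o[1]; q_off <- o[2]
      if (segments) {
        segmat[k, ] <- rec$samples[(o[1] + 1L):(o[1] + seg_len)]
        segmat[h + 1L, ] <- rec$samples[(o[2] + 1L):(o[2] + seg_len)]
      }
    } else {
      if (n < seg_len) stop("recording for ", scope[k], " shorter than one segment")
      o <- sample.int(n - seg_len + 1L, 1L) - 1L
      offs[k] <- o
      if (segments) segmat[k, ] <- rec$samples[(o + 1L):(o + seg_len)]
    }
    recs_used[k] <- ri
  }
  if (segments) {
    segmat <- .prep_segments(segmat, spec, zero_phase)
  }
  list(scope_ids = scope,
       J = if (segments) segmat[seq_len(h), , drop = FALSE],
       query = if (segments) segmat[h + 1L, ],
       label = q_pos,
       provenance = data.frame(position = seq_len(h), identity = scope,
                               database = scope_db, recording = recs_used,
                               offset = offs,
                               query_offset = ifelse(seq_len(h) == q_pos,
                                                     q_off, NA_integer_)))
}

#' Build a dataset of classification examples
#'
#' Repeats [single_example()] `count` times on the chosen partition of the
#' registry (identities in the other partition are never touched).
#'
#' @param registry an `ecg_registry` carrying a train/validation split.
#' @param count number of examples.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param group `"train"`, `"validation"`, or `"all"` (no partitioning).
#' @param scope_size identities per scope.
#' @param segments see [single_example()].
#' @return an `ecg_dataset`: list with `J` (count x h x 384 array), `query`
#'   (count x 384), `label` (integer vector), `provenance` (data.frame),
#'   `scope_size`, `group`, `seed`.
#' @export
build_dataset <- function(registry, count, seed = 1L, group = c("train", "validation", "all"),
                          scope_size = 32L, segments = TRUE) {
  group <- match.arg(group)
  part <- if (group == "all") registry else split_registry(registry)[[group]]
  part <- resample_registry(part)
  J <- if (segments && count > 0) array(0, c(count, scope_size, 384L))
  qmat <- if (segments && count > 0) matrix(0, count, 384L)
  labels <- integer(count)
  prov <- vector("list", count)
  .with_seed(seed, {
    for (i in seq_len(count)) {
      ex <- single_example(part, scope_size = scope_size, segments = segments)
      if (segments) { J[i, , ] <- ex$J; qmat[i, ] <- ex$query }
      labels[i] <- ex$label
      pv <- ex$provenance
      pv$example <- i
      prov[[i]] <- pv
    }
  })
  structure(list(J = J, query = qmat, label = labels,
                 provenance = do.call(rbind, prov),
                 scope_size = as.integer(scope_size), group = group,
                 seed = as.integer(seed), count = as.integer(count)),
            class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset> %d examples, scope size %d, group=%s, seed=%d%s\n",
              x$count, x$scope_size, x$group, x$seed,
              if (is.null(x$J)) " (provenance only)" else ""))
  invisible(x)
}

#' Save / load a dataset
#'
#' Segment arrays go to an RDS container; counts, seed and scope size to a JSON
#' manifest next to it.
#'
#' @param dataset an `ecg_dataset`.
#' @param path RDS file path; the manifest is `<path>.json`.
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the dataset.
#' @export
save_dataset <- function(dataset, path) {
  saveRDS(unclass(dataset), path)
  jsonlite::write_json(list(count = dataset$count, scope_size = dataset$scope_size,
                            group = dataset$group, seed = dataset$seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  structure(readRDS(path), class = "ecg_dataset")
}
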