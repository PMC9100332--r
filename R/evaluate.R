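# Evaluation protocol: each identity's continuous recording is carved into an
# enrollment span [0, r), a time-separation gap, and a classification window
# [r+t, r+t+p); n query segments per identity are sampled inside the window,
# classified against the enrolled scope with voting, and summarized as
# ROC/EER/TPR-at-FPR metrics plus closed identification accuracy.

#' Protocol configuration
#'
#' @param r enrollment length (s, >= 3).
#' @param t time separation between enrollment and classification window (s).
#' @param p classification window length (s, >= 3).
#' @param n queries sampled per identity per window.
#' @param v enrollment votes.
#' @param h scope size (taken from the registry if `NA`).
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(r = 32, t = 0, p = 32, n = 8L, v = 12L, h = NA_integer_) {
  stopifnot(r >= 3, p >= 3, n >= 1, t >= 0, v >= 1)
  structure(list(r = r, t = t, p = p, n = as.integer(n), v = as.integer(v),
                 h = as.integer(h)), class = "protocol_config")
}

#' Partition a recording into enrollment and classification spans
#'
#' Enrollment is `[0, r)` and the classification window `[r + t, r + t + p)`,
#' both as half-open 0-based sample intervals at 128 Hz.
#'
#' @param recording an [ecg_recording()] at 128 Hz.
#' @param cfg a [protocol_config()].
#' @return list of `enrollment` and `window` `c(start, end)` sample intervals.
#' @export
partition_recording <- function(recording, cfg) {
  fs <- 128
  need <- (cfg$r + cfg$t + cfg$p) * fs
  n <- length(recording$samples)
  if (n < need)
    stop("protocol infeasible: recording has ", n, " samples at 128 Hz but ",
         "r + t + p = ", cfg$r + cfg$t + cfg$p, " s requires ", need,
         " (deficit ", need - n, ")")
  list(enrollment = c(0L, as.integer(round(cfg$r * fs))),
       window = c(as.integer(round((cfg$r + cfg$t) * fs)),
                  as.integer(round((cfg$r + cfg$t + cfg$p) * fs))))
}

#' Sample query segments from a classification window
#'
#' Offsets are uniform over all valid 384-sample starts inside the window;
#' segments are filtered and standardized. Uses the caller's RNG stream.
#'
#' @param recording an [ecg_recording()] at 128 Hz.
#' @param window `c(start, end)` sample interval from [partition_recording()].
#' @param n number of queries.
#' @param spec,zero_phase see [bandpass_filter()].
#' @return n x 384 matrix of standardized query segments.
#' @export
sample_queries <- function(recording, window, n, spec = filter_spec(),
                           zero_phase = TRUE) {
  lo <- window[1]; hi <- window[2] - 384L
  if (hi < lo) stop("classification window shorter than one segment")
  offs <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  segm <- matrix(0, n, 384L)
  for (i in seq_len(n)) segm[i, ] <- as.numeric(blind_segment(recording, offs[i]))
  .prep_segments(segm, spec, zero_phase)
}

#' ROC metrics by threshold sweep
#'
#' ROC points over all unique score thresholds; AUC by the trapezoid rule; EER
#' at the crossing FPR = FNR with linear interpolation between the bracketing
#' thresholds; TPR at requested FPR levels by linear interpolation along the
#' curve.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (or 0/1) true-class labels.
#' @param fpr_levels FPR operating points for the TPR table.
#' @return list with `roc` (data.frame of threshold/fpr/tpr), `auc`, `eer`,
#'   `tpr_at_fpr` (named vector).
#' @export
roc_metrics <- function(scores, labels, fpr_levels = c(0.01, 0.05, 0.10)) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("undefined metric: both classes must be present")
  np <- sum(labels); nn <- sum(!labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(s) sum(scores[labels] >= s) / np, numeric(1))
  fpr <- vapply(thr, function(s) sum(scores[!labels] >= s) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  # EER: find where fnr - fpr changes sign along the sweep
  fnr <- 1 - tpr
  d <- fnr - fpr
  i <- which(d <= 0)[1]
  eer <- if (is.na(i)) {
    utils::tail(fpr, 1)
  } else if (i == 1L || d[i] == 0) {
    (fpr[i] + fnr[i]) / 2
  } else {
    # linear interpolation between points i-1 and i
    w <- d[i - 1L] / (d[i - 1L] - d[i])
    f <- fpr[i - 1L] + w * (fpr[i] - fpr[i - 1L])
    g <- fnr[i - 1L] + w * (fnr[i] - fnr[i - 1L])
    (f + g) / 2
  }
  tpr_at <- vapply(fpr_levels, function(lv) {
    if (lv <= min(fpr)) return(tpr[which.min(fpr)])
    stats::approx(fpr, tpr, xout = lv, ties = max, rule = 2)$y
  }, numeric(1))
  names(tpr_at) <- paste0("fpr_", fpr_levels)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc, eer = eer, tpr_at_fpr = tpr_at)
}

#' Closed identification accuracy
#'
#' @param decisions identified positions (or a list of [vote()] decisions).
#' @param truths true positions.
#' @return fraction correct.
#' @export
identification_accuracy <- function(decisions, truths) {
  if (is.list(decisions))
    decisions <- vapply(decisions, function(d) d$final_identified, numeric(1))
  stopifnot(length(decisions) == length(truths), length(truths) >= 1)
  mean(decisions == truths)
}

# enroll every scope identity: list of v x 384 matrices
.enroll_scope <- function(recs, cfg) {
  lapply(recs, function(rec) split_enrollment(rec, cfg$r, cfg$v))
}

# classify one query against the scope with the v votes
.vote_query <- function(model, enrolled, query) {
  v <- nrow(enrolled[[1]])
  votes <- lapply(seq_len(v), function(j) {
    scope <- do.call(rbind, lapply(enrolled, function(E) E[j, ]))
    model_classify(model, scope, query)
  })
  vote(votes)
}

#' Run the evaluation protocol
#'
#' For each configuration: enroll the first `h` registry identities (v evenly
#' spaced enrollment windows each from `[0, r)` of their recording), sample `n`
#' queries per identity from `[r + t, r + t + p)`, classify with voting, and
#' aggregate. Individual-verification ROC trials are the aggregated
#' verification scores of every query at its true position (genuine, n per
#' identity) and at every other position (impostor, h - 1 per query).
#' Scope-verification negatives are queries from `n_out_of_scope` held-out
#' identities (beyond the first h), when available.
#'
#' @param model a trained `scope_model`.
#' @param registry an `ecg_registry`; identities beyond the scope serve as
#'   out-of-scope negatives.
#' @param cfgs a [protocol_config()] or list of them (e.g. a sweep over `t`).
#' @param seed integer seed for query sampling.
#' @param n_out_of_scope how many held-out identities to use for scope
#'   verification negatives (0 disables).
#' @return a `metrics_report` (list, one element per configuration) with
#'   identification accuracy, individual/scope verification metrics and the
#'   protocol tuple.
#' @export
run_protocol <- function(model, registry, cfgs, seed = 1L, n_out_of_scope = 0L) {
  if (inherits(cfgs, "protocol_config")) cfgs <- list(cfgs)
  registry <- resample_registry(registry)
  view <- .registry_view(registry)
  all_ids <- registry_identities(registry)
  get_rec <- function(id) {
    for (d in view) if (id %in% names(d$recs)) return(d$recs[[id]][[1]])
    stop("identity not found: ", id)
  }
  reports <- lapply(seq_along(cfgs), function(ci) {
    cfg <- cfgs[[ci]]
    h <- if (is.na(cfg$h)) length(all_ids) - n_out_of_scope else cfg$h
    if (h < 2L) stop("scope must hold at least 2 identities")
    scope_ids <- all_ids[seq_len(h)]
    oos_ids <- if (n_out_of_scope > 0L)
      all_ids[(h + 1L):min(length(all_ids), h + n_out_of_scope)] else character(0)
    recs <- lapply(scope_ids, get_rec)
    parts <- lapply(recs, partition_recording, cfg = cfg)
    enrolled <- .enroll_scope(recs, cfg)
    .with_seed(seed + 7L * ci, {
      truths <- integer(0); preds <- integer(0)
      gen_scores <- numeric(0); imp_scores <- numeric(0)
      scope_pos_scores <- numeric(0)
      for (k in seq_len(h)) {
        queries <- sample_queries(recs[[k]], parts[[k]]$window, cfg$n)
        for (i in seq_len(cfg$n)) {
          dec <- .vote_query(model, enrolled, queries[i, ])
          truths <- c(truths, k)
          preds <- c(preds, dec$final_identified)
          gen_scores <- c(gen_scores, dec$individual_scores[k])
          imp_scores <- c(imp_scores, dec$individual_scores[-k])
          scope_pos_scores <- c(scope_pos_scores, scope_verify(dec)$score)
        }
      }
      scope_neg_scores <- numeric(0)
      for (id in oos_ids) {
        rec <- get_rec(id)
        part <- partition_recording(rec, cfg)
        queries <- sample_queries(rec, part$window, cfg$n)
        for (i in seq_len(cfg$n)) {
          dec <- .vote_query(model, enrolled, queries[i, ])
          scope_neg_scores <- c(scope_neg_scores, scope_verify(dec)$score)
        }
      }
      indiv <- roc_metrics(c(gen_scores, imp_scores),
                           c(rep(TRUE, length(gen_scores)),
                             rep(FALSE, length(imp_scores))),
                           fpr_levels = c(0.01, 0.05, 0.10))
      scope_roc <- if (length(scope_neg_scores) > 0)
        roc_metrics(c(scope_pos_scores, scope_neg_scores),
                    c(rep(TRUE, length(scope_pos_scores)),
                      rep(FALSE, length(scope_neg_scores))),
                    fpr_levels = c(0.10, 0.20, 0.30))
      list(config = cfg, h = h,
           id_accuracy = identification_accuracy(preds, truths),
           individual_verification = indiv[c("auc", "eer", "tpr_at_fpr")],
           individual_roc = indiv$roc,
           scope_verification = if (!is.null(scope_roc))
             scope_roc[c("auc", "eer", "tpr_at_fpr")],
           scope_roc = scope_roc$roc,
           n_genuine = length(gen_scores), n_impostor = length(imp_scores))
    })
  })
  class(reports) <- "metrics_report"
  reports
}

#' Metric-vs-time-separation sweep
#'
#' Runs [run_protocol()] for each `t` and returns a tidy table of the headline
#' metrics against time separation.
#'
#' @param model,registry,seed,n_out_of_scope see [run_protocol()].
#' @param t_values time separations (s) to sweep.
#' @param base_cfg a [protocol_config()] providing (r, p, n, v, h).
#' @return data.frame with one row per `t`.
#' @export
sweep_time_separation <- function(model, registry, t_values,
                                  base_cfg = protocol_config(), seed = 1L,
                                  n_out_of_scope = 0L) {
  cfgs <- lapply(t_values, function(tt) {
    cfg <- base_cfg; cfg$t <- tt; cfg
  })
  reps <- run_protocol(model, registry, cfgs, seed = seed,
                       n_out_of_scope = n_out_of_scope)
  do.call(rbind, lapply(reps, function(r) {
    data.frame(t = r$config$t, id_accuracy = r$id_accuracy,
               indiv_auc = r$individual_verification$auc,
               indiv_eer = r$individual_verification$eer)
  }))
}
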