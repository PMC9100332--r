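# Voting over long enrollments: an enrollment recording longer than 3 s is cut
# into v evenly spaced (possibly overlapping) 3 s windows; vote j pairs the
# j-th enrollment window of every scope identity with the query. The majority
# identity wins, ties broken by the largest mean identification probability.

#' Split an enrollment recording into v preprocessed windows
#'
#' Window starts are evenly spaced over `[0, (r - 3) * 128]` samples, so
#' windows overlap whenever `(r - 3) / (v - 1) < 3` seconds. Each window is
#' bandpass filtered and standardized.
#'
#' @param recording an [ecg_recording()] at 128 Hz.
#' @param r enrollment length in seconds (>= 3); the recording must cover it.
#' @param v number of windows (>= 1).
#' @param offset_s start of the enrollment span within the recording (s).
#' @param spec,zero_phase see [bandpass_filter()].
#' @return v x 384 matrix of standardized segments.
#' @export
split_enrollment <- function(recording, r, v, offset_s = 0,
                             spec = filter_spec(), zero_phase = TRUE) {
  if (v < 1L) stop("v must be >= 1")
  if (r < 3) stop("enrollment length r must be >= 3 s")
  fs <- 128L
  base <- round(offset_s * fs)
  if (base + r * fs > length(recording$samples))
    stop("recording does not cover the enrollment span")
  span <- (r - 3) * fs
  starts <- if (v == 1L) 0 else round(seq(0, span, length.out = v))
  segm <- matrix(0, v, 384L)
  for (j in seq_len(v)) {
    seg <- blind_segment(recording, base + starts[j])
    segm[j, ] <- as.numeric(seg)
  }
  .prep_segments(segm, spec, zero_phase)
}

#' Aggregate v classification votes into a final decision
#'
#' `votes` is a list of per-vote model outputs over one common scope. The final
#' identified position is the modal argmax of the identification
#' distributions; ties are broken by the largest mean identification
#' probability. The final individual verification at each position is the
#' majority of the per-vote thresholded decisions, ties resolved by the mean
#' verification probability against the threshold; the mean probability is kept
#' as the position's score.
#'
#' @param votes list of lists with `verification` and `identification`
#'   (each length h), e.g. from [model_classify()].
#' @param threshold per-vote verification decision threshold.
#' @return a `final_decision`: `final_identified`, `vote_counts`,
#'   `mean_id_probs`, `individual_verified` (h logicals),
#'   `individual_scores` (h mean probabilities), `v`.
#' @export
vote <- function(votes, threshold = 0.5) {
  if (length(votes) < 1L) stop("empty vote set")
  idm <- do.call(rbind, lapply(votes, function(x) as.numeric(x$identification)))
  vem <- do.call(rbind, lapply(votes, function(x) as.numeric(x$verification)))
  h <- ncol(idm)
  picks <- max.col(idm, ties.method = "first")
  counts <- tabulate(picks, nbins = h)
  mean_id <- colMeans(idm)
  top <- which(counts == max(counts))
  final <- if (length(top) == 1L) top else top[which.max(mean_id[top])]
  mean_ve <- colMeans(vem)
  yes <- colSums(vem >= threshold)
  no <- nrow(vem) - yes
  verified <- ifelse(yes != no, yes > no, mean_ve >= threshold)
  structure(list(final_identified = final, vote_counts = counts,
                 mean_id_probs = mean_id, individual_verified = verified,
                 individual_scores = mean_ve, v = length(votes)),
            class = "final_decision")
}

#' Scope verification from a final decision
#'
#' The scope-verification score is the aggregated individual-verification
#' probability at the final identified position; acceptance thresholds this
#' continuous score (swept for ROC curves).
#'
#' @param decision a [vote()] result.
#' @param threshold acceptance threshold.
#' @return list with `score` and `accept`.
#' @export
scope_verify <- function(decision, threshold = 0.5) {
  score <- decision$individual_scores[decision$final_identified]
  list(score = unname(score), accept = unname(score >= threshold))
}
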