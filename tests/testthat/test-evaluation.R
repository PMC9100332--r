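test_that("recording partition matches the protocol geometry", {
  rec <- ecg_recording(rnorm(300 * 128), 128, "a")
  cfg <- protocol_config(r = 32, t = 0, p = 256, n = 8L, v = 12L)
  part <- partition_recording(rec, cfg)
  expect_equal(part$enrollment, c(0L, 32L * 128L))
  expect_equal(part$window, c(32L * 128L, 288L * 128L))   # [32, 288) s
  # t = 0: window abuts enrollment exactly
  expect_equal(part$window[1], part$enrollment[2])
  # one sample short -> protocol-infeasible error naming the deficit
  rec_short <- ecg_recording(rnorm(288 * 128 - 1), 128, "a")
  expect_error(partition_recording(rec_short, cfg), "deficit 1")
  # t > 0: spans disjoint
  cfg2 <- protocol_config(r = 10, t = 5, p = 10)
  part2 <- partition_recording(ecg_recording(rnorm(26 * 128), 128, "a"), cfg2)
  expect_gte(part2$window[1], part2$enrollment[2])
})

test_that("query sampling is seeded, in-window and degenerate-safe", {
  rec <- ecg_recording(rnorm(40 * 128), 128, "a")
  cfg <- protocol_config(r = 10, t = 0, p = 3, n = 5L)
  part <- partition_recording(rec, cfg)
  # p = 3 s: exactly one possible window, all n queries identical
  set.seed(1)
  qs <- sample_queries(rec, part$window, 5L)
  expect_equal(dim(qs), c(5L, 384L))
  expect_identical(qs[1, ], qs[4, ])
  # fixed seed -> identical offsets
  cfg2 <- protocol_config(r = 10, t = 0, p = 20, n = 6L)
  part2 <- partition_recording(rec, cfg2)
  set.seed(7); a <- sample_queries(rec, part2$window, 6L)
  set.seed(7); b <- sample_queries(rec, part2$window, 6L)
  expect_identical(a, b)
})

test_that("ROC metrics match brute-force enumeration and behave at the extremes", {
  # perfectly separated scores
  r <- roc_metrics(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$eer, 0)
  expect_equal(unname(r$tpr_at_fpr), c(1, 1, 1))
  # the spec'd small case against exhaustive threshold enumeration
  scores <- c(0.9, 0.8, 0.4, 0.2); labels <- c(TRUE, TRUE, FALSE, TRUE)
  r2 <- roc_metrics(scores, labels)
  # brute force over all thresholds
  ths <- sort(unique(c(scores, Inf)), decreasing = TRUE)
  tpr <- sapply(ths, function(s) mean(scores[labels] >= s))
  fpr <- sapply(ths, function(s) mean(scores[!labels] >= s))
  auc_bf <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(r2$auc, auc_bf)
  expect_equal(r2$roc$tpr, tpr, ignore_attr = TRUE)
  # random scores: AUC near 0.5 (Monte-Carlo null)
  set.seed(5)
  s <- runif(10000); l <- runif(10000) > 0.5
  expect_lt(abs(roc_metrics(s, l)$auc - 0.5), 0.02)
  expect_lt(abs(roc_metrics(s, l)$eer - 0.5), 0.02)
  expect_error(roc_metrics(s, rep(TRUE, 10000)), "both classes")
})

test_that("EER/AUC agree with an independent implementation on random sets", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(50:1000, 1)
    lab <- c(rep(TRUE, n), rep(FALSE, n))
    sc <- c(rnorm(n, 1), rnorm(n, 0))
    mine <- roc_metrics(sc, lab)
    ref <- pROC::roc(response = lab, predictor = sc, quiet = TRUE,
                     direction = "<")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
  }
})

test_that("identification accuracy is a plain fraction", {
  expect_equal(identification_accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(identification_accuracy(c(2, 3, 1), c(1, 2, 3)), 0)
  d <- c(1, 2, 2, 4, 5, 1, 7, 8, 3, 10)
  t <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(identification_accuracy(d, t), 0.7)
})

test_that("protocol reports are internally consistent and reproducible", {
  reg <- resample_registry(synth_registry(1L, 10L, 128, seed = 71,
                                          duration_s = 60,
                                          noise = noise_spec_easy()))
  model <- micro_model()
  cfg <- protocol_config(r = 9, t = 0, p = 30, n = 2L, v = 2L, h = 8L)
  rep1 <- run_protocol(model, reg, cfg, seed = 3, n_out_of_scope = 2L)
  r <- rep1[[1]]
  expect_equal(r$h, 8L)
  expect_equal(r$n_genuine, 8L * 2L)
  expect_equal(r$n_impostor, 8L * 2L * 7L)
  expect_true(r$id_accuracy >= 0 && r$id_accuracy <= 1)
  tpr <- r$individual_verification$tpr_at_fpr
  expect_true(tpr["fpr_0.1"] >= tpr["fpr_0.05"])
  expect_true(tpr["fpr_0.05"] >= tpr["fpr_0.01"])
  expect_false(is.null(r$scope_verification))
  # bit-reproducible under the seed
  rep2 <- run_protocol(model, reg, cfg, seed = 3, n_out_of_scope = 2L)
  expect_identical(rep1[[1]]$individual_roc, rep2[[1]]$individual_roc)
})
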