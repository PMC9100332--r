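test_that("learning rate schedule decays to its floor", {
  expect_equal(lr_schedule(0), 0.000012 * exp(2) + 0.00008)
  expect_equal(lr_schedule(0), 1.6867e-4, tolerance = 1e-3)
  expect_lt(lr_schedule(10), lr_schedule(0))
  eps <- lr_schedule(c(0, 50, 200, 1000))
  expect_true(all(diff(eps) < 0))
  expect_lt(lr_schedule(1000) - 0.00008, 1e-16)
  expect_error(lr_schedule(-1), ">= 0")
})

test_that("label smoothing reproduces the stated constants", {
  expect_equal(smooth_labels(c(1, 0), 0.1), c(0.95, 0.05))
  sm <- smooth_labels(3L, 0.1, "multiclass", K = 32L)
  expect_equal(sm[1, 3], 0.903125)
  expect_equal(sm[1, 1], 0.003125)
  expect_equal(sum(sm), 1)
  expect_identical(smooth_labels(c(1, 0), 0), c(1, 0))
  expect_error(smooth_labels(1, 1.2), "eps")
})

test_that("joint loss matches a brute-force oracle and its closed forms", {
  # perfect unsmoothed outputs -> loss ~ 0
  out_perfect <- list(verification = c(1 - 1e-12, rep(1e-12, 7)),
                      identification = c(1 - 1e-12, rep(1e-12 / 7, 7)))
  expect_lt(joint_loss(out_perfect, 1L, eps = 0), 1e-6)
  # uniform identification over 32 -> CE term log(32) against one-hot
  out_unif <- list(verification = rep(0.5, 32), identification = rep(1 / 32, 32))
  expect_equal(joint_loss(out_unif, 4L, eps = 0),
               -log(0.5) + log(32), tolerance = 1e-9)
  # brute-force per-element oracle on random outputs
  set.seed(3)
  h <- 8L
  pv <- runif(h); pid <- {z <- runif(h); z / sum(z)}
  q <- 5L; eps <- 0.1
  oracle <- 0
  for (k in seq_len(h)) {
    t <- if (k == q) 1 - eps / 2 else eps / 2
    oracle <- oracle - (t * log(pv[k]) + (1 - t) * log(1 - pv[k])) / h
    tid <- if (k == q) 1 - eps + eps / h else eps / h
    oracle <- oracle - tid * log(pid[k])
  }
  expect_equal(joint_loss(list(verification = pv, identification = pid), q, eps),
               oracle, tolerance = 1e-9)
})

test_that("combined accuracy is the literal three-way mean", {
  expect_equal(combined_accuracy(1, 0, 1), 2 / 3)
  expect_equal(combined_accuracy(0.4, 0.4, 0.4), 0.4)
  expect_equal(combined_accuracy(1, 0, 1, corrected = TRUE), 1)
  expect_error(combined_accuracy(1.2, 0, 1), "not TRUE")
})

test_that("training updates parameters, records history and early-stops", {
  reg <- tiny_registry(seed = 61, duration_s = 20)
  train_ds <- build_dataset(reg, 24L, seed = 2, group = "train", scope_size = 4L)
  val_ds <- build_dataset(reg, 8L, seed = 3, group = "validation", scope_size = 4L)
  model <- micro_model(dropout = 0.1)
  cfg <- train_config(batch_size = 4L, steps_per_epoch = 2L, max_epochs = 4L,
                      patience = 3L, lr_multiplier = 5, seed = 11L)
  fit <- train_model(model, train_ds, val_ds, cfg)
  expect_equal(fit$epochs_run, nrow(fit$history))
  expect_true(all(c("train_loss", "val_loss", "val_id_acc", "lr") %in%
                    names(fit$history)))
  expect_false(identical(fit$model$params$conv$W, model$params$conv$W))
  expect_equal(fit$history$lr, 5 * lr_schedule(fit$history$epoch))
  # seeded reruns are identical
  fit2 <- train_model(model, train_ds, val_ds, cfg)
  expect_identical(fit$history, fit2$history)
  expect_equal(fit$model$params, fit2$model$params)
  # checkpoint round-trip reproduces the recorded validation loss
  path <- withr::local_tempfile(fileext = ".rds")
  model_save(fit$model, path)
  back <- model_load(path)
  ev <- ecgscope:::.evaluate_dataset(back, val_ds, cfg$label_smoothing,
                                     cfg$loss_weights)
  expect_equal(ev$loss, fit$history$val_loss[fit$best_epoch + 1L],
               tolerance = 1e-5)
})

test_that("early stopping follows the patience rule on a scripted loss trace", {
  # validation losses [1.0, 0.9, 0.95, 0.96, 0.97]: stop after the 5th epoch,
  # best = 2nd. Reproduced by patching the validation evaluator.
  losses <- c(1.0, 0.9, 0.95, 0.96, 0.97, 0.5)
  i <- 0
  fake_eval <- function(model, dataset, eps_ls, weights, chunk = 64L) {
    i <<- i + 1
    list(loss = losses[i], id_acc = 0.5, ver_tpr = 0.5, ver_fpr = 0.5)
  }
  reg <- tiny_registry(seed = 62, duration_s = 20)
  train_ds <- build_dataset(reg, 8L, seed = 2, group = "train", scope_size = 4L)
  val_ds <- build_dataset(reg, 4L, seed = 3, group = "validation", scope_size = 4L)
  model <- micro_model()
  testthat::with_mocked_bindings(
    .evaluate_dataset = fake_eval,
    .package = "ecgscope",
    {
      fit <- train_model(model, train_ds, val_ds,
                         train_config(batch_size = 2L, steps_per_epoch = 1L,
                                      max_epochs = 10L, patience = 3L, seed = 1L))
      expect_equal(fit$epochs_run, 5L)
      expect_equal(fit$best_epoch, 1L)   # 0-based: the second epoch
    })
})
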