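test_that("config arithmetic reproduces the architecture dimensions", {
  cfg <- model_config()
  expect_equal(cfg$conv_out, 384L - 33L + 1L)   # valid convolution: 352
  expect_equal(cfg$n_tokens, 22L)
  expect_equal(cfg$seq_len, 46L)
  expect_equal(cfg$d_model, 512L)
  # width multiplier scales widths, never lengths
  small <- model_config(width_mult = 1 / 8)
  expect_equal(small$d_model, 64L)
  expect_equal(small$ff_dim, 256L)
  expect_equal(small$ver_widths, c(64L, 64L, 64L, 64L, 32L, 16L))
  expect_equal(small$n_tokens, 22L)
  expect_equal(small$seq_len, 46L)
  expect_error(model_config(d_model = 100L, n_heads = 8L), "divisible")
})

test_that("feature space expansion yields 22 nonnegative tokens per segment", {
  model <- micro_model()
  segs <- random_segments(3)
  fse <- ecgscope:::.fse_fwd(segs, model$params, model$config)
  expect_equal(dim(fse$Z), c(3L * 22L, 16L))
  expect_true(all(fse$Z >= 0))       # max of ReLU outputs
  expect_error(ecgscope:::.network_fwd(model, random_segments(2)[, 1:100], 1L, 1L),
               "subscript|dim|length")
})

test_that("composite sequences have the documented 46-token layout", {
  model <- micro_model()
  cfg <- model$config
  # zero embeddings/cls/pos isolate the token copy
  model$params$emb_enr[] <- 0; model$params$emb_qry[] <- 0
  model$params$pos[] <- 0
  model$params$cls_ve[] <- 0; model$params$cls_id[] <- 0
  segs <- random_segments(4)   # one example: h = 3 + query
  fse <- ecgscope:::.fse_fwd(segs, model$params, cfg)
  ix <- ecgscope:::.composite_index(1L, 3L, cfg)
  X0 <- matrix(0, 3L * cfg$seq_len, cfg$d_model)
  X0[ix$dst_enr, ] <- fse$Z[ix$zid_enr, ]
  X0[ix$dst_qry, ] <- fse$Z[ix$zid_qry, ]
  # enrolled half of pair k equals identity k's expanded tokens
  n_seg <- 4L
  Zk2 <- fse$Z[2L + (seq_len(22L) - 1L) * n_seg, ]   # segment 2 tokens
  expect_equal(X0[(1L * cfg$seq_len) + 2L + seq_len(22L), ], Zk2)
  # query halves are identical across the h pairings
  q1 <- X0[(0L * cfg$seq_len) + 24L + seq_len(22L), ]
  q3 <- X0[(2L * cfg$seq_len) + 24L + seq_len(22L), ]
  expect_identical(q1, q3)
})

test_that("outputs are valid probabilities for every scope size", {
  model <- micro_model()
  for (h in c(1L, 2L, 5L, 11L)) {
    scope <- random_segments(h, seed = h)
    out <- model_classify(model, scope, random_segments(1, seed = 99)[1, ])
    expect_length(out$verification, h)
    expect_true(all(out$verification > 0 & out$verification < 1))
    expect_length(out$identification, h)
    expect_lt(abs(sum(out$identification) - 1), 1e-5)
    if (h == 1L) expect_equal(out$identification, 1)
  }
  expect_error(model_classify(model, matrix(numeric(0), 0, 384),
                              random_segments(1)[1, ]),
               "empty")
})

test_that("evaluation mode is deterministic and duplication-consistent", {
  model <- micro_model(dropout = 0.1)   # dropout configured but off in eval
  scope <- random_segments(4, seed = 5)
  q <- random_segments(1, seed = 6)[1, ]
  o1 <- model_classify(model, scope, q)
  o2 <- model_classify(model, scope, q)
  expect_identical(o1, o2)
  # duplicated enrolled segment -> equal verification probabilities
  scope2 <- rbind(scope, scope[2, ])
  o3 <- model_classify(model, scope2, q)
  expect_equal(o3$verification[2], o3$verification[5], tolerance = 1e-5)
})

test_that("permuting the scope permutes both outputs consistently", {
  model <- micro_model()
  h <- 6L
  scope <- random_segments(h, seed = 8)
  q <- random_segments(1, seed = 9)[1, ]
  base <- model_classify(model, scope, q)
  set.seed(10)
  for (rep in 1:3) {
    pi <- sample(h)
    out <- model_classify(model, scope[pi, ], q)
    expect_equal(out$verification, base$verification[pi], tolerance = 1e-5)
    expect_equal(out$identification, base$identification[pi], tolerance = 1e-5)
  }
})

test_that("verification path depends only on its own pair; identification on all", {
  model <- micro_model()
  h <- 4L
  scope <- random_segments(h, seed = 12)
  q <- random_segments(1, seed = 13)[1, ]
  base <- model_classify(model, scope, q)
  scope2 <- scope
  scope2[3, ] <- random_segments(1, seed = 14)[1, ]   # edit position 3 only
  out <- model_classify(model, scope2, q)
  expect_equal(out$verification[-3], base$verification[-3], tolerance = 1e-6)
  expect_gt(abs(out$verification[3] - base$verification[3]), 1e-8)
  # the scope-aware identification distribution shifts at other positions too
  expect_gt(max(abs(out$identification[-3] - base$identification[-3])), 1e-8)
})

test_that("verification head parameter count matches the closed-form sum", {
  model <- micro_model()
  w <- model$config$ver_widths
  ins <- c(model$config$d_model, w)
  expected <- sum(ins[-length(ins)] * w + w + 2 * w) +   # FC W+b, BN gamma+beta
    (w[length(w)] * 1 + 1 + 2)                            # output FC + BN
  desc <- model_describe(model)
  got <- desc$parameters[desc$component %in% c("ver_head", "ver_out")]
  expect_equal(sum(got), expected)
})

test_that("checkpoints round-trip bit-exactly", {
  model <- micro_model(seed = 77)
  path <- withr::local_tempfile(fileext = ".rds")
  model_save(model, path)
  back <- model_load(path)
  expect_equal(back$params, model$params)
  scope <- random_segments(3, seed = 1)
  q <- random_segments(1, seed = 2)[1, ]
  expect_identical(model_classify(model, scope, q), model_classify(back, scope, q))
})
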