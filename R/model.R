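#' Model configuration
#'
#' Hyperparameters of the sequence-pair network. The defaults reproduce the
#' full-size architecture: a 1-D convolution with 512 filters of kernel 33 at
#' stride 1 followed by ReLU and 16/16 max-pooling expands a 384-sample segment
#' into a 22-token sequence of width `d_model = 512`; two classification tokens
#' plus segment embeddings form 46-token composite sequences; the pair encoder
#' and the ID encoder each stack 4 transformer encoder layers (8 heads,
#' feedforward width 2048, dropout 0.1); the verification head is
#' FC512x4/FC256/FC128 with batch norm + ReLU and a sigmoid output; the ID head
#' is a shared FC256 + logit layer followed by softmax over the scope.
#'
#' `width_mult` scales all widths jointly (d_model, conv filters, feedforward
#' and head widths) while preserving every sequence-length relationship
#' (384 -> 352 -> 22 -> 46), which is how desk-scale models are built.
#'
#' @param d_model token width of both encoders.
#' @param conv_filters,conv_kernel,conv_stride convolution of the feature space
#'   expansion. `conv_filters` must equal `d_model`.
#' @param pool_kernel,pool_stride max-pooling of the feature space expansion.
#' @param pair_layers,id_layers number of transformer encoder layers.
#' @param n_heads attention heads; must divide `d_model`.
#' @param ff_dim feedforward width inside each encoder layer.
#' @param dropout dropout probability applied to each sublayer output during
#'   training.
#' @param ver_widths hidden widths of the verification head.
#' @param id_width hidden width of the ID classifier head.
#' @param seg_len input segment length in samples (3 s at 128 Hz).
#' @param width_mult joint width multiplier (e.g. 1/8 for a desk-scale model).
#' @return a `scope_model_config` list with derived lengths `n_tokens` (22) and
#'   `seq_len` (46).
#' @export
model_config <- function(d_model = 512L, conv_filters = d_model, conv_kernel = 33L,
                         conv_stride = 1L, pool_kernel = 16L, pool_stride = 16L,
                         pair_layers = 4L, id_layers = 4L, n_heads = 8L,
                         ff_dim = 2048L, dropout = 0.1,
                         ver_widths = c(512L, 512L, 512L, 512L, 256L, 128L),
                         id_width = 256L, seg_len = 384L, width_mult = 1) {
  scale_w <- function(w) {
    w <- as.integer(round(w * width_mult))
    pmax(w, n_heads)
  }
  if (width_mult != 1) {
    d_model <- scale_w(d_model); conv_filters <- d_model
    ff_dim <- scale_w(ff_dim); ver_widths <- scale_w(ver_widths)
    id_width <- scale_w(id_width)
  }
  d_model <- as.integer(d_model)
  if (conv_filters != d_model)
    stop("conv_filters must equal d_model (pooled features are the tokens)")
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  if (conv_stride != 1L) stop("only stride-1 convolution is supported")
  conv_out <- seg_len - conv_kernel + 1L
  if (conv_out %% pool_stride != 0L || pool_kernel != pool_stride)
    stop("pooling must tile the convolution output exactly")
  n_tokens <- conv_out %/% pool_stride
  cfg <- list(d_model = d_model, conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel), conv_stride = 1L,
              pool_kernel = as.integer(pool_kernel), pool_stride = as.integer(pool_stride),
              pair_layers = as.integer(pair_layers), id_layers = as.integer(id_layers),
              n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
              dropout = dropout, ver_widths = as.integer(ver_widths),
              id_width = as.integer(id_width), seg_len = as.integer(seg_len),
              conv_out = as.integer(conv_out), n_tokens = as.integer(n_tokens),
              seq_len = as.integer(2L + 2L * n_tokens), width_mult = width_mult)
  class(cfg) <- "scope_model_config"
  cfg
}

.init_linear <- function(n_in, n_out) {
  lim <- sqrt(1 / n_in)
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = rep(0, n_out))
}

.init_encoder_layer <- function(d, ff) {
  lim <- sqrt(1 / d)
  rmat <- function(a, b) matrix(stats::runif(a * b, -sqrt(1 / a), sqrt(1 / a)), a, b)
  list(Wq = rmat(d, d), bq = rep(0, d), Wk = rmat(d, d), bk = rep(0, d),
       Wv = rmat(d, d), bv = rep(0, d), Wo = rmat(d, d), bo = rep(0, d),
       ln1_g = rep(1, d), ln1_b = rep(0, d),
       W1 = rmat(d, ff), b1 = rep(0, ff), W2 = rmat(ff, d), b2 = rep(0, d),
       ln2_g = rep(1, d), ln2_b = rep(0, d))
}

.init_bn_state <- function(n) list(mean = rep(0, n), var = rep(1, n))

#' Initialize a model
#'
#' Weights use uniform fan-in initialization; classification tokens, segment
#' embeddings and the learned position table are drawn from N(0, 0.02).
#'
#' @param config a [model_config()].
#' @param seed integer seed controlling the draw.
#' @return a `scope_model` object (parameters, batch-norm state, config).
#' @export
model_init <- function(config = model_config(), seed = 1L) {
  d <- config$d_model
  params <- .with_seed(seed, {
    p <- list()
    lim <- sqrt(1 / config$conv_kernel)
    p$conv <- list(W = matrix(stats::runif(config$conv_kernel * d, -lim, lim),
                              config$conv_kernel, d),
                   b = rep(0, d))
    p$cls_ve <- stats::rnorm(d, 0, 0.02)
    p$cls_id <- stats::rnorm(d, 0, 0.02)
    p$emb_enr <- stats::rnorm(d, 0, 0.02)
    p$emb_qry <- stats::rnorm(d, 0, 0.02)
    p$pos <- matrix(stats::rnorm(config$seq_len * d, 0, 0.02), config$seq_len, d)
    p$pair_enc <- lapply(seq_len(config$pair_layers),
                         function(i) .init_encoder_layer(d, config$ff_dim))
    p$id_enc <- lapply(seq_len(config$id_layers),
                       function(i) .init_encoder_layer(d, config$ff_dim))
    widths <- config$ver_widths
    ins <- c(d, widths)
    p$ver_head <- lapply(seq_along(widths), function(i) {
      c(.init_linear(ins[i], widths[i]),
        list(gamma = rep(1, widths[i]), beta = rep(0, widths[i])))
    })
    p$ver_out <- c(.init_linear(widths[length(widths)], 1L),
                   list(gamma = 1, beta = 0))
    p$id_head <- c(.init_linear(d, config$id_width),
                   list(gamma = rep(1, config$id_width), beta = rep(0, config$id_width)))
    p$id_out <- c(.init_linear(config$id_width, 1L), list(gamma = 1, beta = 0))
    p
  })
  bn <- list(
    ver_head = lapply(config$ver_widths, .init_bn_state),
    ver_out = .init_bn_state(1L),
    id_head = .init_bn_state(config$id_width),
    id_out = .init_bn_state(1L)
  )
  structure(list(params = params, bn = bn, config = config, init_seed = seed),
            class = "scope_model")
}

#' @export
print.scope_model <- function(x, ...) {
  cfg <- x$config
  cat("<scope_model> d_model=", cfg$d_model, ", heads=", cfg$n_heads,
      ", pair/id layers=", cfg$pair_layers, "/", cfg$id_layers,
      ", parameters=", format(.n_params(x$params), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Summarize model layers and parameter counts
#'
#' @param model a `scope_model`.
#' @return data.frame with one row per component and its parameter count.
#' @export
model_describe <- function(model) {
  p <- model$params
  comp <- c("conv", "cls_ve", "cls_id", "emb_enr", "emb_qry", "pos",
            "pair_enc", "id_enc", "ver_head", "ver_out", "id_head", "id_out")
  data.frame(component = comp,
             parameters = vapply(comp, function(k) .n_params(p[[k]]), numeric(1)),
             row.names = NULL)
}

# ---- feature space expansion -------------------------------------------------
# segs: (n_seg x 384). Output Z: (n_seg * n_tokens) x d, rows ordered with the
# SEGMENT index varying fastest (row = seg + (tok-1) * n_seg), which keeps the
# max-pool groups contiguous. Caches im2col matrix + argmax for backward.

.fse_fwd <- function(segs, params, cfg, need_cache = FALSE) {
  n_seg <- nrow(segs)
  k <- cfg$conv_kernel
  # im2col: row (seg + (pos-1)*n_seg) holds segs[seg, pos:(pos+k-1)]
  idx <- outer(seq_len(cfg$conv_out), 0:(k - 1L), "+")      # conv_out x k
  M <- matrix(segs[, idx], n_seg * cfg$conv_out, k)
  A <- .relu_fwd(.linear_fwd(M, params$conv$W, params$conv$b))
  # max-pool: token t pools rows of positions (t-1)*pool+1 .. t*pool
  d <- cfg$d_model
  Z <- matrix(-Inf, n_seg * cfg$n_tokens, d)
  arg <- if (need_cache) matrix(0L, n_seg * cfg$n_tokens, d) else NULL
  for (t in seq_len(cfg$n_tokens)) {
    zrows <- ((t - 1L) * n_seg + 1L):(t * n_seg)
    best <- Z[zrows, , drop = FALSE]
    for (j in seq_len(cfg$pool_kernel)) {
      pos <- (t - 1L) * cfg$pool_stride + j
      cand <- A[((pos - 1L) * n_seg + 1L):(pos * n_seg), , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      if (need_cache) {
        ar <- arg[zrows, , drop = FALSE]
        ar[upd] <- j
        arg[zrows, ] <- ar
      }
    }
    Z[zrows, ] <- best
  }
  list(Z = Z, cache = if (need_cache) list(M = M, act = A, arg = arg, n_seg = n_seg))
}

.fse_bwd <- function(dZ, cache, cfg) {
  n_seg <- cache$n_seg
  nZ <- nrow(dZ)
  nA <- n_seg * cfg$conv_out
  d <- cfg$d_model
  # Z row z covers segment seg = (z-1) %% n_seg + 1 at token t = (z-1) %/% n_seg + 1;
  # its argmax sits at conv position (t-1)*pool + arg, i.e. A row seg + (pos-1)*n_seg
  z <- seq_len(nZ) - 1L
  seg <- z %% n_seg + 1L
  tok <- z %/% n_seg
  arow <- seg + (tok * cfg$pool_stride + cache$arg - 1L) * n_seg   # nZ x d matrix
  lin <- arow + .bc((seq_len(d) - 1L) * nA, nZ)
  dA <- numeric(nA * d)
  dA[lin] <- dZ
  dim(dA) <- c(nA, d)
  dY <- relu_bwd_cpp(dA, cache$act)
  list(dW = crossprod(cache$M, dY), db = colSums(dY))
}

# ---- transformer encoder stack ----------------------------------------------
# X: (n_seq * len) x d, sequence-major. Post-layer-norm residual blocks as in
# the original transformer encoder.

.encoder_fwd <- function(X, layers, n_seq, len, cfg, train, need_cache = FALSE) {
  caches <- if (need_cache) vector("list", length(layers))
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    Q <- .linear_fwd(X, L$Wq, L$bq)
    K <- .linear_fwd(X, L$Wk, L$bk)
    V <- .linear_fwd(X, L$Wv, L$bv)
    att <- attn_forward_cpp(Q, K, V, n_seq, len, cfg$n_heads)
    O <- .linear_fwd(att$out, L$Wo, L$bo)
    dr1 <- .dropout_fwd(O, cfg$dropout, train)
    ln1 <- .layernorm_fwd(X + dr1$out, L$ln1_g, L$ln1_b)
    H <- ln1$out
    F1 <- .linear_fwd(H, L$W1, L$b1)
    F1a <- .relu_fwd(F1)
    F2 <- .linear_fwd(F1a, L$W2, L$b2)
    dr2 <- .dropout_fwd(F2, cfg$dropout, train)
    ln2 <- .layernorm_fwd(H + dr2$out, L$ln2_g, L$ln2_b)
    if (need_cache) {
      caches[[i]] <- list(X = X, Q = Q, K = K, V = V, P = att$P, attn_out = att$out,
                          mask1 = dr1$mask, ln1 = ln1, H = H, F1a = F1a,
                          mask2 = dr2$mask, ln2 = ln2)
    }
    X <- ln2$out
  }
  list(out = X, caches = caches)
}

.encoder_bwd <- function(dX, layers, caches, n_seq, len, cfg) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    L <- layers[[i]]
    cc <- caches[[i]]
    g <- list()
    ln2b <- .layernorm_bwd(dX, cc$ln2, L$ln2_g)
    g$ln2_g <- ln2b$dg; g$ln2_b <- ln2b$db
    dres2 <- ln2b$dX                      # grad wrt H + dropout(F2)
    dF2 <- if (is.null(cc$mask2)) dres2 else dres2 * cc$mask2
    lb2 <- .linear_bwd(dF2, cc$F1a, L$W2)
    g$W2 <- lb2$dW; g$b2 <- lb2$db
    dF1 <- .relu_bwd(lb2$dX, cc$F1a)
    lb1 <- .linear_bwd(dF1, cc$H, L$W1)
    g$W1 <- lb1$dW; g$b1 <- lb1$db
    dH <- dres2 + lb1$dX
    ln1b <- .layernorm_bwd(dH, cc$ln1, L$ln1_g)
    g$ln1_g <- ln1b$dg; g$ln1_b <- ln1b$db
    dres1 <- ln1b$dX                      # grad wrt X + dropout(O)
    dO <- if (is.null(cc$mask1)) dres1 else dres1 * cc$mask1
    lbO <- .linear_bwd(dO, cc$attn_out, L$Wo)
    g$Wo <- lbO$dW; g$bo <- lbO$db
    ab <- attn_backward_cpp(lbO$dX, cc$Q, cc$K, cc$V, cc$P, n_seq, len, cfg$n_heads)
    lbQ <- .linear_bwd(ab$dQ, cc$X, L$Wq); g$Wq <- lbQ$dW; g$bq <- lbQ$db
    lbK <- .linear_bwd(ab$dK, cc$X, L$Wk); g$Wk <- lbK$dW; g$bk <- lbK$db
    lbV <- .linear_bwd(ab$dV, cc$X, L$Wv); g$Wv <- lbV$dW; g$bv <- lbV$db
    dX <- dres1 + lbQ$dX + lbK$dX + lbV$dX
    grads[[i]] <- g
  }
  list(dX = dX, grads = grads)
}

# ---- heads -------------------------------------------------------------------
# Verification head: [FC + BN + ReLU] over ver_widths, then FC1 + BN (+ sigmoid
# outside). ID head: shared FC + BN + ReLU, then FC1 + BN (+ softmax outside).

.ver_head_fwd <- function(X, params, bn, train, need_cache = FALSE, momentum = 0.1) {
  caches <- if (need_cache) vector("list", length(params$ver_head) + 1L)
  for (i in seq_along(params$ver_head)) {
    L <- params$ver_head[[i]]
    Y <- .linear_fwd(X, L$W, L$b)
    bnf <- .batchnorm_fwd(Y, L$gamma, L$beta, bn$ver_head[[i]], train, momentum)
    bn$ver_head[[i]] <- bnf$state
    A <- .relu_fwd(bnf$out)
    if (need_cache) caches[[i]] <- list(X = X, bncache = bnf, act = A)
    X <- A
  }
  L <- params$ver_out
  Y <- .linear_fwd(X, L$W, L$b)
  bnf <- .batchnorm_fwd(Y, L$gamma, L$beta, bn$ver_out, train, momentum)
  bn$ver_out <- bnf$state
  if (need_cache) caches[[length(caches)]] <- list(X = X, bncache = bnf)
  list(z = drop(bnf$out), bn = bn, caches = caches)
}

.ver_head_bwd <- function(dz, params, caches) {
  n_hidden <- length(params$ver_head)
  g <- list(ver_head = vector("list", n_hidden))
  cc <- caches[[n_hidden + 1L]]
  L <- params$ver_out
  dY <- .batchnorm_bwd(matrix(dz, ncol = 1L), cc$bncache, L$gamma)
  gout <- list(dgamma = dY$dgamma, dbeta = dY$dbeta)
  lb <- .linear_bwd(dY$dX, cc$X, L$W)
  g$ver_out <- list(W = lb$dW, b = lb$db, gamma = gout$dgamma, beta = gout$dbeta)
  dX <- lb$dX
  for (i in rev(seq_len(n_hidden))) {
    cc <- caches[[i]]
    L <- params$ver_head[[i]]
    dA <- .relu_bwd(dX, cc$act)
    bnb <- .batchnorm_bwd(dA, cc$bncache, L$gamma)
    lb <- .linear_bwd(bnb$dX, cc$X, L$W)
    g$ver_head[[i]] <- list(W = lb$dW, b = lb$db, gamma = bnb$dgamma, beta = bnb$dbeta)
    dX <- lb$dX
  }
  list(grads = g, dX = dX)
}

.id_head_fwd <- function(X, params, bn, train, need_cache = FALSE, momentum = 0.1) {
  L <- params$id_head
  Y <- .linear_fwd(X, L$W, L$b)
  bn1 <- .batchnorm_fwd(Y, L$gamma, L$beta, bn$id_head, train, momentum)
  bn$id_head <- bn1$state
  A <- .relu_fwd(bn1$out)
  Lo <- params$id_out
  Y2 <- .linear_fwd(A, Lo$W, Lo$b)
  bn2 <- .batchnorm_fwd(Y2, Lo$gamma, Lo$beta, bn$id_out, train, momentum)
  bn$id_out <- bn2$state
  cache <- if (need_cache) list(X = X, bn1 = bn1, act = A, bn2 = bn2)
  list(logits = drop(bn2$out), bn = bn, cache = cache)
}

.id_head_bwd <- function(dlogits, params, cache) {
  Lo <- params$id_out
  bnb2 <- .batchnorm_bwd(matrix(dlogits, ncol = 1L), cache$bn2, Lo$gamma)
  lb2 <- .linear_bwd(bnb2$dX, cache$act, Lo$W)
  dA <- .relu_bwd(lb2$dX, cache$act)
  L <- params$id_head
  bnb1 <- .batchnorm_bwd(dA, cache$bn1, L$gamma)
  lb1 <- .linear_bwd(bnb1$dX, cache$X, L$W)
  list(grads = list(id_out = list(W = lb2$dW, b = lb2$db,
                                  gamma = bnb2$dgamma, beta = bnb2$dbeta),
                    id_head = list(W = lb1$dW, b = lb1$db,
                                   gamma = bnb1$dgamma, beta = bnb1$dbeta)),
       dX = lb1$dX)
}

# ---- full network ------------------------------------------------------------
# Batch layout. Input segments matrix: (B * (h+1)) x 384 with rows ordered
# example-major: for example b, its h enrolled segments then its query.
# Composite sequences: one per (example, enrolled identity), sequence-major,
# s = (b-1)*h + k; within a sequence, position 1 = clsVE, 2 = clsID,
# 3..(2+n_tok) = enrolled tokens + emb_enr, rest = query tokens + emb_qry;
# learned position embeddings are added to all seq_len positions.

.composite_index <- function(B, h, cfg) {
  nt <- cfg$n_tokens
  n_seg <- B * (h + 1L)
  # Z row for (segment seg, token t) = seg + (t-1)*n_seg
  seg_enr <- rep(rep(seq_len(h), each = nt), times = B) +
    rep((seq_len(B) - 1L) * (h + 1L), each = h * nt)
  tok <- rep(seq_len(nt), times = B * h)
  zid_enr <- seg_enr + (tok - 1L) * n_seg
  seg_qry <- rep((seq_len(B) - 1L) * (h + 1L) + h + 1L, each = h * nt)
  zid_qry <- seg_qry + (tok - 1L) * n_seg
  # destination rows in X0 ((B*h*seq_len) x d)
  sl <- cfg$seq_len
  base <- rep((seq_len(B * h) - 1L) * sl, each = nt)
  dst_enr <- base + 2L + rep(seq_len(nt), times = B * h)
  dst_qry <- base + 2L + nt + rep(seq_len(nt), times = B * h)
  cls_rows <- (seq_len(B * h) - 1L) * sl
  list(zid_enr = zid_enr, zid_qry = zid_qry, dst_enr = dst_enr, dst_qry = dst_qry,
       cls_ve = cls_rows + 1L, cls_id = cls_rows + 2L)
}

.network_fwd <- function(model, segs, B, h, train = FALSE, need_cache = FALSE,
                         bn_momentum = 0.1) {
  cfg <- model$config
  p <- model$params
  fse <- .fse_fwd(segs, p, cfg, need_cache = need_cache)
  ix <- .composite_index(B, h, cfg)
  sl <- cfg$seq_len
  X0 <- matrix(0, B * h * sl, cfg$d_model)
  X0[ix$cls_ve, ] <- matrix(p$cls_ve, B * h, cfg$d_model, byrow = TRUE)
  X0[ix$cls_id, ] <- matrix(p$cls_id, B * h, cfg$d_model, byrow = TRUE)
  ne <- length(ix$dst_enr)
  X0[ix$dst_enr, ] <- fse$Z[ix$zid_enr, , drop = FALSE] + .bc(p$emb_enr, ne)
  X0[ix$dst_qry, ] <- fse$Z[ix$zid_qry, , drop = FALSE] + .bc(p$emb_qry, ne)
  pos_rep <- p$pos[rep(seq_len(sl), times = B * h), , drop = FALSE]
  X0 <- X0 + pos_rep
  enc <- .encoder_fwd(X0, p$pair_enc, B * h, sl, cfg, train, need_cache)
  L_ve <- enc$out[ix$cls_ve, , drop = FALSE]
  L_id <- enc$out[ix$cls_id, , drop = FALSE]
  vh <- .ver_head_fwd(L_ve, p, model$bn, train, need_cache, bn_momentum)
  # L_id rows are already (b-major, k-fastest): B sequences of length h
  ide <- .encoder_fwd(L_id, p$id_enc, B, h, cfg, train, need_cache)
  ih <- .id_head_fwd(ide$out, p, vh$bn, train, need_cache, bn_momentum)
  logits <- matrix(ih$logits, nrow = B, ncol = h, byrow = TRUE)
  id_probs <- .softmax_rows(logits)
  ver_probs <- matrix(.sigmoid(vh$z), nrow = B, ncol = h, byrow = TRUE)
  out <- list(verification = ver_probs, identification = id_probs,
              ver_z = vh$z, id_logits = logits, bn = ih$bn)
  if (need_cache) {
    out$cache <- list(fse = fse$cache, ix = ix, X0 = X0, enc = enc$caches,
                      ver = vh$caches, L_id = L_id, ide = ide$caches,
                      idh = ih$cache, B = B, h = h)
  }
  out
}

# Joint loss gradient + parameter gradients for one batch.
# targets: list(q = integer vector length B (1..h)).
.network_grad <- function(model, segs, B, h, q, eps_ls, loss_weights = c(1, 1)) {
  cfg <- model$config
  p <- model$params
  fw <- .network_fwd(model, segs, B, h, train = TRUE, need_cache = TRUE)
  cc <- fw$cache
  n_pair <- B * h
  # verification: BCE against smoothed binary targets, mean over all pairs
  tver <- matrix(eps_ls / 2, B, h)
  tver[cbind(seq_len(B), q)] <- 1 - eps_ls / 2
  pver <- fw$verification
  eps <- 1e-12
  loss_ver <- -mean(tver * log(pver + eps) + (1 - tver) * log(1 - pver + eps))
  # d loss / d z (pre-sigmoid), row-major flattening to match vh$z ordering
  dz <- (pver - tver) / n_pair
  dz_flat <- as.vector(t(dz)) * loss_weights[1]
  # identification: CE against smoothed one-hot, mean over examples
  tid <- matrix(eps_ls / h, B, h)
  tid[cbind(seq_len(B), q)] <- 1 - eps_ls + eps_ls / h
  pid <- fw$identification
  loss_id <- -mean(rowSums(tid * log(pid + eps)))
  dlog <- (pid - tid) / B
  dlog_flat <- as.vector(t(dlog)) * loss_weights[2]

  grads <- list()
  vb <- .ver_head_bwd(dz_flat, p, cc$ver)
  grads$ver_head <- vb$grads$ver_head
  grads$ver_out <- vb$grads$ver_out
  ib <- .id_head_bwd(dlog_flat, p, cc$idh)
  grads$id_head <- ib$grads$id_head
  grads$id_out <- ib$grads$id_out
  ideb <- .encoder_bwd(ib$dX, p$id_enc, cc$ide, B, h, cfg)
  grads$id_enc <- ideb$grads
  # route into pair-encoder output positions
  dEnc <- matrix(0, nrow(cc$X0), cfg$d_model)
  dEnc[cc$ix$cls_ve, ] <- vb$dX
  dEnc[cc$ix$cls_id, ] <- ideb$dX
  eb <- .encoder_bwd(dEnc, p$pair_enc, cc$enc, n_pair, cfg$seq_len, cfg)
  grads$pair_enc <- eb$grads
  dX0 <- eb$dX
  grads$pos <- rowsum(dX0, rep(seq_len(cfg$seq_len), times = n_pair))
  grads$cls_ve <- colSums(dX0[cc$ix$cls_ve, , drop = FALSE])
  grads$cls_id <- colSums(dX0[cc$ix$cls_id, , drop = FALSE])
  d_enr <- dX0[cc$ix$dst_enr, , drop = FALSE]
  d_qry <- dX0[cc$ix$dst_qry, , drop = FALSE]
  grads$emb_enr <- colSums(d_enr)
  grads$emb_qry <- colSums(d_qry)
  # scatter-add into Z rows (query tokens are shared across the h pairs)
  nZ <- nrow(segs) * cfg$n_tokens
  allsrc <- c(cc$ix$zid_enr, cc$ix$zid_qry)
  dZpart <- rowsum(rbind(d_enr, d_qry), group = allsrc)
  dZ <- matrix(0, nZ, cfg$d_model)
  dZ[as.integer(rownames(dZpart)), ] <- dZpart
  cg <- .fse_bwd(dZ, cc$fse, cfg)
  grads$conv <- list(W = cg$dW, b = cg$db)
  # order grads to match params tree
  grads <- grads[names(p)]
  # training metrics at threshold 0.5
  pred <- max.col(pid, ties.method = "first")
  truth01 <- matrix(0, B, h); truth01[cbind(seq_len(B), q)] <- 1
  acc <- mean(pred == q)
  tpr <- mean(pver[truth01 == 1] >= 0.5)
  fpr <- mean(pver[truth01 == 0] >= 0.5)
  list(loss = loss_weights[1] * loss_ver + loss_weights[2] * loss_id,
       loss_ver = loss_ver, loss_id = loss_id,
       grads = grads, bn = fw$bn,
       metrics = list(id_acc = acc, ver_tpr = tpr, ver_fpr = fpr))
}

#' Run the model on one classification scope
#'
#' Computes, in evaluation mode (dropout off, batch norm on running statistics),
#' the per-identity verification probabilities P(q = k) and the closed
#' identification distribution Pq(k) for a scope of h enrolled segments and one
#' query segment.
#'
#' @param model a trained (or freshly initialized) `scope_model`.
#' @param scope matrix (h x 384) of standardized enrolled segments, one row per
#'   scope position, or a list of `ecg_segment`s.
#' @param query standardized query segment (length 384).
#' @return list with `verification` (h probabilities in (0,1)) and
#'   `identification` (h probabilities summing to 1).
#' @export
model_classify <- function(model, scope, query) {
  if (is.list(scope)) scope <- do.call(rbind, lapply(scope, as.numeric))
  scope <- as.matrix(scope)
  query <- as.numeric(query)
  h <- nrow(scope)
  if (h < 1L) stop("empty scope")
  if (ncol(scope) != model$config$seg_len || length(query) != model$config$seg_len)
    stop("segments must have length ", model$config$seg_len)
  segs <- rbind(scope, matrix(query, 1L))
  fw <- .network_fwd(model, segs, B = 1L, h = h, train = FALSE)
  list(verification = drop(fw$verification), identification = drop(fw$identification))
}

# Batched eval-mode forward over a dataset chunk (used for validation and the
# evaluation protocol). J: array (B, h, seg_len); query: (B x seg_len).
.model_classify_batch <- function(model, J, query) {
  B <- dim(J)[1]; h <- dim(J)[2]; sl <- dim(J)[3]
  segs <- matrix(0, B * (h + 1L), sl)
  for (b in seq_len(B)) {
    segs[((b - 1L) * (h + 1L) + 1L):((b - 1L) * (h + 1L) + h), ] <- J[b, , ]
    segs[(b - 1L) * (h + 1L) + h + 1L, ] <- query[b, ]
  }
  fw <- .network_fwd(model, segs, B = B, h = h, train = FALSE)
  list(verification = fw$verification, identification = fw$identification)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores parameters, batch-norm running statistics, the config
#' and a config hash; `model_load` verifies the hash.
#'
#' @param model a `scope_model`.
#' @param path file path.
#' @return `model_save` returns `path` invisibly; `model_load` the model.
#' @export
model_save <- function(model, path) {
  obj <- list(params = model$params, bn = model$bn, config = unclass(model$config),
              init_seed = model$init_seed,
              config_hash = rlang::hash(unclass(model$config)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname model_save
#' @export
model_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(rlang::hash(obj$config), obj$config_hash))
    stop("checkpoint config hash mismatch")
  cfg <- obj$config
  class(cfg) <- "scope_model_config"
  structure(list(params = obj$params, bn = obj$bn, config = cfg,
                 init_seed = obj$init_seed),
            class = "scope_model")
}
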