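#' @useDynLib ecgscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- low-level neural net primitives -----------------------------------------
# All layers operate on matrices whose rows are batch elements (or tokens) and
# whose columns are channels. Every *_fwd returns the output plus whatever the
# matching *_bwd needs; caches are plain lists.

# broadcast a per-column vector across rows (faster than sweep, which aperm()s)
.bc <- function(v, n) rep(v, each = n)

.linear_fwd <- function(X, W, b) {
  addbias_ip(X %*% W, b)   # in-place bias add on the fresh product
}

.linear_bwd <- function(dY, X, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

# relu_ip mutates in place: only ever applied to freshly allocated matrices
.relu_fwd <- function(X) relu_ip(X)

# mask comes from the activation output (its sign pattern equals the input's)
.relu_bwd <- function(dY, act) relu_bwd_cpp(dY, act)

# Layer normalization across columns, independently per row.
.layernorm_fwd <- function(X, g, b) ln_fwd_cpp(X, g, b)

.layernorm_bwd <- function(dY, cache, g) {
  r <- ln_bwd_cpp(dY, cache$xhat, cache$sd, g)
  list(dX = r$dX, dg = as.numeric(r$dg), db = as.numeric(r$db))
}

# Batch normalization across rows, independently per column. `state` carries
# running statistics (used verbatim in eval mode, updated in train mode).
.batchnorm_fwd <- function(X, gamma, beta, state, train, momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (train) {
    mu <- colMeans(X)
    Xc <- X - .bc(mu, n)
    v <- colMeans(Xc * Xc)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    v_unbiased <- if (n > 1) v * n / (n - 1) else v
    state$var <- (1 - momentum) * state$var + momentum * v_unbiased
    sd <- sqrt(v + eps)
    xhat <- Xc / .bc(sd, n)
  } else {
    xhat <- (X - .bc(state$mean, n)) / .bc(sqrt(state$var + eps), n)
    sd <- NULL
  }
  Y <- xhat * .bc(gamma, n) + .bc(beta, n)
  list(out = Y, xhat = xhat, sd = sd, state = state)
}

.batchnorm_bwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  n <- nrow(dY)
  dxhat <- dY * .bc(gamma, n)
  s1 <- colMeans(dxhat)
  s2 <- colMeans(dxhat * xhat)
  # dX = (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) / sd, per column
  dX <- (dxhat - .bc(s1, n) - xhat * .bc(s2, n)) / .bc(cache$sd, n)
  list(dX = dX, dgamma = colSums(dY * xhat), dbeta = colSums(dY))
}

.bn_reset <- function(bn) {
  .tree_map(function(x) x * 0, bn)
}

# global-norm gradient clipping
.clip_grads <- function(grads, max_norm) {
  total <- sqrt(.tree_sum(function(g) sum(g * g), grads))
  if (total > max_norm) grads <- .tree_map(function(g) g * (max_norm / total), grads)
  grads
}

# Inverted dropout; returns the scaled mask so backward is a multiply.
.dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X))
  list(out = X * mask, mask = mask)
}

.softmax_rows <- function(X) {
  X <- X - apply(X, 1L, max)
  E <- exp(X)
  E / rowSums(E)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter-tree utilities ------------------------------------------------
# Parameters, gradients and Adam moments all share one nested-list shape with
# numeric leaves; these walkers keep the optimizer generic.

.tree_map <- function(f, tree) {
  if (is.list(tree)) return(lapply(tree, function(t) .tree_map(f, t)))
  f(tree)
}

.align_tree <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b[names(a)] else b
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    b <- .align_tree(a, b)
    return(mapply(function(x, y) .tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

.tree_map3 <- function(f, a, b, c) {
  if (is.list(a)) {
    b <- .align_tree(a, b)
    c <- .align_tree(a, c)
    return(mapply(function(x, y, z) .tree_map3(f, x, y, z), a, b, c, SIMPLIFY = FALSE))
  }
  f(a, b, c)
}

.tree_sum <- function(f, tree) {
  if (is.list(tree)) return(sum(vapply(tree, function(t) .tree_sum(f, t), numeric(1))))
  f(tree)
}

.n_params <- function(tree) .tree_sum(length, tree)

# ---- Adam --------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = .tree_map(function(p) p * 0, params),
       v = .tree_map(function(p) p * 0, params),
       t = 0L)
}

.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.98, eps = 1e-9) {
  opt$t <- opt$t + 1L
  opt$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  params <- .tree_map3(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                       params, opt$m, opt$v)
  list(params = params, opt = opt)
}

# Deterministic scoped RNG: evaluates expr with the given seed and restores the
# caller's RNG state afterwards, so generators never leak global state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive k reproducible sub-seeds (< 2^31) from one root seed.
.spawn_seeds <- function(seed, k) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
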