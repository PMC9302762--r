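# Low-level neural network primitives on base R matrices.
#
# Every layer is a pair of pure functions: a forward that returns its output
# together with a cache, and a backward that consumes the cache and the
# upstream gradient. Parameters live in plain named lists of matrices/vectors
# so a single Adam routine can update any model.

# Uniform fan-in initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_matrix <- function(nrow, ncol, fan_in = nrow) {
  r <- 1 / sqrt(fan_in)
  matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
}

init_vector <- function(n) rep(0, n)

# y = X W + b (rows are examples)
linear_forward <- function(X, W, b) {
  Z <- X %*% W
  Z <- sweep(Z, 2, b, "+")
  list(out = Z, X = X)
}

linear_backward <- function(dZ, cache, W) {
  list(dX = dZ %*% t(W),
       dW = crossprod(cache$X, dZ),
       db = colSums(dZ))
}

relu_forward <- function(Z) {
  out <- Z
  out[out < 0] <- 0
  list(out = out, mask = Z > 0)
}

relu_backward <- function(dout, cache) {
  dout * cache$mask
}

# Inverted dropout; mask drawn from the session RNG so runs are seed-exact.
dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) {
    return(list(out = X, mask = NULL))
  }
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - p), nrow(X), ncol(X)) /
    (1 - p)
  list(out = X * mask, mask = mask)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# --- Stacked 1D convolution / pooling -----------------------------------
#
# A batch of B equal-length sequences is stored as a single matrix with
# B blocks of L rows (channels in columns). Index maps are precomputed per
# (B, L, kernel) so convolution reduces to one im2col + one matmul.

# rows of the stacked input contributing to each output row, one column per
# kernel offset
conv_index <- function(B, L_in, kernel, stride = 1L) {
  L_out <- (L_in - kernel) %/% stride + 1L
  pos <- (seq_len(L_out) - 1L) * stride # 0-based window starts within a block
  block <- rep((seq_len(B) - 1L) * L_in, each = L_out)
  starts <- block + rep(pos, times = B) # 0-based start row of each window
  idx <- outer(starts, seq_len(kernel), "+")
  list(idx = idx, L_out = L_out, n_out = B * L_out)
}

conv1d_forward <- function(X, W, b, ci) {
  d <- ncol(X)
  k <- ncol(ci$idx)
  Xcol <- matrix(0, ci$n_out, k * d)
  for (w in seq_len(k)) {
    Xcol[, (w - 1L) * d + seq_len(d)] <- X[ci$idx[, w], , drop = FALSE]
  }
  lin <- linear_forward(Xcol, W, b)
  list(out = lin$out, Xcol = Xcol)
}

conv1d_backward <- function(dZ, cache, W, ci, n_in_rows) {
  d_in <- (nrow(W)) / ncol(ci$idx)
  k <- ncol(ci$idx)
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- dZ %*% t(W)
  dX <- matrix(0, n_in_rows, d_in)
  for (w in seq_len(k)) {
    add <- rowsum(dXcol[, (w - 1L) * d_in + seq_len(d_in), drop = FALSE],
                  group = ci$idx[, w])
    rows <- as.integer(rownames(add))
    dX[rows, ] <- dX[rows, , drop = FALSE] + add
  }
  list(dX = dX, dW = dW, db = db)
}

# Non-overlapping max pooling over the stacked layout (stride = kernel).
maxpool_forward <- function(X, ci) {
  d <- ncol(X)
  k <- ncol(ci$idx)
  cur <- X[ci$idx[, 1], , drop = FALSE]
  arg <- matrix(ci$idx[, 1], ci$n_out, d)
  for (w in seq(2L, k)) {
    Xw <- X[ci$idx[, w], , drop = FALSE]
    upd <- Xw > cur
    cur[upd] <- Xw[upd]
    argw <- matrix(ci$idx[, w], ci$n_out, d)
    arg[upd] <- argw[upd]
  }
  list(out = cur, arg = arg)
}

maxpool_backward <- function(dout, cache, n_in_rows) {
  d <- ncol(dout)
  dX <- matrix(0, n_in_rows, d)
  lin <- (rep(seq_len(d), each = nrow(dout)) - 1L) * n_in_rows +
    as.vector(cache$arg)
  # windows are disjoint, so no index collisions
  dX[lin] <- as.vector(dout)
  dX
}

# --- Softmax / cross-entropy --------------------------------------------

#' Softmax over the rows of a logit matrix
#'
#' @param z Numeric matrix (rows are examples) or a single logit vector.
#' @return Matrix of the same shape with rows summing to one.
#' @export
softmax <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  m <- apply(z, 1, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# mean cross-entropy over the batch; gradient wrt logits
softmax_xent <- function(logits, labels) {
  p <- softmax(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

# --- Adam ----------------------------------------------------------------
#
# Parameter trees are nested named lists whose leaves are numeric arrays.
# Adam state mirrors the tree.

tree_map <- function(f, ...) {
  trees <- list(...)
  first <- trees[[1]]
  if (is.list(first)) {
    out <- lapply(seq_along(first), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(first)
    out
  } else {
    do.call(f, trees)
  }
}

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, weight_decay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  if (weight_decay > 0) {
    grads <- tree_map(function(g, p) g + weight_decay * p, grads, params)
  }
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
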