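# Small convolutional-network engine used by the image classifiers.
# Activations are (height, width, batch, channels) arrays: with that layout
# a shifted spatial slice reshapes to a (positions x channels) matrix with
# no permutation, so convolutions reduce to k*k matrix products done in
# BLAS. The input gradient of a convolution is computed as a full
# convolution of the (dilated, padded) output gradient with the rotated
# kernel, avoiding scatter accumulation. Only the pieces the
# truncated-Inception topology needs are implemented: 1x1/3x3 convolution,
# ReLU, 2x2 max pooling, 3x3 same average pooling, global average pooling,
# dropout and a dense sigmoid head trained with Adam on binary
# cross-entropy.

# X: (H, W, N, C); W: (k, k, C, F); returns Y: (H2, W2, N, F).
# The arithmetic lives in src/convops.cpp; the cache keeps the layer input
# so the backward pass can rebuild its patch matrix.
.conv_fwd <- function(X, W, b, stride = 1L, pad = 0L) {
  list(Y = cpp_conv_fwd(X, W, b, stride, pad),
       cache = list(X = X, stride = stride, pad = pad))
}

.conv_bwd <- function(dY, W, cache) {
  cpp_conv_bwd(dY, cache$X, W, cache$stride, cache$pad)
}

.relu_fwd <- function(X) {
  X[X < 0] <- 0
  X
}

.relu_bwd <- function(dY, Y) dY * (Y > 0)

.maxpool2_fwd <- function(X) {
  r <- cpp_maxpool2_fwd(X)
  list(Y = r$Y, cache = r)
}

.maxpool2_bwd <- function(dY, Y, cache) {
  cpp_maxpool2_bwd(dY, cache$argmax, cache$in_dim)
}

# 3x3 average pooling, stride 1, same padding (uniform 1/9 kernel);
# symmetric, so the backward pass is the same operation on the gradient
.avgpool3_fwd <- function(X) cpp_avgpool3(X)

.avgpool3_bwd <- function(dY) cpp_avgpool3(dY)

# X: (H, W, N, C) -> features (N, C)
.gap_fwd <- function(X) {
  d <- dim(X)
  matrix(colMeans(matrix(X, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

.gap_bwd <- function(dF, d) {
  array(rep(dF / (d[1] * d[2]), each = d[1] * d[2]), d)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# ---- truncated-Inception topology ------------------------------------------

# branch filter plan (width 1.0): br1, br2a, br2b, br3a, br3b, br3c, br4
.BLOCK_BASE <- c(br1 = 16L, br2a = 16L, br2b = 32L,
                 br3a = 16L, br3b = 32L, br3c = 32L, br4 = 16L)
.STEM_BASE <- 32L

.block_out_channels <- function(f) unname(f["br1"] + f["br2b"] + f["br3c"] + f["br4"])

.scaled_filters <- function(width) {
  f <- vapply(.BLOCK_BASE, function(x) as.integer(ceiling(width * x)), 0L)
  list(block = f, stem = as.integer(ceiling(width * .STEM_BASE)))
}

.init_block_params <- function(c_in, f) {
  mk <- function(k, cin, cout) {
    list(W = .he_init(c(k, k, cin, cout), k * k * cin), b = numeric(cout))
  }
  list(
    br1 = mk(1L, c_in, f["br1"]),
    br2a = mk(1L, c_in, f["br2a"]), br2b = mk(3L, f["br2a"], f["br2b"]),
    br3a = mk(1L, c_in, f["br3a"]), br3b = mk(3L, f["br3a"], f["br3b"]),
    br3c = mk(3L, f["br3b"], f["br3c"]),
    br4 = mk(1L, c_in, f["br4"])
  )
}

.block_fwd <- function(X, p) {
  r1 <- .conv_fwd(X, p$br1$W, p$br1$b); y1 <- .relu_fwd(r1$Y)
  r2a <- .conv_fwd(X, p$br2a$W, p$br2a$b); y2a <- .relu_fwd(r2a$Y)
  r2b <- .conv_fwd(y2a, p$br2b$W, p$br2b$b, pad = 1L); y2b <- .relu_fwd(r2b$Y)
  r3a <- .conv_fwd(X, p$br3a$W, p$br3a$b); y3a <- .relu_fwd(r3a$Y)
  r3b <- .conv_fwd(y3a, p$br3b$W, p$br3b$b, pad = 1L); y3b <- .relu_fwd(r3b$Y)
  r3c <- .conv_fwd(y3b, p$br3c$W, p$br3c$b, pad = 1L); y3c <- .relu_fwd(r3c$Y)
  pool <- .avgpool3_fwd(X)
  r4 <- .conv_fwd(pool, p$br4$W, p$br4$b); y4 <- .relu_fwd(r4$Y)
  d <- dim(X)
  parts <- list(y1, y2b, y3c, y4)
  ch <- vapply(parts, function(z) dim(z)[4], 0L)
  Y <- array(0, c(d[1], d[2], d[3], sum(ch)))
  at <- 0L
  for (z in parts) {
    Y[, , , at + seq_len(dim(z)[4])] <- z
    at <- at + dim(z)[4]
  }
  list(Y = Y, cache = list(
    r1 = r1, y1 = y1, r2a = r2a, y2a = y2a, r2b = r2b, y2b = y2b,
    r3a = r3a, y3a = y3a, r3b = r3b, y3b = y3b, r3c = r3c, y3c = y3c,
    r4 = r4, y4 = y4, ch = ch
  ))
}

.block_bwd <- function(dY, p, cache) {
  ch <- cache$ch
  off <- cumsum(c(0L, ch))
  take <- function(i) dY[, , , (off[i] + 1L):off[i + 1L], drop = FALSE]
  g <- list()
  d1 <- .relu_bwd(take(1), cache$y1)
  b1 <- .conv_bwd(d1, p$br1$W, cache$r1$cache)
  g$br1 <- list(W = b1$dW, b = b1$db)
  dX <- b1$dX
  d2b <- .relu_bwd(take(2), cache$y2b)
  b2b <- .conv_bwd(d2b, p$br2b$W, cache$r2b$cache)
  g$br2b <- list(W = b2b$dW, b = b2b$db)
  d2a <- .relu_bwd(b2b$dX, cache$y2a)
  b2a <- .conv_bwd(d2a, p$br2a$W, cache$r2a$cache)
  g$br2a <- list(W = b2a$dW, b = b2a$db)
  dX <- dX + b2a$dX
  d3c <- .relu_bwd(take(3), cache$y3c)
  b3c <- .conv_bwd(d3c, p$br3c$W, cache$r3c$cache)
  g$br3c <- list(W = b3c$dW, b = b3c$db)
  d3b <- .relu_bwd(b3c$dX, cache$y3b)
  b3b <- .conv_bwd(d3b, p$br3b$W, cache$r3b$cache)
  g$br3b <- list(W = b3b$dW, b = b3b$db)
  d3a <- .relu_bwd(b3b$dX, cache$y3a)
  b3a <- .conv_bwd(d3a, p$br3a$W, cache$r3a$cache)
  g$br3a <- list(W = b3a$dW, b = b3a$db)
  dX <- dX + b3a$dX
  d4 <- .relu_bwd(take(4), cache$y4)
  b4 <- .conv_bwd(d4, p$br4$W, cache$r4$cache)
  g$br4 <- list(W = b4$dW, b = b4$db)
  dX <- dX + .avgpool3_bwd(b4$dX)
  list(dX = dX, grads = g)
}

# trunk = stem + inception blocks (+ interleaved max pools); returns the
# last feature map before global average pooling
.trunk_fwd <- function(net, X, keep_cache = FALSE) {
  caches <- list()
  r <- .conv_fwd(X, net$params$stem1$W, net$params$stem1$b,
                 stride = 2L, pad = 0L)
  y <- .relu_fwd(r$Y)
  if (keep_cache) caches$stem1 <- list(r = r, y = y)
  r2 <- .conv_fwd(y, net$params$stem2$W, net$params$stem2$b,
                  stride = net$arch$stem2_stride, pad = 1L)
  y <- .relu_fwd(r2$Y)
  if (keep_cache) caches$stem2 <- list(r = r2, y = y)
  mp <- .maxpool2_fwd(y)
  y <- mp$Y
  if (keep_cache) caches$stem_pool <- mp
  for (i in seq_len(net$arch$n_blocks)) {
    bf <- .block_fwd(y, net$params$blocks[[i]])
    y <- bf$Y
    if (keep_cache) caches[[paste0("block", i)]] <- bf$cache
    if (i %in% net$arch$pool_after) {
      mp <- .maxpool2_fwd(y)
      y <- mp$Y
      if (keep_cache) caches[[paste0("pool", i)]] <- mp
    }
  }
  list(Y = y, caches = caches)
}

.trunk_bwd <- function(net, dY, caches) {
  grads <- list(blocks = vector("list", net$arch$n_blocks))
  for (i in rev(seq_len(net$arch$n_blocks))) {
    if (i %in% net$arch$pool_after) {
      mp <- caches[[paste0("pool", i)]]
      dY <- .maxpool2_bwd(dY, mp$Y, mp$cache)
    }
    bb <- .block_bwd(dY, net$params$blocks[[i]], caches[[paste0("block", i)]])
    grads$blocks[[i]] <- bb$grads
    dY <- bb$dX
  }
  mp <- caches$stem_pool
  dY <- .maxpool2_bwd(dY, mp$Y, mp$cache)
  dY <- .relu_bwd(dY, caches$stem2$y)
  b2 <- .conv_bwd(dY, net$params$stem2$W, caches$stem2$r$cache)
  grads$stem2 <- list(W = b2$dW, b = b2$db)
  dY <- .relu_bwd(b2$dX, caches$stem1$y)
  b1 <- .conv_bwd(dY, net$params$stem1$W, caches$stem1$r$cache)
  grads$stem1 <- list(W = b1$dW, b = b1$db)
  grads
}

# ---- Adam ------------------------------------------------------------------

.adam_new <- function() new.env(parent = emptyenv())

.adam_step <- function(state, name, param, grad, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  key_m <- paste0(name, ".m"); key_v <- paste0(name, ".v")
  key_t <- paste0(name, ".t")
  m <- if (exists(key_m, state)) get(key_m, state) else param * 0
  v <- if (exists(key_v, state)) get(key_v, state) else param * 0
  t <- (if (exists(key_t, state)) get(key_t, state) else 0L) + 1L
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad^2
  assign(key_m, m, state); assign(key_v, v, state); assign(key_t, t, state)
  mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
  out <- param - lr * mh / (sqrt(vh) + eps)
  attributes(out) <- attributes(param)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
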