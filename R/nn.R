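# Minimal 1-D convolutional network primitives with explicit forward and
# backward passes, written on BLAS-backed matrix ops. Batches are stored
# sample-major: an activation is a (N*L) x C matrix whose row
# (i-1)*L + t holds sample i at position t. Convolutions gather shifted
# row blocks (im2col per kernel offset) and multiply by the kernel slice;
# within one kernel offset the gather indices are unique, so the backward
# scatter-add is a plain indexed addition. Per-column arithmetic uses
# rep(v, each = M) instead of sweep() for speed.

col_op <- function(X, v, op) op(X, rep(v, each = nrow(X)))

conv_gather <- function(X, shape, k, stride, pad) {
  N <- shape[1]; L <- shape[2]
  Lout <- (L + 2L * pad - k) %/% stride + 1L
  base <- (seq_len(Lout) - 1L) * stride - pad
  offs <- rep((seq_len(N) - 1L) * L, each = Lout)
  idx <- vector("list", k)
  gath <- vector("list", k)
  for (j in seq_len(k)) {
    tin <- base + j
    bad <- tin < 1L | tin > L
    tin[bad] <- 1L
    g <- offs + rep(tin, N)
    Xg <- X[g, , drop = FALSE]
    if (any(bad)) {
      zr <- rep(bad, N)
      Xg[zr, ] <- 0
      g[zr] <- 0L
    }
    idx[[j]] <- g
    gath[[j]] <- Xg
  }
  list(idx = idx, gath = gath, shape = c(N, Lout))
}

conv_fwd <- function(X, shape, W, stride, pad) {
  k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  gg <- conv_gather(X, shape, k, stride, pad)
  Y <- gg$gath[[1]] %*% matrix(W[1, , ], cin, cout)
  for (j in seq_len(k)[-1]) {
    Y <- Y + gg$gath[[j]] %*% matrix(W[j, , ], cin, cout)
  }
  list(Y = Y, idx = gg$idx, gath = gg$gath, shape = gg$shape)
}

conv_bwd <- function(dY, cache, W, n_rows) {
  k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  dW <- array(0, dim(W))
  dX <- matrix(0, n_rows, cin)
  for (j in seq_len(k)) {
    g <- cache$idx[[j]]
    dW[j, , ] <- crossprod(cache$gath[[j]], dY)
    contrib <- dY %*% t(matrix(W[j, , ], cin, cout))
    valid <- g != 0L
    gv <- g[valid]
    dX[gv, ] <- dX[gv, , drop = FALSE] + contrib[valid, , drop = FALSE]
  }
  list(dX = dX, dW = dW)
}

bn_fwd <- function(X, gamma, beta, rmean, rvar, training,
                   momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    v <- pmax(colMeans(X * X) - mu^2, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- col_op(col_op(X, mu, `-`), invstd, `*`)
  Y <- col_op(col_op(xhat, gamma, `*`), beta, `+`)
  list(Y = Y, xhat = xhat, invstd = invstd, rmean = rmean, rvar = rvar,
       training = training)
}

bn_bwd <- function(dY, cache, gamma) {
  M <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- col_op(dY, gamma, `*`)
  if (cache$training) {
    t1 <- colSums(dxhat) / M
    t2 <- colSums(dxhat * cache$xhat) / M
    dX <- col_op(
      col_op(dxhat, t1, `-`) - col_op(cache$xhat, t2, `*`),
      cache$invstd, `*`
    )
  } else {
    dX <- col_op(dxhat, cache$invstd, `*`)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

maxpool_fwd <- function(X, shape, k = 3L, stride = 2L, pad = 1L) {
  N <- shape[1]; L <- shape[2]; C <- ncol(X)
  Lout <- (L + 2L * pad - k) %/% stride + 1L
  base <- (seq_len(Lout) - 1L) * stride - pad
  offs <- rep((seq_len(N) - 1L) * L, each = Lout)
  idx <- vector("list", k)
  Y <- matrix(-Inf, N * Lout, C)
  which_j <- matrix(0L, N * Lout, C)
  for (j in seq_len(k)) {
    tin <- base + j
    bad <- tin < 1L | tin > L
    tin[bad] <- 1L
    g <- offs + rep(tin, N)
    cand <- X[g, , drop = FALSE]
    if (any(bad)) {
      zr <- rep(bad, N)
      cand[zr, ] <- -Inf
      g[zr] <- 0L
    }
    idx[[j]] <- g
    upd <- cand > Y
    Y[upd] <- cand[upd]
    which_j[upd] <- j
  }
  list(Y = Y, idx = idx, which_j = which_j, shape = c(N, Lout))
}

maxpool_bwd <- function(dY, cache, n_rows, C) {
  dX <- matrix(0, n_rows, C)
  for (j in seq_along(cache$idx)) {
    g <- cache$idx[[j]]
    valid <- g != 0L
    contrib <- dY * (cache$which_j == j)
    gv <- g[valid]
    dX[gv, ] <- dX[gv, , drop = FALSE] + contrib[valid, , drop = FALSE]
  }
  dX
}

gap_fwd <- function(X, shape) {
  N <- shape[1]; L <- shape[2]
  grp <- rep(seq_len(N), each = L)
  list(Y = rowsum(X, grp, reorder = FALSE) / L, N = N, L = L)
}

gap_bwd <- function(dY, cache) {
  dY[rep(seq_len(cache$N), each = cache$L), , drop = FALSE] / cache$L
}

# Cosine similarity head: rows of f and columns of W are L2-normalised.
cos_head_fwd <- function(f, W) {
  fn <- sqrt(rowSums(f * f)) + 1e-12
  fhat <- f / fn
  wn <- sqrt(colSums(W * W)) + 1e-12
  what <- col_op(W, wn, `/`)
  list(cos = fhat %*% what, fhat = fhat, fn = fn, what = what, wn = wn)
}

cos_head_bwd <- function(dcos, cache) {
  dfhat <- dcos %*% t(cache$what)
  dwhat <- crossprod(cache$fhat, dcos)
  df <- (dfhat - cache$fhat * rowSums(dfhat * cache$fhat)) / cache$fn
  dW <- col_op(
    dwhat - col_op(cache$what, colSums(dwhat * cache$what), `*`),
    cache$wn, `/`
  )
  list(df = df, dW = dW)
}

rowmax <- function(X) X[cbind(seq_len(nrow(X)), max.col(X, "first"))]
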