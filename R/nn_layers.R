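# Neural-network layer primitives for 1D signals, with explicit forward /
# backward passes. Activations are 3D arrays [N, L, C] (batch, temporal
# position, channel); with N varying fastest this reshapes for free to an
# (N*L) x C matrix, which keeps batch norm and the im2col convolution on
# BLAS-backed matrix operations.

# ---- convolution -----------------------------------------------------------

conv_out_len <- function(L, k, stride, pad) (L + 2L * pad - k) %/% stride + 1L

# Linear gather indices mapping a padded [N, Lp, C] array to the
# (N*L_out) x (k*C) im2col matrix; rows ordered (n, t), columns (j, c).
conv_gather_idx <- function(N, Lp, C, L_out, k, stride) {
  tj <- as.vector(outer((0:(L_out - 1L)) * stride, 1:k, "+"))  # padded l, t fastest
  rep.int(seq_len(N), L_out * k * C) +
    N * rep(rep.int(tj - 1L, rep.int(N, length(tj))), C) +
    (N * Lp) * rep(0:(C - 1L), each = N * L_out * k)
}

pad_temporal <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1], d[2] + 2L * pad, d[3]))
  xp[, pad + seq_len(d[2]), ] <- x
  xp
}

# W is a (k*C_in) x C_out matrix (kernel offset fastest along rows).
conv1d_forward <- function(x, W, k, stride = 1L, pad = k %/% 2L) {
  d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
  L_out <- conv_out_len(L, k, stride, pad)
  xp <- pad_temporal(x, pad)
  idx <- conv_gather_idx(N, L + 2L * pad, C, L_out, k, stride)
  M <- matrix(xp[idx], nrow = N * L_out)
  out <- array(M %*% W, c(N, L_out, ncol(W)))
  list(out = out, cache = list(M = M, idx = idx, dims = d, k = k,
                               stride = stride, pad = pad, L_out = L_out))
}

conv1d_backward <- function(dout, W, cache) {
  N <- cache$dims[1]; L <- cache$dims[2]; C <- cache$dims[3]
  k <- cache$k; pad <- cache$pad; L_out <- cache$L_out
  dom <- matrix(dout, N * L_out, ncol(W))
  dW <- crossprod(cache$M, dom)
  dM <- tcrossprod(dom, W)                      # (N*L_out) x (k*C)
  Lp <- L + 2L * pad
  dxp <- numeric(N * Lp * C)
  ncol_per_j <- C
  for (j in seq_len(k)) {
    cols <- seq.int(j, k * C, by = k)           # columns (j, c) for all c
    sel <- as.vector(outer(seq_len(N * L_out), (cols - 1L) * (N * L_out), "+"))
    tgt <- cache$idx[sel]
    dxp[tgt] <- dxp[tgt] + dM[, cols]
  }
  dx <- array(dxp, c(N, Lp, C))
  if (pad > 0L) dx <- dx[, pad + seq_len(L), , drop = FALSE]
  list(dx = dx, dW = dW)
}

# ---- batch normalization ---------------------------------------------------

bn_forward <- function(x, gamma, beta, rmean, rvar, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); m <- d[1] * d[2]
  xm <- matrix(x, m, d[3])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    va <- colMeans(xc^2)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * va * m / max(1, m - 1)
  } else {
    mu <- rmean; va <- rvar
    xc <- sweep(xm, 2, mu)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  out <- array(sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`), d)
  list(out = out, rmean = rmean, rvar = rvar,
       cache = list(xhat = xhat, istd = istd, dims = d, training = training))
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$dims; m <- d[1] * d[2]
  dy <- matrix(dout, m, d[3])
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  if (cache$training) {
    t1 <- sweep(dy, 2, dbeta / m)
    t2 <- sweep(cache$xhat, 2, dgamma / m, `*`)
    dx <- sweep(t1 - t2, 2, gamma * cache$istd, `*`)
  } else {
    dx <- sweep(dy, 2, gamma * cache$istd, `*`)
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations / pooling / linear ---------------------------------------

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

maxpool_forward <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
  L_out <- conv_out_len(L, k, stride, pad)
  xp <- pad_temporal(x, pad, fill = -Inf)
  Lp <- L + 2L * pad
  best <- array(-Inf, c(N, L_out, C)); arg <- array(1L, c(N, L_out, C))
  for (j in seq_len(k)) {
    lpos <- (0:(L_out - 1L)) * stride + j
    slab <- xp[, lpos, , drop = FALSE]
    upd <- slab > best
    best[upd] <- slab[upd]
    arg[upd] <- j
  }
  list(out = best, cache = list(arg = arg, dims = d, k = k, stride = stride,
                                pad = pad, L_out = L_out, Lp = Lp))
}

maxpool_backward <- function(dout, cache) {
  N <- cache$dims[1]; C <- cache$dims[3]
  L_out <- cache$L_out; Lp <- cache$Lp
  dxp <- numeric(N * Lp * C)
  n_i <- rep.int(seq_len(N), L_out * C)
  t_i <- rep(rep(0:(L_out - 1L), each = N), C)
  c_i <- rep(0:(C - 1L), each = N * L_out)
  argv <- as.vector(cache$arg)
  dv <- as.vector(dout)
  # scatter per kernel offset: within one offset the target indices are
  # unique, while across offsets overlapping windows may share an argmax
  for (j in seq_len(cache$k)) {
    sel <- argv == j
    if (!any(sel)) next
    lin <- n_i[sel] + N * (t_i[sel] * cache$stride + j - 1L) + (N * Lp) * c_i[sel]
    dxp[lin] <- dxp[lin] + dv[sel]
  }
  dx <- array(dxp, c(N, Lp, C))
  pad <- cache$pad
  if (pad > 0L) dx <- dx[, pad + seq_len(cache$dims[2]), , drop = FALSE]
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  out <- matrix(0, d[1], d[3])
  for (l in seq_len(d[2])) out <- out + x[, l, ]
  list(out = out / d[2], cache = d)
}

gap_backward <- function(dout, cache) {
  d <- cache
  dx <- array(0, d)
  for (l in seq_len(d[2])) dx[, l, ] <- dout / d[2]
  dx
}

linear_forward <- function(x, W, b) {
  list(out = sweep(x %*% W, 2, b, `+`), cache = x)
}

linear_backward <- function(dout, W, cache) {
  list(dx = tcrossprod(dout, W), dW = crossprod(cache, dout), db = colSums(dout))
}

# ---- softmax cross-entropy -------------------------------------------------

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class labels in 0..(K-1). Returns mean loss and dlogits.
softmax_xent <- function(logits, y) {
  p <- softmax_probs(logits)
  n <- nrow(logits)
  ii <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[ii], 1e-12)))
  dlog <- p
  dlog[ii] <- dlog[ii] - 1
  list(loss = loss, dlogits = dlog / n, probs = p)
}
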