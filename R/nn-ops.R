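# Minimal neural-network primitives used by the MRL predictor and the
# generative autoencoder. Everything is dense-BLAS-vectorized base R:
# batches are arrays of dim (N, L, C) for sequence layers and (N, D)
# matrices for dense layers. Parameters live in flat named lists of numeric
# arrays, which makes weight averaging (model soups) and Adam bookkeeping
# straightforward.

## ---- initialisation ----------------------------------------------------

glorot <- function(n_in, n_out, dims = c(n_in, n_out)) {
  lim <- sqrt(6 / (n_in + n_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

## ---- activations -------------------------------------------------------

ACTIVATIONS <- c("relu", "elu", "tanh")

act_forward <- function(x, name) {
  switch(name,
         relu = pmax(x, 0),
         elu = pmax(x, 0) + expm1(pmin(x, 0)),
         tanh = tanh(x),
         stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

# Derivative expressed through pre-activation x and activation output y.
act_backward <- function(dy, x, y, name) {
  switch(name,
         relu = dy * (x > 0),
         elu = dy * ((x > 0) + (x <= 0) * (y + 1)),
         tanh = dy * (1 - y * y))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(m, b) m + rep(b, each = nrow(m))

slice_t <- function(a, t) {
  d <- dim(a)
  m <- a[, t, ]
  if (!is.matrix(m)) dim(m) <- c(d[1L], d[3L])
  m
}

reshape2 <- function(x, nr, nc) {
  dim(x) <- c(nr, nc)
  x
}

reshape3 <- function(x, d1, d2, d3) {
  dim(x) <- c(d1, d2, d3)
  x
}

## ---- dense -------------------------------------------------------------

dense_forward <- function(x, W, b) add_bias(x %*% W, b)

dense_backward <- function(dy, x, W) {
  list(dx = tcrossprod(dy, W), dW = crossprod(x, dy), db = colSums(dy))
}

## ---- 1-D convolution ---------------------------------------------------

# `W` is (k * C_in) x C_out with the kernel offset as the outer (slow) block
# index; output length is ceil(L / stride) with centred zero padding.

conv_out_len <- function(L, stride) as.integer(ceiling(L / stride))

conv_pads <- function(L, k, stride) {
  L_out <- conv_out_len(L, stride)
  total <- (L_out - 1L) * stride + k - L
  left <- total %/% 2L
  c(left = left, right = total - left, L_out = L_out)
}

conv_im2col <- function(x, k, stride) {
  d <- dim(x); N <- d[1L]; L <- d[2L]; C <- d[3L]
  p <- conv_pads(L, k, stride)
  L_out <- p[["L_out"]]
  xpad <- array(0, dim = c(N, L + p[["left"]] + p[["right"]], C))
  xpad[, p[["left"]] + seq_len(L), ] <- x
  M <- matrix(0, N * L_out, k * C)
  for (j in seq_len(k)) {
    idx <- seq(j, by = stride, length.out = L_out)
    M[, (j - 1L) * C + seq_len(C)] <- matrix(xpad[, idx, ], N * L_out, C)
  }
  list(M = M, N = N, L = L, C = C, L_out = L_out, pads = p)
}

# Stride-1 fast path: a length-preserving convolution is a sum of k shifted
# block matmuls on the (N*L, C) flattening, avoiding im2col materialisation.
conv_forward_s1 <- function(x, W, b) {
  d <- dim(x); N <- d[1L]; L <- d[2L]; C <- d[3L]
  k <- nrow(W) / C
  pad <- (k - 1L) %/% 2L
  Xp <- matrix(0, (L + k - 1L) * N, C)
  Xp[pad * N + seq_len(N * L), ] <- reshape2(x, N * L, C)
  Fo <- ncol(W)
  Y <- matrix(0, N * L, Fo)
  for (j in seq_len(k)) {
    rows <- (j - 1L) * N + seq_len(N * L)
    Y <- Y + Xp[rows, , drop = FALSE] %*%
      W[(j - 1L) * C + seq_len(C), , drop = FALSE]
  }
  reshape3(add_bias(Y, b), N, L, Fo)
}

conv_backward_s1 <- function(dy, x, W) {
  d <- dim(x); N <- d[1L]; L <- d[2L]; C <- d[3L]
  k <- nrow(W) / C
  pad <- (k - 1L) %/% 2L
  Xp <- matrix(0, (L + k - 1L) * N, C)
  Xp[pad * N + seq_len(N * L), ] <- reshape2(x, N * L, C)
  dY <- reshape2(dy, N * L, ncol(W))
  dW <- matrix(0, nrow(W), ncol(W))
  dXp <- matrix(0, (L + k - 1L) * N, C)
  for (j in seq_len(k)) {
    rows <- (j - 1L) * N + seq_len(N * L)
    cols <- (j - 1L) * C + seq_len(C)
    dW[cols, ] <- crossprod(Xp[rows, , drop = FALSE], dY)
    dXp[rows, ] <- dXp[rows, ] + tcrossprod(dY, W[cols, , drop = FALSE])
  }
  list(dx = reshape3(dXp[pad * N + seq_len(N * L), , drop = FALSE], N, L, C),
       dW = dW, db = colSums(dY))
}

conv_forward <- function(x, W, b, stride = 1L) {
  if (stride == 1L) return(conv_forward_s1(x, W, b))
  k <- nrow(W) / dim(x)[3L]
  ic <- conv_im2col(x, k, stride)
  y <- add_bias(ic$M %*% W, b)
  array(y, dim = c(ic$N, ic$L_out, ncol(W)))
}

conv_backward <- function(dy, x, W, b, stride = 1L) {
  if (stride == 1L) return(conv_backward_s1(dy, x, W))
  C <- dim(x)[3L]
  k <- nrow(W) / C
  ic <- conv_im2col(x, k, stride)
  N <- ic$N; L <- ic$L; L_out <- ic$L_out; p <- ic$pads
  dY <- matrix(dy, N * L_out, ncol(W))
  dW <- crossprod(ic$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, W)
  dxpad <- array(0, dim = c(N, L + p[["left"]] + p[["right"]], C))
  for (j in seq_len(k)) {
    idx <- seq(j, by = stride, length.out = L_out)
    dxpad[, idx, ] <- dxpad[, idx, ] +
      array(dM[, (j - 1L) * C + seq_len(C)], dim = c(N, L_out, C))
  }
  list(dx = dxpad[, p[["left"]] + seq_len(L), , drop = FALSE], dW = dW,
       db = db)
}

## ---- transposed 1-D convolution ----------------------------------------

# Realised as zero-upsampling by `stride` followed by a stride-1 convolution,
# cropped to `L_out` positions; this restores the target length exactly for
# any encoder output length ceil(L_out / stride).

upsample_zeros <- function(x, stride) {
  d <- dim(x)
  xup <- array(0, dim = c(d[1L], d[2L] * stride, d[3L]))
  xup[, seq(1L, by = stride, length.out = d[2L]), ] <- x
  xup
}

tconv_forward <- function(x, W, b, stride, L_out) {
  xup <- upsample_zeros(x, stride)
  y <- conv_forward(xup, W, b, stride = 1L)
  y[, seq_len(L_out), , drop = FALSE]
}

tconv_backward <- function(dy, x, W, b, stride, L_out) {
  xup <- upsample_zeros(x, stride)
  L_up <- dim(xup)[2L]
  dy_full <- array(0, dim = c(dim(dy)[1L], L_up, dim(dy)[3L]))
  dy_full[, seq_len(L_out), ] <- dy
  bw <- conv_backward(dy_full, xup, W, b, stride = 1L)
  dx <- bw$dx[, seq(1L, by = stride, length.out = dim(x)[2L]), , drop = FALSE]
  list(dx = dx, dW = bw$dW, db = bw$db)
}

## ---- GRU (returns final hidden state) ----------------------------------

gru_init <- function(c_in, h) {
  list(Wz = glorot(c_in, h), Wr = glorot(c_in, h), Wh = glorot(c_in, h),
       Uz = glorot(h, h), Ur = glorot(h, h), Uh = glorot(h, h),
       bz = numeric(h), br = numeric(h), bh = numeric(h))
}

gru_forward <- function(x, p, keep_cache = FALSE) {
  d <- dim(x); N <- d[1L]; L <- d[2L]; C <- d[3L]
  H <- ncol(p$Wz)
  xm <- matrix(x, N * L, C)
  Xz <- array(xm %*% p$Wz, dim = c(N, L, H))
  Xr <- array(xm %*% p$Wr, dim = c(N, L, H))
  Xh <- array(xm %*% p$Wh, dim = c(N, L, H))
  h <- matrix(0, N, H)
  cache <- if (keep_cache) {
    list(Z = array(0, dim = c(N, L, H)), R = array(0, dim = c(N, L, H)),
         HH = array(0, dim = c(N, L, H)), Hprev = array(0, dim = c(N, L, H)))
  }
  for (t in seq_len(L)) {
    z <- sigmoid(add_bias(slice_t(Xz, t) + h %*% p$Uz, p$bz))
    r <- sigmoid(add_bias(slice_t(Xr, t) + h %*% p$Ur, p$br))
    hh <- tanh(add_bias(slice_t(Xh, t) + (r * h) %*% p$Uh, p$bh))
    if (keep_cache) {
      cache$Z[, t, ] <- z; cache$R[, t, ] <- r
      cache$HH[, t, ] <- hh; cache$Hprev[, t, ] <- h
    }
    h <- (1 - z) * h + z * hh
  }
  list(h = h, cache = cache, x = if (keep_cache) x)
}

gru_backward <- function(dh_last, fwd, p) {
  x <- fwd$x; cache <- fwd$cache
  d <- dim(x); N <- d[1L]; L <- d[2L]; C <- d[3L]
  H <- ncol(p$Wz)
  dXz <- array(0, dim = c(N, L, H))
  dXr <- array(0, dim = c(N, L, H))
  dXh <- array(0, dim = c(N, L, H))
  dUz <- matrix(0, H, H); dUr <- matrix(0, H, H); dUh <- matrix(0, H, H)
  dbz <- numeric(H); dbr <- numeric(H); dbh <- numeric(H)
  dh <- dh_last
  for (t in rev(seq_len(L))) {
    z <- slice_t(cache$Z, t); r <- slice_t(cache$R, t)
    hh <- slice_t(cache$HH, t); hprev <- slice_t(cache$Hprev, t)
    dz <- dh * (hh - hprev)
    dhh <- dh * z
    dhprev <- dh * (1 - z)
    dah <- dhh * (1 - hh * hh)
    daz <- dz * z * (1 - z)
    dXh[, t, ] <- dah
    drh <- tcrossprod(dah, p$Uh)       # gradient wrt (r * hprev)
    dr <- drh * hprev
    dhprev <- dhprev + drh * r
    dar <- dr * r * (1 - r)
    dXz[, t, ] <- daz
    dXr[, t, ] <- dar
    dhprev <- dhprev + tcrossprod(daz, p$Uz) + tcrossprod(dar, p$Ur)
    dUz <- dUz + crossprod(hprev, daz)
    dUr <- dUr + crossprod(hprev, dar)
    dUh <- dUh + crossprod(r * hprev, dah)
    dbz <- dbz + colSums(daz); dbr <- dbr + colSums(dar)
    dbh <- dbh + colSums(dah)
    dh <- dhprev
  }
  xm <- matrix(x, N * L, C)
  dXzm <- matrix(dXz, N * L, H)
  dXrm <- matrix(dXr, N * L, H)
  dXhm <- matrix(dXh, N * L, H)
  dxm <- tcrossprod(dXzm, p$Wz) + tcrossprod(dXrm, p$Wr) +
    tcrossprod(dXhm, p$Wh)
  list(dx = array(dxm, dim = c(N, L, C)),
       grads = list(Wz = crossprod(xm, dXzm), Wr = crossprod(xm, dXrm),
                    Wh = crossprod(xm, dXhm), Uz = dUz, Ur = dUr, Uh = dUh,
                    bz = dbz, br = dbr, bh = dbh))
}

## ---- row softmax -------------------------------------------------------

softmax_rows <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:2]), d[3L])
  m <- exp(m - apply(m, 1L, max))
  array(m / rowSums(m), dim = d)
}

softmax_rows_backward <- function(dp, p) {
  d <- dim(p)
  pm <- matrix(p, prod(d[1:2]), d[3L])
  dpm <- matrix(dp, prod(d[1:2]), d[3L])
  dlog <- pm * (dpm - rowSums(dpm * pm))
  array(dlog, dim = d)
}

## ---- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Elementwise linear combination of two flat parameter lists.
params_combine <- function(a, b, wa, wb) {
  out <- a
  for (nm in names(a)) out[[nm]] <- wa * a[[nm]] + wb * b[[nm]]
  out
}
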