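# Regression checks on the analytic gradients of the network primitives,
# verified against central finite differences on tiny models.

fd_check <- function(loss_fn, params, grads, n_probe = 4L, eps = 1e-6) {
  worst <- 0
  for (nm in names(params)) {
    p <- params[[nm]]
    for (i in sample(length(p), min(n_probe, length(p)))) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      ana <- grads[[nm]][i]
      worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
    }
  }
  worst
}

test_that("predictor backpropagation matches finite differences", {
  set.seed(42)
  cfg <- predictor_config(n_conv_blocks = 2L, conv_filters = 4L,
                          conv_kernel = 3L, gru_dim = 3L,
                          n_dense_blocks = 2L, dense_units = 5L,
                          activation = "tanh", input_len = 50L)
  m <- build_predictor(cfg, seed = 3L)
  x <- array(rnorm(3L * 50L * 5L), dim = c(3L, 50L, 5L))
  y <- rnorm(3L)
  loss_fn <- function(params) {
    pred <- ribolift:::predictor_forward(params, cfg, x)$pred
    mean((pred - y)^2)
  }
  fw <- ribolift:::predictor_forward(m$params, cfg, x, keep_cache = TRUE)
  bw <- ribolift:::predictor_backward(m$params, cfg, fw$cache,
                                      2 * (fw$pred - y) / 3,
                                      need_dx = TRUE)
  expect_lt(fd_check(loss_fn, m$params, bw$grads), 1e-4)
  # input gradients (the path the generator's RL loss relies on)
  eps <- 1e-6
  idx <- sample(length(x), 10L)
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (mean((ribolift:::predictor_forward(m$params, cfg, xp)$pred - y)^2) -
       mean((ribolift:::predictor_forward(m$params, cfg, xm)$pred - y)^2)) /
      (2 * eps)
  }, numeric(1L))
  expect_equal(num, bw$dx[idx], tolerance = 1e-4)
})

test_that("generator backpropagation (incl. RL term) matches finite differences", {
  set.seed(1)
  gcfg <- generator_config(latent_dim = 7L, conv_filters = 4L,
                           conv_kernel = 5L, input_len = 50L,
                           lambda_rl = 3, activation = "tanh")
  g <- build_generator(gcfg, seed = 2L)
  pcfg <- predictor_config(n_conv_blocks = 1L, conv_filters = 3L,
                           conv_kernel = 3L, gru_dim = 3L,
                           n_dense_blocks = 1L, dense_units = 4L,
                           activation = "tanh", input_len = 50L)
  pm <- build_predictor(pcfg, seed = 5L)
  xb <- encode_batch(c(random_utr(30L), random_utr(50L)), 50L)
  lambda <- 3
  loss_fn <- function(params) {
    p <- ribolift:::generator_forward(params, gcfg, xb)$p
    comp <- ribolift:::recon_loss_components(xb, p)
    mrl_in <- ribolift:::predictor_forward(pm$params, pcfg, xb)$pred
    mrl_out <- ribolift:::predictor_forward(pm$params, pcfg, p)$pred
    comp$cce + comp$bce + lambda * mean(rl_loss(mrl_in, mrl_out))
  }
  gf <- ribolift:::generator_forward(g$params, gcfg, xb, keep_cache = TRUE)
  dp <- ribolift:::recon_loss_grad(xb, gf$p)
  mrl_in <- ribolift:::predictor_forward(pm$params, pcfg, xb)$pred
  pf <- ribolift:::predictor_forward(pm$params, pcfg, gf$p,
                                     keep_cache = TRUE)
  rl <- rl_loss(mrl_in, pf$pred)
  pb <- ribolift:::predictor_backward(pm$params, pcfg, pf$cache,
                                      -lambda * rl / 2, need_dx = TRUE)
  grads <- ribolift:::generator_backward(g$params, gcfg, gf$cache,
                                         dp + pb$dx, gf$p)
  expect_lt(fd_check(loss_fn, g$params, grads), 1e-4)
})

test_that("strided and transposed convolutions are exact shape inverses", {
  set.seed(8)
  x <- array(rnorm(2L * 50L * 4L), dim = c(2L, 50L, 4L))
  W <- ribolift:::glorot(5L * 4L, 6L, c(5L * 4L, 6L))
  y <- ribolift:::conv_forward(x, W, numeric(6L), stride = 2L)
  expect_equal(dim(y), c(2L, 25L, 6L))
  W2 <- ribolift:::glorot(5L * 6L, 4L, c(5L * 6L, 4L))
  z <- ribolift:::tconv_forward(y, W2, numeric(4L), stride = 2L,
                                L_out = 50L)
  expect_equal(dim(z), c(2L, 50L, 4L))
  # odd lengths round-trip too (13 -> 7 -> 13)
  x13 <- array(rnorm(2L * 13L * 4L), dim = c(2L, 13L, 4L))
  y7 <- ribolift:::conv_forward(x13, W, numeric(6L), stride = 2L)
  expect_equal(dim(y7), c(2L, 7L, 6L))
  z13 <- ribolift:::tconv_forward(y7, W2, numeric(4L), stride = 2L,
                                  L_out = 13L)
  expect_equal(dim(z13), c(2L, 13L, 4L))
})

test_that("row softmax produces probability rows and exact Jacobian products", {
  set.seed(9)
  logits <- array(rnorm(2L * 4L * 5L), dim = c(2L, 4L, 5L))
  p <- ribolift:::softmax_rows(logits)
  expect_equal(apply(p, c(1L, 2L), sum), matrix(1, 2L, 4L))
  dp <- array(rnorm(length(p)), dim = dim(p))
  dlog <- ribolift:::softmax_rows_backward(dp, p)
  eps <- 1e-6
  idx <- sample(length(logits), 8L)
  num <- vapply(idx, function(i) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    (sum(dp * ribolift:::softmax_rows(lp)) -
       sum(dp * ribolift:::softmax_rows(lm))) / (2 * eps)
  }, numeric(1L))
  expect_equal(num, dlog[idx], tolerance = 1e-5)
})
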