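test_that("reconstruction loss has its closed-form values", {
  s <- random_utr(50L)
  e <- encode_utr(s, 50L)
  expect_equal(reconstruction_loss(e, e), 0)
  # uniform rows against one-hot truth: CCE = ln 5 per position and the pad
  # channel contributes BCE -log(1 - 0.2)
  unif <- matrix(0.2, 50L, 5L)
  expect_equal(reconstruction_loss(e, unif), log(5) - log(0.8))
  # pad predicted at 0.5 where the truth is pad: BCE ln 2 at those
  # positions (CCE restricted to the 30 non-pad positions is 0)
  short <- random_utr(30L)
  et <- encode_utr(short, 50L)
  ep <- et
  ep[1:20, ] <- matrix(rep(c(0.125, 0.125, 0.125, 0.125, 0.5), each = 20L),
                       20L, 5L)
  expect_equal(reconstruction_loss(et, ep), 20 * log(2) / 50)
  expect_error(reconstruction_loss(et, et[, c(2:5, 1L)] * 2), "probability")
  expect_error(reconstruction_loss(et, et[1:10, ]), "shapes")
})

test_that("rl_loss is multiplicative over score decompositions", {
  set.seed(3)
  a <- rnorm(5); b <- rnorm(5); cc <- rnorm(5); d <- rnorm(5)
  expect_equal(rl_loss(a + b, cc + d), rl_loss(a, cc) * rl_loss(b, d))
  expect_true(all(diff(rl_loss(1, seq(0, 3, by = 0.5))) < 0))
})

test_that("the generator maps encodings to probability rows of equal shape", {
  cfg <- generator_config(input_len = 50L, conv_filters = 6L)
  expect_equal(cfg$latent_dim, 128L)
  g <- build_generator(cfg, seed = 1L)
  x <- encode_batch(c(random_utr(30L), random_utr(50L)), 50L)
  out <- ribolift:::generator_forward(g$params, cfg, x)
  expect_equal(dim(out$p), dim(x))
  expect_equal(apply(out$p, c(1L, 2L), sum),
               matrix(1, 2L, 50L))
  expect_equal(ncol(out$latent), 128L)
  g2 <- build_generator(cfg, seed = 1L)
  expect_identical(g2$params, g$params)
  expect_error(generator_config(n_conv = 3L, n_deconv = 2L), "mirror")
  expect_error(generator_config(lambda_rl = -1), "nonnegative")
})

test_that("identity generators return the query unchanged", {
  g <- build_generator(generator_config(input_len = 50L), identity = TRUE)
  m <- synth_predictor(1L)
  s <- random_utr(42L)
  r <- optimize_utr(g, m, s)
  expect_identical(r$optimized$seq, s)
  expect_equal(r$mrl_opt, r$mrl_orig)
  expect_equal(nrow(r$substitutions), 0L)
  expect_error(train_generator(g, m, c(s)), "pass-through")
})

test_that("optimization preserves length and enumerates substitutions exactly", {
  g <- synth_generator(100)
  m <- synth_predictor(1L)
  for (len in c(34L, 50L)) {
    s <- random_utr(len)
    r <- optimize_utr(g, m, s)
    expect_equal(nchar(r$optimized$seq), len)
    a <- strsplit(r$original$seq, "")[[1L]]
    b <- strsplit(r$optimized$seq, "")[[1L]]
    diff_pos <- len - which(a != b) + 1L
    expect_setequal(r$substitutions$position, diff_pos)
    expect_equal(nrow(r$substitutions), edit_count(s, r$optimized$seq))
    expect_true(all(r$substitutions$from != r$substitutions$to))
  }
  # a fixed-length model rewrites only the last 50 nt of longer queries
  s73 <- random_utr(73L)
  r <- optimize_utr(g, m, s73)
  expect_equal(nchar(r$optimized$seq), 73L)
  expect_identical(substr(r$optimized$seq, 1L, 23L), substr(s73, 1L, 23L))
})

test_that("generator training leaves the frozen predictor bit-identical", {
  sp <- synth_split()
  m <- synth_predictor(1L)
  before <- m$params
  g <- build_generator(generator_config(lambda_rl = 100, input_len = 50L,
                                        conv_filters = 8L,
                                        latent_dim = 16L), seed = 7L)
  g <- train_generator(g, m, sp$train$seq[1:256], epochs = 2L, seed = 8L)
  expect_identical(m$params, before)
  expect_true(g$trained)
  expect_equal(nrow(g$history), 2L)
  # an untrained predictor is refused
  fresh <- build_predictor(predictor_config(input_len = 50L), seed = 1L)
  expect_error(train_generator(g, fresh, sp$train$seq[1:10]), "trained")
})

test_that("lambda = 100 rewrites stay focused and well below random distance", {
  res <- synth_opt_results(100)
  ns <- vapply(res, function(r) nrow(r$substitutions), numeric(1L))
  # edits must stay below the expected Hamming distance between unrelated
  # uniform sequences (0.75 * 50 = 37.5): the output is a rewrite of the
  # query, not an unrelated high-MRL sequence
  expect_lt(mean(ns), 37.5)
  # and concentrate in the MRL-informative region (upstream 1..20, which is
  # 40% of positions)
  pos <- unlist(lapply(res, function(r) r$substitutions$position))
  expect_gt(mean(pos <= 20L), 0.40)
  # lambda = 0 makes essentially no edits
  ns0 <- vapply(synth_opt_results(0), function(r) nrow(r$substitutions),
                numeric(1L))
  expect_equal(median(ns0), 0)
})
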