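tiny_cfg <- function(input_len = 50L) {
  predictor_config(conv_filters = 6L, conv_kernel = 3L, gru_dim = 6L,
                   dense_units = 6L, input_len = input_len)
}

test_that("prediction honours the shape contract and seeding", {
  m <- build_predictor(tiny_cfg(), seed = 1L)
  x <- encode_batch(replicate(4L, random_utr(40L)), 50L)
  scores <- predict_mrl(m, x)
  expect_length(scores, 4L)
  m2 <- build_predictor(tiny_cfg(), seed = 1L)
  expect_identical(predict_mrl(m2, x), scores)
  m3 <- build_predictor(tiny_cfg(), seed = 2L)
  expect_false(identical(predict_mrl(m3, x), scores))
  # a 50-nt model rejects 100-position encodings
  x100 <- encode_batch(random_utr(80L), 100L)
  expect_error(predict_mrl(m, x100), "must be")
})

test_that("predictions are order-preserving and batch-size invariant", {
  m <- build_predictor(tiny_cfg(), seed = 3L)
  seqs <- replicate(7L, random_utr(50L))
  x <- encode_batch(seqs, 50L)
  all_at_once <- predict_mrl(m, x)
  perm <- c(3L, 1L, 7L, 5L, 2L, 6L, 4L)
  expect_equal(predict_mrl(m, x[perm, , , drop = FALSE]),
               all_at_once[perm])
  expect_equal(predict_mrl(m, x[1L, , ]), all_at_once[1L])
  expect_equal(predict_mrl(m, x, batch_size = 2L), all_at_once)
})

test_that("the split is exhaustive, disjoint, seeded, and sized 10% / 80:20", {
  lib <- sample_mpra_library(synth_oracle(), 1000L, c(25L, 30L), seed = 2L)
  sp <- split_library(lib, seed = 5L)
  expect_equal(nrow(sp$test), 100L)
  expect_equal(nrow(sp$val), 180L)
  expect_equal(nrow(sp$train), 720L)
  ids <- c(sp$train$id, sp$val$id, sp$test$id)
  expect_setequal(ids, lib$id)
  expect_equal(anyDuplicated(ids), 0L)
  sp2 <- split_library(lib, seed = 5L)
  expect_identical(sp$test$id, sp2$test$id)
  expect_error(split_library(lib[1:5, ], test_frac = 0.01), "too small")
})

test_that("spearman evaluation uses average-rank ties and flags degeneracy", {
  m <- build_predictor(tiny_cfg(), seed = 1L)
  lib <- data.frame(seq = replicate(4L, random_utr(50L)),
                    mrl = c(1, 3, 2, 4))
  # direct rank-correlation identities on the underlying statistic
  expect_equal(stats::cor(c(1, 2, 3, 4), c(1, 3, 2, 4),
                          method = "spearman"), 0.8)
  pred <- predict_mrl(m, lib$seq)
  expect_equal(evaluate_spearman(m, transform(lib, mrl = pred)), 1.0)
  expect_equal(evaluate_spearman(m, transform(lib, mrl = -pred)), -1.0)
  expect_error(evaluate_spearman(m, transform(lib, mrl = rep(1, 4L))),
               "constant")
  expect_error(evaluate_spearman(m, lib[0L, ]), "empty")
})

test_that("the LR schedule decays on plateau and stops after the patience window", {
  lib <- sample_mpra_library(synth_oracle(), 80L, c(30L, 30L), seed = 8L)
  sched <- train_schedule(initial_lr = 1e-300, max_epochs = 40L)
  m <- build_predictor(tiny_cfg(), seed = 2L)
  # an LR this small cannot move the validation loss, so epoch 1 is the
  # only improvement: decay must fire 5 epochs later and again every 5,
  # and training must stop 12 improvement-free epochs after epoch 1
  m <- train_predictor(m, lib[1:60, ], lib[61:80, ], sched = sched,
                       seed = 3L)
  h <- m$history
  expect_equal(nrow(h), 13L)
  expect_equal(h$lr, c(rep(1e-300, 6L), rep(1e-301, 5L), rep(1e-302, 2L)))
  # zero-variance labels are learnable to ~zero validation MSE
  const <- transform(lib, mrl = 3)
  m2 <- build_predictor(tiny_cfg(), seed = 4L)
  m2 <- train_predictor(m2, const[1:60, ], const[61:80, ],
                        sched = train_schedule(initial_lr = 0.05,
                                               batch_size = 8L,
                                               max_epochs = 40L),
                        seed = 5L)
  expect_lt(min(m2$history$val_loss), 0.01)
  expect_error(train_predictor(m2, const[0L, ], const[61:80, ]), "empty")
})

test_that("training resumes across fixed-epoch calls (halving budgets)", {
  lib <- sample_mpra_library(synth_oracle(), 200L, c(30L, 30L), seed = 9L)
  tr <- lib[1:150, ]; va <- lib[151:200, ]
  m <- build_predictor(tiny_cfg(), seed = 6L)
  m <- train_predictor(m, tr, va, seed = 7L, epochs = 2L)
  l1 <- tail(m$history$val_loss, 1L)
  m <- train_predictor(m, tr, va, seed = 8L, epochs = 4L)
  expect_equal(nrow(m$history), 6L)
  expect_lt(tail(m$history$val_loss, 1L), l1 * 1.5)
})
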