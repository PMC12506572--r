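# Shared end-to-end synthetic study artifacts, built lazily and cached for
# the whole test session. Study conditions: a noiseless default oracle, a
# 5,000-record 50-nt library split 10% test / 80:20 train:val, predictors
# trained for a 12-epoch budget, and generators trained for 30 epochs on
# 2,000 training sequences with lambda in {0, 1, 100}.

.synth_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .synth_cache)) {
    assign(key, builder(), envir = .synth_cache)
  }
  get(key, envir = .synth_cache)
}

synth_oracle <- function() memo("oracle", function() {
  mpra_oracle(noise_sd = 0)
})

synth_split <- function() memo("split", function() {
  lib <- sample_mpra_library(synth_oracle(), 5000L, c(50L, 50L), seed = 11L)
  split_library(lib, seed = 12L)
})

synth_predictor <- function(seed) memo(paste0("pred", seed), function() {
  sp <- synth_split()
  m <- build_predictor(predictor_config(input_len = 50L), seed = seed)
  train_predictor(m, sp$train, sp$val,
                  sched = train_schedule(max_epochs = 12L),
                  seed = seed + 100L)
})

synth_generator <- function(lambda) memo(paste0("gen", lambda), function() {
  sp <- synth_split()
  g <- build_generator(generator_config(lambda_rl = lambda,
                                        input_len = 50L), seed = 3L)
  train_generator(g, synth_predictor(1L), sp$train$seq[1:2000],
                  epochs = 30L, seed = 4L)
})

synth_heldout <- function() synth_split()$test$seq[1:200]

synth_opt_results <- function(lambda) {
  memo(paste0("opt", lambda), function() {
    g <- synth_generator(lambda)
    m <- synth_predictor(1L)
    lapply(synth_heldout(), function(s) optimize_utr(g, m, s))
  })
}

# Dataset-level attribution maps for the seed-1 predictor: 16 held-out
# sequences against a 100-sequence training background.
synth_attribution <- function() memo("attr", function() {
  m <- synth_predictor(1L)
  sp <- synth_split()
  bg <- encode_batch(sp$train$seq[1:100], 50L)
  seqs <- sp$test$seq[1:16]
  maps <- lapply(seq_along(seqs), function(i) {
    shap_values(m, seqs[i], bg, n_perm = 12L, seed = 500L + i)
  })
  list(maps = maps, seqs = seqs)
})
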