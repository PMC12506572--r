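test_that("substitution matrices count and normalise mismatches", {
  same <- data.frame(original = c("ACGT", "TTTT"),
                     optimized = c("ACGT", "TTTT"))
  expect_equal(sum(substitution_matrix(same)), 0)
  m <- substitution_matrix(data.frame(original = "TTTT",
                                      optimized = "AAAA"))
  expect_equal(m["T", "A"], 1)
  expect_equal(sum(m), 1)
  m2 <- substitution_matrix(data.frame(original = c("TACG", "CCCC"),
                                       optimized = c("AACG", "ACCC")))
  expect_equal(m2["T", "A"], 0.5)
  expect_equal(m2["C", "A"], 0.5)
  expect_equal(sum(diag(m2)), 0)
  expect_error(substitution_matrix(data.frame(original = "ACGTA",
                                              optimized = "ACGT")),
               "length-matched")
})

test_that("content shift reports composition at mutated sites only", {
  none <- content_shift(data.frame(original = "ACGT", optimized = "ACGT"))
  expect_equal(nrow(none), 0L)
  expect_true(attr(none, "no_mutations"))
  cs <- content_shift(data.frame(original = "TGCC", optimized = "AACC"))
  expect_equal(cs$before_pct[cs$nucleotide == "T"], 50)
  expect_equal(cs$before_pct[cs$nucleotide == "G"], 50)
  expect_equal(cs$after_pct[cs$nucleotide == "A"], 100)
  expect_equal(sum(cs$before_pct), 100)
  expect_equal(sum(cs$after_pct), 100)
})

test_that("uAUG counting includes overlapping occurrences", {
  expect_equal(count_uaugs(strrep("A", 30L)), 0L)
  expect_equal(count_uaugs("ATGATG"), 2L)
  expect_equal(count_uaugs("ATATGA"), 1L)
  expect_equal(count_uaugs("ATGTGATGATGG"), 3L)
  expect_equal(count_uaugs("AUGAUG"), 2L)  # RNA spelling
})

test_that("edit counts are Hamming distances", {
  expect_equal(edit_count("ACGT", "ACGT"), 0L)
  expect_equal(edit_count("ACGT", "AAGT"), 1L)
  expect_equal(edit_count("AAAA", "TTTT"), 4L)
  expect_error(edit_count("ACGT", "ACG"), "equal length")
})

test_that("directed Hausdorff distances match brute force", {
  A <- matrix(c(0, 0), 1L, 2L)
  B <- matrix(c(3, 4), 1L, 2L)
  expect_equal(hausdorff_directed(A, B), 5)
  A2 <- rbind(c(0, 0), c(10, 0))
  B2 <- matrix(c(0, 0), 1L, 2L)
  expect_equal(hausdorff_directed(A2, B2), 10)
  # directed A -> B can be far smaller than B -> A
  expect_equal(hausdorff_directed(B2, A2), 0)
  expect_equal(hausdorff_symmetric(A2, B2), 10)
  set.seed(12)
  X <- matrix(rnorm(40L), 20L, 2L)
  expect_equal(hausdorff_directed(X, X), 0, tolerance = 1e-6)
  # brute force cross-check on random sets
  Y <- matrix(rnorm(30L), 15L, 2L)
  brute <- max(apply(X, 1L, function(a) {
    min(apply(Y, 1L, function(b) sqrt(sum((a - b)^2))))
  }))
  expect_equal(hausdorff_directed(X, Y), brute)
  expect_lte(hausdorff_directed(X, Y), hausdorff_symmetric(X, Y))
  expect_error(hausdorff_directed(X[0L, , drop = FALSE], Y), "non-empty")
  expect_error(hausdorff_directed(X, matrix(0, 2L, 3L)), "dimensionality")
})

test_that("optimized sequences drift toward A and away from uAUGs", {
  res <- synth_opt_results(100)
  m <- substitution_matrix(res)
  expect_equal(sum(m), 1)
  cs <- content_shift(res)
  expect_gt(cs$after_pct[cs$nucleotide == "A"],
            cs$before_pct[cs$nucleotide == "A"])
  # latent embeddings of optimized sequences stay nearer the originals
  # than unrelated random sequences do (closeness in the learned space)
  g <- synth_generator(100)
  latent_of <- function(seqs) {
    ribolift:::generator_forward(g$params, g$cfg,
                                 encode_batch(seqs, 50L))$latent
  }
  orig <- synth_heldout()[1:60]
  opt <- vapply(res[1:60], function(r) r$optimized$seq, character(1L))
  lo <- latent_of(orig); lp <- latent_of(opt)
  d_direct <- hausdorff_directed(lp, lo)
  expect_gt(d_direct, 0)
  expect_lte(d_direct, hausdorff_symmetric(lp, lo))
  expect_gt(mean(vapply(res, function(r) r$mrl_opt - r$mrl_orig,
                        numeric(1L))), 0)
})
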