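# ribolift

Predict the translation efficiency of 5′ UTR sequences — and rewrite them
to translate better.

The 5′ untranslated region upstream of a start codon largely determines
how efficiently ribosomes initiate translation of an mRNA. Massively
parallel reporter assays (MPRAs) measure this as **mean ribosome loading
(MRL)** for libraries of UTR variants. `ribolift` is an R implementation
of a two-stage design framework over such data, for computational
biologists and mRNA engineers:

1. **Discriminative model** — a residual 1-D convolution + GRU + residual
   dense regression network `f(s) → MRL` over one-hot encoded UTRs
   (25–100 nt, left-padded, channels A/T/C/G/pad), trained with MSE under
   a reduce-on-plateau schedule (lr 0.001 → ×0.1 after 5 stalled epochs,
   stop after 12), with successive-halving hyperparameter search and
   greedy weight-averaging model soups.
2. **Generative autoencoder** — encoder → latent (length 128) → decoder
   with row-softmax output `g(s) → p`, trained against the *frozen*
   predictor with the composite loss

   ```
   L = CCE(x, p) + BCE(x_pad, p_pad) + λ · exp(MRL(x) − MRL(p)),  λ = 100
   ```

   so the output stays close to the query (reconstruction terms) while the
   exponential ribosome-loading term pushes predicted MRL up — and decays
   once the output outruns the input, bounding how far the rewrite drifts.

Supporting modules: a seeded **synthetic MPRA oracle** (position-dependent
nucleotide effects near the start codon, an upstream-AUG penalty, Gaussian
noise) giving every pipeline stage a known ground truth; **permutation
Shapley attribution** with exact-efficiency maps, presence-conditioned
summaries and motif (uAUG) effects; sequence-pair analytics (substitution
matrices, composition shifts at mutated sites, Hamming distances, directed
Hausdorff distances on embeddings); and FASTA/TSV I/O with a command-line
front end. The neural networks are implemented natively (BLAS-vectorized
conv/GRU/dense layers with analytic gradients, verified against finite
differences in the test suite).

## Worked example

Train on a synthetic oracle library, then optimize a query UTR:

```r
library(ribolift)

oracle <- mpra_oracle(noise_sd = 0)                 # known ground truth
lib <- sample_mpra_library(oracle, 5000, c(50, 50), seed = 11)
sp  <- split_library(lib, seed = 12)                # 10% test, 80:20

pred <- build_predictor(predictor_config(input_len = 50), seed = 1)
pred <- train_predictor(pred, sp$train, sp$val,
                        sched = train_schedule(max_epochs = 12), seed = 2)
evaluate_spearman(pred, sp$test)
#> [1] 0.9434216

gen <- build_generator(generator_config(lambda_rl = 100, input_len = 50),
                       seed = 3)
gen <- train_generator(gen, pred, sp$train$seq[1:2000], epochs = 30,
                       seed = 4)

optimize_utr(gen, pred, validate_utr(sp$test$seq[1], id = "query"))
#> <optimization_result> query
#>   original : GTTGGGTGACGGAACCCACCACTTTATTTCTCCTCGTTGTAACGGACCTG (MRL 4.223)
#>   optimized: GTTTAACAGAGGAACCAACCACTATATAAAAAAAAAAAAAAAAAACAAAA (MRL 6.638)
#>   30 substitution(s)
```

The held-out Spearman correlation (≈ 0.94) says the predictor has
recovered the oracle's ranking of sequences from data alone. The
optimization lifts the predicted MRL of the query (here 4.22 → 6.64,
arbitrary ribosome-loading units) while editing only part of the sequence,
mostly next to the start codon where the oracle concentrates its effects —
on this synthetic landscape the rewrite is more aggressive than on real
MPRA data, whose landscape near the optimum is flatter. Batch analytics
(`substitution_matrix()`, `content_shift()`, `count_uaugs()`,
`shap_presence_summary()`) quantify the A-enrichment and uAUG removal
behind such gains.

The installed script wraps the same functions for shell use:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ribolift", package = "ribolift"))')
$CLI simulate --out lib.tsv --n 2000 --min-len 50 --max-len 50 --seed 1
$CLI train    --library lib.tsv --out model.ckpt --input-len 50 --epochs 8
$CLI predict  --fasta queries.fa --checkpoint model.ckpt --out scores.tsv
```

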