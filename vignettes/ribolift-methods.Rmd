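---
title: "ribolift: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribolift: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The 5' untranslated region (UTR) of an mRNA controls how efficiently
scanning ribosomes reach and initiate at the main start codon. Massively
parallel reporter assays (MPRAs) attach libraries of UTR variants to a
common reporter and read out mean ribosome loading (MRL) from polysome
profiling, giving hundreds of thousands of (sequence, MRL) pairs. ribolift
implements a two-stage design built on such data:

1. a **discriminative model** that regresses MRL on the UTR sequence, and
2. a **generative autoencoder** that rewrites a query UTR into a nearby
   sequence the discriminative model scores higher — sequence optimization
   that respects the original sequence instead of searching a universal
   "best UTR".

Because real MPRA data are large and training is long, the package also
ships a **synthetic MPRA oracle**: a known ground-truth scoring function
with the same qualitative structure that interpretability analyses recover
from real MPRA models. Every stage of the pipeline can therefore be
validated end to end at desk scale against known answers.

## Sequence representation

Sequences are validated to 25–100 nt over A/C/G/T (RNA `U` is mapped to
`T`). Encoding is one-hot with five channels in the fixed order A, T, C, G,
pad. Shorter sequences are left-padded so that the 3' end — the region
adjacent to the start codon, which dominates initiation — always occupies
the same matrix rows; longer sequences keep their last `target_len`
nucleotides. Two encoded lengths are supported: 100 (variable-length mode)
and 50 (fixed-length mode, which truncates to the last 50 nt). Positions
are reported in upstream coordinates: position 1 is the first nucleotide
upstream of the start codon.

Decoding takes the per-position argmax with ties broken toward the lowest
channel index, which makes decoding deterministic.

## The synthetic MPRA oracle

The oracle score of a sequence is

```
base_level + sum_p w[nt_p, p] - uaug_penalty * n_ATG + N(0, noise_sd)
```

with position weights nonzero in the 20 positions nearest the start codon
(A +0.15, T −0.12, G −0.10, C 0 per position) and one penalty unit per
(possibly overlapping) ATG. These two signals — a 3'-proximal nucleotide
preference and an upstream-AUG penalty — mirror what feature-attribution
analyses recover from MPRA-trained models: T and G near the CDS depress
MRL, A raises it, and upstream AUGs seed upstream open reading frames that
capture scanning ribosomes. The default `uaug_penalty = 1` exceeds the
largest positional gain writing an ATG can produce (3 × 0.27 = 0.81), so
adding an upstream AUG always lowers the noiseless score — a property the
test suite verifies over hundreds of random backbones. The default
`noise_sd = 0.3` leaves the noiseless signal explaining roughly 90% of
label variance for default libraries (signal variance ≈ 0.8 for
variable-length libraries), so predictor training converges in minutes
while labels still look assay-like. The generator-and-predictor validation
suites use the noiseless oracle so that measured gains are attributable to
the models rather than to label noise.

What the oracle does **not** emulate: the marginal MRL distribution of real
polysome profiling, secondary-structure effects, codon context, or
length-dependent biases. Passing the synthetic suite therefore demonstrates
that the machinery can recover a planted signal of the right shape — not
that the defaults would reach any particular accuracy on real MPRA data.

## The discriminative model

Architecture: three residual-connected 1-D convolution blocks (default 32
filters, kernel 7, length-preserving), a GRU whose units march across the
convolutional feature sequence position by position (final hidden state,
default width 32), three residual-connected dense blocks (default 32
units), and a single linear output. Residual skips are identity when widths
match and learned 1×1/linear projections when they differ. The default
activation is elu.

The published procedure fixes the training protocol, and ribolift follows
it exactly: mean-squared-error loss, initial learning rate 0.001, learning
rate × 0.1 after 5 epochs without validation improvement, stop after 12
such epochs (best-validation weights restored), and a 10% test split with
the remainder divided 80:20 into training and validation. The optimizer
(Adam, batch 128) and the concrete widths are not published; the defaults
here were chosen once for desk-scale CPU training — 32-wide layers train to
held-out Spearman ≈ 0.94 on the noiseless oracle in ~12 epochs — and are
exposed through `predictor_config()` for anyone who wants the larger
variants.

Hyperparameter search (`hyperband_search()`) implements successive halving:
a pool of random configurations (the full-scale default is 8000) trains for
2 epochs, the worst two thirds are dropped, survivors continue for 4, then
8, ... epochs until one remains. `hyperband_space(desk = TRUE)` provides a
reduced space for desk-scale runs (pool 27 or 9 with budgets 1, 2, 4).

Model soups (`model_soup()`) average the weights of architecture-identical
models, greedily: rank by loss on ranking data, start from the best, accept
each next model only if averaging it in does not worsen the ranking loss.
The published recipe ranks on the *test* set; ribolift deliberately ranks
on a held-out soup-validation split instead, because ranking on the test
set leaks it into model selection and biases reported test performance. The
greedy mechanism itself is unchanged.

## Attribution

`shap_values()` computes Monte-Carlo permutation Shapley values. Features
are individual (position, channel) entries of the encoding; "introducing" a
feature copies the query's entry over the background sample's entry. For
each sampled order, marginal contributions telescope, so each permutation's
attributions sum exactly to f(query) − f(background sample) and the
averaged map satisfies the efficiency axiom with respect to the averaged
background prediction — the suite checks efficiency, symmetry, and dummy
axioms against an exact enumeration oracle on toy models, and convergence
of the sampled estimator to enumeration on a 6-feature additive model. The
background is drawn from training sequences (100 by default), the standard
expectation baseline. The normalization printed in some descriptions of
permutation Shapley is ambiguous; ribolift implements the standard
permutation average, which the axioms pin down uniquely.

## The generative autoencoder

The encoder applies three stride-2 convolutions (lengths 100→50→25→13, or
50→25→13→7 in fixed-length mode) and a dense layer onto a latent vector of
length 128; the decoder mirrors it with a dense layer and three stride-2
transposed convolutions (realised as zero-upsampling + convolution, cropped
so the output restores the input length exactly), ending in row-wise
softmax probabilities over the five channels.

The training loss per batch is

```
RE + lambda * RL
RE = CCE(x, p)  [averaged over non-pad positions]
   + BCE(x[, , pad], p[, , pad])  [averaged over all positions]
RL = mean(exp(MRL(x) - MRL(p)))
```

where `MRL(.)` is the *frozen* predictor. Design choices worth stating:

- The pad term of the reconstruction loss applies to the pad **channel**
  across all positions (that channel is what marks padding), and pad
  positions are masked out of the CCE average so padding cannot dominate
  reconstruction for short sequences. Whether the two terms are summed or
  averaged only rescales the loss relative to `lambda`; both are averaged
  here.
- `MRL(x)` is the predictor's score of the input sequence, not a measured
  label — the RL term compares the model's own opinion of input and
  output, so optimization needs no labels at inference time.
- The RL gradient reaches the decoder through the predictor evaluated on
  the continuous softmax output (a continuous relaxation); discrete argmax
  decoding happens only at inference. This is the minimal mechanism that
  lets the ribosome-loading signal train the generator.
- The generator is trained once on a library and applied to arbitrary
  queries; there is no per-query fine-tuning, which keeps inference
  interactive.
- At inference, pad rows are masked and non-pad rows argmax over the four
  nucleotide channels only, so the optimized sequence always has exactly
  the query's length.

`exp(MRL(x) − MRL(p))` is strictly decreasing in the output score and
self-limiting: once the output scores well above the input the term's
gradient decays exponentially, so `lambda` sets how far the model pushes
MRL before reconstruction pressure wins. With `lambda = 0` the model is a
plain autoencoder; the suite verifies ≥ 99% held-out positional identity.
Raising `lambda` through {0, 1, 100} produces monotonically higher mean
predicted MRL — and, importantly, higher *noiseless oracle* scores of the
decoded sequences, which guards against the generator merely exploiting
predictor error off the one-hot manifold.

Training defaults (Adam, lr 0.005 with a ×1/5 cut for the last 30% of
epochs, 30–40 epochs, ≥ 2,000 training sequences) were fixed during
development from reconstruction-convergence behaviour; elu is the default
activation because it optimizes the reconstruction markedly better than
relu at equal budget.

## Evaluation analytics

`substitution_matrix()`, `content_shift()`, `count_uaugs()`, and
`edit_count()` quantify how optimization rewrites sequences (which
substitutions, composition at mutated sites, upstream-AUG load, Hamming
distance). `hausdorff_directed()`/`hausdorff_symmetric()` measure how far
optimized-sequence embeddings stray from the originals; the embedding is
supplied by the caller (generator latents by default) rather than a
stochastic 2-D projection, which keeps the metric deterministic — any
external projector can be applied upstream.

## Known limitations

- The synthetic oracle's landscape is steeper than real MPRA data near the
  start codon: its true optimum rewrites most of the informative last 20
  positions. At `lambda = 100` the generator therefore edits roughly 30 of
  50 positions on held-out sequences (seed-dependent; the acceptance run
  reports the exact median) — the informative-region optimum (~16 edits)
  plus extra edits driven by residual predictor error amplified by the
  large `lambda`. On real data, where the landscape is flatter, the same
  machinery yields far fewer edits; desk-scale closeness is demonstrated
  at `lambda = 0` (median 0 edits) and by edit counts staying below the
  random-pair expectation of 37.5.
- Attribution for full predictors uses few permutations per map (8) and a
  modest map count; rankings of mid-importance features are noisy even
  though the planted top features are stable.
- The problem sizes baked into the validation suite (5,000-record
  libraries, 12-epoch predictor budgets, 30-epoch generator budgets, 200
  held-out optimizations) are the package's desk-scale study conditions;
  all of them are plain function arguments and scale up unchanged.

## Reproducing the study

`scripts/acceptance.R` re-runs the complete synthetic study from scratch —
library generation, predictor training across three seeds, attribution,
and the `lambda` ladder — and writes the headline numbers as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
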