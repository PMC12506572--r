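# Permutation-sampling Shapley attribution for sequence models.
#
# Features are the individual (position, channel) entries of the encoded
# input. A feature is "introduced" by taking the query's value at that
# entry; entries not yet introduced take the value of a background sample.
# Each sampled permutation yields one marginal contribution per feature;
# averaging over permutations gives the Monte-Carlo Shapley estimate, and
# by construction the attributions of one permutation sum exactly to
# f(query) - f(background sample), so the averaged map satisfies the
# efficiency axiom relative to the averaged background prediction.

#' Monte-Carlo permutation Shapley values for an encoded sequence
#'
#' @param model An `mrl_predictor`, or any function mapping an (N, L, 5)
#'   array to a numeric vector of N scores (useful for toy models and
#'   cross-checks).
#' @param x Query: an L x 5 encoded matrix, or a sequence (string /
#'   `utr_sequence`) encoded at the model's input length.
#' @param background Background distribution: (B, L, 5) array, L x 5 matrix,
#'   or character vector of sequences. Permutation `i` uses background
#'   sample `1 + (i-1) mod B`.
#' @param n_perm Number of sampled feature orders (>= 1).
#' @param seed Integer seed for the permutation draws.
#' @return An `attribution_map`: list with `values` (L x 5 matrix of Shapley
#'   values), `baseline` (mean background prediction over the used samples),
#'   `prediction` (model score of the query), and `labels` (L x 5 character
#'   matrix of feature labels in upstream coordinates, e.g. `"3-A"`).
#' @export
shap_values <- function(model, x, background, n_perm = 100L, seed = 1L) {
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  score_fn <- as_score_fn(model)
  input_len <- if (inherits(model, "mrl_predictor")) model$cfg$input_len
  if (!is.matrix(x)) {
    if (is.null(input_len)) {
      stop("`x` must be an encoded matrix when `model` is a plain function",
           call. = FALSE)
    }
    x <- encode_utr(as_utr_string(x), input_len)
  }
  L <- nrow(x); C <- ncol(x)
  bg <- as_background(background, input_len)
  if (dim(bg)[2L] != L || dim(bg)[3L] != C) {
    stop("background shape does not match the query encoding",
         call. = FALSE)
  }
  B <- dim(bg)[1L]
  n_feat <- L * C
  xv <- as.vector(x)
  phi <- numeric(n_feat)
  baseline_acc <- 0
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      bgv <- as.vector(matrix(bg[1L + (i - 1L) %% B, , ], L, C))
      ord <- sample.int(n_feat)
      comp <- matrix(bgv, nrow = n_feat + 1L, ncol = n_feat, byrow = TRUE)
      for (j in seq_len(n_feat)) {
        comp[(j + 1L):(n_feat + 1L), ord[j]] <- xv[ord[j]]
      }
      vals <- score_fn(array(comp, dim = c(n_feat + 1L, L, C)))
      phi[ord] <- phi[ord] + diff(vals)
      baseline_acc <- baseline_acc + vals[1L]
    }
  })
  values <- matrix(phi / n_perm, L, C, dimnames = list(NULL, colnames(x)))
  structure(list(values = values,
                 baseline = baseline_acc / n_perm,
                 prediction = score_fn(array(x, dim = c(1L, L, C))),
                 labels = feature_labels(L, C)),
            class = "attribution_map")
}

as_score_fn <- function(model) {
  if (inherits(model, "mrl_predictor")) {
    function(arr) predict_mrl(model, arr)
  } else if (is.function(model)) {
    model
  } else {
    stop("`model` must be an mrl_predictor or a scoring function",
         call. = FALSE)
  }
}

as_background <- function(background, input_len = NULL) {
  if (is.character(background)) {
    if (length(background) == 0L) {
      stop("background must be non-empty", call. = FALSE)
    }
    if (is.null(input_len)) {
      stop("sequence backgrounds need a predictor model", call. = FALSE)
    }
    return(encode_batch(background, input_len))
  }
  if (is.matrix(background)) {
    background <- array(background, dim = c(1L, dim(background)))
  }
  if (!is.array(background) || length(dim(background)) != 3L ||
      dim(background)[1L] == 0L) {
    stop("background must be non-empty", call. = FALSE)
  }
  background
}

feature_labels <- function(L, C) {
  ch <- if (C == 5L) UTR_CHANNELS else as.character(seq_len(C))
  outer(seq_len(L), seq_len(C),
        function(r, c) paste0(L - r + 1L, "-", ch[c]))
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf(paste0("<attribution_map> %d features | prediction %.4f | ",
                     "baseline %.4f | sum(values) %.4f\n"),
              length(x$values), x$prediction, x$baseline, sum(x$values)))
  invisible(x)
}

#' Rank features by mean absolute Shapley value across maps
#'
#' Aggregates a set of per-sequence attribution maps into a dataset-level
#' feature ranking: features are sorted by the mean of |SHAP| across maps,
#' and the sign summary is the mean signed attribution.
#'
#' @param maps List of `attribution_map` objects with congruent shapes.
#' @param k Number of top features to return (default 20; `Inf` for all).
#' @return A data.frame with columns `feature`, `position`, `channel`,
#'   `mean_shap`, `mean_abs_shap`, sorted by decreasing `mean_abs_shap`.
#' @export
rank_features <- function(maps, k = 20L) {
  if (inherits(maps, "attribution_map")) maps <- list(maps)
  if (length(maps) == 0L) stop("`maps` must be non-empty", call. = FALSE)
  dims <- lapply(maps, function(m) dim(m$values))
  if (length(unique(vapply(dims, paste, character(1L),
                           collapse = "x"))) != 1L) {
    stop("attribution maps have mismatched shapes", call. = FALSE)
  }
  L <- dims[[1L]][1L]; C <- dims[[1L]][2L]
  acc_abs <- matrix(0, L, C)
  acc_sgn <- matrix(0, L, C)
  for (m in maps) {
    acc_abs <- acc_abs + abs(m$values)
    acc_sgn <- acc_sgn + m$values
  }
  ch <- if (C == 5L) UTR_CHANNELS else as.character(seq_len(C))
  out <- data.frame(feature = as.vector(feature_labels(L, C)),
                    position = rep(L - seq_len(L) + 1L, times = C),
                    channel = rep(ch, each = L),
                    mean_shap = as.vector(acc_sgn) / length(maps),
                    mean_abs_shap = as.vector(acc_abs) / length(maps),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_shap), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Value-conditioned attribution summary per nucleotide
#'
#' A feature's raw Shapley sign mixes two situations: the query carrying the
#' nucleotide (feature value 1) and the query lacking it (introducing a 0
#' that erases the background's nucleotide). Interpreting "does T depress
#' the prediction" requires conditioning on presence, as beeswarm-style SHAP
#' summaries do. For each nucleotide this returns the mean attribution over
#' all (map, position) pairs where the query sequence actually carries that
#' nucleotide, restricted to the given upstream positions.
#'
#' @param maps List of `attribution_map`s from [shap_values()].
#' @param seqs Character vector of the query sequences, parallel to `maps`.
#' @param positions Upstream positions to include (default 1:20).
#' @return Data.frame with columns `nucleotide`, `mean_shap_present`, `n`.
#' @export
shap_presence_summary <- function(maps, seqs, positions = 1:20) {
  stopifnot(length(maps) == length(seqs))
  out <- lapply(c("A", "T", "C", "G"), function(nuc) {
    chan <- match(nuc, UTR_CHANNELS)
    vals <- numeric(0)
    for (i in seq_along(maps)) {
      ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
      L <- length(ch)
      Lenc <- nrow(maps[[i]]$values)
      for (p in positions) {
        if (p <= L && ch[L - p + 1L] == nuc) {
          vals <- c(vals, maps[[i]]$values[Lenc - p + 1L, chan])
        }
      }
    }
    data.frame(nucleotide = nuc,
               mean_shap_present = if (length(vals)) mean(vals)
                                   else NA_real_,
               n = length(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summed attribution of motif occurrences
#'
#' For every occurrence of `motif` in each query sequence, sums the Shapley
#' values of the (position, channel) features spelling the occurrence. For
#' `"ATG"` this measures how much each upstream AUG contributes to the
#' prediction; a model that has learned the uORF penalty assigns these
#' triplets strongly negative mass.
#'
#' @inheritParams shap_presence_summary
#' @param motif Motif string over A/C/G/T (default `"ATG"`).
#' @return Numeric vector of per-occurrence summed attributions (length 0
#'   when the motif never occurs).
#' @export
shap_motif_effect <- function(maps, seqs, motif = "ATG") {
  stopifnot(length(maps) == length(seqs))
  k <- nchar(motif)
  chans <- match(strsplit(motif, "", fixed = TRUE)[[1L]], UTR_CHANNELS)
  effects <- numeric(0)
  for (i in seq_along(maps)) {
    s <- seqs[[i]]
    L <- nchar(s)
    Lenc <- nrow(maps[[i]]$values)
    hits <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1L]]
    for (h in hits[hits > 0L]) {
      rows <- (Lenc - L) + h:(h + k - 1L)
      effects <- c(effects,
                   sum(maps[[i]]$values[cbind(rows, chans)]))
    }
  }
  effects
}

#' Export a dataset-level attribution table
#'
#' Writes the full feature table (long format: feature, position, channel,
#' mean_shap, mean_abs_shap) as tab-separated text.
#'
#' @param maps List of `attribution_map` objects.
#' @param path Output path.
#' @export
export_attribution <- function(maps, path) {
  tab <- rank_features(maps, k = Inf)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
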