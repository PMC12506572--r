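# Sequence-pair and set-level analytics for optimization runs: substitution
# matrices, composition shifts at mutated sites, uAUG counts, edit counts,
# and directed / symmetric Hausdorff distances between embedding sets.

NUCS <- c("A", "C", "G", "T")

pairs_to_strings <- function(pairs) {
  if (inherits(pairs, "optimization_result")) pairs <- list(pairs)
  if (is.list(pairs) && length(pairs) > 0L &&
      inherits(pairs[[1L]], "optimization_result")) {
    orig <- vapply(pairs, function(r) r$original$seq, character(1L))
    opt <- vapply(pairs, function(r) r$optimized$seq, character(1L))
  } else if (is.data.frame(pairs)) {
    orig <- as.character(pairs$original)
    opt <- as.character(pairs$optimized)
  } else {
    stop(paste("`pairs` must be a data.frame with columns",
               "`original`/`optimized` or a list of optimization results"),
         call. = FALSE)
  }
  if (any(nchar(orig) != nchar(opt))) {
    stop("original and optimized sequences must be length-matched",
         call. = FALSE)
  }
  list(orig = orig, opt = opt)
}

mismatch_chars <- function(p) {
  from <- character(0); to <- character(0)
  for (i in seq_along(p$orig)) {
    a <- strsplit(p$orig[i], "", fixed = TRUE)[[1L]]
    b <- strsplit(p$opt[i], "", fixed = TRUE)[[1L]]
    d <- a != b
    from <- c(from, a[d]); to <- c(to, b[d])
  }
  list(from = from, to = to)
}

#' Substitution matrix over optimized sequence pairs
#'
#' Counts every position-wise mismatch between each original and optimized
#' sequence and normalises by the total number of mismatches, giving the
#' proportion of each from->to substitution class.
#'
#' @param pairs Data.frame with character columns `original` and `optimized`
#'   (length-matched per row), or a list of `optimization_result` objects.
#' @return 4 x 4 matrix (rows = from, cols = to; A,C,G,T) with zero
#'   diagonal; entries sum to 1 when any substitution exists, and are all
#'   zero otherwise.
#' @export
substitution_matrix <- function(pairs) {
  p <- pairs_to_strings(pairs)
  mm <- mismatch_chars(p)
  m <- matrix(0, 4L, 4L, dimnames = list(from = NUCS, to = NUCS))
  if (length(mm$from) > 0L) {
    tab <- table(factor(mm$from, NUCS), factor(mm$to, NUCS))
    m <- unclass(tab / sum(tab))
    dimnames(m) <- list(from = NUCS, to = NUCS)
  }
  m
}

#' Nucleotide composition shift at mutated sites
#'
#' Restricted to the positions where the optimized sequence differs from the
#' original, reports the nucleotide composition (in percent) before and
#' after optimization.
#'
#' @inheritParams substitution_matrix
#' @return Data.frame with columns `nucleotide`, `before_pct`, `after_pct`
#'   (each column of percentages sums to 100). With no mutated sites, a
#'   zero-row data.frame with attribute `no_mutations = TRUE`.
#' @export
content_shift <- function(pairs) {
  p <- pairs_to_strings(pairs)
  mm <- mismatch_chars(p)
  if (length(mm$from) == 0L) {
    out <- data.frame(nucleotide = character(0), before_pct = numeric(0),
                      after_pct = numeric(0))
    attr(out, "no_mutations") <- TRUE
    return(out)
  }
  data.frame(nucleotide = NUCS,
             before_pct = 100 * as.vector(table(factor(mm$from, NUCS))) /
               length(mm$from),
             after_pct = 100 * as.vector(table(factor(mm$to, NUCS))) /
               length(mm$to),
             stringsAsFactors = FALSE)
}

#' Count upstream AUGs in a sequence
#'
#' Possibly-overlapping ATG occurrences; each one can seed an upstream open
#' reading frame that competes with the main start codon.
#'
#' @param s Sequence string or `utr_sequence` (RNA `U` accepted).
#' @return Nonnegative integer count.
#' @export
count_uaugs <- function(s) {
  s <- chartr("Uu", "Tt", as_utr_string(s))
  count_atg_fast(toupper(s))
}

#' Hamming distance between an original and an optimized sequence
#'
#' @param original,optimized Equal-length sequence strings (or
#'   `utr_sequence`s).
#' @return Number of differing positions.
#' @export
edit_count <- function(original, optimized) {
  a <- as_utr_string(original); b <- as_utr_string(optimized)
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  sum(strsplit(a, "", fixed = TRUE)[[1L]] !=
        strsplit(b, "", fixed = TRUE)[[1L]])
}

cross_dist <- function(A, B) {
  a2 <- rowSums(A * A)
  b2 <- rowSums(B * B)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

as_points <- function(x, name) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || nrow(x) == 0L) {
    stop(sprintf("`%s` must be a non-empty numeric point matrix", name),
         call. = FALSE)
  }
  x
}

#' Directed Hausdorff distance between point sets
#'
#' `max over a in A of min over b in B` of the Euclidean distance: how far
#' the worst-placed point of `A` strays from `B`. Useful for quantifying how
#' far optimized-sequence embeddings move from the originals (any embedding
#' may be supplied: generator latents, or an external 2-D projection).
#'
#' @param A,B Point matrices (rows = points) of equal dimensionality.
#' @return Nonnegative scalar.
#' @export
hausdorff_directed <- function(A, B) {
  A <- as_points(A, "A"); B <- as_points(B, "B")
  if (ncol(A) != ncol(B)) {
    stop("point sets must share dimensionality", call. = FALSE)
  }
  max(apply(cross_dist(A, B), 1L, min))
}

#' Symmetric Hausdorff distance
#'
#' The maximum of the two directed distances.
#'
#' @inheritParams hausdorff_directed
#' @return Nonnegative scalar.
#' @export
hausdorff_symmetric <- function(A, B) {
  max(hausdorff_directed(A, B), hausdorff_directed(B, A))
}
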