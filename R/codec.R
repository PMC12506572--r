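# Sequence codec: validated UTR sequences and their fixed-shape one-hot
# encoding shared by the predictor and the generator.
#
# Channel order is fixed package-wide as A, T, C, G, pad (columns 1..5).
# Upstream coordinates: position 1 is the first nucleotide upstream of the
# start codon, i.e. the *last* character of the UTR string; position 2 the
# second-to-last, and so on.

UTR_CHANNELS <- c("A", "T", "C", "G", "pad")
UTR_MIN_LEN <- 25L
UTR_MAX_LEN <- 100L

#' Validate a 5' UTR sequence
#'
#' Uppercases the input, maps RNA `U` to `T`, and checks that the result is a
#' 25-100 nt string over the alphabet A/C/G/T.
#'
#' @param raw Character scalar, the candidate sequence (DNA or RNA spelling).
#' @param id Optional identifier carried along with the sequence.
#' @return An object of class `utr_sequence`: a list with elements `seq`
#'   (validated string) and `id`.
#' @examples
#' s <- validate_utr("acguacguacguacguacguacguacgu")
#' s$seq
#' @export
validate_utr <- function(raw, id = "utr") {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("input sequence must be a non-empty character scalar", call. = FALSE)
  }
  seq <- chartr("u", "t", raw)
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  n <- nchar(seq)
  if (n < UTR_MIN_LEN || n > UTR_MAX_LEN) {
    stop(sprintf("sequence '%s' has length %d; accepted lengths are %d-%d nt",
                 id, n, UTR_MIN_LEN, UTR_MAX_LEN), call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1L]]),
                 c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop(sprintf("sequence '%s' contains invalid character(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(seq = seq, id = as.character(id)), class = "utr_sequence")
}

#' @export
print.utr_sequence <- function(x, ...) {
  cat(sprintf("<utr_sequence> %s (%d nt)\n%s\n", x$id, nchar(x$seq), x$seq))
  invisible(x)
}

as_utr_string <- function(s) {
  if (inherits(s, "utr_sequence")) s$seq
  else if (is.character(s) && length(s) == 1L) s
  else stop("expected a utr_sequence or a character scalar", call. = FALSE)
}

#' One-hot encode a UTR sequence
#'
#' Encodes a sequence as a `target_len` x 5 one-hot matrix with channel order
#' A, T, C, G, pad. Sequences shorter than `target_len` are left-padded with
#' pad one-hots; sequences longer than `target_len` keep only their last
#' `target_len` nucleotides, so the region adjacent to the start codon is
#' always retained.
#'
#' @param s A `utr_sequence` or plain character scalar.
#' @param target_len Encoded length, 50 (fixed-length mode) or 100 (default).
#' @return A `target_len` x 5 numeric matrix with column names
#'   `A`, `T`, `C`, `G`, `pad`.
#' @export
encode_utr <- function(s, target_len = 100L) {
  if (!target_len %in% c(50L, 100L)) {
    stop("`target_len` must be 50 or 100", call. = FALSE)
  }
  seq <- as_utr_string(s)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n > target_len) {
    chars <- chars[(n - target_len + 1L):n]
    n <- target_len
  }
  m <- matrix(0, nrow = target_len, ncol = 5L,
              dimnames = list(NULL, UTR_CHANNELS))
  n_pad <- target_len - n
  if (n_pad > 0L) m[seq_len(n_pad), 5L] <- 1
  idx <- match(chars, UTR_CHANNELS[1:4])
  m[cbind(n_pad + seq_len(n), idx)] <- 1
  m
}

#' Decode an encoded matrix back to a nucleotide string
#'
#' Takes the per-position argmax over the five channels; ties are broken by
#' the lowest channel index (A < T < C < G < pad). Positions whose argmax is
#' the pad channel are dropped.
#'
#' @param e An L x 5 numeric matrix (one-hot or probabilities).
#' @return A character scalar (possibly empty when every row is pad).
#' @export
decode_utr <- function(e) {
  if (!is.matrix(e) || ncol(e) != 5L) {
    stop("encoded input must be an L x 5 matrix", call. = FALSE)
  }
  arg <- max.col(e, ties.method = "first")
  keep <- arg != 5L
  paste(UTR_CHANNELS[arg[keep]], collapse = "")
}

#' Encode a batch of sequences into a 3-D array
#'
#' @param seqs Character vector or list of `utr_sequence` objects.
#' @param target_len Encoded length (50 or 100).
#' @return Numeric array of dim `c(length(seqs), target_len, 5)`.
#' @export
encode_batch <- function(seqs, target_len = 100L) {
  seqs <- vapply(seqs, as_utr_string, character(1L))
  n <- length(seqs)
  x <- array(0, dim = c(n, target_len, 5L))
  for (i in seq_len(n)) x[i, , ] <- encode_utr(seqs[[i]], target_len)
  x
}

#' Read UTR sequences from a FASTA file
#'
#' Multi-record FASTA with wrapped lines is supported; record descriptions
#' after the first whitespace are ignored. Records are returned unvalidated;
#' use [validate_utr()] per record (the CLI does this and reports per-record
#' failures).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of raw sequences.
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_utr_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  if (is.null(names(seqs))) names(set) <- paste0("utr", seq_along(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Convert an encoded row index to an upstream coordinate
#'
#' Row `L` of an L-row encoding is position 1 (first nucleotide upstream of
#' the start codon), row `L - 1` is position 2, and so on.
#'
#' @param row Row index (1-based, from the top of the encoded matrix).
#' @param target_len Encoded length.
#' @return Integer upstream position.
#' @export
upstream_position <- function(row, target_len) {
  as.integer(target_len - row + 1L)
}
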