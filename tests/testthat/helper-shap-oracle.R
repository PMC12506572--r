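# Independent exact-Shapley oracle used to validate the package's sampled
# permutation estimator: enumerates all n! feature orders directly from the
# Shapley definition. Feasible for toy models with <= 7 features.

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# f: function over numeric vectors; x, bg: feature vectors.
exact_shapley <- function(f, x, bg) {
  n <- length(x)
  perms <- all_permutations(n)
  phi <- numeric(n)
  for (ord in perms) {
    cur <- bg
    prev <- f(cur)
    for (j in ord) {
      cur[j] <- x[j]
      v <- f(cur)
      phi[j] <- phi[j] + (v - prev)
      prev <- v
    }
  }
  phi / length(perms)
}

random_utr <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
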