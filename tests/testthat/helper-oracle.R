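# Independent brute-force oracles used to validate the alignment-backed
# implementation. Kept deliberately separate from the package code paths.

# full dynamic-programming affine-gap Smith-Waterman (score only);
# a gap of length L costs gap_open + L * gap_extend
oracle_local_score <- function(q, t, match = 5, mismatch = -4,
                               gap_open = 12, gap_extend = 2) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  n <- length(qs)
  m <- length(ts)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_extend, H[i, j - 1] - gap_open - gap_extend)
      F[i, j] <- max(F[i - 1, j] - gap_extend, H[i - 1, j] - gap_open - gap_extend)
      s <- if (qs[i - 1] == ts[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# brute-force canonical motif: enumerate every rotation of every primitive
# reduction of the motif and its reverse complement, take the lexicographic
# minimum
oracle_canonical <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  rots <- function(x) {
    n <- nchar(x)
    vapply(seq_len(n), function(i) paste0(substr(x, i, n), substr(x, 1, i - 1)),
           character(1))
  }
  reduce <- function(x) {
    n <- nchar(x)
    for (p in seq_len(n)) {
      if (n %% p == 0 &&
          paste(rep(substr(x, 1, p), n / p), collapse = "") == x)
        return(substr(x, 1, p))
    }
    x
  }
  r <- reduce(motif)
  min(c(rots(r), rots(rc(r))))
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
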