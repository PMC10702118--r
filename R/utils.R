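#' @importFrom stats median quantile rbinom rgeom runif setNames
#' @importFrom utils head tail write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

# score matrix over A,C,G,T,N; N scores worse than a mismatch so masked
# regions of a window can never seed a new alignment
scoring_matrix <- function(match = 5, mismatch = -4, n_penalty = -5) {
  b <- c(DNA_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- n_penalty
  m[, "N"] <- n_penalty
  m
}

#' Default alignment scoring parameters
#'
#' Affine-gap scoring used throughout the package: match +5, mismatch -4,
#' gap open -12, gap extension -2 per position (a gap of length L costs
#' 12 + 2L). Close to classical DNA local-alignment defaults.
#'
#' @param match,mismatch Per-column match/mismatch scores.
#' @param gap_open,gap_extend Positive gap costs (opening, per-position).
#' @return A list with the four parameters plus the substitution matrix.
#' @export
default_scoring <- function(match = 5, mismatch = -4, gap_open = 12, gap_extend = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       matrix = scoring_matrix(match, mismatch))
}

#' Reverse complement of a nucleotide string
#'
#' @param x A character string over the DNA alphabet (IUPAC codes allowed).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# component-wise integer mode; ties resolved toward `tie`
mode_int <- function(x, tie = c("min", "max")) {
  tie <- match.arg(tie)
  tab <- table(x)
  best <- as.integer(names(tab)[tab == max(tab)])
  if (tie == "min") min(best) else max(best)
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# derive a distinct child seed from a parent seed (kept below 2^31)
child_seed <- function(seed, i) {
  (as.double(seed) * 1103L + as.double(i) * 12289L) %% 2147483647
}

assert_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x))
    stop(sprintf("`%s` must be a single integer", name), call. = FALSE)
  if (!is.null(min) && x < min)
    stop(sprintf("`%s` must be >= %s", name, min), call. = FALSE)
  invisible(as.integer(x))
}
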