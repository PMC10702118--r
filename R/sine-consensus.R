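#' SINE family consensus sequence
#'
#' A named SINE consensus with optional labeled segments (head, promoter
#' boxes, body, LINE-derived region, tail) in 1-based inclusive consensus
#' coordinates.
#'
#' @param name Identifier, e.g. `"Squam3C"`.
#' @param sequence Nucleotide string.
#' @param family Family label (`"Squam1"`, `"Squam2"`, `"Squam3"`, or other).
#' @param segments Optional named list of `c(start, end)` integer pairs.
#' @return An object of class `sine_consensus`.
#' @export
sine_consensus <- function(name, sequence, family = "other", segments = list()) {
  stopifnot(nzchar(name), nzchar(sequence))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  for (s in segments) {
    if (length(s) != 2 || s[1] < 1 || s[2] > L || s[1] > s[2])
      stop("segment out of consensus bounds", call. = FALSE)
  }
  structure(list(name = name, family = family,
                 sequence = sequence, segments = segments),
            class = "sine_consensus")
}

#' @export
print.sine_consensus <- function(x, ...) {
  cat("sine_consensus", x$name, sprintf("(%s), %d nt", x$family,
                                        nchar(x$sequence)), "\n")
  if (length(x$segments))
    for (nm in names(x$segments))
      cat(sprintf("  %-6s %d-%d\n", nm, x$segments[[nm]][1], x$segments[[nm]][2]))
  invisible(x)
}

#' Deterministic synthetic SINE consensus
#'
#' Builds a squamate-like synthetic SINE consensus for simulations: a
#' tRNA-sized head, a body carrying a `(TC)n` microsatellite region at a
#' configurable anchor, a LINE-derived region, and an A-rich tail. Purely
#' synthetic - a stand-in used by the simulator and tests, not a biological
#' consensus.
#'
#' @param length Total consensus length (>= 150).
#' @param seed Seed for the random portions.
#' @param tc_anchor 1-based position where the `(TC)n` run starts.
#' @param tc_units Number of TC units embedded at the anchor.
#' @return A [sine_consensus()] named `"synSINE"`.
#' @export
synth_sine_consensus <- function(length = 300, seed = 42L,
                                 tc_anchor = 110, tc_units = 6) {
  stopifnot(length >= 150, tc_anchor + 2 * tc_units <= length - 20)
  base <- with_seed(seed,
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""))
  tc <- strvrep("TC", tc_units)
  seqn <- paste0(substr(base, 1, tc_anchor - 1), tc,
                 substr(base, tc_anchor + nchar(tc), length - 10),
                 strvrep("A", 10))
  seqn <- substr(seqn, 1, length)
  sine_consensus("synSINE", seqn, family = "Squam3",
                 segments = list(head = c(1, 110),
                                 body = c(111, length - 60),
                                 ldr = c(length - 59, length - 10),
                                 tail = c(length - 9, length)))
}
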