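#' Find telomeric repeat tracts
#'
#' Maximal tandem runs of the telomere motif (default `TTAGGG`) or its
#' reverse complement with at least `min_repeats` units. Adjacent motif
#' matches are chained into tracts; short interruptions are tolerated as
#' long as non-motif positions make up at most `interruption_frac` of the
#' tract. Both orientations are reported.
#'
#' @param chrom Chromosome sequence (character string).
#' @param motif Telomere motif.
#' @param min_repeats Minimum motif units per tract (default 1000).
#' @param interruption_frac Maximum tolerated fraction of non-motif
#'   positions within a tract.
#' @return A data.frame with 0-based half-open `start`, `end`, `strand`,
#'   and `n_repeats` (motif matches in the tract), sorted by start.
#' @export
find_telomere_tracts <- function(chrom, motif = "TTAGGG", min_repeats = 1000L,
                                 interruption_frac = 0.05) {
  out <- list()
  w <- nchar(motif)
  subj <- Biostrings::DNAString(chrom)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") motif else revcomp(motif)
    starts <- Biostrings::start(Biostrings::matchPattern(pat, subj))
    if (!length(starts)) next
    # chain matches whose inter-match gap keeps interruptions within bounds
    max_gap <- max(0, floor(interruption_frac * w * min_repeats))
    runs <- split_runs(starts, w, max_gap)
    for (r in runs) {
      n <- length(r)
      span <- (r[n] + w - 1) - r[1] + 1
      interrupted <- span - n * w
      if (n >= min_repeats && interrupted <= interruption_frac * span) {
        out[[length(out) + 1L]] <- data.frame(
          start = r[1] - 1L, end = r[n] + w - 1L, strand = strand,
          n_repeats = n, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), n_repeats = integer()))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# split sorted match starts into runs: consecutive matches may be separated
# by up to `max_gap` extra bases beyond the exact period
split_runs <- function(starts, w, max_gap) {
  gaps <- diff(starts)
  brk <- which(gaps > w + max_gap)
  split(starts, cumsum(c(0L, seq_along(gaps) %in% brk)))
}

#' Scan a chromosome for a (possibly degenerate) motif
#'
#' IUPAC-aware motif matching on both strands with up to `max_mismatches`
#' mismatches.
#'
#' @param chrom Chromosome sequence.
#' @param motif Motif, possibly containing IUPAC degenerate codes.
#' @param max_mismatches Allowed mismatches (default 0).
#' @return A data.frame of 0-based half-open `start`, `end`, `strand`.
#' @export
scan_motif <- function(chrom, motif, max_mismatches = 0L) {
  subj <- Biostrings::DNAString(chrom)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") motif else revcomp(motif)
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatches,
                                  fixed = FALSE)
    if (length(m)) {
      out[[length(out) + 1L]] <- data.frame(
        start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), strand = character()))
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$strand), , drop = FALSE]
}

#' CENP-B box motif
#'
#' The canonical 17-mer degenerate CENP-B box (`NTTCGNNNNANNCGGGN`), an
#' external literature constant shipped as a configurable default for
#' centromeric-satellite screening.
#'
#' @export
CENPB_BOX <- "NTTCGNNNNANNCGGGN"

#' Find tandem blocks of a satellite consensus
#'
#' Local-alignment hits of a satellite consensus are merged into blocks
#' (reusing the hit-merging machinery); each block's tandem count is the
#' number of member hits.
#'
#' @param chrom Chromosome sequence.
#' @param satellite_consensus The satellite repeat consensus sequence.
#' @param min_identity Minimum hit identity in percent (default 65).
#' @param min_tandems Minimum member hits per reported block.
#' @param max_gap Merge gap (bp).
#' @param scoring Alignment scoring.
#' @return A data.frame of 0-based half-open `start`, `end`, `n_tandems`.
#' @export
find_satellite_blocks <- function(chrom, satellite_consensus,
                                  min_identity = 65, min_tandems = 2L,
                                  max_gap = 100L,
                                  scoring = default_scoring()) {
  cons <- sine_consensus("satellite", satellite_consensus)
  hits <- find_sine_hits(c(chrom = chrom), cons, min_cov_frac = 0.5,
                         min_hit_identity = min_identity, scoring = scoring)
  regions <- merge_hits(hits, max_gap)
  rows <- lapply(regions, function(r)
    data.frame(start = r$start, end = r$end, n_tandems = nrow(r$hits)))
  res <- if (length(rows)) do.call(rbind, rows)
    else data.frame(start = integer(), end = integer(), n_tandems = integer())
  res[res$n_tandems >= min_tandems, , drop = FALSE]
}

#' Distance of features to the nearest chromosome end
#'
#' @param features Data.frame with 0-based half-open `start`, `end`.
#' @param chrom_length Chromosome length.
#' @return Numeric vector `min(start, chrom_length - end)` per feature.
#' @export
distance_to_end <- function(features, chrom_length) {
  pmin(features$start, chrom_length - features$end)
}

#' Permutation test for subtelomeric enrichment
#'
#' Statistic: difference in median normalized distance-to-end (control
#' minus sSat; positive when sSats sit closer to chromosome ends than the
#' control class). The null distribution permutes class labels across the
#' pooled feature set; one-sided p-value with add-one correction.
#'
#' @param ssat_features,control_features Data.frames with `start`, `end`,
#'   and a `chrom` column naming the chromosome of each feature.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return A list with `statistic` and `p_value`.
#' @export
subtelomeric_enrichment <- function(ssat_features, control_features,
                                    chrom_lengths, n_perm = 10000L,
                                    seed = 1L) {
  norm_dist <- function(f) {
    L <- chrom_lengths[f$chrom]
    distance_to_end(f, L) / (L / 2)
  }
  ds <- norm_dist(ssat_features)
  dc <- norm_dist(control_features)
  pooled <- c(ds, dc)
  ns <- length(ds)
  obs <- median(dc) - median(ds)
  p <- with_seed(seed, {
    b <- sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), ns)
      (median(pooled[-idx]) - median(pooled[idx])) >= obs
    }, logical(1)))
    (b + 1) / (n_perm + 1)
  })
  list(statistic = unname(obs), p_value = unname(p))
}

#' Classify loci into tandem-count size fractions
#'
#' Default split mirrors the chromosomal-profile tracks: a low fraction of
#' 1-5 tandems and a high fraction of >= 6.
#'
#' @param counts Integer vector of per-locus tandem counts.
#' @param split First count belonging to the high fraction (default 6).
#' @param labels Labels for the two fractions.
#' @return Character vector of class labels.
#' @export
size_fraction_track <- function(counts, split = 6L,
                                labels = c("low", "high")) {
  if (!length(counts)) return(character(0))
  ifelse(counts >= split, labels[2], labels[1])
}
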