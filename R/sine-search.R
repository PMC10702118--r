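#' Find SINE-derived local-alignment hits in a genome
#'
#' Seed-and-extend search of a SINE family consensus against every contig on
#' both strands. Exact k-mer seeds (via a preprocessed dictionary) define
#' candidate windows; each window is scanned by iterated Smith-Waterman with
#' masking, so tandem arrays yield one hit per repeated SINE sub-region.
#' A hit is reported when its consensus interval covers at least
#' `min_cov_frac` of the consensus length (the fragment-size criterion used
#' for candidate discovery) and its identity reaches `min_hit_identity`
#' (a floor that suppresses the long, low-identity chance alignments local
#' alignment produces on random sequence).
#'
#' @param genome A [sim_genome()], named character vector, or
#'   `Biostrings::DNAStringSet`.
#' @param consensus A [sine_consensus()].
#' @param min_cov_frac Minimum consensus coverage fraction (default 0.20).
#' @param min_hit_identity Minimum percent identity for a reported hit.
#' @param scoring Scoring from [default_scoring()].
#' @param seed_k Exact seed k-mer length.
#' @param max_iter Safety cap on masking iterations per window.
#' @return A data.frame of hits with 0-based half-open genome coordinates
#'   (`contig`, `start`, `end`, `strand`), 1-based inclusive consensus
#'   coordinates (`cons_start`, `cons_end`), `identity` and `score`,
#'   sorted by contig then start, redundancy-resolved (greedy best-score
#'   first, >= 50% reciprocal-overlap suppression per strand).
#' @export
find_sine_hits <- function(genome, consensus, min_cov_frac = 0.20,
                           min_hit_identity = 60,
                           scoring = default_scoring(), seed_k = 11L,
                           max_iter = 5000L) {
  seqs <- genome_seqs(genome)
  stopifnot(inherits(consensus, "sine_consensus"))
  cons <- consensus$sequence
  L <- nchar(cons)
  min_cov_nt <- ceiling(min_cov_frac * L)
  hits <- list()
  for (contig in names(seqs)) {
    subj <- Biostrings::DNAString(seqs[[contig]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") cons else revcomp(cons)
      wins <- seed_windows(pat, subj, seed_k, margin = L)
      for (w in seq_len(nrow(wins))) {
        wh <- window_hits(pat, seqs[[contig]], wins$start[w], wins$end[w],
                          min_cov_nt, min_hit_identity, scoring, max_iter)
        if (nrow(wh)) {
          # map pattern coords back to forward-consensus coordinates
          if (strand == "-") {
            cs <- L - wh$cons_end + 1L
            ce <- L - wh$cons_start + 1L
            wh$cons_start <- cs
            wh$cons_end <- ce
          }
          wh$contig <- contig
          wh$strand <- strand
          hits[[length(hits) + 1L]] <- wh
        }
      }
    }
  }
  if (!length(hits)) return(empty_hits())
  h <- do.call(rbind, hits)
  h <- resolve_redundancy(h)
  h <- h[order(h$contig, h$start), c("contig", "start", "end", "strand",
                                     "cons_start", "cons_end", "identity",
                                     "score")]
  rownames(h) <- NULL
  h
}

empty_hits <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), cons_start = integer(),
             cons_end = integer(), identity = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

genome_seqs <- function(genome) {
  if (inherits(genome, "sim_genome")) return(genome$seqs)
  if (inherits(genome, "DNAStringSet")) {
    s <- as.character(genome)
    return(s)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
    return(toupper(genome))
  }
  stop("unsupported genome representation", call. = FALSE)
}

# candidate windows from exact k-mer seed matches, merged and padded;
# `stride` subsamples the pattern k-mers (dictionary construction dominates
# for long patterns, and a strided dictionary keeps sensitivity at the
# divergence levels the search targets)
seed_windows <- function(pattern, subject, k, margin, merge_gap = 90L,
                         stride = 1L) {
  L <- nchar(pattern)
  if (L < k) return(data.frame(start = integer(), end = integer()))
  kmers <- substring(pattern, seq(1L, L - k + 1L, by = stride),
                     seq(1L, L - k + 1L, by = stride) + k - 1L)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers)) return(data.frame(start = integer(), end = integer()))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unique(kmers)))
  m <- Biostrings::matchPDict(pd, subject)
  starts <- unlist(Biostrings::startIndex(m), use.names = FALSE)
  if (is.null(starts) || !length(starts))
    return(data.frame(start = integer(), end = integer()))
  r <- IRanges::reduce(IRanges::IRanges(starts, width = k),
                       min.gapwidth = merge_gap)
  s <- pmax(1L, IRanges::start(r) - margin)
  e <- pmin(length(subject), IRanges::end(r) + margin)
  r2 <- IRanges::reduce(IRanges::IRanges(s, e))
  data.frame(start = IRanges::start(r2), end = IRanges::end(r2))
}

# iterated masked Smith-Waterman within one window (1-based coords in/out)
window_hits <- function(pattern, contig_seq, wstart, wend, min_cov_nt,
                        min_identity, scoring, max_iter) {
  sub <- substr(contig_seq, wstart, wend)
  patL <- nchar(pattern)
  # stop once the best remaining score drops below half the score of a
  # minimal gap-free qualifying hit
  q <- min_identity / 100
  stop_score <- 0.5 * min_cov_nt *
    (scoring$match * q + scoring$mismatch * (1 - q))
  out <- list()
  fails <- 0L
  pat <- Biostrings::DNAString(pattern)
  for (it in seq_len(max_iter)) {
    aln <- Biostrings::pairwiseAlignment(
      pat, Biostrings::DNAString(sub), type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    s <- alignment_summary(aln, scoring = scoring, trim = min_identity / 100)
    if (s$score < stop_score || s$target_end < s$target_start) break
    ok <- (s$query_end - s$query_start + 1L) >= min_cov_nt &&
      s$identity >= min_identity
    if (ok) {
      out[[length(out) + 1L]] <- data.frame(
        start = wstart + s$target_start - 2L,            # 0-based half-open
        end = wstart + s$target_end - 1L,
        cons_start = s$query_start, cons_end = s$query_end,
        identity = s$identity, score = s$score,
        stringsAsFactors = FALSE)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= 15L) break
    }
    # mask the aligned target span and continue
    sub <- paste0(substr(sub, 1, s$target_start - 1),
                  strvrep("N", s$target_end - s$target_start + 1L),
                  substr(sub, s$target_end + 1, nchar(sub)))
  }
  if (!length(out)) return(empty_hits()[, c("start", "end", "cons_start",
                                            "cons_end", "identity", "score")])
  do.call(rbind, out)
}

# greedy best-score-first suppression of >=50% reciprocal-overlap hits
resolve_redundancy <- function(h) {
  if (nrow(h) <= 1) return(h)
  keep <- logical(nrow(h))
  for (contig in unique(h$contig)) {
    idx <- which(h$contig == contig)
    idx <- idx[order(-h$score[idx], h$start[idx])]
    kept <- integer(0)
    for (i in idx) {
      redundant <- FALSE
      for (j in kept) {
        ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j])
        if (ov > 0) {
          li <- h$end[i] - h$start[i]
          lj <- h$end[j] - h$start[j]
          if (ov >= 0.5 * li && ov >= 0.5 * lj) { redundant <- TRUE; break }
        }
      }
      if (!redundant) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  h[keep, , drop = FALSE]
}

#' Filter hits to near-full-length SINE copies
#'
#' Retains hits covering more than `min_len_frac` of the consensus length
#' with more than `min_identity` percent identity - both strict
#' inequalities, so a hit at exactly 90% coverage or exactly 65% identity
#' is excluded.
#'
#' @param hits Hit data.frame from [find_sine_hits()].
#' @param consensus The [sine_consensus()] searched.
#' @param min_len_frac Consensus-coverage fraction threshold (strict).
#' @param min_identity Identity threshold in percent (strict).
#' @return The filtered hit data.frame.
#' @export
filter_full_length <- function(hits, consensus, min_len_frac = 0.90,
                               min_identity = 65) {
  L <- nchar(consensus$sequence)
  cov <- (hits$cons_end - hits$cons_start + 1) / L
  hits[cov > min_len_frac & hits$identity > min_identity, , drop = FALSE]
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column: the most frequent non-gap symbol if non-gap symbols form the
#' column majority, otherwise the column is dropped. Ties are broken by the
#' fixed base order A < C < G < T.
#'
#' @param msa Character vector of equal-length aligned rows (`-` for gaps).
#' @return The consensus sequence (gaps removed).
#' @export
column_consensus <- function(msa) {
  if (!length(msa)) stop("empty alignment", call. = FALSE)
  if (length(unique(nchar(msa))) != 1)
    stop("alignment rows must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  n <- nrow(m)
  counts <- vapply(DNA_BASES, function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  nongap <- rowSums(counts)
  keep <- nongap * 2 > n
  best <- DNA_BASES[max.col(counts, ties.method = "first")]  # A<C<G<T ties
  paste(best[keep], collapse = "")
}

# star alignment: align each copy to a reference (one vectorized aligner
# call) and project onto reference columns; insertions relative to the
# reference are dropped, which is exactly what `aligned()` returns for a
# PairwiseAlignments object
star_align <- function(copies, reference, scoring = default_scoring()) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(copies), Biostrings::DNAString(reference),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  rows <- do.call(rbind, strsplit(as.character(Biostrings::aligned(aln)),
                                  "", fixed = TRUE))
  rows
}

collapse_rows <- function(rows) apply(rows, 1, paste, collapse = "")

#' Refine a set of SINE copies into subfamily consensuses
#'
#' The SubFam-style grouping procedure: copies are ordered so that similar
#' copies are adjacent (leaf order of an average-linkage clustering on
#' star-alignment Hamming distances), chunked into consecutive groups of
#' `group_size` (the last group may be smaller), each group is star-aligned
#' and majority-consensus called, and the group consensuses are aligned to
#' each other for inspection.
#'
#' @param copies Character vector of SINE copy sequences (>= 1).
#' @param group_size Copies per group (default 100).
#' @param scoring Alignment scoring.
#' @return A list of class `subfamily_set`: `groups` (data.frame with
#'   `group`, `consensus`, `n_members`), `members` (list of member index
#'   vectors per group), and `consensus_alignment` (star alignment of the
#'   group consensuses against the first one).
#' @export
refine_consensus <- function(copies, group_size = 100L,
                             scoring = default_scoring()) {
  if (!length(copies)) stop("no copies supplied", call. = FALSE)
  assert_scalar_int(group_size, "group_size", min = 1)
  n <- length(copies)
  ord <- if (n <= 2) seq_len(n) else similarity_order(copies, scoring)
  starts <- seq(1L, n, by = group_size)
  groups <- lapply(starts, function(s) ord[s:min(n, s + group_size - 1L)])
  cons <- vapply(groups, function(idx) {
    grp <- copies[idx]
    ref <- grp[which.max(nchar(grp))]
    cc <- column_consensus(collapse_rows(star_align(grp, ref, scoring)))
    # one refinement pass against the first-round consensus
    column_consensus(collapse_rows(star_align(grp, cc, scoring)))
  }, character(1))
  aln <- if (length(cons) > 1)
    collapse_rows(star_align(cons, cons[1], scoring)) else cons
  structure(list(
    groups = data.frame(group = seq_along(groups), consensus = cons,
                        n_members = lengths(groups), stringsAsFactors = FALSE),
    members = groups,
    consensus_alignment = aln), class = "subfamily_set")
}

# order copies so similar ones are adjacent: average-linkage leaf order on
# Hamming distances in a common star-alignment column space
similarity_order <- function(copies, scoring = default_scoring()) {
  ref <- copies[which.max(nchar(copies))]
  rows <- star_align(copies, ref, scoring)
  d <- hamming_dist(rows)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  hc$order
}

hamming_dist <- function(rows) {
  n <- nrow(rows)
  tm <- t(rows)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) d[, i] <- colMeans(tm != tm[, i])
  d
}
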