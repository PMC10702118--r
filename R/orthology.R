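#' Extract flanking sequences of a locus
#'
#' @param locus An `ssat_locus` or a list with `contig`, `start`, `end`
#'   (0-based half-open).
#' @param genome The genome the locus lives in.
#' @param flank_len Flank length in bp.
#' @return A list with `left`, `right` (character), and logical
#'   `left_truncated` / `right_truncated` flags set when a contig end cut a
#'   flank short.
#' @export
extract_flanks <- function(locus, genome, flank_len = 500L) {
  seqs <- genome_seqs(genome)
  contig <- seqs[[locus$contig]]
  L <- nchar(contig)
  ls <- max(0L, locus$start - flank_len)
  left <- substr(contig, ls + 1L, locus$start)
  re <- min(L, locus$end + flank_len)
  right <- substr(contig, locus$end + 1L, re)
  list(left = left, right = right,
       left_truncated = nchar(left) < flank_len,
       right_truncated = nchar(right) < flank_len)
}

# locate many flanks in a genome at once: one strided k-mer dictionary over
# all flanks and orientations, one scan per contig, then windowed local
# alignment per seeded flank. Batching matters: dictionary construction has
# a large fixed cost, so per-flank dictionaries would dominate the run.
# Returns a list (one element per flank) of candidate placement data.frames
# (0-based half-open) or NULL.
locate_flanks_batch <- function(flanks, seqs, min_identity, scoring,
                                seed_k = 15L, stride = 10L,
                                max_candidates = 20L, max_windows = 10L) {
  nf <- length(flanks)
  pats <- character(0)
  pat_flank <- integer(0)
  pat_strand <- character(0)
  oriented <- vector("list", nf)
  for (f in seq_len(nf)) {
    oriented[[f]] <- list("+" = flanks[f], "-" = revcomp(flanks[f]))
    for (strand in c("+", "-")) {
      p <- oriented[[f]][[strand]]
      L <- nchar(p)
      if (L < seed_k) next
      starts <- seq(1L, L - seed_k + 1L, by = stride)
      km <- substring(p, starts, starts + seed_k - 1L)
      keep <- !grepl("[^ACGT]", km)
      pats <- c(pats, km[keep])
      pat_flank <- c(pat_flank, rep(f, sum(keep)))
      pat_strand <- c(pat_strand, rep(strand, sum(keep)))
    }
  }
  cands <- vector("list", nf)
  if (!length(pats)) return(cands)
  upats <- unique(pats)
  pmap <- match(pats, upats)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(upats))
  for (contig in names(seqs)) {
    subj <- Biostrings::DNAString(seqs[[contig]])
    m <- Biostrings::matchPDict(pd, subj)
    sidx <- Biostrings::startIndex(m)
    if (!sum(lengths(sidx))) next
    for (f in unique(pat_flank)) {
      for (strand in c("+", "-")) {
        rows <- which(pat_flank == f & pat_strand == strand)
        if (!length(rows)) next
        starts <- unlist(sidx[pmap[rows]], use.names = FALSE)
        if (is.null(starts) || !length(starts)) next
        fl <- nchar(flanks[f])
        r <- IRanges::reduce(IRanges::IRanges(starts, width = seed_k),
                             min.gapwidth = fl)
        if (length(r) > max_windows) {
          # keep the windows with the most seed support
          support <- IRanges::countOverlaps(
            r, IRanges::IRanges(starts, width = seed_k))
          r <- r[order(-support)[seq_len(max_windows)]]
        }
        ws <- pmax(1L, IRanges::start(r) - fl)
        we <- pmin(length(subj), IRanges::end(r) + fl)
        wr <- IRanges::reduce(IRanges::IRanges(ws, we))
        pat <- oriented[[f]][[strand]]
        for (w in seq_along(wr)) {
          a <- local_align(pat, substr(seqs[[contig]], IRanges::start(wr)[w],
                                       IRanges::end(wr)[w]),
                           scoring, trim = min_identity / 100)
          cov <- (a$query_end - a$query_start + 1) / fl
          if (a$identity >= min_identity && cov >= 0.5) {
            cands[[f]] <- rbind(cands[[f]], data.frame(
              contig = contig, strand = strand,
              start = IRanges::start(wr)[w] + a$target_start - 2L,
              end = IRanges::start(wr)[w] + a$target_end - 1L,
              identity = a$identity, coverage = cov,
              stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  lapply(cands, function(x) {
    if (is.null(x)) return(NULL)
    head(x[order(-x$identity), , drop = FALSE], max_candidates)
  })
}

# choose the best co-linear placement of the two flank candidate sets and
# count monomers in the enclosed genome-B interval with locus A's unit
pair_from_candidates <- function(locusA, lc, rc, seqsB, max_span, scoring) {
  if (is.null(lc) || is.null(rc)) return(NULL)
  best <- NULL
  ties <- 0L
  for (i in seq_len(nrow(lc))) for (j in seq_len(nrow(rc))) {
    if (lc$contig[i] != rc$contig[j] || lc$strand[i] != rc$strand[j]) next
    if (lc$strand[i] == "+") {
      if (rc$start[j] < lc$end[i]) next
      span <- rc$start[j] - lc$end[i]
      interval <- c(lc$end[i], rc$start[j])
    } else {
      if (lc$start[i] < rc$end[j]) next
      span <- lc$start[i] - rc$end[j]
      interval <- c(rc$end[j], lc$start[i])
    }
    if (span > max_span) next
    combined <- lc$identity[i] + rc$identity[j]
    cand <- list(contig = lc$contig[i], strand = lc$strand[i],
                 startB = interval[1], endB = interval[2], span = span,
                 left_identity = lc$identity[i],
                 right_identity = rc$identity[j], combined = combined)
    if (is.null(best) || combined > best$combined + 1e-9) {
      best <- cand
      ties <- 0L
    } else if (abs(combined - best$combined) <= 1e-9 &&
               !identical(cand[c("contig", "startB", "endB")],
                          best[c("contig", "startB", "endB")])) {
      ties <- ties + 1L
    }
  }
  if (is.null(best)) return(NULL)
  if (ties > 0L) {
    message("ambiguous ortholog placement for locus at ", locusA$contig, ":",
            locusA$start, "; reporting none")
    return(NULL)
  }
  # monomer counting in B uses the same unit as locus A
  bseq <- substr(seqsB[[best$contig]], best$startB + 1L, best$endB)
  if (best$strand == "-") bseq <- revcomp(bseq)
  nB <- if (nchar(bseq) >= 10) {
    nrow(tile_monomers(bseq, locusA$unit_consensus, min_identity = 60,
                       scoring = scoring))
  } else 0L
  structure(list(
    contigA = locusA$contig, startA = locusA$start, endA = locusA$end,
    contigB = best$contig, startB = best$startB, endB = best$endB,
    strand = best$strand,
    left_identity = best$left_identity, right_identity = best$right_identity,
    inter_flank_span_B = best$span,
    n_monomers_A = locusA$n_monomers, n_monomers_B = nB,
    delta_monomers = nB - locusA$n_monomers), class = "ortholog_pair")
}

#' Find the ortholog of an sSat locus in a second genome
#'
#' The flank-matching pipeline: both flanks of `locusA` (which must contain
#' at least two repeat units) are located in genome B; the best co-linear
#' placement (same contig, same orientation, left flank before right flank,
#' enclosed span <= `max_span`, both identities >= `min_flank_identity`) is
#' selected; the enclosed B interval is re-tiled with locus A's repeat unit
#' and the monomer-count difference is reported. Returns `NULL` when no
#' placement qualifies or when equally scoring placements remain tied.
#'
#' @param locusA An `ssat_locus` (>= 2 monomers).
#' @param genomeA,genomeB The two genomes.
#' @param flank_len Flank length (default 500).
#' @param min_flank_identity Percent identity required of each flank match.
#' @param max_span Maximum distance between flank matches in B.
#' @param scoring Alignment scoring.
#' @return A list of class `ortholog_pair`: coordinates in both genomes,
#'   flank identities, `n_monomers_A`, `n_monomers_B`, `delta_monomers`.
#' @export
find_ortholog <- function(locusA, genomeA, genomeB, flank_len = 500L,
                          min_flank_identity = 80, max_span = 100000L,
                          scoring = default_scoring()) {
  if (locusA$n_monomers < 2)
    stop("locusA must contain at least two repeat units", call. = FALSE)
  seqsB <- genome_seqs(genomeB)
  fl <- extract_flanks(locusA, genomeA, flank_len)
  cands <- locate_flanks_batch(c(fl$left, fl$right), seqsB,
                               min_flank_identity, scoring)
  pair_from_candidates(locusA, cands[[1]], cands[[2]], seqsB, max_span,
                       scoring)
}

#' Find orthologs for a list of loci
#'
#' All flanks are located with a single batched dictionary scan of genome B,
#' then each locus is paired independently.
#'
#' @param lociA List of `ssat_locus` objects in genome A.
#' @inheritParams find_ortholog
#' @return A data.frame with one row per successfully paired locus.
#' @export
find_orthologs <- function(lociA, genomeA, genomeB, flank_len = 500L,
                           min_flank_identity = 80, max_span = 100000L,
                           scoring = default_scoring()) {
  seqsB <- genome_seqs(genomeB)
  eligible <- which(vapply(lociA, function(l) l$n_monomers >= 2, logical(1)))
  if (!length(eligible)) return(data.frame())
  fls <- lapply(lociA[eligible], extract_flanks, genome = genomeA,
                flank_len = flank_len)
  flanks <- c(vapply(fls, `[[`, character(1), "left"),
              vapply(fls, `[[`, character(1), "right"))
  cands <- locate_flanks_batch(flanks, seqsB, min_flank_identity, scoring)
  ne <- length(eligible)
  rows <- list()
  for (k in seq_len(ne)) {
    i <- eligible[k]
    p <- pair_from_candidates(lociA[[i]], cands[[k]], cands[[ne + k]],
                              seqsB, max_span, scoring)
    if (is.null(p)) next
    rows[[length(rows) + 1L]] <- data.frame(
      locusA = i, contigA = p$contigA, startA = p$startA, endA = p$endA,
      contigB = p$contigB, startB = p$startB, endB = p$endB,
      strand = p$strand, left_identity = p$left_identity,
      right_identity = p$right_identity,
      inter_flank_span_B = p$inter_flank_span_B,
      n_monomers_A = p$n_monomers_A, n_monomers_B = p$n_monomers_B,
      delta_monomers = p$delta_monomers, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Histogram of absolute monomer-count differences
#'
#' @param pairs Data.frame from [find_orthologs()] (or any table with a
#'   `delta_monomers` column).
#' @return A list with `histogram` (data.frame of `abs_delta`, `count`),
#'   `fraction_zero`, and `fraction_one`.
#' @export
delta_distribution <- function(pairs) {
  d <- abs(pairs$delta_monomers)
  tab <- table(d)
  data_hist <- data.frame(abs_delta = as.integer(names(tab)),
                          count = as.integer(tab))
  list(histogram = data_hist,
       fraction_zero = if (length(d)) mean(d == 0) else NA_real_,
       fraction_one = if (length(d)) mean(d == 1) else NA_real_)
}
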