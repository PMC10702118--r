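#' Merge nearby hits into candidate regions
#'
#' Transitive closure of the "gap < max_gap" relation per contig,
#' strand-agnostic: hit fragments found less than `max_gap` bp apart are
#' merged (a gap of exactly `max_gap` is not merged). Member hits are
#' preserved per region.
#'
#' @param hits Hit data.frame from [find_sine_hits()].
#' @param max_gap Strict gap threshold in bp (default 100).
#' @return A list of candidate regions, each a list with `contig`, `start`,
#'   `end` (0-based half-open) and `hits` (the member data.frame).
#' @export
merge_hits <- function(hits, max_gap = 100L) {
  if (!nrow(hits)) return(list())
  out <- list()
  for (contig in unique(hits$contig)) {
    h <- hits[hits$contig == contig, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    # gap between [s1,e1) and [s2,e2) is s2 - e1; merge iff gap < max_gap
    r <- IRanges::reduce(IRanges::IRanges(h$start + 1L, h$end),
                         min.gapwidth = max_gap)
    grp <- IRanges::findOverlaps(
      IRanges::IRanges(h$start + 1L, h$end), r, select = "first")
    for (g in seq_along(r)) {
      members <- h[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        contig = contig,
        start = min(members$start), end = max(members$end),
        hits = members)
    }
  }
  out
}

#' Select candidate satellite loci by merged length
#'
#' Keeps merged regions strictly longer than `min_len` bp ("longer than
#' 500 bp after fusion"); a region of exactly `min_len` is excluded.
#'
#' @param regions Output of [merge_hits()].
#' @param min_len Strict length threshold (default 500).
#' @return The retained regions.
#' @export
select_candidates <- function(regions, min_len = 500L) {
  Filter(function(r) (r$end - r$start) > min_len, regions)
}

# estimate the tandem period of a locus from exact k-mer recurrence:
# the modal spacing between consecutive occurrences of the same k-mer
# (spacings below `min_period` - microsatellite runs - are ignored)
estimate_period <- function(locus_seq, k = 12L, min_period = 10L,
                            max_period = NULL, min_support = 3L) {
  L <- nchar(locus_seq)
  if (L < 2L * min_period) return(NULL)
  kmers <- substring(locus_seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  occ <- split(seq_along(kmers), kmers)
  occ <- occ[lengths(occ) >= 2L]
  if (!length(occ)) return(NULL)
  pos <- integer(0); dif <- integer(0)
  for (o in occ) {
    d <- diff(o)
    keep <- d >= min_period
    if (any(keep)) {
      pos <- c(pos, o[-length(o)][keep])
      dif <- c(dif, d[keep])
    }
  }
  if (!is.null(max_period)) {
    pos <- pos[dif < max_period]
    dif <- dif[dif < max_period]
  }
  if (length(dif) < min_support) return(NULL)
  tab <- table(dif)
  P <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) < min_support) return(NULL)
  list(period = P, anchors = pos[dif == P])
}

# representative unit of a periodic locus, anchored on the SINE consensus.
# The consensus is aligned against a two-period window of the locus; the
# unit is the length-P consensus window with the highest matched-column
# count, which pins the unit's phase on the consensus even though the local
# alignment itself may stretch across monomer junctions.
infer_unit <- function(region, locus_seq, consensus, min_identity,
                       scoring) {
  L <- nchar(consensus$sequence)
  per <- estimate_period(locus_seq, max_period = L)
  if (is.null(per)) return(NULL)
  P <- per$period
  mid <- (nchar(locus_seq) - 2L * P) / 2
  a <- per$anchors[which.min(abs(per$anchors - mid))]
  rep2 <- substr(locus_seq, a, min(nchar(locus_seq), a + 2L * P - 1L))
  mvec <- consensus_match_profile(consensus$sequence, rep2, scoring)
  if (sum(mvec) < min_identity / 100 * P * 0.5) return(NULL)
  if (L <= P) return(NULL)
  wsum <- stats::filter(mvec, rep(1, P), sides = 1)  # sum over [s-P+1, s]
  wsum <- wsum[P:L]                                  # window starts 1..L-P+1
  s <- which.max(wsum)                               # ties -> smallest start
  best_frac <- wsum[s] / P
  if (best_frac < min_identity / 100) return(NULL)
  list(unit_start = s, unit_end = s + P - 1L, period = P,
       unit_seq = substr(consensus$sequence, s, s + P - 1L))
}

# logical vector over consensus positions: TRUE where the local alignment
# of the consensus against `window` has a matching column
consensus_match_profile <- function(consensus_seq, window, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(consensus_seq), Biostrings::DNAString(window),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  out <- logical(nchar(consensus_seq))
  cpos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  for (k in seq_along(p)) {
    if (p[k] != "-") {
      cpos <- cpos + 1L
      if (s[k] == p[k]) out[cpos] <- TRUE
    }
  }
  out
}

#' Detect tandemly repeated SINE-derived units within a candidate locus
#'
#' The locus's tandem period is estimated from exact k-mer recurrence
#' (modal spacing between repeated k-mers), the repeat unit is anchored on
#' the SINE consensus by aligning the consensus against a two-period window
#' of the locus, and the locus is tiled by repeated glocal alignment of the
#' unit in both directions from an anchor. Each monomer is then re-aligned
#' to the consensus individually to record its consensus interval, which
#' lets terminal monomers extend beyond the repeat unit toward a SINE
#' terminus. Returns an empty data.frame when no periodic SINE-derived
#' structure shorter than the SINE is found.
#'
#' @param region A candidate region from [select_candidates()].
#' @param genome The genome searched.
#' @param consensus The [sine_consensus()].
#' @param min_identity Monomer acceptance identity (percent).
#' @param max_gap Strict inter-monomer gap bound in bp.
#' @param pad Padding in bp added to each side of the region for detection.
#' @param scoring Alignment scoring.
#' @return A data.frame of monomers with locus-relative 0-based half-open
#'   `start`/`end`, genome coordinates `gstart`/`gend`, consensus interval
#'   `cons_start`/`cons_end` (1-based), `identity` and `seq`, ordered along
#'   the locus; zero rows if no tandem structure.
#' @export
detect_tandem_units <- function(region, genome, consensus,
                                min_identity = 60, max_gap = 100L,
                                pad = 200L, scoring = default_scoring()) {
  seqs <- genome_seqs(genome)
  strand_tab <- table(region$hits$strand)
  strand <- if (length(strand_tab)) names(strand_tab)[which.max(strand_tab)]
    else "+"
  # hit-derived regions can underestimate the array extent by up to about a
  # monomer on each side; pad the detection window so terminal monomers and
  # their extensions are visible to the tiler
  rstart <- max(0L, region$start - pad)
  rend <- min(nchar(seqs[[region$contig]]), region$end + pad)
  locus_seq <- substr(seqs[[region$contig]], rstart + 1L, rend)
  if (strand == "-") locus_seq <- revcomp(locus_seq)
  unit <- infer_unit(region, locus_seq, consensus, min_identity, scoring)
  if (is.null(unit)) return(empty_monomers())
  mon <- tile_monomers(locus_seq, unit$unit_seq, min_identity, max_gap, scoring)
  if (!nrow(mon)) return(empty_monomers())
  mon <- align_monomers(mon, locus_seq, consensus, unit, min_identity, scoring)
  mon$seq <- substring(locus_seq, mon$start + 1L, mon$end)
  if (strand == "-") {
    # map back to forward-genome coordinates
    L <- nchar(locus_seq)
    s <- L - mon$end
    e <- L - mon$start
    mon$start <- s
    mon$end <- e
    mon <- mon[order(mon$start), , drop = FALSE]
  }
  mon$gstart <- rstart + mon$start
  mon$gend <- rstart + mon$end
  mon$strand <- strand
  rownames(mon) <- NULL
  mon
}

empty_monomers <- function() {
  data.frame(start = integer(), end = integer(), identity = numeric(),
             cons_start = integer(), cons_end = integer(),
             gstart = integer(), gend = integer(), strand = character(),
             seq = character(), stringsAsFactors = FALSE)
}

# tile a locus sequence with a repeat unit by glocal alignment in both
# directions from the best anchor; coordinates 0-based half-open relative
# to the locus sequence
tile_monomers <- function(locus_seq, unit_seq, min_identity = 60,
                          max_gap = 100L, scoring = default_scoring()) {
  u <- nchar(unit_seq)
  L <- nchar(locus_seq)
  # glocal anchor: the whole unit against its best-matching locus substring
  # (a plain local alignment can stretch across monomer junctions)
  anchor <- local_align(unit_seq, locus_seq, scoring, type = "global-local")
  if (anchor$identity < min_identity)
    return(data.frame(start = integer(), end = integer(), identity = numeric()))
  mons <- data.frame(start = anchor$target_start - 1L, end = anchor$target_end,
                     identity = anchor$identity)
  # window sizes tried in order: the tight window sees only the adjacent
  # copy; the wide one allows a diverged-edge monomer or a larger gap
  wlens <- unique(c(u + 20L, u + max_gap + ceiling(u / 2)))
  # forward
  pos <- anchor$target_end
  repeat {
    if (pos + 10 > L) break
    step <- NULL
    for (wlen in wlens) {
      win <- substr(locus_seq, pos + 1L, min(L, pos + wlen))
      if (nchar(win) < 10) next
      a <- local_align(unit_seq, win, scoring, type = "global-local")
      gap <- a$target_start - 1L
      if (a$identity >= min_identity && gap < max_gap) {
        step <- data.frame(start = pos + a$target_start - 1L,
                           end = pos + a$target_end, identity = a$identity)
        break
      }
    }
    if (is.null(step) || step$end <= pos) break
    mons <- rbind(mons, step)
    pos <- step$end
  }
  # backward from the anchor; the unit and window are string-reversed so
  # the aligner's preference for the window start selects the nearest copy
  runit <- strrev(unit_seq)
  pos <- mons$start[1]
  repeat {
    if (pos < 10) break
    step <- NULL
    for (wlen in wlens) {
      wstart <- max(1L, pos - wlen + 1L)
      win <- strrev(substr(locus_seq, wstart, pos))
      if (nchar(win) < 10) next
      a <- local_align(runit, win, scoring, type = "global-local")
      gap <- a$target_start - 1L
      if (a$identity >= min_identity && gap < max_gap) {
        step <- data.frame(start = pos - a$target_end,
                           end = pos - a$target_start + 1L,
                           identity = a$identity)
        break
      }
    }
    if (is.null(step) || step$start >= pos) break
    mons <- rbind(step, mons)
    pos <- step$start
  }
  mons[order(mons$start), , drop = FALSE]
}

strrev <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")

# re-align every monomer tile against the SINE consensus to obtain its
# consensus interval; terminal monomers additionally probe the region just
# outside the array for an abutting extension toward the SINE terminus
align_monomers <- function(mon, locus_seq, consensus, unit, min_identity,
                           scoring) {
  n <- nrow(mon)
  L <- nchar(consensus$sequence)
  cs <- integer(n); ce <- integer(n)
  for (i in seq_len(n)) {
    a <- local_align(substr(locus_seq, mon$start[i] + 1L, mon$end[i]),
                     consensus$sequence, scoring, trim = min_identity / 100)
    if (a$identity >= min_identity) {
      mon$start[i] <- mon$start[i] + a$query_start - 1L
      mon$end[i] <- mon$start[i] + (a$query_end - a$query_start + 1L)
      cs[i] <- a$target_start
      ce[i] <- a$target_end
      mon$identity[i] <- a$identity
    } else {
      cs[i] <- unit$unit_start
      ce[i] <- min(L, unit$unit_start + (mon$end[i] - mon$start[i]) - 1L)
    }
  }
  # leading extension: consensus 5' of the unit, immediately before the tile
  if (cs[1] > 1) {
    rs <- max(0L, mon$start[1] - (cs[1] - 1L) - 20L)
    if (mon$start[1] - rs >= 5) {
      a <- local_align(substr(locus_seq, rs + 1L, mon$start[1]),
                       substr(consensus$sequence, 1, cs[1] - 1L), scoring,
                       trim = min_identity / 100)
      if (a$score > 0 && a$identity >= min_identity &&
          (mon$start[1] - rs) - a$query_end <= 3 &&
          (cs[1] - 1L) - a$target_end <= 3) {
        mon$start[1] <- rs + a$query_start - 1L
        cs[1] <- a$target_start
      }
    }
  }
  # trailing extension: consensus 3' of the unit, immediately after the tile
  if (ce[n] < L) {
    re <- min(nchar(locus_seq), mon$end[n] + (L - ce[n]) + 20L)
    if (re - mon$end[n] >= 5) {
      a <- local_align(substr(locus_seq, mon$end[n] + 1L, re),
                       substr(consensus$sequence, ce[n] + 1L, L), scoring,
                       trim = min_identity / 100)
      if (a$score > 0 && a$identity >= min_identity &&
          a$query_start <= 4 && a$target_start <= 4) {
        mon$end[n] <- mon$end[n] + a$query_end
        ce[n] <- ce[n] + a$target_end
      }
    }
  }
  mon$cons_start <- cs
  mon$cons_end <- ce
  mon
}

#' Assign leading / middle / trailing roles to monomers
#'
#' The first monomer of an array is the 5' (leading) monomer, the last the
#' 3' (trailing) one, the rest are middle monomers. Terminal monomers may
#' extend along the SINE consensus beyond the repeat unit; the recorded
#' consensus intervals carry that extension.
#'
#' @param monomers Monomer data.frame from [detect_tandem_units()].
#' @return The data.frame with a `role` column.
#' @export
classify_monomers <- function(monomers) {
  n <- nrow(monomers)
  if (n == 0) {
    monomers$role <- character(0)
    return(monomers)
  }
  role <- rep("middle", n)
  # leading = 5'-terminal monomer in SINE orientation: first in genome order
  # on the plus strand, last on the minus strand
  minus <- n > 0 && !is.null(monomers$strand) && monomers$strand[1] == "-"
  role[if (minus) n else 1] <- "leading"
  role[if (minus) 1 else n] <- "trailing"
  monomers$role <- role
  monomers
}

#' Call an sSat locus from classified monomers
#'
#' Emits an sSat locus when the middle-monomer count reaches
#' `min_middle_monomers` and all adjacent monomer gaps are < `max_gap`.
#' The repeat-unit interval is the component-wise mode of the middle
#' monomers' consensus intervals (ties toward the longer unit), and must be
#' shorter than the source SINE.
#'
#' @param region The candidate region the monomers came from.
#' @param monomers Classified monomer data.frame ([classify_monomers()]).
#' @param consensus The source [sine_consensus()].
#' @param min_middle_monomers Minimum middle monomers (default 4).
#' @param max_gap Strict adjacent-gap bound in bp.
#' @return An object of class `ssat_locus`, or `NULL` if the locus does not
#'   qualify.
#' @export
call_ssat <- function(region, monomers, consensus, min_middle_monomers = 4L,
                      max_gap = 100L) {
  n <- nrow(monomers)
  if (n < 2) return(NULL)
  n_middle <- sum(monomers$role == "middle")
  if (n_middle < min_middle_monomers) return(NULL)
  gaps <- monomers$gstart[-1] - monomers$gend[-n]
  if (any(gaps >= max_gap)) return(NULL)
  mid <- monomers[monomers$role == "middle", , drop = FALSE]
  ref <- if (nrow(mid)) mid else monomers
  us <- mode_int(round(ref$cons_start), tie = "min")  # ties -> longer unit
  ue <- mode_int(round(ref$cons_end), tie = "max")
  unit_len <- ue - us + 1L
  if (unit_len >= nchar(consensus$sequence)) return(NULL)
  unit_cons <- if (nrow(mid) >= 2) {
    ref_seq <- mid$seq[which.max(nchar(mid$seq))]
    column_consensus(collapse_rows(star_align(mid$seq, ref_seq)))
  } else monomers$seq[1]
  structure(list(
    contig = region$contig,
    start = min(monomers$gstart), end = max(monomers$gend),
    strand = monomers$strand[1],
    monomers = monomers,
    unit_start = us, unit_end = ue, unit_length = unit_len,
    n_middle = n_middle, n_monomers = n,
    unit_consensus = unit_cons,
    family = consensus$family, sine = consensus$name),
    class = "ssat_locus")
}

#' @export
print.ssat_locus <- function(x, ...) {
  cat(sprintf("ssat_locus %s:%d-%d (%s) %d monomers (%d middle), unit %d-%d (%d nt)\n",
              x$contig, x$start, x$end, x$strand, x$n_monomers, x$n_middle,
              x$unit_start, x$unit_end, x$unit_length))
  invisible(x)
}

#' Run hit search, locus assembly and sSat calling on a genome
#'
#' Convenience driver: [find_sine_hits()] -> [merge_hits()] ->
#' [select_candidates()] -> [detect_tandem_units()] ->
#' [classify_monomers()] -> [call_ssat()].
#'
#' @inheritParams find_sine_hits
#' @param max_gap,min_candidate_len,min_middle_monomers Calling thresholds.
#' @param min_monomer_identity Monomer acceptance identity for tiling.
#' @return A list of `ssat_locus` objects.
#' @export
call_ssat_loci <- function(genome, consensus, min_cov_frac = 0.20,
                           max_gap = 100L, min_candidate_len = 500L,
                           min_middle_monomers = 4L,
                           min_monomer_identity = 60,
                           scoring = default_scoring()) {
  hits <- find_sine_hits(genome, consensus, min_cov_frac, scoring = scoring)
  call_from_hits(hits, genome, consensus, max_gap, min_candidate_len,
                 min_middle_monomers, min_monomer_identity, scoring)
}

# shared calling stage: merge -> select -> detect -> classify -> call,
# followed by stitching of called loci whose padded tilings touch
call_from_hits <- function(hits, genome, consensus, max_gap = 100L,
                           min_candidate_len = 500L, min_middle_monomers = 4L,
                           min_monomer_identity = 60,
                           scoring = default_scoring()) {
  regions <- select_candidates(merge_hits(hits, max_gap), min_candidate_len)
  call_one <- function(r) {
    mon <- detect_tandem_units(r, genome, consensus,
                               min_identity = min_monomer_identity,
                               max_gap = max_gap, scoring = scoring)
    if (!nrow(mon)) return(NULL)
    call_ssat(r, classify_monomers(mon), consensus,
              min_middle_monomers, max_gap)
  }
  loci <- Filter(Negate(is.null), lapply(regions, call_one))
  # a run of diverged monomers can break the hit chain and split one array
  # into two candidate regions; re-detect over the union when called loci
  # end up overlapping or within the merge gap of each other
  repeat {
    if (length(loci) < 2) break
    ord <- order(vapply(loci, function(l) l$contig, character(1)),
                 vapply(loci, function(l) l$start, numeric(1)))
    loci <- loci[ord]
    merged <- FALSE
    for (i in seq_len(length(loci) - 1L)) {
      a <- loci[[i]]; b <- loci[[i + 1L]]
      if (a$contig == b$contig && b$start < a$end + max_gap &&
          abs(a$unit_start - b$unit_start) <= 10) {
        region <- list(contig = a$contig, start = min(a$start, b$start),
                       end = max(a$end, b$end),
                       hits = data.frame(strand = c(a$strand, b$strand)))
        stitched <- call_one(region)
        if (!is.null(stitched)) {
          loci[[i]] <- stitched
          loci[[i + 1L]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  loci
}
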