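#' Mean pairwise identity of a set of monomer sequences
#'
#' Mean, over all unordered pairs, of global-alignment percent identity
#' (matches / alignment columns, gap columns counted as mismatches). This
#' is the "average sequence similarity of tandem repeat units" statistic.
#'
#' @param monomers Character vector of >= 2 sequences.
#' @param scoring Alignment scoring.
#' @return Mean identity in percent.
#' @export
mean_pairwise_identity <- function(monomers, scoring = default_scoring()) {
  if (length(monomers) < 2)
    stop("need at least two sequences", call. = FALSE)
  ids <- pairwise_identity_matrix(monomers, scoring)
  mean(ids[upper.tri(ids)])
}

# symmetric percent-identity matrix under global alignment
pairwise_identity_matrix <- function(seqs, scoring = default_scoring()) {
  n <- length(seqs)
  ids <- matrix(100, n, n)
  dna <- lapply(seqs, Biostrings::DNAString)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- Biostrings::pairwiseAlignment(
        dna[[i]], dna[[j]], type = "global",
        substitutionMatrix = scoring$matrix,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
      s <- alignment_summary(aln)
      ids[i, j] <- ids[j, i] <- s$identity
    }
  }
  ids
}

#' Cluster sSat loci into genome-wide variants
#'
#' Single-linkage clustering of locus unit consensuses: two loci are linked
#' when their unit identity reaches `identity_threshold` percent and their
#' unit-interval endpoints agree within `boundary_tolerance` nt. Variants
#' are ordered by member count (descending) and labeled 1, 2, 3, ...;
#' each variant's consensus is the majority consensus of its member units.
#'
#' @param loci List of `ssat_locus` objects.
#' @param identity_threshold Percent identity to join a cluster.
#' @param boundary_tolerance Maximum endpoint disagreement in nt.
#' @param scoring Alignment scoring.
#' @return A data.frame with `variant`, `unit_consensus`, `unit_start`,
#'   `unit_end`, `n_loci`, `fraction_of_loci`, and a `members` list-column
#'   of locus indices.
#' @export
cluster_variants <- function(loci, identity_threshold = 80,
                             boundary_tolerance = 10,
                             scoring = default_scoring()) {
  n <- length(loci)
  if (!n) return(data.frame(variant = integer(), unit_consensus = character(),
                            unit_start = integer(), unit_end = integer(),
                            n_loci = integer(), fraction_of_loci = numeric()))
  units <- vapply(loci, function(l) l$unit_consensus, character(1))
  us <- vapply(loci, function(l) l$unit_start, numeric(1))
  ue <- vapply(loci, function(l) l$unit_end, numeric(1))
  ids <- pairwise_identity_matrix(units, scoring)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    link[i, j] <- ids[i, j] >= identity_threshold &&
      abs(us[i] - us[j]) <= boundary_tolerance &&
      abs(ue[i] - ue[j]) <= boundary_tolerance
  }
  comp <- connected_components(link)
  sizes <- table(comp)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  out <- lapply(seq_along(ord), function(v) {
    members <- which(comp == as.integer(names(sizes))[ord[v]])
    useq <- units[members]
    cons <- if (length(useq) > 1) {
      ref <- useq[which.max(nchar(useq))]
      column_consensus(collapse_rows(star_align(useq, ref, scoring)))
    } else useq
    data.frame(variant = v, unit_consensus = cons,
               unit_start = mode_int(us[members], "min"),
               unit_end = mode_int(ue[members], "max"),
               n_loci = length(members),
               fraction_of_loci = length(members) / n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$members <- lapply(seq_along(ord), function(v)
    which(comp == as.integer(names(sizes))[ord[v]]))
  res
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Label locus-specific monomer subvariants
#'
#' Clusters the middle monomers of one locus into at most `k_max` subvariant
#' groups by single-linkage on pairwise global-alignment distance. The
#' number of groups is chosen by the largest merge-height gap; a split is
#' only accepted when that gap exceeds both `min_gap` and half the top merge
#' height, so homogeneous loci stay single-subvariant. Labels are reported
#' in array order, numbered by first appearance.
#'
#' @param locus An `ssat_locus`.
#' @param k_max Maximum number of subvariants (default 3).
#' @param min_gap Minimum absolute merge-height gap (distance units,
#'   1 = 100% divergent) for accepting a split.
#' @param scoring Alignment scoring.
#' @return A list with `labels` (integer vector over middle monomers in
#'   array order), `k`, and `heights` (the dendrogram merge heights).
#' @export
label_subvariants <- function(locus, k_max = 3L, min_gap = 0.02,
                              scoring = default_scoring()) {
  mid <- locus$monomers[locus$monomers$role == "middle", , drop = FALSE]
  m <- nrow(mid)
  if (m == 0) return(list(labels = integer(0), k = 0L, heights = numeric(0)))
  if (m == 1) return(list(labels = 1L, k = 1L, heights = numeric(0)))
  d <- 1 - pairwise_identity_matrix(mid$seq, scoring) / 100
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  h <- hc$height
  nh <- length(h)
  k <- 1L
  if (nh >= 2) {
    ks <- 2:min(k_max, m - 1)
    gaps <- vapply(ks, function(kk) h[nh - kk + 2] - h[nh - kk + 1], numeric(1))
    best <- which.max(gaps)
    # accept a split only when the gap dominates both the absolute floor and
    # the largest within-group merge height below the cut
    if (gaps[best] > max(min_gap, h[nh - ks[best] + 1])) k <- ks[best]
  }
  raw <- if (k == 1) rep(1L, m) else stats::cutree(hc, k = k)
  # renumber by first appearance along the array
  labels <- match(raw, unique(raw))
  list(labels = as.integer(labels), k = as.integer(k), heights = h)
}

#' Permutation test for subvariant alternation
#'
#' Observed statistic: the number of adjacent monomer pairs with different
#' subvariant labels. The null distribution is generated by random
#' permutations of the label multiset; the returned one-sided p-value (with
#' add-one correction, `(b + 1) / (n_perm + 1)`) measures alternation
#' excess.
#'
#' @param labels Integer/character label sequence along the array.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return The p-value.
#' @export
alternation_test <- function(labels, n_perm = 10000L, seed = 1L) {
  n <- length(labels)
  if (n < 2) return(1)
  stat <- function(x) sum(x[-1] != x[-length(x)])
  obs <- stat(labels)
  with_seed(seed, {
    b <- sum(vapply(seq_len(n_perm),
                    function(i) stat(sample(labels)) >= obs, logical(1)))
    (b + 1) / (n_perm + 1)
  })
}

#' Genome-wide sSat summary
#'
#' Counts sSat loci per family, binned by middle-monomer number into the
#' standard size classes 4-5, 6-8, and >= 9, alongside the total SINE hit
#' count and genome size.
#'
#' @param loci List of `ssat_locus` objects.
#' @param sine_hits Hit data.frame (e.g. full-length-filtered).
#' @param genome The genome (for its size).
#' @return A data.frame with one row per family.
#' @export
summarize_genome <- function(loci, sine_hits = empty_hits(), genome = NULL) {
  gsize <- if (is.null(genome)) NA_integer_ else sum(nchar(genome_seqs(genome)))
  fams <- unique(vapply(loci, function(l) l$family, character(1)))
  if (!length(loci)) {
    return(data.frame(family = character(), n_loci = integer(),
                      n_4_5 = integer(), n_6_8 = integer(), n_9_plus = integer(),
                      n_sine_hits = integer(), genome_size = integer()))
  }
  out <- lapply(fams, function(f) {
    nm <- vapply(Filter(function(l) l$family == f, loci),
                 function(l) l$n_middle, numeric(1))
    data.frame(family = f, n_loci = length(nm),
               n_4_5 = sum(nm >= 4 & nm <= 5),
               n_6_8 = sum(nm >= 6 & nm <= 8),
               n_9_plus = sum(nm >= 9),
               n_sine_hits = nrow(sine_hits),
               genome_size = gsize, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Measure a microsatellite run inside SINE copies
#'
#' For each copy, maps the consensus `anchor` position into copy coordinates
#' by local alignment and measures the maximal uninterrupted run of `motif`
#' starting at (or within a few bases of) the mapped anchor, in repeat
#' units. Copies in which the anchor does not align, or that lack the
#' motif there, score 0.
#'
#' @param sine_copies Character vector of copy sequences.
#' @param consensus The [sine_consensus()].
#' @param motif Microsatellite motif (default `"TC"`).
#' @param anchor 1-based consensus position where the run begins.
#' @param slack Allowed start offset in bases around the mapped anchor.
#' @param scoring Alignment scoring.
#' @return Integer vector of per-copy run lengths in motif units.
#' @export
scan_internal_microsat <- function(sine_copies, consensus, motif = "TC",
                                   anchor = 110, slack = 3L,
                                   scoring = default_scoring()) {
  w <- nchar(motif)
  vapply(sine_copies, function(cp) {
    a <- local_align(cp, consensus$sequence, scoring)
    if (anchor < a$target_start || anchor > a$target_end) return(0L)
    # walk the alignment to map the consensus anchor into copy coordinates
    p <- map_position(cp, consensus$sequence, anchor, scoring)
    if (is.na(p)) return(0L)
    best <- 0L
    for (off in -slack:slack) {
      q <- p + off
      if (q < 1 || q + w - 1 > nchar(cp)) next
      runs <- 0L
      while (q + w - 1 <= nchar(cp) && substr(cp, q, q + w - 1) == motif) {
        runs <- runs + 1L
        q <- q + w
      }
      best <- max(best, runs)
    }
    best
  }, integer(1), USE.NAMES = FALSE)
}

# map a 1-based consensus position into copy coordinates via local alignment
map_position <- function(copy, consensus_seq, pos, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(copy), Biostrings::DNAString(consensus_seq),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  cpos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  ppos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  for (k in seq_along(s)) {
    if (p[k] != "-") ppos <- ppos + 1L
    if (s[k] != "-") {
      cpos <- cpos + 1L
      if (cpos == pos) return(if (p[k] == "-") NA_integer_ else ppos)
    }
  }
  NA_integer_
}

#' Canonical form of a microsatellite motif
#'
#' The representative of a motif's equivalence class under rotation and
#' reverse complement: the primitive root of the motif is taken first (so
#' `"AAAA"` reduces to `"A"`), then the lexicographically smallest string
#' over all rotations of the root and of its reverse complement. Rotated,
#' complemented annotations of the same microsatellite (e.g. `(ATGGA)n`,
#' `(TGGAA)n`, `(TCCAT)n`) thereby collapse to one canonical motif.
#'
#' @param motif A short motif over ACGT.
#' @return The canonical motif string.
#' @examples
#' canonical_motif("ATGGA") == canonical_motif("GGAAT")  # TRUE
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif))
    stop("motif must be a non-empty string over ACGT", call. = FALSE)
  root <- primitive_root(motif)
  rc <- revcomp(root)
  min(c(rotations(root), rotations(rc)))
}

rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n), function(i)
    paste0(substr(x, i, n), substr(x, 1, i - 1)), character(1))
}

primitive_root <- function(x) {
  n <- nchar(x)
  for (p in seq_len(n)) {
    if (n %% p == 0 && strvrep(substr(x, 1, p), n / p) == x)
      return(substr(x, 1, p))
  }
  x
}
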