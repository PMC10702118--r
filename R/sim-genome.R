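#' Sequence mutation model
#'
#' Per-site independent substitution/indel model used by the simulator to
#' emulate the divergence of real SINE copies and satellite monomers.
#' Substitutions pick uniformly among the three alternative bases (a
#' Jukes-Cantor-like scheme, so a substituted site never keeps its base and
#' the expected identity of a substitution-only mutant to its source is
#' exactly `1 - substitution_rate`). Indel lengths are geometric with mean
#' `indel_length_mean`; inserted bases are uniform random.
#'
#' @param substitution_rate,insertion_rate,deletion_rate Per-site
#'   probabilities, each in `[0, 1)`; their sum must be < 1.
#' @param indel_length_mean Expected indel length (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(substitution_rate = 0, insertion_rate = 0,
                           deletion_rate = 0, indel_length_mean = 1.5,
                           seed = 1L) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1)
    stop("rates must be in [0,1) and sum to < 1", call. = FALSE)
  if (indel_length_mean < 1)
    stop("indel_length_mean must be >= 1", call. = FALSE)
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 indel_length_mean = indel_length_mean,
                 seed = seed),
            class = "mutation_model")
}

#' Generate an i.i.d. random background sequence
#'
#' @param length Sequence length (> 0).
#' @param gc_fraction Probability that a site is G or C (0 < gc < 1).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return A character string of the requested length.
#' @export
generate_background <- function(length, gc_fraction = 0.42, seed = 1L) {
  if (length(length) != 1L || !is.numeric(length) || is.na(length) || length <= 0)
    stop("`length` must be a positive integer", call. = FALSE)
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("`gc_fraction` must be in (0, 1)", call. = FALSE)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
                        collapse = ""))
}

# geometric length with mean m (support >= 1)
rgeom1 <- function(n, mean_len) 1L + rgeom(n, prob = 1 / mean_len)

#' Mutate a sequence under a mutation model
#'
#' Each site is independently hit by a substitution, an insertion (random
#' bases inserted after the site), or a deletion of geometric length
#' starting at the site, per the model's rates. Deterministic under the
#' model's seed.
#'
#' @param seq Non-empty character string.
#' @param model A [mutation_model()].
#' @return The mutated sequence (possibly empty if deletion rate is extreme).
#' @export
mutate_seq <- function(seq, model) {
  stopifnot(inherits(model, "mutation_model"))
  if (!nzchar(seq)) stop("`seq` must be non-empty", call. = FALSE)
  with_seed(model$seed, mutate_impl(seq, model))
}

# mutation under the *current* RNG stream (used by the planters, which
# manage their own seeds)
mutate_impl <- function(seq, model) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  u <- runif(n)
  ps <- model$substitution_rate
  pi <- model$insertion_rate
  pd <- model$deletion_rate
  sub_idx <- which(u < ps)
  ins_idx <- which(u >= ps & u < ps + pi)
  del_idx <- which(u >= ps + pi & u < ps + pi + pd)
  if (length(sub_idx)) {
    # uniform choice among the 3 alternative bases
    alt <- vapply(x[sub_idx], function(b) {
      cand <- DNA_BASES[DNA_BASES != b]
      if (length(cand) == 3L) sample(cand, 1L) else sample(DNA_BASES, 1L)
    }, character(1))
    x[sub_idx] <- alt
  }
  drop <- rep(FALSE, n)
  if (length(del_idx)) {
    lens <- rgeom1(length(del_idx), model$indel_length_mean)
    for (k in seq_along(del_idx)) {
      i <- del_idx[k]
      drop[i:min(n, i + lens[k] - 1L)] <- TRUE
    }
  }
  ins <- character(n)
  if (length(ins_idx)) {
    lens <- rgeom1(length(ins_idx), model$indel_length_mean)
    for (k in seq_along(ins_idx)) {
      ins[ins_idx[k]] <- paste(sample(DNA_BASES, lens[k], replace = TRUE),
                               collapse = "")
    }
  }
  keep <- !drop
  pieces <- paste0(ifelse(keep, x, ""), ins)
  paste(pieces, collapse = "")
}

## ---- genome container ------------------------------------------------------

new_sim_genome <- function(seqs, truth = empty_truth()) {
  structure(list(seqs = seqs, truth = truth), class = "sim_genome")
}

empty_truth <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             kind = character(), strand = character(), name = character(),
             n_monomers = integer(), breakpoints = character(),
             params = character(), stringsAsFactors = FALSE)
}

truth_row <- function(contig, start, end, kind, strand = "+", name = kind,
                      n_monomers = NA_integer_, breakpoints = NA_character_,
                      params = "") {
  data.frame(contig = contig, start = as.integer(start), end = as.integer(end),
             kind = kind, strand = strand, name = name,
             n_monomers = as.integer(n_monomers), breakpoints = breakpoints,
             params = params, stringsAsFactors = FALSE)
}

#' Create a simulated genome container
#'
#' @param seqs Named character vector of contig sequences, or a single
#'   unnamed string (named `"contig1"`).
#' @return A `sim_genome` object holding sequences and a ground-truth table
#'   of planted features (0-based half-open genome coordinates).
#' @export
sim_genome <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("contig", seq_along(seqs))
  new_sim_genome(seqs)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$seqs), "contig(s),",
      sum(nchar(x$seqs)), "bp,", nrow(x$truth), "planted feature(s)\n")
  if (nrow(x$truth)) print(table(x$truth$kind))
  invisible(x)
}

# sample a non-overlapping placement interval [start, start+len) on `contig`,
# rejecting overlaps with `occupied` (IRanges); bounded retries
sample_placement <- function(contig_len, len, occupied, max_tries = 1000L) {
  if (contig_len < len) stop("feature longer than contig", call. = FALSE)
  for (t in seq_len(max_tries)) {
    start0 <- floor(runif(1, 0, contig_len - len + 1))  # 0-based
    cand <- IRanges::IRanges(start0 + 1L, start0 + len)
    if (length(occupied) == 0L ||
        !any(IRanges::overlapsAny(cand, occupied))) return(start0)
  }
  stop("could not place feature without overlap after ", max_tries,
       " retries", call. = FALSE)
}

occupied_ranges <- function(genome, contig) {
  tr <- genome$truth[genome$truth$contig == contig, , drop = FALSE]
  if (!nrow(tr)) return(IRanges::IRanges())
  IRanges::IRanges(tr$start + 1L, tr$end)
}

# replace genome bases [start0, start0+len) with `feature` (equal length)
splice_replace <- function(seq, start0, feature) {
  stopifnot(start0 + nchar(feature) <= nchar(seq))
  paste0(substr(seq, 1, start0), feature,
         substr(seq, start0 + nchar(feature) + 1, nchar(seq)))
}

## ---- planters --------------------------------------------------------------

#' Plant diverged SINE copies into a genome
#'
#' Inserts `n` copies of the consensus at uniform random non-overlapping
#' positions (features replace background of equal length so coordinates of
#' previously planted features are preserved). Each copy is independently
#' 5'-truncated, mutated, given a simple-repeat tail, and placed on a
#' uniformly random strand.
#'
#' @param genome A [sim_genome()].
#' @param consensus A [sine_consensus()].
#' @param n Number of copies.
#' @param model A [mutation_model()]; its seed drives all randomness here.
#' @param truncation_5p_dist Function `n -> integer vector` of 5' truncation
#'   lengths (bases removed from the consensus 5' end). Default: none.
#' @param tail_motif Simple-repeat tail motif (e.g. `"A"`, `"CTT"`).
#' @param tail_len_dist Function `n -> integer vector` of tail lengths in
#'   motif units. Default: none.
#' @param contig Contig to plant into (default first).
#' @return The genome with `n` new `sine_copy` truth records.
#' @export
plant_sine_copies <- function(genome, consensus, n, model,
                              truncation_5p_dist = function(n) rep(0L, n),
                              tail_motif = "A",
                              tail_len_dist = function(n) rep(0L, n),
                              contig = names(genome$seqs)[1]) {
  stopifnot(inherits(genome, "sim_genome"), inherits(consensus, "sine_consensus"))
  assert_scalar_int(n, "n", min = 1)
  with_seed(model$seed, {
    trunc <- truncation_5p_dist(n)
    tails <- tail_len_dist(n)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    for (i in seq_len(n)) {
      cs <- consensus$sequence
      if (trunc[i] > 0) cs <- substr(cs, trunc[i] + 1L, nchar(cs))
      cs <- mutate_impl(cs, model)
      if (tails[i] > 0)
        cs <- paste0(cs, strvrep(tail_motif, tails[i]))
      if (strands[i] == "-") cs <- revcomp(cs)
      occ <- occupied_ranges(genome, contig)
      start0 <- sample_placement(nchar(genome$seqs[[contig]]), nchar(cs), occ)
      genome$seqs[[contig]] <- splice_replace(genome$seqs[[contig]], start0, cs)
      genome$truth <- rbind(genome$truth, truth_row(
        contig, start0, start0 + nchar(cs), "sine_copy", strands[i],
        name = paste0(consensus$name, "_copy", i),
        params = jsonlite::toJSON(list(truncation_5p = trunc[i],
                                       tail_len = tails[i],
                                       substitution_rate = model$substitution_rate),
                                  auto_unbox = TRUE)))
    }
    genome
  })
}

strvrep <- function(motif, n_units) paste(rep(motif, n_units), collapse = "")

#' Specification of a planted tandem array
#'
#' An sSat array is built as: leading monomer (the repeat unit plus
#' `leading_extension` extra consensus bases toward the SINE 5' terminus),
#' `n_monomers - 2` middle monomers (the bare unit), and a trailing monomer
#' (unit plus `trailing_extension` bases toward the 3' terminus) - the
#' longer-terminal-monomer architecture characteristic of SINE-derived
#' satellites. Units must be shorter than the SINE consensus.
#'
#' @param unit_start,unit_end 1-based inclusive consensus coordinates of the
#'   repeat unit.
#' @param n_monomers Total monomer count (>= 2).
#' @param model Per-monomer [mutation_model()].
#' @param leading_extension,trailing_extension Extra consensus bases carried
#'   by the terminal monomers toward the 5'/3' SINE terminus (>= 0, bounded
#'   by the remaining consensus span).
#' @param homogeneity_mode `"independent"`: each monomer diverges from the
#'   unit independently; `"serial"`: each monomer is a mutated copy of its
#'   predecessor (older, less homogenized arrays).
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(unit_start, unit_end, n_monomers, model,
                       leading_extension = 0L, trailing_extension = 0L,
                       homogeneity_mode = c("independent", "serial")) {
  homogeneity_mode <- match.arg(homogeneity_mode)
  assert_scalar_int(n_monomers, "n_monomers", min = 2)
  stopifnot(unit_start >= 1, unit_end >= unit_start,
            leading_extension >= 0, trailing_extension >= 0)
  structure(list(unit_start = as.integer(unit_start),
                 unit_end = as.integer(unit_end),
                 n_monomers = as.integer(n_monomers),
                 model = model,
                 leading_extension = as.integer(leading_extension),
                 trailing_extension = as.integer(trailing_extension),
                 homogeneity_mode = homogeneity_mode),
            class = "array_spec")
}

# construct the array sequence + relative breakpoints under current RNG
build_array <- function(consensus, spec) {
  L <- nchar(consensus$sequence)
  if (spec$unit_end > L)
    stop("unit interval outside consensus", call. = FALSE)
  unit_len <- spec$unit_end - spec$unit_start + 1L
  if (unit_len >= L)
    stop("repeat unit must be shorter than the SINE consensus", call. = FALSE)
  if (spec$unit_start - spec$leading_extension < 1 ||
      spec$unit_end + spec$trailing_extension > L)
    stop("terminal extension exceeds remaining consensus span", call. = FALSE)
  unit <- substr(consensus$sequence, spec$unit_start, spec$unit_end)
  lead <- substr(consensus$sequence,
                 spec$unit_start - spec$leading_extension, spec$unit_end)
  trail <- substr(consensus$sequence, spec$unit_start,
                  spec$unit_end + spec$trailing_extension)
  n <- spec$n_monomers
  sources <- c(lead, rep(unit, max(0L, n - 2L)), if (n >= 2) trail)
  monomers <- character(n)
  prev <- NULL
  for (i in seq_len(n)) {
    src <- if (spec$homogeneity_mode == "serial" && i > 1 && i < n) {
      # serial mode: middle monomers copy their predecessor's unit part
      if (is.null(prev)) sources[i] else prev
    } else sources[i]
    m <- mutate_impl(src, spec$model)
    monomers[i] <- m
    if (i >= 2 && i < n) prev <- m
  }
  lens <- nchar(monomers)
  list(seq = paste(monomers, collapse = ""),
       breakpoints = cumsum(c(0L, lens)))  # relative, length n+1
}

#' Plant a tandem sSat array
#'
#' @inheritParams plant_sine_copies
#' @param spec An [array_spec()].
#' @param at Optional 0-based start position; default uniform random
#'   non-overlapping placement.
#' @return The genome with one `ssat_array` truth record carrying monomer
#'   breakpoints (genome coordinates, `n_monomers + 1` values).
#' @export
plant_ssat_array <- function(genome, consensus, spec,
                             contig = names(genome$seqs)[1], at = NULL) {
  stopifnot(inherits(genome, "sim_genome"), inherits(spec, "array_spec"))
  with_seed(spec$model$seed, {
    arr <- build_array(consensus, spec)
    len <- nchar(arr$seq)
    start0 <- if (is.null(at)) {
      sample_placement(nchar(genome$seqs[[contig]]), len,
                       occupied_ranges(genome, contig))
    } else at
    genome$seqs[[contig]] <- splice_replace(genome$seqs[[contig]], start0, arr$seq)
    genome$truth <- rbind(genome$truth, truth_row(
      contig, start0, start0 + len, "ssat_array", "+",
      name = paste0(consensus$name, "_array"),
      n_monomers = spec$n_monomers,
      breakpoints = paste(start0 + arr$breakpoints, collapse = ","),
      params = jsonlite::toJSON(list(
        unit_start = spec$unit_start, unit_end = spec$unit_end,
        n_monomers = spec$n_monomers,
        leading_extension = spec$leading_extension,
        trailing_extension = spec$trailing_extension,
        substitution_rate = spec$model$substitution_rate,
        homogeneity_mode = spec$homogeneity_mode), auto_unbox = TRUE)))
    genome
  })
}

#' Plant an exact tandem motif tract
#'
#' Used for telomeric `(TTAGGG)n` tracts at contig ends and internal
#' microsatellite / centromeric-satellite blocks.
#'
#' @inheritParams plant_sine_copies
#' @param motif Short motif.
#' @param n_repeats Number of exact tandem units (> 0).
#' @param location `"end5"`, `"end3"`, or `"internal"` (uniform random
#'   internal placement requires a `seed`).
#' @param kind Truth kind: `"telomere_tract"`, `"microsat_tract"` or
#'   `"centromeric_block"`.
#' @param seed Seed for internal placement.
#' @param at Optional explicit 0-based start (overrides `location`).
#' @return The genome with one truth record.
#' @export
plant_motif_tract <- function(genome, motif, n_repeats,
                              location = c("internal", "end5", "end3"),
                              kind = "microsat_tract",
                              contig = names(genome$seqs)[1],
                              seed = 1L, at = NULL) {
  location <- match.arg(location)
  stopifnot(inherits(genome, "sim_genome"), nzchar(motif))
  assert_scalar_int(n_repeats, "n_repeats", min = 1)
  tract <- strvrep(motif, n_repeats)
  len <- nchar(tract)
  clen <- nchar(genome$seqs[[contig]])
  start0 <- if (!is.null(at)) at
    else switch(location,
      end5 = 0L,
      end3 = clen - len,
      internal = with_seed(seed, sample_placement(
        clen, len, occupied_ranges(genome, contig))))
  genome$seqs[[contig]] <- splice_replace(genome$seqs[[contig]], start0, tract)
  genome$truth <- rbind(genome$truth, truth_row(
    names(genome$seqs[contig]), start0, start0 + len, kind, "+",
    name = paste0("(", motif, ")", n_repeats),
    n_monomers = n_repeats,
    params = jsonlite::toJSON(list(motif = motif, n_repeats = n_repeats),
                              auto_unbox = TRUE)))
  genome
}

#' Generate a pair of genomes with orthologous sSat arrays
#'
#' Builds two genomes with an identical flank layout: shared background
#' segments alternate with tandem arrays planted from `consensus`. Each
#' array's monomer count in genome B equals its count in genome A plus a
#' draw from `jitter` (floored at 1 monomer). Both genomes are then
#' independently mutated at `model`'s rates.
#'
#' @param consensus A [sine_consensus()].
#' @param n_arrays Number of orthologous arrays.
#' @param unit_start,unit_end Repeat unit on the consensus (1-based).
#' @param count_dist Function `n -> integer vector` of genome-A monomer
#'   counts (default uniform 4..10).
#' @param jitter Function `n -> integer vector` of signed count differences.
#' @param model A [mutation_model()] applied independently to each genome
#'   (genome-wide divergence between the assemblies).
#' @param spacer_len Background separation between consecutive arrays.
#' @param seedA,seedB Seeds for the two genomes' independent mutation.
#' @param seed Seed for the shared layout.
#' @return List with `genomeA`, `genomeB` (both [sim_genome()]) and `pairs`,
#'   a data.frame linking the arrays with their true count difference.
#' @export
generate_ortholog_pair <- function(consensus, n_arrays,
                                   unit_start, unit_end,
                                   count_dist = function(n) sample(4:10, n, replace = TRUE),
                                   jitter = function(n) rep(0L, n),
                                   model = mutation_model(),
                                   spacer_len = 1500L,
                                   seedA = 11L, seedB = 12L, seed = 10L) {
  stopifnot(inherits(consensus, "sine_consensus"))
  assert_scalar_int(n_arrays, "n_arrays", min = 1)
  layout <- with_seed(seed, {
    countsA <- pmax(2L, as.integer(count_dist(n_arrays)))
    deltas <- as.integer(jitter(n_arrays))
    countsB <- pmax(1L, countsA + deltas)
    spacers <- vapply(seq_len(n_arrays + 1L), function(i)
      paste(sample(DNA_BASES, spacer_len, replace = TRUE), collapse = ""),
      character(1))
    arr_seeds <- vapply(seq_len(n_arrays), function(i) child_seed(seed, i),
                        numeric(1))
    list(countsA = countsA, countsB = countsB, deltas = countsB - countsA,
         spacers = spacers, arr_seeds = arr_seeds)
  })
  build_one <- function(counts, tag) {
    seqs <- character(0)
    truth <- empty_truth()
    pos <- 0L
    pieces <- character(0)
    for (i in seq_len(n_arrays)) {
      pieces <- c(pieces, layout$spacers[i])
      pos <- pos + nchar(layout$spacers[i])
      arr <- with_seed(layout$arr_seeds[i], {
        if (counts[i] == 1L) {
          # floored single-monomer locus: one bare unit copy
          m <- mutate_impl(substr(consensus$sequence, unit_start, unit_end),
                           mutation_model(seed = 1L))
          list(seq = m, breakpoints = c(0L, nchar(m)))
        } else {
          build_array(consensus, array_spec(unit_start, unit_end, counts[i],
                                            mutation_model(seed = 1L)))
        }
      })
      pieces <- c(pieces, arr$seq)
      truth <- rbind(truth, truth_row(
        "contig1", pos, pos + nchar(arr$seq), "ssat_array", "+",
        name = paste0("ortho_array", i), n_monomers = counts[i],
        breakpoints = paste(pos + arr$breakpoints, collapse = ","),
        params = ""))
      pos <- pos + nchar(arr$seq)
    }
    pieces <- c(pieces, layout$spacers[n_arrays + 1L])
    g <- new_sim_genome(c(contig1 = paste(pieces, collapse = "")), truth)
    g
  }
  gA <- build_one(layout$countsA, "A")
  gB <- build_one(layout$countsB, "B")
  # independent genome-wide mutation; truth coordinates only remain exact
  # when the model introduces no indels
  if (model$substitution_rate + model$insertion_rate + model$deletion_rate > 0) {
    gA$seqs[[1]] <- with_seed(seedA, mutate_impl(gA$seqs[[1]], model))
    gB$seqs[[1]] <- with_seed(seedB, mutate_impl(gB$seqs[[1]], model))
  }
  pairs <- data.frame(
    name = paste0("ortho_array", seq_len(n_arrays)),
    startA = gA$truth$start, endA = gA$truth$end,
    startB = gB$truth$start, endB = gB$truth$end,
    n_monomers_A = layout$countsA, n_monomers_B = layout$countsB,
    delta = layout$deltas, stringsAsFactors = FALSE)
  list(genomeA = gA, genomeB = gB, pairs = pairs)
}

#' Simulate a full study-condition genome
#'
#' Builds a background genome and plants tandem sSat arrays, solo diverged
#' SINE copies, and (optionally) telomeric tracts, mirroring the repeat
#' landscape the pipeline is designed for.
#'
#' @param genome_len Background length in bp.
#' @param consensus A [sine_consensus()].
#' @param n_arrays,n_sines Numbers of planted arrays / solo copies.
#' @param unit_start,unit_end Repeat unit on the consensus.
#' @param monomer_range Inclusive range from which array monomer counts are
#'   drawn uniformly.
#' @param max_array_divergence Array per-monomer substitution rates are drawn
#'   uniformly on `[0, max_array_divergence]`.
#' @param sine_divergence_range Solo-copy substitution rates drawn uniformly
#'   on this range.
#' @param telomeres If `TRUE`, plant `(TTAGGG)` tracts at both contig ends.
#' @param telomere_repeats Units per telomeric tract.
#' @param seed Master seed.
#' @return A [sim_genome()] with truth records for every planted feature.
#' @export
simulate_ssat_genome <- function(genome_len = 5e6, consensus,
                                 n_arrays = 30, n_sines = 200,
                                 unit_start = 42, unit_end = 108,
                                 monomer_range = c(4, 50),
                                 max_array_divergence = 0.10,
                                 sine_divergence_range = c(0.05, 0.15),
                                 telomeres = FALSE, telomere_repeats = 1000,
                                 seed = 1L) {
  g <- sim_genome(setNames(generate_background(genome_len, 0.42, seed), "contig1"))
  if (telomeres) {
    g <- plant_motif_tract(g, "TTAGGG", telomere_repeats, location = "end5",
                           kind = "telomere_tract")
    g <- plant_motif_tract(g, "CCCTAA", telomere_repeats, location = "end3",
                           kind = "telomere_tract")
  }
  params <- with_seed(child_seed(seed, 1), list(
    n_mono = sample(monomer_range[1]:monomer_range[2], n_arrays, replace = TRUE),
    arr_div = runif(n_arrays, 0, max_array_divergence),
    lead_ext = sample(0:20, n_arrays, replace = TRUE),
    trail_ext = sample(0:20, n_arrays, replace = TRUE),
    sine_div = runif(n_sines, sine_divergence_range[1], sine_divergence_range[2])))
  for (i in seq_len(n_arrays)) {
    sp <- array_spec(unit_start, unit_end, params$n_mono[i],
                     mutation_model(substitution_rate = params$arr_div[i],
                                    seed = child_seed(seed, 100 + i)),
                     leading_extension = params$lead_ext[i],
                     trailing_extension = params$trail_ext[i])
    g <- plant_ssat_array(g, consensus, sp)
  }
  for (i in seq_len(n_sines)) {
    g <- plant_sine_copies(
      g, consensus, 1,
      mutation_model(substitution_rate = params$sine_div[i],
                     seed = child_seed(seed, 10000 + i)),
      truncation_5p_dist = function(n) pmin(rgeom(n, 0.05),
                                            nchar(consensus$sequence) %/% 2),
      tail_motif = "A", tail_len_dist = function(n) rgeom1(n, 8))
  }
  g
}
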