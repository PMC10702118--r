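#' Read a genome FASTA
#'
#' Sequences are uppercase-normalized, record order is preserved, and N /
#' IUPAC codes pass through. A record with an empty sequence (header-only)
#' is a parse error naming the record.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(ss) == 0))
    stop("header-only FASTA record: ",
         paste(names(ss)[Biostrings::width(ss) == 0], collapse = ", "),
         call. = FALSE)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genome FASTA
#'
#' @param seqs Named character vector or a [sim_genome()].
#' @param path Output path; sequence lines wrapped at 60 columns.
#' @export
write_genome_fasta <- function(seqs, path) {
  seqs <- genome_seqs(seqs)
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Write features as BED
#'
#' 0-based half-open, tab-separated, sorted by contig then start. BED6
#' columns: contig, start, end, name, score, strand. For BED12 the
#' `blocks` list-column (data.frames with 0-based half-open `start`/`end`
#' in genome coordinates) supplies the block structure.
#'
#' @param features Data.frame with at least `contig`, `start`, `end`;
#'   optional `name`, `score`, `strand`, and `blocks` for BED12.
#' @param path Output path.
#' @param dialect `"BED6"` or `"BED12"`.
#' @export
write_bed <- function(features, path, dialect = c("BED6", "BED12")) {
  dialect <- match.arg(dialect)
  f <- features[order(features$contig, features$start), , drop = FALSE]
  nm <- if ("name" %in% names(f)) f$name else paste0("feature", seq_len(nrow(f)))
  sc <- if ("score" %in% names(f)) f$score else 0
  st <- if ("strand" %in% names(f)) f$strand else "."
  base <- data.frame(f$contig, f$start, f$end, nm, sc, st)
  if (dialect == "BED12") {
    stopifnot("blocks" %in% names(f))
    b12 <- t(vapply(seq_len(nrow(f)), function(i) {
      bl <- f$blocks[[i]]
      bl <- bl[order(bl$start), , drop = FALSE]
      c(paste0(f$start[i]), paste0(f$end[i]), nrow(bl),
        paste(bl$end - bl$start, collapse = ","),
        paste(bl$start - f$start[i], collapse = ","))
    }, character(5)))
    base <- cbind(base, f$start, f$end, "0,0,0",
                  b12[, 3], b12[, 4], b12[, 5])
  }
  write_atomic(path, function(tmp)
    write.table(base, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE))
  invisible(path)
}

#' Read a BED file
#'
#' @param path Path to a BED6 or BED12 file.
#' @return A data.frame with `contig`, `start`, `end`, `name`, `score`,
#'   `strand`, and for BED12 a `blocks` list-column of reconstructed
#'   genome-coordinate block intervals.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(contig = x[[1]], start = x[[2]], end = x[[3]],
                    name = if (ncol(x) >= 4) x[[4]] else NA,
                    score = if (ncol(x) >= 5) x[[5]] else 0,
                    strand = if (ncol(x) >= 6) x[[6]] else ".",
                    stringsAsFactors = FALSE)
  if (ncol(x) >= 12) {
    out$blocks <- lapply(seq_len(nrow(x)), function(i) {
      sizes <- as.integer(strsplit(as.character(x[[11]][i]), ",")[[1]])
      starts <- as.integer(strsplit(as.character(x[[12]][i]), ",")[[1]])
      data.frame(start = out$start[i] + starts,
                 end = out$start[i] + starts + sizes)
    })
  }
  out
}

write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
}

#' Export sSat loci as a BED12-ready data.frame
#'
#' @param loci List of `ssat_locus` objects.
#' @return Data.frame with one row per locus, monomers as `blocks`.
#' @export
loci_to_bed <- function(loci) {
  if (!length(loci))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character()))
  out <- data.frame(
    contig = vapply(loci, function(l) l$contig, character(1)),
    start = vapply(loci, function(l) l$start, numeric(1)),
    end = vapply(loci, function(l) l$end, numeric(1)),
    name = vapply(loci, function(l)
      sprintf("sSat_%s_%d", l$sine, l$n_middle), character(1)),
    score = vapply(loci, function(l) l$n_monomers, numeric(1)),
    strand = vapply(loci, function(l) l$strand, character(1)),
    stringsAsFactors = FALSE)
  out$blocks <- lapply(loci, function(l)
    data.frame(start = l$monomers$gstart, end = l$monomers$gend))
  out
}

#' Per-locus summary table
#'
#' @param loci List of `ssat_locus` objects.
#' @return Data.frame mirroring the per-locus report columns.
#' @export
loci_table <- function(loci) {
  if (!length(loci))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_monomers = integer(), n_middle = integer(),
                      unit_start = integer(), unit_end = integer(),
                      unit_length = integer()))
  data.frame(
    contig = vapply(loci, function(l) l$contig, character(1)),
    start = vapply(loci, function(l) l$start, numeric(1)),
    end = vapply(loci, function(l) l$end, numeric(1)),
    strand = vapply(loci, function(l) l$strand, character(1)),
    n_monomers = vapply(loci, function(l) l$n_monomers, numeric(1)),
    n_middle = vapply(loci, function(l) l$n_middle, numeric(1)),
    unit_start = vapply(loci, function(l) l$unit_start, numeric(1)),
    unit_end = vapply(loci, function(l) l$unit_end, numeric(1)),
    unit_length = vapply(loci, function(l) l$unit_length, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Write the simulator ground truth
#'
#' BED6 with a TSV parameter sidecar.
#'
#' @param genome A [sim_genome()].
#' @param bed_path,tsv_path Output paths.
#' @export
write_truth <- function(genome, bed_path, tsv_path) {
  tr <- genome$truth
  write_bed(data.frame(contig = tr$contig, start = tr$start, end = tr$end,
                       name = paste(tr$kind, tr$name, sep = "|"),
                       score = 0, strand = tr$strand), bed_path)
  write_atomic(tsv_path, function(tmp)
    write.table(tr, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(genome)
}

#' Pipeline configuration
#'
#' All thresholds exposed by the pipeline stages with their defaults:
#' `min_cov_frac` 0.20 (fragment search coverage), `max_gap` 100 (strict
#' merge / adjacency gap), `min_candidate_len` 500 (strict candidate
#' length), `min_len_frac` 0.90 and `min_identity` 65 (strict full-length
#' filter), `min_middle_monomers` 4 (sSat call), plus alignment, orthology
#' and chromosomal-profiling settings.
#'
#' @param ... Overrides of the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_cov_frac = 0.20, min_len_frac = 0.90, min_identity = 65,
    min_hit_identity = 60, max_gap = 100L, min_candidate_len = 500L,
    min_middle_monomers = 4L, min_monomer_identity = 60,
    flank_len = 500L, min_flank_identity = 80, max_span = 100000L,
    telomere_min_repeats = 1000L, n_perm = 10000L, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (cfg$min_middle_monomers < 1)
    stop("min_middle_monomers must be >= 1", call. = FALSE)
  if (cfg$min_cov_frac <= 0 || cfg$min_cov_frac > 1)
    stop("min_cov_frac must be in (0, 1]", call. = FALSE)
  if (cfg$max_gap < 1 || cfg$min_candidate_len < 1)
    stop("gap/length thresholds must be positive", call. = FALSE)
  invisible(cfg)
}

#' Save / load a pipeline configuration
#'
#' Configurations round-trip losslessly through JSON.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  write_atomic(path, function(tmp)
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the full discovery pipeline
#'
#' search -> merge -> candidate selection -> tandem calling -> profiling,
#' writing a report bundle (hits TSV, candidate BED6, sSat BED12, per-locus
#' TSV, genome summary TSV, and a JSON run manifest with the configuration
#' and feature counts). Output files are written atomically; a stage
#' failure aborts with the stage name and removes partial outputs.
#'
#' @param genome Genome (path to FASTA, named character vector, or
#'   [sim_genome()]).
#' @param consensus A [sine_consensus()].
#' @param outdir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `hits`, `candidates`, `loci`, `summary`
#'   and the output paths.
#' @export
run_pipeline <- function(genome, consensus, outdir,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_genome_fasta(genome)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(hits = file.path(outdir, "hits.tsv"),
                candidates = file.path(outdir, "candidates.bed"),
                loci_bed = file.path(outdir, "ssat_loci.bed"),
                loci_tsv = file.path(outdir, "ssat_loci.tsv"),
                summary = file.path(outdir, "summary.tsv"),
                manifest = file.path(outdir, "manifest.json"))
  written <- character(0)
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  hits <- tryCatch(find_sine_hits(genome, consensus, config$min_cov_frac,
                                  config$min_hit_identity),
                   error = function(e) fail("search", e))
  regions <- tryCatch(select_candidates(merge_hits(hits, config$max_gap),
                                        config$min_candidate_len),
                      error = function(e) fail("merge", e))
  loci <- tryCatch(
    call_from_hits(hits, genome, consensus, config$max_gap,
                   config$min_candidate_len, config$min_middle_monomers,
                   config$min_monomer_identity),
    error = function(e) fail("call", e))
  summary <- tryCatch(
    summarize_genome(loci, filter_full_length(hits, consensus,
                                              config$min_len_frac,
                                              config$min_identity), genome),
    error = function(e) fail("profile", e))

  write_atomic(paths$hits, function(tmp)
    write.table(hits, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
  written <- c(written, paths$hits)
  cand_df <- if (length(regions)) data.frame(
    contig = vapply(regions, `[[`, character(1), "contig"),
    start = vapply(regions, `[[`, numeric(1), "start"),
    end = vapply(regions, `[[`, numeric(1), "end")) else
    data.frame(contig = character(), start = integer(), end = integer())
  write_bed(cand_df, paths$candidates)
  written <- c(written, paths$candidates)
  bed <- loci_to_bed(loci)
  if (nrow(bed)) write_bed(bed, paths$loci_bed, "BED12")
  else write_bed(bed, paths$loci_bed)
  written <- c(written, paths$loci_bed)
  write_atomic(paths$loci_tsv, function(tmp)
    write.table(loci_table(loci), tmp, sep = "\t", quote = FALSE,
                row.names = FALSE))
  write_atomic(paths$summary, function(tmp)
    write.table(summary, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
  manifest <- list(
    config = unclass(config),
    consensus = consensus$name,
    counts = list(hits = nrow(hits), candidates = length(regions),
                  loci = length(loci)))
  write_atomic(paths$manifest, function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA))
  message(sprintf("pipeline: %d hits, %d candidates, %d sSat loci",
                  nrow(hits), length(regions), length(loci)))
  invisible(list(hits = hits, candidates = regions, loci = loci,
                 summary = summary, paths = paths))
}
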