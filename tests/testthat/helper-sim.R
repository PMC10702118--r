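# shared fixtures: one deterministic synthetic SINE consensus and small
# genome builders used across test files

test_cons <- synth_sine_consensus()

# a small background genome with one planted array
array_genome <- function(n_monomers = 10, rate = 0, seed = 3,
                         bg_len = 50000, unit = c(42, 108),
                         lead_ext = 0, trail_ext = 0,
                         homogeneity = "independent") {
  g <- sim_genome(generate_background(bg_len, 0.42, seed))
  sp <- array_spec(unit[1], unit[2], n_monomers,
                   mutation_model(substitution_rate = rate, seed = seed + 1),
                   leading_extension = lead_ext,
                   trailing_extension = trail_ext,
                   homogeneity_mode = homogeneity)
  plant_ssat_array(g, test_cons, sp)
}

# extract the candidate region containing a planted array
array_region <- function(g, ...) {
  hits <- find_sine_hits(g, test_cons, ...)
  regions <- select_candidates(merge_hits(hits), 500)
  tr <- g$truth[g$truth$kind == "ssat_array", ][1, ]
  for (r in regions) {
    if (r$start < tr$end && r$end > tr$start) return(r)
  }
  NULL
}

truth_breakpoints <- function(g, i = 1) {
  tr <- g$truth[g$truth$kind == "ssat_array", ][i, ]
  as.integer(strsplit(tr$breakpoints, ",")[[1]])
}

# interval-overlap matching of called loci against truth arrays:
# returns the index of the called locus covering >= `frac` of each truth
match_loci <- function(loci_tab, truth, frac = 0.5) {
  vapply(seq_len(nrow(truth)), function(i) {
    if (!nrow(loci_tab)) return(NA_integer_)
    ov <- pmax(0, pmin(loci_tab$end, truth$end[i]) -
                  pmax(loci_tab$start, truth$start[i]))
    j <- which.max(ov)
    if (ov[j] >= frac * (truth$end[i] - truth$start[i])) j else NA_integer_
  }, integer(1))
}
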