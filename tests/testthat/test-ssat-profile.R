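fake_locus <- function(unit_start, unit_end, monomer_seqs = NULL,
                       n_middle = NULL, unit_consensus = NULL) {
  if (is.null(unit_consensus))
    unit_consensus <- substr(test_cons$sequence, unit_start, unit_end)
  mon <- if (!is.null(monomer_seqs)) {
    n <- length(monomer_seqs)
    data.frame(start = seq_len(n), end = seq_len(n) + 1,
               gstart = seq_len(n), gend = seq_len(n) + 1,
               role = c("leading", rep("middle", max(0, n - 2)),
                        if (n > 1) "trailing"),
               seq = monomer_seqs, strand = "+", stringsAsFactors = FALSE)
  } else data.frame()
  structure(list(contig = "c1", start = 0L, end = 1000L, strand = "+",
                 monomers = mon, unit_start = unit_start,
                 unit_end = unit_end,
                 unit_length = unit_end - unit_start + 1,
                 n_middle = if (is.null(n_middle)) max(0, nrow(mon) - 2)
                            else n_middle,
                 n_monomers = nrow(mon),
                 unit_consensus = unit_consensus,
                 family = "Squam3", sine = "synSINE"),
            class = "ssat_locus")
}

test_that("mean pairwise identity has the exact arithmetic and invariances", {
  unit <- substr(test_cons$sequence, 42, 108)
  expect_equal(mean_pairwise_identity(rep(unit, 4)), 100)
  # one substitution in a 67-nt pair: 66/67 matched columns
  mut <- paste0(substr(unit, 1, 30),
                setdiff(c("A", "C", "G", "T"), substr(unit, 31, 31))[1],
                substr(unit, 32, 67))
  expect_equal(mean_pairwise_identity(c(unit, mut)), 100 * 66 / 67)
  # permutation invariance
  set.seed(1)
  mons <- vapply(1:6, function(i)
    mutate_seq(unit, mutation_model(substitution_rate = 0.05, seed = i)),
    character(1))
  expect_equal(mean_pairwise_identity(mons),
               mean_pairwise_identity(rev(mons)))
  expect_lt(mean_pairwise_identity(mons), 100)
  expect_error(mean_pairwise_identity(unit), "two")
})

test_that("variant clustering groups loci by unit and truncation offset", {
  # all loci from one unit -> one variant with fraction 1
  l1 <- lapply(1:5, function(i) fake_locus(42, 108))
  v1 <- cluster_variants(l1)
  expect_equal(nrow(v1), 1)
  expect_equal(v1$fraction_of_loci, 1)
  expect_equal(sort(v1$members[[1]]), 1:5)

  # two disjoint consensus regions -> two variants with correct memberships
  l2 <- c(lapply(1:4, function(i) fake_locus(42, 108)),
          lapply(1:3, function(i) fake_locus(150, 260)))
  v2 <- cluster_variants(l2)
  expect_equal(nrow(v2), 2)
  expect_equal(v2$n_loci, c(4, 3))
  expect_equal(sort(v2$members[[1]]), 1:4)
  expect_equal(sort(v2$members[[2]]), 5:7)

  # three 5'-truncation variants, offsets 16 and 23 nt, mixture 14/10/9;
  # the two truncated variants differ by only 7 nt at the 5' end, so the
  # boundary tolerance must sit below that offset to resolve them
  l3 <- c(lapply(1:14, function(i) fake_locus(42, 108)),
          lapply(1:10, function(i) fake_locus(58, 108)),
          lapply(1:9, function(i) fake_locus(65, 108)))
  v3 <- cluster_variants(l3, boundary_tolerance = 5)
  expect_equal(nrow(v3), 3)
  expect_equal(v3$n_loci, c(14, 10, 9))
  starts <- v3$unit_start
  expect_equal(starts[2] - starts[1], 16)
  expect_equal(starts[3] - starts[1], 23)
})

test_that("subvariant labelling recovers homogeneous and alternating loci", {
  unit <- substr(test_cons$sequence, 42, 108)
  # homogeneous: all labels 1
  hom <- fake_locus(42, 108, monomer_seqs = rep(unit, 12))
  s1 <- label_subvariants(hom)
  expect_equal(s1$k, 1L)
  expect_true(all(s1$labels == 1))

  # two subvariants ~5% apart, strictly alternating
  svA <- unit
  svB <- mutate_seq(unit, mutation_model(substitution_rate = 0.05, seed = 31))
  arr <- rep(c(svA, svB), 10)
  alt <- fake_locus(42, 108, monomer_seqs = c(unit, arr, unit))
  s2 <- label_subvariants(alt)
  expect_equal(s2$k, 2L)
  expect_equal(s2$labels, rep(c(1L, 2L), 10))

  # three interleaved subvariants recovered with high agreement
  svC <- mutate_seq(unit, mutation_model(substitution_rate = 0.08, seed = 33))
  arr3 <- rep(c(svA, svB, svC), 6)
  three <- fake_locus(42, 108, monomer_seqs = c(unit, arr3, unit))
  s3 <- label_subvariants(three)
  expect_lte(s3$k, 3L)
  truth <- rep(c(1L, 2L, 3L), 6)
  agreement <- mean(s3$labels == truth)
  expect_gte(agreement, 0.9)
})

test_that("the alternation permutation test behaves at its extremes", {
  expect_equal(alternation_test(rep(1, 15)), 1)
  # strict 1212... with 20 labels: the exact tail is 2 / choose(20, 10)
  p <- alternation_test(rep(c(1, 2), 10), n_perm = 10000, seed = 5)
  expect_lte(p, 0.001)
  # determinism under seed
  expect_equal(p, alternation_test(rep(c(1, 2), 10), n_perm = 10000, seed = 5))
})

test_that("genome summaries bin loci by middle-monomer count", {
  loci <- lapply(c(4, 5, 6, 8, 9, 20), function(n)
    fake_locus(42, 108, n_middle = n))
  s <- summarize_genome(loci)
  expect_equal(s$n_loci, 6)
  expect_equal(c(s$n_4_5, s$n_6_8, s$n_9_plus), c(2, 2, 2))
  s0 <- summarize_genome(list())
  expect_equal(nrow(s0), 0)
})

test_that("internal microsatellite runs are measured at the anchor", {
  # copy with (TC)x12 at anchor 110, terminated by AA
  mk_copy <- function(n_tc) {
    paste0(substr(test_cons$sequence, 1, 109), strrep("TC", n_tc), "AA",
           substr(test_cons$sequence, 124, 300))
  }
  expect_equal(scan_internal_microsat(mk_copy(12), test_cons), 12L)
  # copy lacking the motif at the anchor
  no_tc <- paste0(substr(test_cons$sequence, 1, 109), "GATAGGAAGATAG",
                  substr(test_cons$sequence, 123, 300))
  expect_equal(scan_internal_microsat(no_tc, test_cons), 0L)

  # planted geometric run lengths are recovered exactly
  withr::with_seed(71, {
    lens <- 1L + stats::rgeom(40, 0.35)
    copies <- vapply(lens, mk_copy, character(1))
    got <- scan_internal_microsat(copies, test_cons)
    expect_equal(got, lens)
  })
})

test_that("canonical motif collapses rotation/complement classes", {
  # the published microsatellite equivalence: all these are one satellite
  expect_equal(canonical_motif("ATGGA"), canonical_motif("TGGAA"))
  expect_equal(canonical_motif("ATGGA"), canonical_motif("GGAAT"))
  expect_equal(canonical_motif("ATGGA"), oracle_canonical("ATGGA"))
  # dinucleotide class TC/CT/GA/AG
  forms <- c("TC", "CT", "GA", "AG")
  cans <- vapply(forms, canonical_motif, character(1))
  expect_equal(length(unique(cans)), 1)
  # homopolymer reduces to its primitive root
  expect_equal(canonical_motif("AAAAA"), "A")
  # idempotence and class invariance on random motifs vs brute force
  withr::with_seed(72, {
    for (i in 1:25) {
      m <- paste(sample(c("A", "C", "G", "T"), sample(2:10, 1),
                        replace = TRUE), collapse = "")
      cm <- canonical_motif(m)
      expect_equal(cm, oracle_canonical(m))
      expect_equal(canonical_motif(cm), cm)
      expect_equal(canonical_motif(revcomp(m)), cm)
    }
  })
})

test_that("similarity increases with locus length under homogenizing simulation", {
  # concerted-evolution-style regime: longer arrays are planted more
  # homogeneous (lower per-monomer divergence), mirroring the higher
  # within-array identity of long satellite loci
  sizes <- c(5, 5, 8, 8, 16, 16)
  rates <- c(0.095, 0.095, 0.067, 0.067, 0.046, 0.046)
  g <- sim_genome(generate_background(200000, 0.42, 73))
  for (i in seq_along(sizes)) {
    g <- plant_ssat_array(g, test_cons, array_spec(
      42, 108, sizes[i],
      mutation_model(substitution_rate = rates[i], seed = 7300 + i)))
  }
  # 5-monomer arrays are 335 nt, below the default candidate-length rule;
  # relax it so every planted stratum is callable
  loci <- call_ssat_loci(g, test_cons, min_middle_monomers = 2,
                         min_candidate_len = 300)
  expect_gte(length(loci), 5)
  mpi <- vapply(loci, function(l)
    mean_pairwise_identity(l$monomers$seq[l$monomers$role == "middle"]),
    numeric(1))
  nm <- vapply(loci, function(l) l$n_monomers, numeric(1))
  bins <- cut(nm, c(0, 6, 10, Inf))
  means <- tapply(mpi, bins, mean)
  expect_false(anyNA(means))
  expect_true(all(diff(means) > 0))
})
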