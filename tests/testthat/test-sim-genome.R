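test_that("background generation is deterministic and honours GC content", {
  a <- generate_background(1000, 0.5, 7)
  b <- generate_background(1000, 0.5, 7)
  expect_identical(a, b)
  expect_equal(nchar(a), 1000)

  # observed GC within 3 SD of binomial(n, gc)
  n <- 100000
  s <- generate_background(n, 0.40, 1)
  gc <- lengths(regmatches(s, gregexpr("[GC]", s))) / n
  sd3 <- 3 * sqrt(0.40 * 0.60 / n)
  expect_lt(abs(gc - 0.40), sd3)

  expect_error(generate_background(0, 0.5, 1), "positive")
  expect_error(generate_background(100, 1.2, 1), "gc_fraction")
})

test_that("mutation model validates rates and preserves identity at zero rates", {
  expect_error(mutation_model(substitution_rate = 1.2), "rates")
  expect_error(mutation_model(0.5, 0.3, 0.4), "rates")
  s <- generate_background(500, 0.42, 2)
  expect_identical(mutate_seq(s, mutation_model(seed = 9)), s)
})

test_that("substitution-only mutation matches the analytic identity expectation", {
  # the substitution scheme always changes the base, so expected identity
  # is exactly 1 - r; for n = 10000 and r = 0.10 the 3 SD band is +- 0.009
  s <- generate_background(10000, 0.42, 3)
  m <- mutate_seq(s, mutation_model(substitution_rate = 0.10, seed = 4))
  expect_equal(nchar(m), nchar(s))
  ident <- mean(strsplit(s, "")[[1]] == strsplit(m, "")[[1]])
  expect_lt(abs(ident - 0.90), 3 * sqrt(0.9 * 0.1 / 10000))
})

test_that("extreme deletion rate removes essentially the whole sequence", {
  s <- strrep("ACGT", 25)
  out <- mutate_seq(s, mutation_model(deletion_rate = 0.99,
                                      indel_length_mean = 5, seed = 5))
  expect_lt(nchar(out), 5)
})

test_that("mutation is deterministic under its seed", {
  s <- generate_background(2000, 0.42, 6)
  m <- mutation_model(0.05, 0.01, 0.01, seed = 11)
  expect_identical(mutate_seq(s, m), mutate_seq(s, m))
})

test_that("planted SINE copies are exact at zero mutation and non-overlapping", {
  g <- sim_genome(generate_background(20000, 0.42, 8))
  g <- plant_sine_copies(g, test_cons, 1, mutation_model(seed = 2))
  tr <- g$truth
  planted <- substr(g$seqs[[1]], tr$start + 1, tr$end)
  if (tr$strand == "-") planted <- revcomp(planted)
  expect_identical(planted, test_cons$sequence)

  g2 <- sim_genome(generate_background(2e6, 0.42, 9))
  g2 <- plant_sine_copies(g2, test_cons, 50, mutation_model(seed = 3))
  expect_equal(nrow(g2$truth), 50)
  o <- order(g2$truth$start)
  expect_true(all(g2$truth$start[o][-1] >= g2$truth$end[o][-50]))
})

test_that("planted array geometry matches the spec of the planted unit", {
  # 10 monomers of the 67-nt unit (consensus 42-108), zero divergence
  g <- array_genome(n_monomers = 10, rate = 0)
  tr <- g$truth[g$truth$kind == "ssat_array", ]
  expect_equal(tr$end - tr$start, 670)
  bp <- truth_breakpoints(g)
  expect_equal(length(bp), 11)
  mons <- substring(g$seqs[[1]], head(bp, -1) + 1, bp[-1])
  expect_equal(length(unique(mons)), 1)
  expect_equal(nchar(mons[1]), 67)
})

test_that("a two-monomer array is exactly leading + trailing", {
  g <- array_genome(n_monomers = 2, rate = 0, lead_ext = 10, trail_ext = 5)
  bp <- truth_breakpoints(g)
  expect_equal(length(bp), 3)
  expect_equal(diff(bp), c(77, 72))
})

test_that("array spec validation enforces unit and extension bounds", {
  expect_error(array_spec(42, 108, 1, mutation_model()), "n_monomers")
  g <- sim_genome(generate_background(5000, 0.42, 1))
  # unit as long as the consensus is rejected
  sp <- array_spec(1, nchar(test_cons$sequence), 5, mutation_model(seed = 1))
  expect_error(plant_ssat_array(g, test_cons, sp), "shorter than")
  # extension beyond the 5' terminus is rejected
  sp2 <- array_spec(42, 108, 5, mutation_model(seed = 1),
                    leading_extension = 60)
  expect_error(plant_ssat_array(g, test_cons, sp2), "extension")
})

test_that("mean pairwise monomer identity tracks the Monte-Carlo expectation", {
  # frozen from a 30-replicate simulation oracle at substitution rate 0.05:
  # mean 90.38, SD 1.21 (close to the analytic (1-r)^2 + r^2/3 = 90.33%)
  g <- array_genome(n_monomers = 20, rate = 0.05, seed = 21)
  bp <- truth_breakpoints(g)
  mons <- substring(g$seqs[[1]], head(bp, -1) + 1, bp[-1])
  mpi <- mean_pairwise_identity(mons[2:19])
  expect_lt(abs(mpi - 90.38), 3 * 1.21)
})

test_that("motif tracts are planted exactly where requested", {
  g <- sim_genome(generate_background(20000, 0.42, 4))
  g <- plant_motif_tract(g, "TTAGGG", 1000, location = "end5",
                         kind = "telomere_tract")
  expect_equal(g$truth$end[1] - g$truth$start[1], 6000)
  expect_identical(substr(g$seqs[[1]], 1, 12), "TTAGGGTTAGGG")

  g <- plant_motif_tract(g, "GGAAT", 200, location = "internal",
                         kind = "microsat_tract", seed = 5)
  tr <- g$truth[2, ]
  expect_equal(tr$end - tr$start, 1000)
  expect_identical(substr(g$seqs[[1]], tr$start + 1, tr$start + 10),
                   "GGAATGGAAT")

  expect_error(plant_motif_tract(g, "TTAGGG", 0), "n_repeats")
})

test_that("truth records reproduce planted sequences byte-for-byte", {
  g <- sim_genome(generate_background(100000, 0.42, 12))
  g <- plant_motif_tract(g, "TTAGGG", 50, location = "internal", seed = 3)
  sp <- array_spec(42, 108, 6, mutation_model(substitution_rate = 0.05,
                                              seed = 13))
  g <- plant_ssat_array(g, test_cons, sp)
  bp <- truth_breakpoints(g)
  tr <- g$truth[g$truth$kind == "ssat_array", ]
  expect_equal(bp[1], tr$start)
  expect_equal(bp[length(bp)], tr$end)
  expect_true(all(diff(bp) > 0))
  # re-planting with the same seeds reproduces the identical genome
  g2 <- sim_genome(generate_background(100000, 0.42, 12))
  g2 <- plant_motif_tract(g2, "TTAGGG", 50, location = "internal", seed = 3)
  g2 <- plant_ssat_array(g2, test_cons,
                         array_spec(42, 108, 6,
                                    mutation_model(substitution_rate = 0.05,
                                                   seed = 13)))
  expect_identical(g$seqs, g2$seqs)
  expect_identical(g$truth, g2$truth)
})

test_that("ortholog pairs share flanks and respect jitter and the floor rule", {
  # degenerate jitter, zero mutation: identical genomes
  p <- generate_ortholog_pair(test_cons, 5, 42, 108, seed = 20)
  expect_identical(p$genomeA$seqs, p$genomeB$seqs)
  expect_true(all(p$pairs$delta == 0))

  # constant -5 jitter on 4-monomer arrays floors at 1
  p2 <- generate_ortholog_pair(test_cons, 6, 42, 108,
                               count_dist = function(n) rep(4L, n),
                               jitter = function(n) rep(-5L, n), seed = 21)
  expect_true(all(p2$pairs$n_monomers_B == 1))
  # genome B arrays really are one monomer long
  trB <- p2$genomeB$truth
  expect_true(all(trB$end - trB$start == 67))
})

test_that("the study-condition simulator is deterministic and complete", {
  g1 <- simulate_ssat_genome(200000, test_cons, n_arrays = 3, n_sines = 5,
                             seed = 30)
  g2 <- simulate_ssat_genome(200000, test_cons, n_arrays = 3, n_sines = 5,
                             seed = 30)
  expect_identical(g1$seqs, g2$seqs)
  expect_equal(sum(g1$truth$kind == "ssat_array"), 3)
  expect_equal(sum(g1$truth$kind == "sine_copy"), 5)
})
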