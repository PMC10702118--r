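plant_exact <- function(bg_len, at, fragment, seed = 50) {
  g <- sim_genome(generate_background(bg_len, 0.42, seed))
  g$seqs[[1]] <- paste0(substr(g$seqs[[1]], 1, at), fragment,
                        substr(g$seqs[[1]], at + nchar(fragment) + 1, bg_len))
  g
}

test_that("an exact full-length copy yields one full-coverage hit", {
  g <- plant_exact(20000, 8000, test_cons$sequence)
  hits <- find_sine_hits(g, test_cons)
  hits <- hits[hits$identity == 100, ]
  expect_equal(nrow(hits), 1)
  expect_equal(hits$cons_start, 1)
  expect_equal(hits$cons_end, nchar(test_cons$sequence))
  expect_equal(hits$start, 8000)
})

test_that("the consensus-coverage threshold gates fragment hits", {
  # a fragment covering 15% of the consensus: invisible at the default 20%
  # threshold, found at 10%
  # non-repetitive body region, away from the embedded (TC)n run
  frag <- substr(test_cons$sequence, 151, 150 + round(0.15 * 300))
  g <- plant_exact(20000, 9000, frag, seed = 51)
  expect_equal(nrow(find_sine_hits(g, test_cons, min_cov_frac = 0.20)), 0)
  h <- find_sine_hits(g, test_cons, min_cov_frac = 0.10)
  expect_gte(nrow(h), 1)
  expect_lte(abs(h$start[1] - 9000), 3)
})

test_that("hits at 10% divergence recover nearly all planted copies", {
  g <- sim_genome(generate_background(400000, 0.42, 52))
  g <- plant_sine_copies(g, test_cons, 50,
                         mutation_model(substitution_rate = 0.10, seed = 53))
  hits <- find_sine_hits(g, test_cons)
  tr <- g$truth
  recovered <- vapply(seq_len(nrow(tr)), function(i) {
    ov <- pmax(0, pmin(hits$end, tr$end[i]) - pmax(hits$start, tr$start[i]))
    any(ov >= 0.9 * (tr$end[i] - tr$start[i]))
  }, logical(1))
  expect_gte(sum(recovered), 48)
})

test_that("strand symmetry: reverse-complementing the genome mirrors the hits", {
  g <- sim_genome(generate_background(50000, 0.42, 54))
  g <- plant_sine_copies(g, test_cons, 3,
                         mutation_model(substitution_rate = 0.05, seed = 55))
  # confident hits only: marginal near-threshold alignments are not
  # guaranteed to survive masking order symmetrically
  h1 <- find_sine_hits(g, test_cons)
  h1 <- h1[h1$identity >= 70, ]
  L <- nchar(g$seqs[[1]])
  g2 <- sim_genome(setNames(revcomp(g$seqs[[1]]), names(g$seqs)))
  h2 <- find_sine_hits(g2, test_cons)
  h2 <- h2[h2$identity >= 70, ]
  expect_equal(nrow(h1), nrow(h2))
  m1 <- h1[order(h1$start), ]
  m2 <- h2[order(-h2$end), ]
  expect_equal(m1$start, L - m2$end)
  expect_equal(m1$end, L - m2$start)
  expect_true(all(m1$strand != m2$strand))
  expect_equal(m1$cons_start, m2$cons_start)
  expect_equal(m1$identity, m2$identity)
})

test_that("coverage threshold is monotone: lowering it never removes hits", {
  g <- sim_genome(generate_background(100000, 0.42, 56))
  g <- plant_sine_copies(g, test_cons, 10,
                         mutation_model(substitution_rate = 0.10, seed = 57),
                         truncation_5p_dist = function(n)
                           sample(0:250, n, replace = TRUE))
  h_hi <- find_sine_hits(g, test_cons, min_cov_frac = 0.30)
  h_lo <- find_sine_hits(g, test_cons, min_cov_frac = 0.10)
  key <- function(h) paste(h$start, h$end, h$strand)
  expect_true(all(key(h_hi) %in% key(h_lo)))
  expect_gte(nrow(h_lo), nrow(h_hi))
})

test_that("the full-length filter applies strict coverage and identity bounds", {
  L <- nchar(test_cons$sequence)
  mk <- function(cs, ce, id) data.frame(
    contig = "c", start = 0L, end = 1000L, strand = "+",
    cons_start = cs, cons_end = ce, identity = id, score = 100)
  # coverage exactly 0.90 -> excluded; identity exactly 65 -> excluded
  exact_cov <- mk(1L, as.integer(0.90 * L), 99)
  expect_equal(nrow(filter_full_length(exact_cov, test_cons)), 0)
  exact_id <- mk(1L, L, 65)
  expect_equal(nrow(filter_full_length(exact_id, test_cons)), 0)
  pass <- mk(1L, L, 65.1)
  expect_equal(nrow(filter_full_length(pass, test_cons)), 1)
  # raising min_identity never adds hits
  hits <- rbind(mk(1L, L, 70), mk(1L, L, 80), mk(1L, L, 90))
  n_by_id <- vapply(c(60, 75, 85), function(t)
    nrow(filter_full_length(hits, test_cons, min_identity = t)), numeric(1))
  expect_true(all(diff(n_by_id) <= 0))
})

test_that("full-length retention under divergence matches the simulation oracle", {
  # frozen from a 300-replicate oracle (mutate -> local align -> strict
  # cov > 0.90 & identity > 65): retention 0.99 at rate 0.30, 0.107 at 0.40
  ret <- function(rate, n = 60, seed0) {
    hits <- do.call(rbind, lapply(seq_len(n), function(i) {
      cp <- mutate_seq(test_cons$sequence,
                       mutation_model(substitution_rate = rate,
                                      seed = seed0 + i))
      a <- local_align(cp, test_cons$sequence)
      data.frame(contig = "c", start = 0L, end = nchar(cp), strand = "+",
                 cons_start = a$target_start, cons_end = a$target_end,
                 identity = a$identity, score = a$score)
    }))
    nrow(filter_full_length(hits, test_cons)) / n
  }
  sd30 <- sqrt(0.99 * 0.01 / 60)
  sd40 <- sqrt(0.107 * 0.893 / 60)
  expect_lt(abs(ret(0.30, seed0 = 58000) - 0.99), 3 * sd30 + 0.02)
  expect_lt(abs(ret(0.40, seed0 = 60000) - 0.107), 3 * sd40)
})

test_that("column consensus applies majority rule with fixed tie order", {
  expect_equal(column_consensus(c("ACGT", "ACGT", "ACGT")), "ACGT")
  expect_equal(column_consensus(c("AAAA", "AAAA", "GAAA")), "AAAA")
  # tie A/A/G/G -> A by base order
  expect_equal(column_consensus(c("A", "A", "G", "G")), "A")
  # gap-majority column dropped
  expect_equal(column_consensus(c("A-C", "A-C", "AGC", "A--")), "AC")
  expect_error(column_consensus(character(0)), "empty")
})

test_that("refine_consensus chunks copies and recovers a clean consensus", {
  copies <- rep(substr(test_cons$sequence, 1, 200), 100)
  sf <- refine_consensus(copies)
  expect_equal(nrow(sf$groups), 1)
  expect_equal(sf$groups$consensus[1], copies[1])
  expect_equal(sf$groups$n_members[1], 100)

  sf2 <- refine_consensus(rep(copies[1], 101))
  expect_equal(sf2$groups$n_members, c(100, 1))
  expect_error(refine_consensus(character(0)), "copies")
})

test_that("two subfamilies 15% apart are separated and recovered", {
  src1 <- test_cons$sequence
  src2 <- mutate_seq(src1, mutation_model(substitution_rate = 0.15, seed = 70))
  make_copies <- function(src, n, seed0)
    vapply(seq_len(n), function(i)
      mutate_seq(src, mutation_model(substitution_rate = 0.03,
                                     seed = seed0 + i)), character(1))
  copies <- c(make_copies(src1, 100, 7000), make_copies(src2, 100, 8000))
  sf <- refine_consensus(copies)
  expect_equal(nrow(sf$groups), 2)
  id_to <- function(cons, src) local_align(cons, src)$identity
  best1 <- max(id_to(sf$groups$consensus[1], src1),
               id_to(sf$groups$consensus[1], src2))
  best2 <- max(id_to(sf$groups$consensus[2], src1),
               id_to(sf$groups$consensus[2], src2))
  expect_gte(best1, 98)
  expect_gte(best2, 98)
  # the two groups match different sources
  g1_src <- which.max(c(id_to(sf$groups$consensus[1], src1),
                        id_to(sf$groups$consensus[1], src2)))
  g2_src <- which.max(c(id_to(sf$groups$consensus[2], src1),
                        id_to(sf$groups$consensus[2], src2)))
  expect_true(g1_src != g2_src)
})
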