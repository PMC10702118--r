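---
title: "Discovering SINE-derived satellites: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering SINE-derived satellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinesat)
```

## The problem

Satellite DNA — long tandem arrays of a short repeat unit — usually has no
recognisable ancestry. A striking exception are satellites derived from
SINE retrotransposons (here called *sSats*): tandem arrays whose repeat
unit is a sub-region of a SINE consensus, always shorter than the SINE
itself (units of roughly 70–290 nt for SINEs of 190–350 nt). In squamate
reptiles such satellites arise repeatedly from the Squam1/Squam2/Squam3
SINE families; in snakes the dominant sSat3 unit spans 67 nt of the
snake-specific Squam3 consensus (positions 42–108, 1-based inclusive).
`sinesat` implements the full discovery and characterization pipeline for
such elements, plus a synthetic-genome simulator that provides exact
ground truth so that every stage is testable without any external genome.

## Pipeline model

The discovery pipeline is consensus-anchored throughout:

1. **Hit search** (`find_sine_hits`). Affine-gap Smith–Waterman local
   alignment of the family consensus against both strands, accelerated by
   exact k-mer seeding (default k = 11) into candidate windows, with
   iterated masking so each repeated SINE sub-region in a tandem array
   yields its own hit. A hit must cover ≥ 20 % of the consensus length —
   the fragment size that still identifies loci with tandemly duplicated
   SINE fragments — and reach a 60 % identity floor (below, under
   "numerical choices", why a floor is needed at all).
2. **Locus assembly** (`merge_hits`, `select_candidates`). Hits less than
   100 bp apart are fused (a gap of exactly 100 bp is not); fused regions
   longer than 500 bp (strictly) become candidate loci.
3. **Tandem detection** (`detect_tandem_units`). The array period *P* is
   estimated from the modal spacing between recurrences of identical
   k-mers inside the locus; the unit's phase on the consensus is the
   length-*P* consensus window with the most matched columns against a
   two-period sample of the locus; the locus is then tiled by repeated
   glocal alignment of the unit in both directions, accepting monomers at
   ≥ 60 % identity with inter-monomer gaps < 100 bp. Every monomer is
   finally re-aligned to the consensus to record its own consensus
   interval, which lets the 5′ (leading) and 3′ (trailing) terminal
   monomers extend beyond the unit toward a SINE terminus — the
   characteristic longer-terminal-monomer architecture of these
   satellites.
4. **Calling** (`call_ssat`). A locus is an sSat when it has at least four
   middle monomers (configurable; the count deliberately follows the
   "at least four middle monomers" convention rather than the stricter
   "more than four tandems" phrasing, and both are reachable through
   `min_middle_monomers`), all adjacent gaps are < 100 bp, and the modal
   unit is shorter than the SINE. The reported `unit_interval` is the
   component-wise mode of the middle monomers' consensus intervals.
5. **Profiling** (`cluster_variants`, `label_subvariants`,
   `alternation_test`, `summarize_genome`, `scan_internal_microsat`,
   `canonical_motif`), **orthology** (`find_orthologs`) and
   **chromosomal localization** (`find_telomere_tracts`, `scan_motif`,
   `find_satellite_blocks`, `subtelomeric_enrichment`,
   `size_fraction_track`).

`run_pipeline()` drives stages 1–5 and writes a reproducible report
bundle (TSV/BED6/BED12 plus a JSON manifest of all thresholds).

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `min_cov_frac` | 0.20 | minimum consensus coverage of a reported hit (fraction of consensus length) |
| `max_gap` | 100 bp | strict fusion / adjacency gap |
| `min_candidate_len` | 500 bp | strict minimum fused-region length |
| `min_len_frac`, `min_identity` | 0.90, 65 % | strict full-length-copy filter (for consensus refinement) |
| `min_middle_monomers` | 4 | middle monomers required to call an sSat |
| `min_monomer_identity` | 60 % | monomer acceptance identity in tiling |
| `flank_len`, `min_flank_identity`, `max_span` | 500 bp, 80 %, 100 kb | orthology flank matching |
| `telomere min_repeats` | 1000 | units of (TTAGGG)n marking a telomere |
| scoring | +5/−4, gap 12 + 2·L | match/mismatch and affine gap costs |

All are exposed both as function arguments and through
`pipeline_config()`.

## The synthetic-data generator

The simulator emulates the repeat landscape this pipeline is designed
for, with exact ground truth (`sim_genome` objects carry a truth table
whose coordinates slice the emitted sequence byte-for-byte):

* i.i.d. background at GC 0.42 — a typical squamate genome-wide GC level;
* interspersed SINE copies with geometric 5′ truncations, simple-repeat
  tails and per-copy substitution divergence (default 5–15 %, spanning
  young to moderately old copies);
* tandem arrays built as *leading monomer (unit + 5′ extension) +
  middle monomers + trailing monomer (unit + 3′ extension)*, each
  monomer independently mutated ("independent" mode) or serially copied
  from its predecessor ("serial" mode);
* exact `(TTAGGG)n` telomere tracts and internal microsatellite or
  centromeric-satellite blocks;
* genome pairs with identical flank layout whose shared arrays differ in
  monomer count by a configurable jitter distribution (floored at one
  monomer), independently mutated per genome.

Substitutions pick uniformly among the three alternative bases, so a
substitution-only mutant has expected identity exactly 1 − *r* to its
source; indel lengths are geometric. Placement is uniform with bounded
rejection (1000 retries) to keep planted features disjoint. What the
generator does **not** model: realistic base composition beyond GC
content, CpG decay, lineage-specific subfamily histories, or assembly
artifacts other than N runs. Passing tests therefore demonstrate
algorithmic correctness under a controlled divergence model, not
performance on any particular real assembly.

Simulated problem sizes used by the test suite were chosen to exercise
the method at desk scale: a 5-Mbp genome with 30 arrays (4–50 monomers,
≤ 10 % divergence) and 200 solo copies for end-to-end recovery; 500
orthologous arrays at 2 % genome divergence for the pairing regime; 500
null replicates for each permutation-test calibration. For the
end-to-end genome the planted unit is 150 nt — inside the observed
70–290 nt range — so that even the smallest (4-monomer) arrays exceed
the 500-bp candidate rule and every planted array is a valid recovery
target.

## Numerical choices worth knowing about

**Why hits need an identity floor and end-trimming.** Under the soft
affine-gap parameters used for DNA search (+5/−4, gap 12 + 2L), optimal
local alignments drift through *unrelated* sequence at 50–60 % column
identity (gaps are cheap enough that the aligner cherry-picks matches).
Two consequences, both measured during development: a coverage-only hit
criterion admits long chance alignments, and alignments of a consensus
against a tandem array glue adjacent monomers together. The package
therefore (a) applies a 60 % identity floor to reported hits, and
(b) trims every extracted hit to its maximal-scoring run of columns
under +(1−q)/−q weights, q being the identity floor — so any segment
whose column identity falls below q is removed from the ends. The
`local_align()` primitive itself reports untrimmed Smith–Waterman
optima, and is validated against a brute-force dynamic-programming
oracle in the test suite.

**Why the unit comes from locus periodicity, not hit intervals.** For
the same gluing reason, member-hit consensus intervals are unreliable
estimators of the repeat unit. The period estimated from exact k-mer
recurrence spacing is immune to alignment drift, and anchoring the
phase by maximal matched-column count on the consensus recovers the
planted 42–108 unit to ±1 nt at zero divergence (the remaining ±1 is a
genuine rotational ambiguity when the bases flanking the unit happen to
repeat its edge).

**Subfamily grouping order.** The SubFam-style procedure
(`refine_consensus`) orders copies so similar copies are adjacent before
chunking into groups of 100. Ordering by identity to the overall
majority consensus cannot separate symmetric subfamilies (both lie at
the same expected distance from the chimeric consensus), so the package
orders by the leaf order of average-linkage clustering on star-alignment
Hamming distances — a deterministic, MSA-tool-independent surrogate for
guide-tree ordering.

**Subvariant count selection.** `label_subvariants` cuts a
single-linkage dendrogram at the largest merge-height gap with k ≤ 3
(two or three locus-specific subvariants are what these satellites
exhibit); a split is accepted only when the gap exceeds both an absolute
floor (0.02 distance units) and the largest within-group merge height,
which keeps homogeneous loci single-subvariant.

**Permutation tests.** Both `alternation_test` (statistic: adjacent
label pairs that differ) and `subtelomeric_enrichment` (statistic:
difference in median normalized distance-to-end, control − sSat) are
one-sided label-permutation tests with add-one correction
((b+1)/(n+1)), which makes them valid (conservative) at any permutation
count. The alternation statistic is discrete, so its attained size can
sit below the nominal level on short label sequences.

**Degenerate inputs.** Empty hit sets, empty candidate lists, loci with
fewer than two monomers, single-copy `refine_consensus` input, and
N runs ≥ 20 nt inside loci are all exercised in the tests; monomer
tiling treats masked N stretches as mismatching sequence and the gap
rule decides whether a locus survives them.

**Boundary conventions.** All genomic intervals are 0-based half-open
(BED convention) in every data frame and output file; all consensus
positions are 1-based inclusive, matching how repeat units are described
in the literature (e.g. "positions 42–108"). Threshold comparisons at
Methods boundaries are strict: a 100-bp gap does not fuse, a 500-bp
region is not a candidate, 90 % coverage and 65 % identity do not pass
the full-length filter.

## Known limitations

* Sensitivity of the genome-wide search decays for copies beyond ~30 %
  divergence: exact-k-mer seeding misses copies with no conserved
  11-mer, exactly as seed-based search tools do. The full-length filter
  semantics are unaffected (they are tested alignment-level).
* Heavily diverged satellite blocks (~32 % divergence) fragment into
  several reported blocks when individual monomers fall below the
  identity floor and break the 100-bp chain.
* Orthology pairing requires both flanks on one contig of the second
  assembly, in consistent orientation; rearranged or flank-deleted loci
  are reported as unpaired rather than guessed.
* The pericentromeric interpretation of satellite blocks is positional
  only; no centromere caller is included.

## A worked example

```{r example, eval = FALSE}
cons <- synth_sine_consensus()                    # 300-nt synthetic SINE
g <- sim_genome(generate_background(50000, 0.42, seed = 7))
g <- plant_ssat_array(g, cons,
                      array_spec(42, 108, 10, mutation_model(seed = 3)))
loci <- call_ssat_loci(g, cons)
loci[[1]]
#> ssat_locus contig1:46174-46843 (+) 10 monomers (8 middle), unit 41-107 (67 nt)
```

The called unit length is 67 nt and the interval sits within ±1 nt of
the planted 42–108 (the rotational ambiguity discussed above).
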