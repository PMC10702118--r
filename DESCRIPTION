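Package: sinesat
Title: Discovery and Characterization of SINE-Derived Satellite DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering satellites derived from SINE
    retrotransposons (sSats) in genome assemblies: local-alignment search
    for SINE copies, consensus refinement into subfamilies, assembly of
    hits into candidate loci, tandem-unit detection and sSat calling,
    variant and subvariant profiling with an alternation permutation test,
    orthologous-locus comparison between two assemblies via flank
    matching, and chromosomal profiling (telomere tracts, motif scans,
    subtelomeric enrichment). Includes a synthetic-genome generator that
    plants diverged SINE copies, tandem arrays, telomeric and satellite
    tracts with exact ground-truth coordinates, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
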