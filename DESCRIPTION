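Package: pandiallel
Title: Pan-Genome Structural Variation and Half-Diallel Trait Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating assembly-based structural-variant calls
    across a panel of inbred founders and projecting the resulting
    polymorphism onto a half-diallel mating design, in the style of
    multi-parental pan-genome frameworks for crop trait dissection.
    Collapses per-accession InDel/SV calls into a multi-allelic site matrix,
    enumerates all pairwise crosses and their polymorphic sites, computes
    allele-frequency spectra and permutation-based pan-variant rarefaction
    curves, and provides Mendelian segregation machinery for F2/RIL panels:
    single- and two-locus (epistatic) expected ratios, goodness-of-fit and
    marker-trait contingency tests, allelism tests, mode-of-inheritance
    classification, mid-parent regression, tail-segregant selection,
    gene-interval haplotype grouping and association, substitution mapping
    over recombinant panels, and coding-effect classification. A seeded
    synthetic founder/cross generator reproduces the statistical structure
    the analyses assume, so the full pipeline is testable without external
    genome assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
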