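Package: supmapr
Title: Simulated Suppressor Screens and One-Step Mapping-by-Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates forward-genetic suppressor screens in a selfing
    nematode crossed to a polymorphic (Hawaiian-like) mapping strain:
    EMS mutagenesis, backcrossing and introgression, F2 recombinant
    generation, genotype-dependent selection, and en-masse propagation of
    the sequenced pool. Converts the pool's true allele frequencies into
    pooled short-read evidence (per-site allele depths emitted as VCF),
    implements SNP-frequency mapping of candidate intervals by depletion
    of polymorphic-strain markers (absence mode for recessive suppressors,
    reduction mode for dominant ones) with subtraction of known
    introgression gaps, and filters candidate mutations inside mapped
    intervals by parental subtraction, cross-strain background removal,
    allele-frequency thresholds, and missense/nonsense/splice-site effect
    classification against toy gene models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
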