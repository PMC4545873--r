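Package: sweepscan
Title: Cross-Population Selective Sweep Scans from Phased Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects signatures of recent positive selection by contrasting
    two populations: a cross-population extended haplotype homozygosity scan
    (XP-EHH) computed from phased haplotypes, and a composite-likelihood
    sweep scan in the XP-CLR family computed from allele frequencies.
    Per-site statistics are summarised over consecutive non-overlapping
    25-kb windows with SNP-count-binned empirical p-values (XP-EHH) or a
    top-1% empirical threshold (XP-CLR), significant windows are mapped to
    overlapping gene intervals, and breed-specific amino-acid or Indel
    enrichment is assessed with one-sided Fisher's exact tests under
    Bonferroni correction. A forward Wright-Fisher simulator with
    recombination and a hard sweep provides fully seeded synthetic data for
    power and calibration studies, and a single pipeline driver chains all
    stages through plain-text file interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    methods,
    yaml,
    vcfR,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
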