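Package: cnapair
Title: Somatic Copy-Number Alteration Calling and Tumor Purity Estimation
    from Paired Tumor-Normal Variant Files
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects somatic copy-number alterations (CNAs) from paired
    tumor-normal variant files (VCF, MAF, or tab-delimited allele-count
    tables) without access to raw sequencing reads.  Per-site allele depths
    are binned into fixed 100-bp coverage windows, normalized against an
    automatically inferred (or user-specified) diploid baseline, and
    segmented by recursive partitioning of the windowed log2 coverage
    ratios.  Tumor purity is estimated from B-allele-frequency and
    loss-of-heterozygosity signals in copy-neutral and single-copy
    gain/loss segments, with per-segment estimates summarized by a
    Gaussian-mixture cluster analysis.  Includes a paired tumor-normal
    VCF simulator with known segmental copy number, purity, subclones and
    library-artifact coverage noise, and concordance metrics (per-base
    precision/recall/F1 and segmental corroboration) for comparing CNA
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    mclust,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
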