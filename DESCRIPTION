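Package: deepspike
Title: Simulation and Benchmarking of Low-Fraction Somatic Variants in
    Ultra-Deep Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates artificial ultra-deep targeted sequencing samples with a
    germline mutational background, spikes low variant-allele-fraction somatic
    SNVs and INDELs directly into aligned reads with consistent CIGAR rewriting,
    verifies spike-in fidelity (insertion success and VAF distribution
    preservation), and benchmarks variant-caller VCF output against the spiked
    ground truth with TPR/PPV/FDR in tumor-only or tumor-normal paired mode.
    Includes reproducible fragment-level BAM downsampling, a synthetic
    reference/panel fixture generator, and a DREAM-challenge-comparable preset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    methods,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
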