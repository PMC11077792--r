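# deepspike

Simulation and benchmarking of **low-fraction somatic variants** in
**ultra-deep targeted sequencing**.

Somatic variants in circulating tumor DNA (ctDNA) sit at allele fractions
below 5% — often below 1% — because tumor-derived molecules are a small
minority of plasma cell-free DNA. Detecting them requires ultra-deep
(10,000x+) targeted sequencing *and* callers tuned for the low-VAF regime,
and tuning callers requires samples whose somatic content is known exactly.
Real specimens cannot provide that ground truth. deepspike builds it:

1. **Artificial normal samples** — paired-end reads simulated over a target
   panel at any requested depth, on top of a germline background planted at
   50% allele fraction (heterozygous) from a parametric mutational model.
   Reads are emitted pre-aligned (the simulator knows every read's true
   origin), as coordinate-sorted indexed BAM.
2. **Somatic spike-in** — randomly generated SNVs and indels with target
   VAFs drawn from a requested range (e.g. 0.1–5%) are inserted by editing
   the aligned reads directly. Fragments are selected
   Bernoulli(target VAF), both mates are edited consistently, indel edits
   rewrite the CIGAR and preserve read length, and a variant always
   receives at least one supporting read. Outputs: tumor BAM, a truth VCF
   of the successfully inserted variants (`INFO/VAF` = observed allele
   fraction), and a fidelity report with a Kolmogorov–Smirnov comparison of
   target vs observed VAF distributions.
3. **Benchmarking** — caller VCFs are matched against the truth on exact
   normalized alleles (left-alignment + trimming), with germline variants
   excluded, in tumor-only or tumor-normal paired mode:
   TPR = TP/(TP+FN), PPV = TP/(TP+FP), FDR = 1 − PPV, overall and
   stratified by VAF bin and variant type. Seeded fragment-level BAM
   downsampling and a deterministic train/test split support depth
   titration and parameter-tuning protocols.

A synthetic reference/panel generator (`make_fixture()`) makes every run
self-contained — no downloads, no real genome required — and a
DREAM-challenge-comparable preset (`dream_preset()`: 30x, 101 bp reads,
100 SNVs per sample at VAF 0.3–0.5) reproduces a classic benchmark design.

## Worked example

```r
library(deepspike)

# 1. synthetic 20 kb reference with a 4 kb target panel
fx <- make_fixture(seed = 7, size = 20000, region_length = 4000)

# 2. artificial normal sample at 1,000x with a germline background
normal <- make_normal_sample(fx$ref, fx$regions,
                             coverage = 1000, seed = 1,
                             out_dir = "example_out",
                             sample_id = "s01", keep_reads = TRUE)

# 3. one hundred low-fraction somatic variants, VAF 0.1-5%
specs <- generate_specs(fx$regions, fx$ref, normal$germline,
                        n = 100, vtypes = c("SNV", "INS", "DEL"),
                        vaf_range = c(0.001, 0.05), max_indel_len = 90,
                        seed = 2)

# 4. spike them into the normal reads -> tumor BAM + truth VCF
tumor <- make_tumor_sample(normal, specs, fx$ref,
                           max_depth = 2000, seed = 3,
                           out_dir = "example_out")
tumor$fidelity
#> <fidelity_report> 100/100 variants inserted
#>   DEL: 30/30
#>   INS: 35/35
#>   SNV: 35/35
#>   KS target vs observed VAF: D = 0.07, p = 0.967
```

All 100 requested variants were inserted, and the KS test cannot
distinguish the observed allele-fraction distribution from the requested
one (p = 0.97): the spike-in reproduces the designed VAFs up to binomial
counting noise at 1,000x.

```r
# 5. benchmark a (mock) caller VCF against the truth
truth <- read_vcf(tumor$truth_vcf)
calls <- truth[seq(1, nrow(truth), by = 2), ]   # a caller that finds half
cfg <- match_config(mode = "tumor_only", germline = normal$germline)
m <- compute_metrics(match_calls(truth, calls, cfg, ref = fx$ref))
m$overall
#>   tp fp fn tpr ppv fdr
#> 1 50  0 50 0.5   1   0
```

A caller reporting every other truth variant scores sensitivity 0.5 at
perfect precision, as it should. With real callers, point `read_vcf()` at
their output VCFs; `render_report()` writes the long-format TSV/JSON
report across samples, callers and modes.

A thin command-line wrapper with the same stages
(`make-fixture`, `simulate-normal`, `full-run`, `dream-preset`,
`downsample`, `evaluate`) ships in `inst/cli/deepspike`.

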