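---
title: "Simulating ultra-deep targeted sequencing with low-fraction somatic spike-ins"
author: "deepspike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ultra-deep targeted sequencing with low-fraction somatic spike-ins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Somatic variants in liquid-biopsy material occur at low allele fractions:
circulating tumor DNA is a small minority of the cell-free DNA in plasma, so
a clonal tumor mutation may be supported by well under 5% of the reads even
at ultra-deep (10,000x+) targeted coverage. Benchmarking variant callers in
this regime requires samples whose somatic content is *known*, which real
specimens cannot provide. deepspike builds such samples end to end:

1. **Artificial normal samples.** Paired-end reads are simulated over a
   target panel at a requested mean depth, on top of a germline mutational
   background planted at 50%/100% allele fraction.
2. **Somatic spike-in.** Low-VAF SNVs and indels are introduced by editing
   the aligned reads directly, with consistent CIGAR rewriting, yielding a
   tumor BAM plus a truth VCF of exactly the variants that made it in.
3. **Benchmarking.** Caller VCFs are compared against the truth with
   germline exclusion, allele normalization and exact matching, in
   tumor-only or tumor-normal paired mode, producing TPR/PPV/FDR overall
   and per VAF bin / variant type.

Because the simulator knows every read's true origin, reads are emitted
pre-aligned: the alignment is exact by construction and no external aligner
is needed. FASTQ export (`write_fastq()`) is available for users who want
to push reads through a real aligner and accept its noise.

## The sequencing model

`sequencing_model()` is a parametric description of the instrument, not a
model learned from data — users who have platform-specific numbers supply
them as parameters (or a YAML config via `load_model()`):

* `read_length` (default 150 bp) and a fragment-length distribution,
  normal with mean 350 bp / sd 50 bp, truncated below the read length.
  These are ordinary short-insert Illumina library values.
* A per-cycle quality profile decaying linearly Q37 to Q30, sd 3, clipped
  to [2, 41]. Substitution errors are drawn per base at the Phred-implied
  rate `10^(-q/10)`; `error_scale` rescales it, and `error_scale = 0` gives
  an error-free instrument, which the test suite uses whenever exact pileup
  arithmetic is asserted.
* An optional piecewise-linear GC bias curve over fragment GC fraction,
  normalised to mean 1 so it redistributes coverage without changing the
  genome-wide mean; the default is flat.
* `strand_balance`, the probability a fragment is forward-oriented (0.5).

Fragment placement is uniform over the region extended by one fragment
length at each side, so every base *inside* a target region has identical
expected depth and coverage tapers naturally outside the region edges. The
number of fragments per region is `coverage * (L + frag_mean - 1) /
(2 * read_length)`, which makes the expected in-region per-base depth equal
the requested coverage; empirically the realised mean depth lands within
about 1% of the request, and the acceptance suite holds it to 5%.

## The mutational model

`mutation_model()` plants the germline background:

* `rate` (default 0.016 variants/bp) is a documented constant chosen so a
  three-gene panel of roughly 186 kb carries on the order of 3,000
  background variants — the density a normal human sample shows on a
  typical hereditary-cancer panel. It is a stand-in, not a claim about any
  particular genome.
* The type mix is 89.24% SNV, 5.21% insertion, 5.55% deletion, matching
  the composition of germline backgrounds in normal samples.
* Indel lengths follow a geometric distribution (p = 0.3) truncated at
  10 bp — a one-parameter family that matches the sharply decaying
  empirical indel length spectrum.
* `het_fraction = 1`: every background variant is heterozygous, planted on
  one of the two region haplotypes, so its expected allele fraction is
  50%. Homozygous planting (both haplotypes, VAF 1.0) is available by
  lowering `het_fraction`.
* SNV alternate alleles respect a transition/transversion ratio of 2.

Each target region is materialised as a *pair of haplotypes*: the padded
reference sequence with the allele's variants applied, plus a per-base map
back to reference coordinates. Reads are drawn from one haplotype with
probability 0.5, and their CIGARs are derived from that coordinate map, so
indel-spanning reads carry correct I/D operations without any alignment
step.

## The spike-in sampler

For each somatic spec (position, alleles, target VAF), the fragments whose
reads cover the site are enumerated and each is selected independently with
probability equal to the target VAF — Bernoulli thinning at the fragment
level, which preserves the binomial VAF noise real data shows at finite
depth. Two details matter:

* **At least one supporting read.** If the Bernoulli draw selects no
  fragment at an adequately covered site, one fragment is force-selected.
  Without this, the lowest-VAF variants would silently vanish from the
  truth set; with it, a variant with target VAF 0.08% at 30,000x is still
  present, just near its expected ~24 supporting reads.
* **Pair consistency.** Every read of a selected fragment that covers the
  site is edited, so mates never disagree about the allele.

SNVs are spiked first, indels second, in two separate passes. SNV edits
replace one base and leave qualities untouched. Indel edits rebuild the
read's reference map: insertions splice the new bases after the anchor
(qualities copied from the anchor base) and truncate at the 3' end;
deletions remove the covered deleted bases and refill the 3' end from the
reference past the read's old endpoint. Read length is therefore invariant
under editing, and the CIGAR is re-derived from the edited map (a deletion
turns `150M` into e.g. `75M3D75M` with the sequence still 150 bp). Reads
whose alignment *starts inside* a deletion are left unedited — they count
toward depth but not toward the mutated reads — a conservative choice that
avoids shifting alignments. An insertion whose bases would run off the 3'
end is soft-clipped rather than emitted as a trailing I operation.

The observed VAF of a spiked site is `reads_mutated / depth_at_site`,
counting reads (not fragments), and the truth VCF records this observed
value in `INFO/VAF` (keys `VAF`, `VTYPE` and `ORIGIN` are this package's
own convention, documented here because no standard truth-VAF key exists).
For long deletions the observed VAF sits systematically below the target:
depth at a deletion counts every read overlapping its span, including reads
that start inside it and cannot be edited. This mirrors what a pileup-based
caller would measure at such a site.

`verify_spike_in()` summarises a run: insertion successes per type and a
two-sample Kolmogorov–Smirnov test between the target and observed VAF
distributions of the inserted variants. At ultra-deep coverage the binomial
noise is small relative to the VAF range, so an undistorted sampler yields
a high KS p-value; the acceptance suite requires p > 0.05 over a
1,000-variant cohort.

### Site placement and the guard distance

`generate_specs()` draws sites uniformly over the target, VAFs uniformly
over the requested range (the range is the study condition; nothing in the
sampler favours either end), and indel lengths uniformly up to
`max_indel_len`. Placement excludes:

* germline allele spans plus a guard of 5 bp on each side — a somatic edit
  inside a heterozygous germline deletion would see only half the
  fragments and distort its allele fraction;
* other somatic *anchors* plus the same guard. Somatic indel spans may
  overlap other sites: two variants at VAF ≤ 5% live on essentially
  disjoint fragment subsets, so interference is second-order, and
  forbidding span overlap would make dense designs (100 indels up to 90 bp
  in a 5 kb target) geometrically unplaceable.

The guard is configurable. A much larger guard (say, a read length) makes
dense panels infeasible; 5 bp is enough to keep alleles distinct and
normalization windows from colliding in random sequence, where homopolymer
runs are short. Panels with long homopolymers may warrant a larger value.

### Depth window

Spike functions accept a `[min_depth, max_depth]` window and skip sites
outside it (`inserted = FALSE`), the usual protection against editing
abnormally covered sites. Site depth fluctuates around the sample coverage
(sd roughly `sqrt(coverage)`), so a window pinned exactly at the nominal
coverage would reject about half of all sites; the cohort presets therefore
default to `max_depth = 2 * coverage` with a small `min_depth`, keeping the
window tied to the sample's depth scale while accepting ordinary
fluctuation.

## Benchmarking

Truth and calls are matched on the exact `(contig, pos, ref, alt)` key
after normalization — shared-suffix/prefix trimming with left-alignment of
indels through repeats, the standard parsimony procedure, implemented here
because no installed package exposes it as a per-record operation.
Germline variants (or a matched normal's call set, in paired mode) are
removed from the calls before comparison, and a variant-type scope filter
can restrict the evaluation to SNVs or indels only. Exact matching is
conservative and reproducible; no positional fuzz is applied, so a caller
must represent the allele correctly (after normalization) to score a TP.
Metrics follow the standard definitions — TPR = TP/(TP+FN),
PPV = TP/(TP+FP), FDR = 1 − PPV — with empty denominators reported as
missing rather than 0/0, stratified by variant type and by VAF bin with
default edges at 0.1/0.5/1/2/5%, covering the low-fraction range.

Truth means *inserted* variants only: a spec that failed to insert is not
part of the ground truth, so callers are never penalised for missing a
variant that is not in the BAM.

Downsampling retains each fragment (both mates) with probability equal to
the requested fraction under a fixed seed — reproducible, orphan-free, and
binomially exact. The titration schedule (2–8% in steps of 2%, then
20–80% in steps of 20%) is available as `downsample_schedule()`. The
train/test split (`make_split()`) deterministically assigns, per
composition label, the lexicographically first seven samples to training,
reproducing a 14-train / 6-test protocol on a 10+10 cohort.

## What the synthetic fixtures do and do not emulate

`make_fixture()` generates an i.i.d. random contig at a target GC fraction
with a centered panel of 1–3 regions. This reproduces the *geometry* of a
targeted panel at desk scale, but not the sequence pathology of real
genomes: no long homopolymers, no segmental duplications, no mappability
issues, no SNP density structure. Consequently a spike-in completeness of
100% on synthetic fixtures is an upper bound; on real panel sequence a few
sites fail for sequence-context reasons, and the benchmark layer is
agnostic to where the BAMs came from. Likewise, passing VAF-fidelity tests
here demonstrates the sampler is unbiased, not that any particular caller
will behave well on real data.

## Numerical and design choices

* All randomness flows through explicit integer seeds; every operation is
  bit-reproducible given (inputs, seed). Cohort runs derive per-stage
  seeds from per-sample seeds.
* Qualities are integers in [2, 41]; error bases are substituted uniformly
  among the three alternatives.
* Reads are kept as plain data-frame columns (position, CIGAR, sequence,
  quality strings); BAM round-trips go through Rsamtools/htslib, which
  also validates our CIGARs independently.
* Degenerate inputs: regions shorter than the requested indel length are
  rejected at spec generation; a coverage so low that a region receives no
  fragments warns rather than errors; an empty spec list yields a tumor
  identical to the normal plus an empty truth set.
* Problem sizes in the acceptance suite: one 5 kb target at 30,000x for
  indel completeness, ten 3 kb targets at 30,000x for SNV completeness and
  VAF fidelity, a 20 kb panel at 2,000x for germline VAF recovery, and a
  50 kb panel at 30x for the read-geometry preset. These reproduce the
  study conditions at panel rather than exome scale.

## Known limitations

* No duplicate marking, UMIs, or sequencer-specific artifact spectra
  (e.g. oxidative damage); the error model is substitution-only.
* Indel spike-in does not re-align edited reads; reads starting inside a
  spiked deletion keep their original alignment.
* The germline rate is a documented constant, not a learned model; it is
  not claimed equivalent to any specific reference cell line.
* Structural variants and copy-number events are out of scope, as is
  executing variant callers — the benchmark consumes their VCFs as files.
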