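# Desk-scale fixtures and end-to-end presets: a synthetic reference/panel
# generator standing in for a real gene panel, the full
# normal -> spike -> truth pipeline over a cohort, and the
# DREAM-challenge-comparable preset.

#' Generate a synthetic reference and target panel
#'
#' A random-sequence contig with a configurable GC fraction plus a BED-style
#' panel of 1-3 gene-like target regions, as a desk-scale stand-in for a
#' real targeted panel. Deterministic under a fixed seed.
#'
#' @param seed integer seed.
#' @param size contig length in bp (>= 1 kb).
#' @param gc target GC fraction.
#' @param n_regions number of target regions (1-3).
#' @param region_length total target length in bp; defaults to
#'   `size - 2 * margin`. Regions are centered and evenly spaced.
#' @param margin bp kept free of targets at each contig end so fragments
#'   overhanging a region stay on the contig.
#' @param contig contig name.
#' @param out_dir when given, `fixture.fa` and `fixture.bed` are written
#'   there.
#' @return list with `ref` (a [Biostrings::DNAStringSet]), `regions`
#'   ([GenomicRanges::GRanges]), and `fasta`/`bed` paths when written.
#' @export
make_fixture <- function(seed = 7L, size = 20000L, gc = 0.45,
                         n_regions = 1L, region_length = NULL,
                         margin = 1000L, contig = "chrS", out_dir = NULL) {
  size <- as.integer(size)
  if (size < 1000L) stop("size must be >= 1 kb")
  stopifnot(n_regions >= 1L, n_regions <= 3L, gc > 0, gc < 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste0(sample(names(p), size, replace = TRUE, prob = p),
                collapse = "")
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- contig
  avail_start <- margin + 1L
  avail_end <- size - margin
  if (is.null(region_length)) region_length <- avail_end - avail_start + 1L
  region_length <- as.integer(region_length)
  if (region_length > avail_end - avail_start + 1L) {
    stop("region_length does not fit inside the contig margins")
  }
  per <- region_length %/% n_regions
  gap <- if (n_regions > 1L) {
    (avail_end - avail_start + 1L - region_length) %/% (n_regions - 1L)
  } else 0L
  # center the panel
  used <- per * n_regions + gap * (n_regions - 1L)
  off <- avail_start + (avail_end - avail_start + 1L - used) %/% 2L
  starts <- off + (seq_len(n_regions) - 1L) * (per + gap)
  regions <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = starts, width = per),
    seqlengths = structure(size, names = contig))
  out <- list(ref = ref, regions = regions)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fasta <- file.path(out_dir, "fixture.fa")
    Biostrings::writeXStringSet(ref, fasta)
    bed <- file.path(out_dir, "fixture.bed")
    write_bed(regions, bed)
    out$fasta <- fasta
    out$bed <- bed
  }
  out
}

#' Run the full simulation pipeline over a cohort
#'
#' For each sample: plant a germline background and simulate the normal
#' sample, generate a unique somatic variant set, spike it in, and emit the
#' tumor BAM / truth VCF / fidelity report. All per-sample randomness is
#' derived from `seeds`; rerunning with the same configuration reproduces
#' identical truth sets.
#'
#' @param ref,regions reference and target regions.
#' @param sm,mm sequencing and mutation models.
#' @param coverage mean target depth per sample.
#' @param n_samples cohort size.
#' @param seeds one integer per sample (default `1:n_samples`).
#' @param somatic list describing the somatic design: `n` (variants per
#'   sample), `vtypes`, `vaf_range`, `max_indel_len`; `NULL` for a
#'   normal-only run.
#' @param min_depth,max_depth spike depth window; `NULL` `max_depth`
#'   defaults to twice the coverage.
#' @param out_dir output directory.
#' @param write_bam write per-sample BAMs (normal + tumor).
#' @param sample_prefix prefix for sample ids.
#' @return list of per-sample lists with elements `normal` and (when a
#'   somatic design is given) `tumor`; a `manifest.json` run manifest is
#'   written to `out_dir`.
#' @export
run_cohort <- function(ref, regions, sm = default_sequencing_model(),
                       mm = default_mutation_model(), coverage,
                       n_samples = 1L, seeds = seq_len(n_samples),
                       somatic = list(n = 100L, vtypes = "SNV",
                                      vaf_range = c(0.001, 0.05),
                                      max_indel_len = 90L),
                       min_depth = 2L, max_depth = NULL,
                       out_dir = tempdir(), write_bam = TRUE,
                       sample_prefix = "sample") {
  stopifnot(length(seeds) >= n_samples)
  if (is.null(max_depth)) max_depth <- 2 * coverage
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cohort <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    sid <- sprintf("%s%02d", sample_prefix, i)
    normal <- make_normal_sample(ref, regions, sm, mm, coverage,
                                 seed = seeds[i], out_dir = out_dir,
                                 sample_id = sid, write_bam = write_bam,
                                 keep_reads = TRUE)
    entry <- list(normal = normal)
    if (!is.null(somatic)) {
      set.seed(seeds[i] + 500000L)
      sub <- sample.int(.Machine$integer.max, 2L)
      specs <- generate_specs(regions, ref, germline = normal$germline,
                              n = somatic$n,
                              vtypes = somatic$vtypes,
                              vaf_range = somatic$vaf_range,
                              max_indel_len = somatic$max_indel_len %||% 90L,
                              seed = sub[1L])
      entry$tumor <- make_tumor_sample(normal, specs, ref,
                                       min_depth = min_depth,
                                       max_depth = max_depth,
                                       seed = sub[2L], out_dir = out_dir,
                                       write_bam = write_bam)
      entry$specs <- specs
    }
    # reads were only kept to avoid a BAM round trip between stages
    entry$normal$reads <- NULL
    cohort[[i]] <- entry
  }
  manifest <- list(
    n_samples = n_samples, coverage = coverage,
    read_length = sm$read_length, seeds = seeds[seq_len(n_samples)],
    somatic = somatic,
    samples = lapply(cohort, function(e) {
      list(sample_id = e$normal$sample_id,
           normal_bam = e$normal$bam,
           germline_vcf = e$normal$germline_vcf,
           tumor_bam = if (!is.null(e$tumor)) e$tumor$tumor_bam,
           truth_vcf = if (!is.null(e$tumor)) e$tumor$truth_vcf,
           n_inserted = if (!is.null(e$tumor)) e$tumor$fidelity$n_inserted)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DREAM-challenge-comparable preset
#'
#' Generates a cohort with the DREAM synthetic-dataset characteristics:
#' coverage 30x, read length 101, 100 random SNVs per sample with VAF
#' uniform on [0.3, 0.5].
#'
#' @param ref,regions reference and target regions (a synthetic fixture is
#'   acceptable).
#' @param out_dir output directory.
#' @param n_samples cohort size (default 10).
#' @param seeds per-sample seeds.
#' @param write_bam write BAMs.
#' @return the [run_cohort()] result; the preset's configuration is
#'   attached as the `config` attribute.
#' @export
dream_preset <- function(ref, regions, out_dir = tempdir(),
                         n_samples = 10L, seeds = seq_len(n_samples),
                         write_bam = TRUE) {
  sm <- sequencing_model(read_length = 101L)
  cohort <- run_cohort(ref, regions, sm = sm,
                       mm = default_mutation_model(), coverage = 30,
                       n_samples = n_samples, seeds = seeds,
                       somatic = list(n = 100L, vtypes = "SNV",
                                      vaf_range = c(0.3, 0.5),
                                      max_indel_len = 0L),
                       min_depth = 2L, max_depth = Inf,
                       out_dir = out_dir, write_bam = write_bam,
                       sample_prefix = "dream")
  attr(cohort, "config") <- list(coverage = 30, read_length = 101L,
                                 n_snv = 100L, vaf_range = c(0.3, 0.5),
                                 n_samples = n_samples)
  cohort
}

#' Load a run configuration from YAML
#'
#' Keys: `reference` (FASTA path), `regions` (BED path), `coverage`,
#' `n_samples`, `seeds`, `out_dir`, optional `sequencing_model` /
#' `mutation_model` blocks (constructor arguments) and a `somatic` block
#' (`n_variants`, `vtypes`, `vaf_range`, `max_indel_len`; `n_variants`
#' rather than `n`, which YAML 1.1 would read as a boolean).
#'
#' @param path YAML config.
#' @return list of arguments ready for [run_cohort()].
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("reference", "regions", "coverage")) {
    if (is.null(cfg[[k]])) stop("run config misses required key: ", k)
  }
  ref <- load_reference(cfg$reference)
  regions <- load_regions(cfg$regions, ref)
  sm <- if (!is.null(cfg$sequencing_model)) {
    do.call(sequencing_model, cfg$sequencing_model)
  } else default_sequencing_model()
  mm <- if (!is.null(cfg$mutation_model)) {
    cfg$mutation_model$type_probs <- unlist(cfg$mutation_model$type_probs) %||%
      NULL
    do.call(mutation_model, cfg$mutation_model[
      !vapply(cfg$mutation_model, is.null, TRUE)])
  } else default_mutation_model()
  somatic <- cfg$somatic
  if (!is.null(somatic)) {
    if (!is.null(somatic$n_variants)) {
      somatic$n <- somatic$n_variants
      somatic$n_variants <- NULL
    }
    if (!is.null(somatic$vaf_range)) {
      somatic$vaf_range <- as.numeric(unlist(somatic$vaf_range))
    }
  }
  list(ref = ref, regions = regions, sm = sm, mm = mm,
       coverage = cfg$coverage,
       n_samples = cfg$n_samples %||% 1L,
       seeds = as.integer(unlist(cfg$seeds %||% seq_len(cfg$n_samples %||% 1L))),
       somatic = somatic,
       out_dir = cfg$out_dir %||% ".")
}
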