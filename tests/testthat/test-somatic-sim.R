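# somatic variant generation and spike-in

test_that("generate_specs honours counts, ranges and exclusions", {
  fx <- small_fixture()
  sn <- small_normal()
  germ <- sn$pg$variants

  expect_equal(nrow(generate_specs(fx$regions, fx$ref, germ, n = 0,
                                   seed = 1)), 0L)

  specs <- generate_specs(fx$regions, fx$ref, germ, n = 200,
                          vtypes = c("SNV", "INS", "DEL"),
                          vaf_range = c(0.001, 0.05), max_indel_len = 3,
                          seed = 2)
  expect_equal(nrow(specs), 200L)
  expect_true(all(specs$target_vaf >= 0.001 & specs$target_vaf <= 0.05))
  ind <- specs$vtype != "SNV"
  expect_true(all(specs$indel_len[ind] >= 1L & specs$indel_len[ind] <= 3L))
  expect_true(all(specs$indel_len[!ind] == 0L))
  expect_true(all(specs$pos >= GenomicRanges::start(fx$regions)[1] &
                    specs$pos <= GenomicRanges::end(fx$regions)[1]))
  # anchors keep the guard distance from each other and germline spans
  d <- diff(sort(specs$pos))
  expect_true(all(d > 5L))
  for (i in seq_len(nrow(germ))) {
    span <- nchar(germ$ref[i]) - 1L
    expect_false(any(specs$pos >= germ$pos[i] - 5L &
                       specs$pos <= germ$pos[i] + span + 5L))
  }
  # alleles are reference-consistent, SNV alt differs from ref
  expect_true(all(deepspike:::ref_consistent(
    variant_records(specs$contig, specs$pos, specs$ref, specs$alt,
                    vtype = specs$vtype), fx$ref)))
  expect_true(all(specs$ref[!ind] != specs$alt[!ind]))

  # determinism
  specs2 <- generate_specs(fx$regions, fx$ref, germ, n = 200,
                           vtypes = c("SNV", "INS", "DEL"),
                           vaf_range = c(0.001, 0.05), max_indel_len = 3,
                           seed = 2)
  expect_identical(specs, specs2)

  # an unplaceable request fails with a count
  tiny <- GenomicRanges::GRanges("chrS", IRanges::IRanges(5001, 5100))
  expect_error(generate_specs(tiny, fx$ref, NULL, n = 500, seed = 3),
               "could only place")
})

test_that("SNV spike hits the binomial target and guarantees support", {
  sn <- small_normal()
  fx <- sn$fx
  # deeper sample for a stable depth of ~1000
  pg <- plant_germline(fx$ref, fx$regions, mutation_model(rate = 0.002),
                       seed = 41, pad = 700)
  reads <- simulate_reads(pg$haplotypes, exact_model(), coverage = 1000,
                          seed = 42)
  specs <- generate_specs(fx$regions, fx$ref, pg$variants, n = 25,
                          vaf_range = c(0.04999, 0.05001), seed = 43)
  res <- spike_snvs(reads, specs, min_depth = 2, max_depth = Inf,
                    seed = 44)$results
  expect_true(all(res$inserted))
  # reads_mutated ~ Binomial(depth, 0.05): each site within 3 SD + the
  # one-read floor
  sd3 <- 3 * sqrt(res$depth_at_site * 0.05 * 0.95)
  expect_true(all(abs(res$reads_mutated - res$depth_at_site * 0.05) <
                    sd3 + 1))
  # a tiny VAF still gets >= 1 supporting read at adequate depth
  lo <- generate_specs(fx$regions, fx$ref, pg$variants, n = 10,
                       vaf_range = c(1e-6, 2e-6), seed = 45)
  res_lo <- spike_snvs(reads, lo, min_depth = 2, max_depth = Inf,
                       seed = 46)$results
  expect_true(all(res_lo$reads_mutated >= 1L))
  expect_true(all(res_lo$inserted))
})

test_that("sites outside the depth window are skipped, not edited", {
  sn <- small_normal()
  specs <- generate_specs(sn$fx$regions, sn$fx$ref, sn$pg$variants, n = 5,
                          vaf_range = c(0.01, 0.05), seed = 51)
  skip_hi <- spike_snvs(sn$reads, specs, min_depth = 2, max_depth = 10,
                        seed = 52)
  expect_true(all(!skip_hi$results$inserted))
  expect_identical(skip_hi$reads$seq, sn$reads$seq)
  skip_lo <- spike_snvs(sn$reads, specs, min_depth = 1e6, max_depth = Inf,
                        seed = 53)
  expect_true(all(!skip_lo$results$inserted))
})

test_that("spike-in conserves reads and keeps mate pairs consistent", {
  sn <- small_normal()
  fx <- sn$fx
  specs <- generate_specs(fx$regions, fx$ref, sn$pg$variants, n = 40,
                          vtypes = c("SNV", "INS", "DEL"),
                          vaf_range = c(0.05, 0.2), max_indel_len = 12,
                          seed = 61)
  snv <- specs[specs$vtype == "SNV", ]
  ind <- specs[specs$vtype != "SNV", ]
  s1 <- spike_snvs(sn$reads, snv, seed = 62)
  s2 <- spike_indels(s1$reads, ind, fx$ref, seed = 63)
  out <- s2$reads
  # read-count conservation and identity of read names
  expect_equal(nrow(out), nrow(sn$reads))
  expect_identical(out$qname, sn$reads$qname)
  # read length preserved through indel edits
  expect_true(all(nchar(out$seq) == 150L))
  expect_true(all(deepspike:::cigar_query_width(out$cigar) == 150L))
  # pair consistency at SNV sites: within a fragment, no ref/alt disagreement
  for (i in which(s1$results$inserted)) {
    p <- snv$pos[i]
    ridx <- which(out$pos <= p &
                    out$pos + deepspike:::cigar_ref_width(out$cigar) - 1L >= p)
    qoff <- deepspike:::query_offsets_at(out$pos[ridx], out$cigar[ridx], p)
    ok <- !is.na(qoff)
    base <- substr(out$seq[ridx[ok]], qoff[ok], qoff[ok])
    carrier <- tapply(base == snv$alt[i], out$fragment_id[ridx[ok]],
                      function(z) all(z) || all(!z))
    expect_true(all(carrier))
  }
})

test_that("indel edits rewrite CIGARs correctly at full insertion rate", {
  sn <- small_normal()
  fx <- sn$fx
  specs <- generate_specs(fx$regions, fx$ref, sn$pg$variants, n = 30,
                          vtypes = c("INS", "DEL"),
                          vaf_range = c(0.05, 0.2), max_indel_len = 12,
                          seed = 71)
  res <- spike_indels(sn$reads, specs, fx$ref, seed = 72)
  expect_true(all(res$results$inserted))
  # a deletion shows as <len>D in edited reads; an insertion as <len>I
  for (i in seq_len(nrow(specs))) {
    p <- specs$pos[i]
    il <- specs$indel_len[i]
    op <- if (specs$vtype[i] == "DEL") "D" else "I"
    pat <- paste0("(^|[0-9A-Z])", il, op)
    edited <- grepl(pat, res$reads$cigar) &
      res$reads$pos <= p &
      res$reads$pos + 200L >= p
    expect_gte(sum(edited), res$results$reads_mutated[i] * 0.5)
  }
  # pileup recovers the observed VAF within 3 binomial SD of target
  pv <- pileup_vaf(res$reads, data.frame(contig = specs$contig,
                                         pos = specs$pos, ref = specs$ref,
                                         alt = specs$alt,
                                         vtype = specs$vtype))
  sd3 <- 3 * sqrt(specs$target_vaf * (1 - specs$target_vaf) / pv$depth)
  expect_true(all(abs(pv$vaf - specs$target_vaf) < sd3 + 3 / pv$depth))
})

test_that("observed VAF in results matches an independent pileup", {
  sn <- small_normal()
  fx <- sn$fx
  specs <- generate_specs(fx$regions, fx$ref, sn$pg$variants, n = 30,
                          vaf_range = c(0.02, 0.1), seed = 81)
  res <- spike_snvs(sn$reads, specs, seed = 82)
  bam <- file.path(tempdir(), "spiked.bam")
  write_alignments(res$reads, bam, fx$ref)
  back <- read_alignments(bam)
  pv <- pileup_vaf(back, data.frame(contig = specs$contig, pos = specs$pos,
                                    ref = specs$ref, alt = specs$alt,
                                    vtype = specs$vtype))
  expect_true(all(abs(pv$alt_count - res$results$reads_mutated) <= 1L))
})

test_that("fidelity report counts and KS behave as specified", {
  res <- data.frame(contig = "chrS", pos = 1:100, ref = "A", alt = "T",
                    vtype = "SNV", target_vaf = runif(100, 0.01, 0.05),
                    inserted = rep(c(TRUE, FALSE), c(97, 3)),
                    depth_at_site = 1000L, reads_mutated = 10L,
                    observed_vaf = NA_real_)
  res$observed_vaf[res$inserted] <- res$target_vaf[res$inserted]
  rep <- verify_spike_in(res)
  expect_equal(rep$n_requested, 100L)
  expect_equal(rep$n_inserted, 97L)
  expect_lte(rep$n_inserted, rep$n_requested)
  # identical target and observed samples: D = 0, p = 1
  expect_equal(rep$ks_statistic, 0)
  expect_equal(rep$ks_pvalue, 1)
  # serialises to JSON
  path <- tempfile(fileext = ".json")
  verify_spike_in(res, path = path)
  j <- jsonlite::read_json(path)
  expect_equal(j$n_inserted, 97L)
  # no inserted variants -> KS absent
  res$inserted <- FALSE
  expect_true(is.na(verify_spike_in(res)$ks_pvalue))
})

test_that("make_tumor_sample leaves the normal untouched and is reproducible", {
  fx <- small_fixture()
  od <- file.path(tempdir(), "ts")
  ns <- make_normal_sample(fx$ref, fx$regions, sm = exact_model(),
                           mm = mutation_model(rate = 0.004),
                           coverage = 120, seed = 91, out_dir = od,
                           sample_id = "t1s", keep_reads = TRUE)
  norm_md5 <- tools::md5sum(ns$bam)
  specs <- generate_specs(fx$regions, fx$ref, ns$germline, n = 25,
                          vtypes = c("SNV", "INS", "DEL"),
                          vaf_range = c(0.05, 0.2), max_indel_len = 6,
                          seed = 92)
  ts1 <- make_tumor_sample(ns, specs, fx$ref, seed = 93, out_dir = od)
  expect_identical(tools::md5sum(ns$bam), norm_md5)
  truth <- read_vcf(ts1$truth_vcf)
  expect_equal(nrow(truth), sum(ts1$results$inserted))
  expect_true(all(truth$origin == "somatic"))
  expect_true(all(!is.na(truth$vaf)))
  # same seed reproduces the truth VCF byte for byte
  ts2 <- make_tumor_sample(ns, specs, fx$ref, seed = 93, out_dir = od)
  expect_identical(readLines(ts1$truth_vcf), readLines(ts2$truth_vcf))
  # zero specs: payload-identical tumor
  ts0 <- make_tumor_sample(ns, specs[0, ], fx$ref, seed = 94,
                           out_dir = od, write_bam = FALSE)
  expect_identical(ts0$reads$seq, ns$reads$seq)
  expect_equal(nrow(read_vcf(ts0$truth_vcf)), 0L)
})
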