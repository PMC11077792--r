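# variant normalization, matching, metrics, downsampling, split, report

test_that("normalization trims shared bases and is idempotent", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c", paste0(strrep("ACGT", 5), "CATTTTTTGCA",
                            strrep("TGCA", 5))), fa)
  ref <- load_reference(fa)
  # shared prefix/suffix: pos 10 CA>CT == pos 11 A>T
  r <- normalize_variants(variant_records("c", 21L, "CA", "CT"), ref)
  # suffix equal? here ref at 21-22 is "CA"; "CA" -> "CT" trims prefix C
  expect_equal(r$pos, 22L)
  expect_equal(r$ref, "A")
  expect_equal(r$alt, "T")
  expect_true(r$ref_ok)

  # already-minimal SNV unchanged
  b <- deepspike:::ref_slice(ref, "c", 5L, 5L)
  s <- normalize_variants(variant_records("c", 5L,
                                          b, setdiff(c("A", "C"), b)[1]),
                          ref)
  expect_equal(s$pos, 5L)
  expect_equal(nchar(s$ref), 1L)

  # ref mismatch flagged
  bad <- normalize_variants(variant_records("c", 5L,
                                            setdiff(c("A", "G"), b)[1], "T"),
                            ref)
  expect_false(bad$ref_ok)
})

test_that("right-shifted homopolymer deletions left-align to the truth", {
  # reference carries TTTTTT at positions 23-28 (CA TTTTTT GCA)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c", paste0(strrep("ACGT", 5), "CATTTTTTGCA",
                            strrep("TGCA", 5))), fa)
  ref <- load_reference(fa)
  hp_start <- 23L
  stopifnot(deepspike:::ref_slice(ref, "c", 23L, 28L) == "TTTTTT")
  # canonical truth: deletion of one T anchored left of the run
  truth <- normalize_variants(
    variant_records("c", hp_start - 1L, "AT", "A"), ref)
  # brute-force oracle: every equivalent representation along the run
  for (k in 0:5) {
    p <- hp_start - 1L + k
    rep_k <- variant_records("c", p,
                             deepspike:::ref_slice(ref, "c", p, p + 1L),
                             deepspike:::ref_slice(ref, "c", p, p))
    norm <- normalize_variants(rep_k, ref)
    expect_equal(norm$pos, truth$pos)
    expect_equal(norm$ref, truth$ref)
    expect_equal(norm$alt, truth$alt)
    # idempotence
    again <- normalize_variants(norm[, names(norm) != "ref_ok"], ref)
    expect_equal(again$pos, norm$pos)
    expect_equal(again$ref, norm$ref)
  }
})

test_that("match_calls performs exact set arithmetic with exclusions", {
  fx <- small_fixture()
  rec <- random_records(fx, 6L, seed = 7L)
  truth <- rec[1:3, ]   # A, B, C
  calls <- rec[c(1, 2, 4), ]  # A, B, D
  cfg <- match_config(normalize = FALSE)
  mr <- match_calls(truth, calls, cfg)
  expect_equal(nrow(mr$tp), 2L)
  expect_equal(nrow(mr$fp), 1L)
  expect_equal(nrow(mr$fn), 1L)

  # a call equal to a germline record contributes nothing
  cfg_g <- match_config(germline = rec[4, , drop = FALSE],
                        normalize = FALSE)
  mr_g <- match_calls(truth, calls, cfg_g)
  expect_equal(nrow(mr_g$fp), 0L)
  expect_equal(nrow(mr_g$tp), 2L)

  # scope filtering drops both sides
  cfg_s <- match_config(scope = "SNV", normalize = FALSE)
  mr_s <- match_calls(truth, calls, cfg_s)
  expect_true(all(mr_s$tp$vtype == "SNV"))
  expect_true(all(mr_s$fp$vtype == "SNV"))
  expect_true(all(mr_s$fn$vtype == "SNV"))

  # duplicate calls collapse
  expect_message(mr_d <- match_calls(truth, rbind(calls, calls[1, ]),
                                     cfg), "collapsed 1 duplicate")
  expect_equal(nrow(mr_d$tp), 2L)

  # paired mode requires an exclusion source
  expect_error(match_config(mode = "paired"), "paired mode requires")
})

test_that("matcher agrees with the brute-force oracle on random instances", {
  fx <- small_fixture()
  pool <- random_records(fx, 300L, seed = 15L)
  cfg <- match_config(normalize = FALSE)
  set.seed(16)
  for (rep in 1:100) {
    truth <- pool[sample(300L, sample(10:60, 1L)), ]
    truth <- truth[!duplicated(deepspike:::variant_key(truth)), ]
    calls <- pool[sample(300L, sample(10:60, 1L)), ]
    calls <- calls[!duplicated(deepspike:::variant_key(calls)), ]
    mr <- match_calls(truth, calls, cfg)
    bf <- brute_force_match(truth, calls)
    expect_equal(nrow(mr$tp), bf$tp)
    expect_equal(nrow(mr$fp), bf$fp)
    expect_equal(nrow(mr$fn), bf$fn)
  }
})

test_that("metric formulas, identities and degenerate cases hold", {
  m <- compute_metrics(2, 1, 1)
  expect_equal(round(m$overall$tpr, 3), 0.667)
  expect_equal(round(m$overall$ppv, 3), 0.667)
  expect_equal(round(m$overall$fdr, 3), 0.333)

  z <- compute_metrics(0, 0, 5)
  expect_true(is.na(z$overall$ppv))
  expect_true(is.na(z$overall$fdr))
  expect_equal(z$overall$tpr, 0)

  p <- compute_metrics(100, 0, 0)
  expect_equal(p$overall$tpr, 1)
  expect_equal(p$overall$ppv, 1)
  expect_equal(p$overall$fdr, 0)

  set.seed(33)
  for (i in 1:20) {
    tp <- rpois(1, 40); fp <- rpois(1, 10); fn <- rpois(1, 10)
    mm <- compute_metrics(tp, fp, fn)$overall
    if (tp + fp > 0) expect_equal(mm$fdr, 1 - mm$ppv)
    if (tp + fn > 0) expect_equal(mm$tpr, tp / (tp + fn))
  }
})

test_that("match-result metrics stratify and respect count identities", {
  fx <- small_fixture()
  pool <- random_records(fx, 120L, seed = 25L)
  pool <- pool[!duplicated(deepspike:::variant_key(pool)), ]
  truth <- pool[1:60, ]
  calls <- pool[31:90, ]
  mr <- match_calls(truth, calls, match_config(normalize = FALSE))
  m <- compute_metrics(mr)
  expect_equal(m$overall$tp + m$overall$fn, nrow(truth))
  expect_equal(m$overall$tp + m$overall$fp, nrow(calls))
  vt <- m$strata[m$strata$stratum == "vtype", ]
  expect_equal(sum(vt$tp), m$overall$tp)
  expect_equal(sum(vt$fp), m$overall$fp)
  expect_equal(sum(vt$fn), m$overall$fn)
})

test_that("downsampling is fragment-exact, seeded and orphan-free", {
  sn <- small_normal()
  reads <- sn$reads
  nfrag <- length(unique(reads$fragment_id))

  # fraction 1.0 keeps everything
  all_kept <- downsample_reads(reads, 1.0, seed = 1)
  expect_equal(nrow(all_kept), nrow(reads))

  kept <- downsample_reads(reads, 0.2, seed = 2)
  kfrag <- length(unique(kept$fragment_id))
  expect_lt(abs(kfrag - 0.2 * nfrag), 3 * sqrt(nfrag * 0.2 * 0.8))
  # no orphan mates
  expect_true(all(table(kept$fragment_id) == 2L))
  # seed-exact reproducibility
  kept2 <- downsample_reads(reads, 0.2, seed = 2)
  expect_identical(kept$qname, kept2$qname)
  # a different seed gives a different subset
  kept3 <- downsample_reads(reads, 0.2, seed = 3)
  expect_false(identical(kept$qname, kept3$qname))

  expect_error(downsample_reads(reads, 0, seed = 1), "fraction")
  expect_error(downsample_reads(reads, 1.2, seed = 1), "fraction")

  # retention is monotone in expectation across the schedule
  fr <- vapply(downsample_schedule(), function(f) {
    nrow(downsample_reads(reads, f, seed = 7))
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("the titration schedule follows the stepwise design", {
  expect_equal(downsample_schedule(),
               c(0.02, 0.04, 0.06, 0.08, 0.20, 0.40, 0.60, 0.80))
})

test_that("downsample_bam round-trips through BAM without orphans", {
  sn <- small_normal()
  bam_in <- file.path(tempdir(), "ds_in.bam")
  write_alignments(sn$reads, bam_in, sn$fx$ref)
  bam_out <- file.path(tempdir(), "ds_out.bam")
  downsample_bam(bam_in, bam_out, 0.5, seed = 5, ref = sn$fx$ref)
  out <- read_alignments(bam_out)
  expect_true(all(table(out$fragment_id) == 2L))
  nfrag <- length(unique(sn$reads$fragment_id))
  expect_lt(abs(length(unique(out$fragment_id)) - 0.5 * nfrag),
            3 * sqrt(nfrag * 0.25))
})

test_that("train/test splits are deterministic and respect the design", {
  ids <- sprintf("s%02d", 1:20)
  comp <- rep(c("snv_only", "snv_indel"), each = 10)
  sp <- make_split(ids, comp)
  expect_length(sp$training_ids, 14L)
  expect_length(sp$test_ids, 6L)
  expect_length(intersect(sp$training_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$training_ids, sp$test_ids), ids)
  sp2 <- make_split(ids, comp)
  expect_identical(sp, sp2)
  expect_error(make_split(ids[1:8], comp[1:8]), "insufficient samples")
})

test_that("reports round-trip through TSV and JSON", {
  fx <- small_fixture()
  pool <- random_records(fx, 80L, seed = 55L)
  pool <- pool[!duplicated(deepspike:::variant_key(pool)), ]
  mr <- match_calls(pool[1:40, ], pool[21:60, ],
                    match_config(normalize = FALSE))
  m <- compute_metrics(mr)
  out <- file.path(tempdir(), "report")
  df <- render_report(list(list(sample = "s01", caller = "callerA",
                                mode = "tumor_only", scope = "both",
                                metrics = m)),
                      out)
  expect_true(file.exists(paste0(out, ".tsv")))
  expect_equal(df$tp[df$stratum == "overall"], m$overall$tp)
  back <- jsonlite::read_json(paste0(out, ".json"), simplifyVector = TRUE)
  ov <- back[back$stratum == "overall", ]
  expect_equal(ov$tpr, m$overall$tpr)
  expect_equal(ov$fdr, m$overall$fdr)
  # counts-only metrics emit no stratum rows
  df0 <- render_report(list(list(sample = "s", caller = "c", mode = "m",
                                 scope = "both",
                                 metrics = compute_metrics(1, 1, 1))),
                       file.path(tempdir(), "report0"))
  expect_equal(nrow(df0), 1L)
})
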