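# Shared fixtures and independent oracles for the test suite. Heavy objects
# are built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# small synthetic panel: 12 kb contig, one 4 kb target
small_fixture <- function() {
  cached("small_fixture", make_fixture(seed = 42L, size = 12000L,
                                       region_length = 4000L))
}

# error-free instrument: exact pileup arithmetic applies
exact_model <- function(read_length = 150L) {
  sequencing_model(read_length = read_length, error_scale = 0)
}

# a modest error-free normal sample shared by several tests
small_normal <- function() {
  cached("small_normal", {
    fx <- small_fixture()
    pg <- plant_germline(fx$ref, fx$regions,
                         mutation_model(rate = 0.004), seed = 5L, pad = 700L)
    reads <- simulate_reads(pg$haplotypes, exact_model(), coverage = 500,
                            seed = 6L)
    list(fx = fx, pg = pg, reads = reads)
  })
}

# write records to a temporary truth VCF and return the path
tmp_vcf <- function(records, ref = NULL) {
  path <- tempfile(fileext = ".vcf")
  write_truth_vcf(records, path, ref = ref)
  path
}

# random variant records over a fixture, for round-trip tests
random_records <- function(fx, n, seed) {
  set.seed(seed)
  pos <- sort(sample(GenomicRanges::start(fx$regions)[1] +
                       seq_len(3000L), n))
  vtype <- sample(c("SNV", "INS", "DEL"), n, replace = TRUE)
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    b <- deepspike:::ref_slice(fx$ref, "chrS", pos[i], pos[i])
    if (vtype[i] == "SNV") {
      ref[i] <- b
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    } else if (vtype[i] == "INS") {
      ref[i] <- b
      alt[i] <- paste0(b, paste0(sample(c("A", "C", "G", "T"), 3L,
                                        replace = TRUE), collapse = ""))
    } else {
      ref[i] <- deepspike:::ref_slice(fx$ref, "chrS", pos[i], pos[i] + 2L)
      alt[i] <- b
    }
  }
  variant_records(contig = "chrS", pos = pos, ref = ref, alt = alt,
                  vaf = round(runif(n, 0.001, 0.5), 4L), vtype = vtype,
                  origin = sample(c("germline", "somatic"), n,
                                  replace = TRUE))
}

# brute-force matcher: for every truth record scan the calls for an exact
# allele match, consuming each call at most once
brute_force_match <- function(truth, calls) {
  used <- rep(FALSE, nrow(calls))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(calls))) {
      if (!used[j] &&
          truth$contig[i] == calls$contig[j] &&
          truth$pos[i] == calls$pos[j] &&
          truth$ref[i] == calls$ref[j] &&
          truth$alt[i] == calls$alt[j]) {
        used[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  list(tp = tp, fp = nrow(calls) - sum(used), fn = nrow(truth) - tp)
}

# independent htslib pileup of one SNV site (depth and per-base counts)
htslib_snv_pileup <- function(bam, contig, pos) {
  pp <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))),
    pileupParam = Rsamtools::PileupParam(distinguish_strands = FALSE,
                                         min_base_quality = 0L,
                                         min_nucleotide_depth = 1L,
                                         max_depth = 10000000L))
  pp[pp$pos == pos & pp$nucleotide %in% c("A", "C", "G", "T"), ]
}
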