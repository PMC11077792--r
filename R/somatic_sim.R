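# Somatic variant generation and spike-in by direct read editing. Fragments
# are selected Bernoulli(target VAF) so the observed allele fraction keeps
# the binomial noise real data would show; a selected fragment has every
# read that overlaps the site edited, so mates never disagree. CIGARs of
# indel-edited reads are rebuilt from the per-base reference map, and read
# length is preserved by filling or truncating at the 3' end.

#' Randomly generate somatic variant specifications
#'
#' Sites are drawn uniformly over the target regions, excluding a guard
#' window around germline variants, previously chosen sites (and their
#' indel spans), and region edges so indels always fit. Target VAFs are
#' drawn uniformly on `vaf_range`.
#'
#' @param regions target [GenomicRanges::GRanges].
#' @param ref reference from [load_reference()].
#' @param germline germline [variant_records()] to keep clear of (may be
#'   empty).
#' @param n number of variants to generate.
#' @param vtypes types to draw from, uniformly: subset of
#'   `c("SNV", "INS", "DEL")`.
#' @param vaf_range `c(lo, hi)` fractions, `0 < lo < hi <= 1`.
#' @param max_indel_len maximum indel length in bp (lengths uniform on
#'   `1:max_indel_len`).
#' @param guard minimum distance in bp between a somatic anchor and any
#'   germline allele span or other somatic anchor. Germline spans are
#'   excluded entirely (a somatic edit inside a heterozygous deletion would
#'   distort its allele fraction); somatic anchors only need to keep the
#'   guard distance from each other — their spans may overlap, as distinct
#'   low-fraction variants live on mostly disjoint fragment subsets.
#' @param seed integer seed.
#' @return a `data.frame` of specs: `contig`, `pos`, `ref`, `alt`, `vtype`,
#'   `target_vaf`, `indel_len`.
#' @export
generate_specs <- function(regions, ref, germline = NULL, n,
                           vtypes = c("SNV"), vaf_range = c(0.001, 0.05),
                           max_indel_len = 90L, guard = 5L, seed = 1L) {
  stopifnot(length(vaf_range) == 2L, vaf_range[1L] < vaf_range[2L],
            vaf_range[1L] > 0, vaf_range[2L] <= 1)
  vtypes <- match.arg(vtypes, c("SNV", "INS", "DEL"), several.ok = TRUE)
  set.seed(seed)
  if (n == 0L) {
    out <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vtype = character(), target_vaf = numeric(),
                      indel_len = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  max_span <- if (any(vtypes != "SNV")) max_indel_len else 0L
  reg_df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions)
  )
  reg_df$hi <- reg_df$end - max_span - 1L
  reg_df <- reg_df[reg_df$hi >= reg_df$start, , drop = FALSE]
  if (nrow(reg_df) == 0L) stop("regions too short for requested indel length")
  wts <- reg_df$hi - reg_df$start + 1L
  # exclusion intervals: germline allele spans +/- guard; somatic anchors
  # +/- guard are appended as sites are placed
  if (!is.null(germline) && nrow(germline) > 0L) {
    gspan <- nchar(germline$ref) - 1L
    ex_ctg <- germline$contig
    ex_lo <- germline$pos - guard
    ex_hi <- germline$pos + gspan + guard
  } else {
    ex_ctg <- character(0)
    ex_lo <- integer(0)
    ex_hi <- integer(0)
  }
  blocked <- function(contig, p, span) {
    any(ex_ctg == contig & p + span >= ex_lo & p <= ex_hi)
  }
  specs <- vector("list", n)
  placed <- 0L
  tries <- 0L
  max_tries <- 200L * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    g <- if (nrow(reg_df) == 1L) 1L else
      sample.int(nrow(reg_df), 1L, prob = wts)
    p <- reg_df$start[g] +
      floor(stats::runif(1L) * (reg_df$hi[g] - reg_df$start[g] + 1L))
    vt <- if (length(vtypes) == 1L) vtypes else
      vtypes[sample.int(length(vtypes), 1L)]
    il <- if (vt == "SNV") 0L else
      sample.int(max_indel_len, 1L)
    if (blocked(reg_df$contig[g], p, 0L)) next
    b <- ref_slice(ref, reg_df$contig[g], p, p)
    if (vt == "SNV") {
      refa <- b
      alta <- BASES[BASES != b][sample.int(3L, 1L)]
      if (!b %in% BASES) alta <- BASES[sample.int(4L, 1L)]
    } else if (vt == "INS") {
      refa <- b
      alta <- paste0(b, paste0(BASES[sample.int(4L, il, replace = TRUE)],
                               collapse = ""))
    } else {
      refa <- ref_slice(ref, reg_df$contig[g], p, p + il)
      alta <- b
    }
    placed <- placed + 1L
    specs[[placed]] <- data.frame(
      contig = reg_df$contig[g], pos = p, ref = refa, alt = alta,
      vtype = vt,
      target_vaf = stats::runif(1L, vaf_range[1L], vaf_range[2L]),
      indel_len = il, stringsAsFactors = FALSE)
    ex_ctg <- c(ex_ctg, reg_df$contig[g])
    ex_lo <- c(ex_lo, p - guard)
    ex_hi <- c(ex_hi, p + guard)
  }
  if (placed < n) {
    stop("could only place ", placed, " of ", n,
         " somatic sites without collision; enlarge regions or lower guard")
  }
  out <- do.call(rbind, specs)
  rownames(out) <- NULL
  out
}

# shared site bookkeeping: per-spec list of indices of overlapping reads
.spec_overlaps <- function(reads, specs) {
  ref_end <- reads$pos + cigar_ref_width(reads$cigar) - 1L
  span <- ifelse(specs$vtype == "DEL", specs$indel_len, 0L)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(specs$pos, specs$pos + span),
    IRanges::IRanges(reads$pos, ref_end)
  )
  by_spec <- split(S4Vectors::subjectHits(hits),
                   factor(S4Vectors::queryHits(hits),
                          levels = seq_len(nrow(specs))))
  list(by_spec = by_spec, ref_end = ref_end)
}

.empty_results <- function(specs) {
  n <- nrow(specs)
  data.frame(contig = specs$contig, pos = specs$pos, ref = specs$ref,
             alt = specs$alt, vtype = specs$vtype,
             target_vaf = specs$target_vaf, inserted = rep(FALSE, n),
             depth_at_site = rep(0L, n), reads_mutated = rep(0L, n),
             observed_vaf = rep(NA_real_, n), stringsAsFactors = FALSE)
}

# Bernoulli fragment selection with the >= 1 supporting-read guarantee
.select_fragments <- function(frag_ids, vaf) {
  uf <- unique(frag_ids)
  sel <- uf[stats::runif(length(uf)) < vaf]
  if (length(sel) == 0L && vaf > 0 && length(uf) > 0L) {
    sel <- uf[sample.int(length(uf), 1L)]
  }
  sel
}

#' Spike SNVs into aligned reads
#'
#' For each spec, fragments with a read whose alignment covers the site (an
#' M base) are enumerated; each is selected independently with probability
#' `target_vaf`, with one fragment force-selected when none is drawn, so a
#' variant with positive target VAF always has at least one supporting
#' read. Both mates of a selected fragment that overlap the site receive
#' the alternate base; base qualities are untouched. Sites whose depth
#' falls outside `[min_depth, max_depth]` are skipped (`inserted = FALSE`).
#'
#' @param reads read table (from [simulate_reads()] or
#'   [read_alignments()]).
#' @param specs SNV rows from [generate_specs()].
#' @param min_depth,max_depth site depth window; outside it the spec is
#'   skipped. The window exists to avoid editing abnormal-depth sites;
#'   `max_depth` should sit comfortably above the sample's nominal coverage
#'   (site depth fluctuates around it).
#' @param seed integer seed.
#' @return list with `reads` (edited table) and `results` (one row per
#'   spec: `inserted`, `depth_at_site`, `reads_mutated`, `observed_vaf`).
#' @export
spike_snvs <- function(reads, specs, min_depth = 2L, max_depth = Inf,
                       seed = 1L) {
  stopifnot(all(specs$vtype == "SNV"))
  set.seed(seed)
  results <- .empty_results(specs)
  if (nrow(specs) == 0L) return(list(reads = reads, results = results))
  ov <- .spec_overlaps(reads, specs)
  simple <- grepl("^[0-9]+M$", reads$cigar)
  seqv <- reads$seq
  for (i in seq_len(nrow(specs))) {
    ridx <- ov$by_spec[[i]]
    ridx <- ridx[reads$contig[ridx] == specs$contig[i]]
    if (length(ridx) == 0L) next
    p <- specs$pos[i]
    qoff <- query_offsets_at(reads$pos[ridx], reads$cigar[ridx], p,
                             simple[ridx])
    elig <- !is.na(qoff)
    depth <- sum(elig)
    results$depth_at_site[i] <- depth
    if (depth < min_depth || depth > max_depth) next
    sel <- .select_fragments(reads$fragment_id[ridx[elig]],
                             specs$target_vaf[i])
    if (length(sel) == 0L) next
    hit <- elig & reads$fragment_id[ridx] %in% sel
    rows <- ridx[hit]
    x <- seqv[rows]
    substr(x, qoff[hit], qoff[hit]) <- specs$alt[i]
    seqv[rows] <- x
    results$inserted[i] <- TRUE
    results$reads_mutated[i] <- length(rows)
    results$observed_vaf[i] <- length(rows) / depth
  }
  reads$seq <- seqv
  list(reads = reads, results = results)
}

# carry the last aligned reference position forward over NA (insertion)
# bases; leading NAs stay NA
.fill_refpos <- function(rp) {
  notna <- !is.na(rp)
  idx <- cumsum(notna)
  out <- rep(NA_integer_, length(rp))
  has <- idx > 0L
  out[has] <- rp[notna][idx[has]]
  out
}

# edit one read for an insertion; returns NULL when ineligible
.edit_read_ins <- function(seq, qual, cigar, pos, p, ins_seq) {
  rp <- cigar_to_refpos(cigar, pos)
  n <- length(rp)
  qa <- match(p, rp)
  if (is.na(qa) || qa >= n) return(NULL)
  ilen <- nchar(ins_seq)
  s <- strsplit(seq, "")[[1L]]
  q <- strsplit(qual, "")[[1L]]
  new_rp <- c(rp[seq_len(qa)], rep(NA_integer_, ilen), rp[(qa + 1L):n])
  new_s <- c(s[seq_len(qa)], strsplit(ins_seq, "")[[1L]], s[(qa + 1L):n])
  new_q <- c(q[seq_len(qa)], rep(q[qa], ilen), q[(qa + 1L):n])
  new_rp <- new_rp[seq_len(n)]
  new_s <- new_s[seq_len(n)]
  new_q <- new_q[seq_len(n)]
  dc <- derive_cigar(new_rp)
  list(seq = paste0(new_s, collapse = ""),
       qual = paste0(new_q, collapse = ""),
       cigar = dc$cigar, pos = dc$pos)
}

# edit one read for a deletion of span (p, p+dlen]; returns NULL when
# ineligible (read must cover the anchor and at least one base beyond it)
.edit_read_del <- function(seq, qual, cigar, pos, p, dlen, ref, contig) {
  rp <- cigar_to_refpos(cigar, pos)
  n <- length(rp)
  qa <- match(p, rp)
  if (is.na(qa) || qa >= n) return(NULL)
  span_end <- p + dlen
  filled <- .fill_refpos(rp)
  after <- seq_len(n) > qa
  drop <- after & !is.na(filled) & filled >= p + 1L & filled <= span_end
  m <- sum(drop)
  if (m == 0L) return(NULL)  # no read base falls in the deleted span
  s <- strsplit(seq, "")[[1L]]
  q <- strsplit(qual, "")[[1L]]
  keep <- !drop
  e <- max(rp, na.rm = TRUE)
  fill_start <- max(e, span_end) + 1L
  fill_end <- min(fill_start + m - 1L, contig_length(ref, contig))
  fill_n <- max(0L, fill_end - fill_start + 1L)
  fill_s <- if (fill_n > 0L) {
    strsplit(ref_slice(ref, contig, fill_start, fill_end), "")[[1L]]
  } else character(0)
  new_rp <- c(rp[keep], if (fill_n > 0L) fill_start:fill_end)
  new_s <- c(s[keep], fill_s)
  new_q <- c(q[keep], rep(q[n], fill_n))
  dc <- derive_cigar(new_rp)
  list(seq = paste0(new_s, collapse = ""),
       qual = paste0(new_q, collapse = ""),
       cigar = dc$cigar, pos = dc$pos)
}

#' Spike insertions and deletions into aligned reads
#'
#' Fragment selection follows [spike_snvs()]. For each selected read that
#' covers the site: insertions splice the new bases after the anchor (CIGAR
#' gains an I operation; inserted-base qualities copy the anchor base);
#' deletions remove the covered deleted bases (CIGAR gains a D operation).
#' Read length is preserved by truncating, or filling from the reference
#' past the read's 3' end, so every edited read keeps its original length.
#' Reads whose alignment starts strictly inside a deletion are left
#' unedited (they count toward depth, not toward the mutated reads).
#'
#' @inheritParams spike_snvs
#' @param specs INS/DEL rows from [generate_specs()].
#' @param ref reference, used for 3' fill sequence.
#' @export
spike_indels <- function(reads, specs, ref, min_depth = 2L, max_depth = Inf,
                         seed = 1L) {
  stopifnot(all(specs$vtype %in% c("INS", "DEL")))
  set.seed(seed)
  results <- .empty_results(specs)
  if (nrow(specs) == 0L) return(list(reads = reads, results = results))
  ov <- .spec_overlaps(reads, specs)
  # work on local column vectors: element assignment stays in place instead
  # of copying a data.frame column per edited read
  seqv <- reads$seq
  qualv <- reads$qual
  cigv <- reads$cigar
  posv <- reads$pos
  fragv <- reads$fragment_id
  ctgv <- reads$contig
  for (i in seq_len(nrow(specs))) {
    ridx <- ov$by_spec[[i]]
    ridx <- ridx[ctgv[ridx] == specs$contig[i]]
    if (length(ridx) == 0L) next
    p <- specs$pos[i]
    is_del <- specs$vtype[i] == "DEL"
    dlen <- specs$indel_len[i]
    clen <- contig_length(ref, specs$contig[i])
    if (p + (if (is_del) dlen else 1L) > clen) {
      next  # indel would extend past the contig
    }
    rl_max <- max(nchar(seqv[ridx]))
    loc_end <- min(clen, p + dlen + 2L * rl_max)
    loc_ref <- ref_slice(ref, specs$contig[i], p, loc_end)
    ref_end <- posv[ridx] + cigar_ref_width(cigv[ridx]) - 1L
    # eligible: alignment covers the anchor and extends beyond it
    simple <- grepl("^[0-9]+M$", cigv[ridx])
    qoff <- query_offsets_at(posv[ridx], cigv[ridx], p, simple)
    covers <- posv[ridx] <= p & ref_end >= p + 1L
    elig <- covers & !is.na(qoff) & qoff < nchar(seqv[ridx])
    depth <- if (is_del) length(ridx) else sum(covers)
    results$depth_at_site[i] <- depth
    if (depth < min_depth || depth > max_depth || !any(elig)) next
    sel <- .select_fragments(fragv[ridx[elig]], specs$target_vaf[i])
    if (length(sel) == 0L) next
    hit <- which(elig & fragv[ridx] %in% sel)
    mutated <- 0L
    fast <- hit[simple[hit]]
    slow <- hit[!simple[hit]]
    if (length(fast)) {
      rows <- ridx[fast]
      w <- nchar(seqv[rows])
      qa <- qoff[fast]
      if (is_del) {
        m <- pmin(dlen, ref_end[fast] - p)
        fill_start <- pmax(ref_end[fast], p + dlen) + 1L
        fill_end <- pmin(fill_start + m - 1L, clen)
        fill_n <- pmax(0L, fill_end - fill_start + 1L)
        tail_m <- w - qa - m + fill_n
        ok <- tail_m >= 1L
        if (any(ok)) {
          rows <- rows[ok]
          fill <- substr(rep(loc_ref, sum(ok)), fill_start[ok] - p + 1L,
                         fill_end[ok] - p + 1L)
          seqv[rows] <- paste0(substr(seqv[rows], 1L, qa[ok]),
                               substr(seqv[rows], qa[ok] + m[ok] + 1L,
                                      w[ok]),
                               fill)
          qualv[rows] <- paste0(substr(qualv[rows], 1L, qa[ok]),
                                substr(qualv[rows], qa[ok] + m[ok] + 1L,
                                       w[ok]),
                                strrep(substr(qualv[rows], w[ok], w[ok]),
                                       fill_n[ok]))
          cigv[rows] <- sprintf("%dM%dD%dM", qa[ok], dlen, tail_m[ok])
          mutated <- mutated + sum(ok)
        }
      } else {
        ins <- substr(specs$alt[i], 2L, nchar(specs$alt[i]))
        ilen <- nchar(ins)
        n_ins <- pmin(ilen, w - qa)
        n_keep <- w - qa - n_ins
        seqv[rows] <- paste0(substr(seqv[rows], 1L, qa),
                             substr(rep(ins, length(rows)), 1L, n_ins),
                             substr(seqv[rows], qa + 1L, w - ilen))
        qualv[rows] <- paste0(substr(qualv[rows], 1L, qa),
                              strrep(substr(qualv[rows], qa, qa), n_ins),
                              substr(qualv[rows], qa + 1L, w - ilen))
        cigv[rows] <- ifelse(
          n_keep > 0L,
          sprintf("%dM%dI%dM", qa, n_ins, n_keep),
          # insertion runs to the read end: unaligned tail is soft-clipped
          sprintf("%dM%dS", qa, n_ins))
        mutated <- mutated + length(rows)
      }
    }
    for (j in slow) {
      row <- ridx[j]
      ed <- if (is_del) {
        .edit_read_del(seqv[row], qualv[row], cigv[row], posv[row], p, dlen,
                       ref, specs$contig[i])
      } else {
        .edit_read_ins(seqv[row], qualv[row], cigv[row], posv[row], p,
                       substr(specs$alt[i], 2L, nchar(specs$alt[i])))
      }
      if (is.null(ed)) next
      seqv[row] <- ed$seq
      qualv[row] <- ed$qual
      cigv[row] <- ed$cigar
      posv[row] <- ed$pos
      mutated <- mutated + 1L
    }
    if (mutated > 0L) {
      results$inserted[i] <- TRUE
      results$reads_mutated[i] <- mutated
      results$observed_vaf[i] <- mutated / depth
    }
  }
  reads$seq <- seqv
  reads$qual <- qualv
  reads$cigar <- cigv
  reads$pos <- posv
  list(reads = reads, results = results)
}

#' Verify spike-in fidelity
#'
#' Counts insertion successes per variant type and compares the target and
#' observed VAF distributions of the inserted variants with a two-sample
#' Kolmogorov-Smirnov test; a high p-value indicates the spike-in process
#' did not distort the requested allele-fraction distribution.
#'
#' @param results rbind of `results` from [spike_snvs()] /
#'   [spike_indels()].
#' @param path optional path to serialise the report as JSON.
#' @return an object of class `fidelity_report`: `n_requested`,
#'   `n_inserted`, `by_type` (per-type requested/inserted), `ks_statistic`,
#'   `ks_pvalue` (NA when fewer than two variants were inserted).
#' @export
verify_spike_in <- function(results, path = NULL) {
  ins <- results$inserted
  by_type <- do.call(rbind, lapply(split(results, results$vtype), function(d) {
    data.frame(vtype = d$vtype[1L], n_requested = nrow(d),
               n_inserted = sum(d$inserted), stringsAsFactors = FALSE)
  }))
  rownames(by_type) <- NULL
  ks_stat <- NA_real_
  ks_p <- NA_real_
  if (sum(ins) >= 2L) {
    kt <- suppressWarnings(
      stats::ks.test(results$target_vaf[ins], results$observed_vaf[ins]))
    ks_stat <- unname(kt$statistic)
    ks_p <- unname(kt$p.value)
  }
  rep <- structure(
    list(n_requested = nrow(results), n_inserted = sum(ins),
         by_type = by_type, ks_statistic = ks_stat, ks_pvalue = ks_p),
    class = "fidelity_report")
  if (!is.null(path)) {
    jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  rep
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report> ", x$n_inserted, "/", x$n_requested,
      " variants inserted\n", sep = "")
  if (!is.null(x$by_type)) {
    for (i in seq_len(nrow(x$by_type))) {
      cat("  ", x$by_type$vtype[i], ": ", x$by_type$n_inserted[i], "/",
          x$by_type$n_requested[i], "\n", sep = "")
    }
  }
  cat("  KS target vs observed VAF: D = ",
      signif(x$ks_statistic, 3), ", p = ", signif(x$ks_pvalue, 3), "\n",
      sep = "")
  invisible(x)
}

#' Build an artificial tumor sample from a normal sample
#'
#' Spikes the given somatic specs into the normal sample's reads (SNVs
#' first, then indels), writes the tumor BAM, the truth VCF of successfully
#' inserted variants (INFO `VAF` carries the observed allele fraction), and
#' the fidelity report. The normal BAM is left untouched and serves as the
#' matched normal in paired-mode benchmarking.
#'
#' @param normal a `normal_sample` from [make_normal_sample()].
#' @param specs spec table from [generate_specs()] (any mix of types).
#' @param ref reference.
#' @param min_depth,max_depth site depth window passed to the spike
#'   functions.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param write_bam write `<sample>.tumor.bam`; disable for in-memory runs.
#' @return an object of class `tumor_sample`: `sample_id`, `tumor_bam`,
#'   `truth_vcf`, `truth` (inserted variant table), `results`, `fidelity`,
#'   and `reads` when `write_bam = FALSE`.
#' @export
make_tumor_sample <- function(normal, specs, ref, min_depth = 2L,
                              max_depth = Inf, seed = 1L,
                              out_dir = tempdir(), write_bam = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  reads <- if (!is.null(normal$reads)) normal$reads else {
    read_alignments(normal$bam)
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, 2L)
  snv <- specs[specs$vtype == "SNV", , drop = FALSE]
  ind <- specs[specs$vtype != "SNV", , drop = FALSE]
  res_s <- spike_snvs(reads, snv, min_depth, max_depth, seed = sub_seeds[1L])
  res_i <- spike_indels(res_s$reads, ind, ref, min_depth, max_depth,
                        seed = sub_seeds[2L])
  reads <- res_i$reads
  results <- rbind(res_s$results, res_i$results)
  sid <- normal$sample_id
  fid_path <- file.path(out_dir, paste0(sid, ".fidelity.json"))
  fidelity <- verify_spike_in(results, path = fid_path)
  ok <- results[results$inserted, , drop = FALSE]
  truth <- variant_records(contig = ok$contig, pos = ok$pos, ref = ok$ref,
                           alt = ok$alt, vaf = ok$observed_vaf,
                           vtype = ok$vtype, origin = "somatic")
  vcf <- file.path(out_dir, paste0(sid, ".truth.vcf"))
  write_truth_vcf(truth, vcf, ref = ref)
  bam <- NULL
  if (write_bam) {
    bam <- file.path(out_dir, paste0(sid, ".tumor.bam"))
    write_alignments(reads, bam, ref)
  }
  res <- list(sample_id = sid, tumor_bam = bam, truth_vcf = vcf,
              truth = truth, results = results, fidelity = fidelity,
              fidelity_json = fid_path)
  if (!write_bam) res$reads <- reads
  class(res) <- "tumor_sample"
  res
}

#' @export
print.tumor_sample <- function(x, ...) {
  cat("<tumor_sample> ", x$sample_id, "\n",
      " inserted: ", x$fidelity$n_inserted, "/", x$fidelity$n_requested,
      " somatic variants\n",
      " truth vcf: ", x$truth_vcf, "\n", sep = "")
  invisible(x)
}
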