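# Artificial normal-sample generation: plant a germline mutational
# background into per-region haplotype pairs, then simulate aligned
# paired-end reads at a requested mean depth straight into BAM. The true
# alignment of every read is known by construction, so no external aligner
# is involved.

## ---- haplotypes ------------------------------------------------------------

# Build one haplotype: the padded region sequence with a set of variants
# applied, plus the per-base map back to reference coordinates (NA for
# inserted bases). Variants must be sorted, non-overlapping and lie inside
# the core region.
build_haplotype <- function(ref, contig, pad_start, pad_end, core_start,
                            core_end, vars) {
  refseq <- ref_slice(ref, contig, pad_start, pad_end)
  if (is.null(vars) || nrow(vars) == 0L) {
    hap <- list(contig = contig, seq = refseq,
                rp = pad_start:pad_end,
                core_start = core_start, core_end = core_end)
    class(hap) <- "haplotype"
    return(hap)
  }
  vars <- vars[order(vars$pos), , drop = FALSE]
  pieces_seq <- vector("list", 2L * nrow(vars) + 1L)
  pieces_rp <- vector("list", 2L * nrow(vars) + 1L)
  k <- 0L
  cur <- pad_start
  for (i in seq_len(nrow(vars))) {
    p <- vars$pos[i]
    r <- vars$ref[i]
    a <- vars$alt[i]
    stopifnot(p >= cur, p + nchar(r) - 1L <= pad_end)
    if (p > cur) {
      k <- k + 1L
      pieces_seq[[k]] <- substr(refseq, cur - pad_start + 1L, p - pad_start)
      pieces_rp[[k]] <- cur:(p - 1L)
    }
    k <- k + 1L
    pieces_seq[[k]] <- a
    # alt base(s): anchor maps to p; extra inserted bases map to NA
    rp <- rep(NA_integer_, nchar(a))
    rp[1L] <- p
    if (nchar(a) == nchar(r) && nchar(a) == 1L) rp <- p  # SNV
    pieces_rp[[k]] <- rp
    cur <- p + nchar(r)
  }
  if (cur <= pad_end) {
    k <- k + 1L
    pieces_seq[[k]] <- substr(refseq, cur - pad_start + 1L,
                              pad_end - pad_start + 1L)
    pieces_rp[[k]] <- cur:pad_end
  }
  hap <- list(contig = contig,
              seq = paste0(unlist(pieces_seq[seq_len(k)]), collapse = ""),
              rp = unlist(pieces_rp[seq_len(k)]),
              core_start = core_start, core_end = core_end)
  stopifnot(nchar(hap$seq) == length(hap$rp))
  class(hap) <- "haplotype"
  hap
}

# cumulative count of "irregular" haplotype offsets: positions where the
# reference map is not a plain +1 walk. A read whose span contains none of
# them aligns as a single M run.
hap_irregular_cumsum <- function(hap) {
  rp <- hap$rp
  n <- length(rp)
  d <- diff(rp)
  irr <- is.na(rp)
  if (n > 1L) {
    step_bad <- is.na(d) | d != 1L
    irr[-n] <- irr[-n] | step_bad
    irr[-1L] <- irr[-1L] | step_bad
  }
  cumsum(irr)
}

#' Plant a germline mutational background
#'
#' For every target region, draws a Poisson number of germline variants at
#' the model rate, places them without positional collisions, assigns
#' heterozygous variants to one random haplotype (expected VAF 0.5) and
#' homozygous ones to both (VAF 1.0), and materialises the two
#' variant-bearing haplotype sequences per region.
#'
#' @param ref reference from [load_reference()].
#' @param regions target [GenomicRanges::GRanges] from [load_regions()].
#' @param mm a [mutation_model()].
#' @param seed integer seed; identical seeds give identical variant sets.
#' @param pad bp of flanking reference kept on each side of a region so that
#'   fragments overlapping the region edges have sequence to draw on.
#' @return list with `haplotypes` (per region, a list of two `haplotype`
#'   objects) and `variants` (a [variant_records()] table, sorted, with
#'   `origin = "germline"` and `vaf` 0.5/1.0 by zygosity).
#' @export
plant_germline <- function(ref, regions, mm, seed = 1L, pad = 1000L) {
  set.seed(seed)
  n_reg <- length(regions)
  haplotypes <- vector("list", n_reg)
  all_vars <- vector("list", n_reg)
  guard <- mm$max_indel_len + 2L
  for (g in seq_len(n_reg)) {
    contig <- as.character(GenomicRanges::seqnames(regions)[g])
    core_start <- GenomicRanges::start(regions)[g]
    core_end <- GenomicRanges::end(regions)[g]
    clen <- contig_length(ref, contig)
    pad_start <- max(1L, core_start - pad)
    pad_end <- min(clen, core_end + pad)
    L <- core_end - core_start + 1L
    n <- stats::rpois(1L, mm$rate * L)
    vars <- NULL
    if (n > 0L) {
      # indel spans must fit inside the core; keep a small margin
      lo <- core_start
      hi <- core_end - mm$max_indel_len - 1L
      if (hi < lo) {
        warning("region ", contig, ":", core_start, "-", core_end,
                " too short for the requested indel lengths; skipped")
        n <- 0L
      } else {
        pos <- integer(0)
        tries <- 0L
        while (length(pos) < n && tries < 200L) {
          cand <- sample(lo:hi, min(n - length(pos), hi - lo + 1L))
          pos <- sort(unique(c(pos, cand)))
          # enforce pairwise spacing >= guard
          while (length(pos) > 1L && any(diff(pos) < guard)) {
            drop <- which(diff(pos) < guard)[1L] + 1L
            pos <- pos[-drop]
          }
          tries <- tries + 1L
        }
        n <- length(pos)
      }
      if (n > 0L) {
        vtype <- sample(c("SNV", "INS", "DEL"), n, replace = TRUE,
                        prob = mm$type_probs)
        ilen <- integer(n)
        idx <- vtype != "SNV"
        ilen[idx] <- sample_indel_len(sum(idx), mm$indel_geom_p,
                                      mm$max_indel_len)
        refa <- character(n)
        alta <- character(n)
        for (i in seq_len(n)) {
          b <- ref_slice(ref, contig, pos[i], pos[i])
          if (vtype[i] == "SNV") {
            refa[i] <- b
            alta[i] <- sample_snv_alt(b, mm$ts_tv)
          } else if (vtype[i] == "INS") {
            refa[i] <- b
            alta[i] <- paste0(b, paste0(
              BASES[sample.int(4L, ilen[i], replace = TRUE)], collapse = ""))
          } else {
            refa[i] <- ref_slice(ref, contig, pos[i], pos[i] + ilen[i])
            alta[i] <- b
          }
        }
        het <- stats::runif(n) < mm$het_fraction
        allele <- ifelse(het, sample.int(2L, n, replace = TRUE), 0L)
        vars <- variant_records(contig = contig, pos = pos, ref = refa,
                                alt = alta, vaf = ifelse(het, 0.5, 1.0),
                                vtype = vtype, origin = "germline")
        vars$allele <- allele  # 0 = both haplotypes
      }
    }
    on_allele <- function(a) {
      if (is.null(vars)) return(NULL)
      vars[vars$allele == 0L | vars$allele == a, , drop = FALSE]
    }
    h1 <- build_haplotype(ref, contig, pad_start, pad_end, core_start,
                          core_end, on_allele(1L))
    h2 <- build_haplotype(ref, contig, pad_start, pad_end, core_start,
                          core_end, on_allele(2L))
    haplotypes[[g]] <- list(h1, h2)
    all_vars[[g]] <- vars
  }
  variants <- do.call(rbind, all_vars[!vapply(all_vars, is.null, TRUE)])
  if (is.null(variants)) {
    variants <- variant_records()
    variants$allele <- integer(0)
  } else {
    variants <- variants[order(variants$contig, variants$pos), , drop = FALSE]
    rownames(variants) <- NULL
  }
  list(haplotypes = haplotypes, variants = variants)
}

## ---- read simulation -------------------------------------------------------

# quality matrix (cycles x reads, column-major) -> one Phred+33 string per
# read, without transposition
qual_strings <- function(qm) {
  rl <- nrow(qm)
  n <- ncol(qm)
  big <- rawToChar(as.raw(qm + 33L))
  substring(big, (seq_len(n) - 1L) * rl + 1L, seq_len(n) * rl)
}

# inject substitution errors into `seqs` given the cycles x reads phred
# matrix; error probability is the Phred-implied rate via a lookup table
inject_errors <- function(seqs, qm, error_scale) {
  if (error_scale <= 0) return(seqs)
  rl <- nrow(qm)
  ptab <- error_scale * 10^(-(0:41) / 10)
  hits <- which(stats::runif(length(qm)) < ptab[qm + 1L])
  if (length(hits) == 0L) return(seqs)
  read_i <- (hits - 1L) %/% rl + 1L   # column = read
  cyc <- (hits - 1L) %% rl + 1L       # row = position in stored sequence
  rk <- sequence(rle(read_i)$lengths) # hits are already ordered by read
  for (r in unique(rk)) {
    sel <- rk == r
    rows <- read_i[sel]
    cols <- cyc[sel]
    x <- seqs[rows]
    orig <- substr(x, cols, cols)
    oi <- match(orig, BASES)
    shift <- sample.int(3L, length(rows), replace = TRUE)
    oi[is.na(oi)] <- sample.int(4L, sum(is.na(oi)), replace = TRUE)
    newb <- BASES[((oi - 1L + shift) %% 4L) + 1L]
    substr(x, cols, cols) <- newb
    seqs[rows] <- x
  }
  seqs
}

#' Simulate aligned paired-end reads over haplotype pairs
#'
#' Fragment counts are chosen so that the expected per-base depth inside
#' each target region equals `coverage`; fragment lengths follow the model's
#' truncated normal; each fragment is drawn from one of the two haplotypes
#' with probability 0.5 and, under a non-flat GC-bias curve, accepted with
#' probability proportional to the curve at its GC fraction. Per-base
#' substitution errors are injected at the Phred-implied rate of each
#' sampled cycle quality. Alignment coordinates and CIGARs are derived
#' through the haplotype coordinate map, so indel-spanning reads carry
#' correct I/D operations.
#'
#' @param haplotypes per-region haplotype pairs from [plant_germline()].
#' @param sm a [sequencing_model()].
#' @param coverage requested mean depth over the target regions.
#' @param seed integer seed.
#' @param sample_id prefix for read names.
#' @return a read table (see [read_alignments()] for columns).
#' @export
simulate_reads <- function(haplotypes, sm, coverage, seed = 1L,
                           sample_id = "S1") {
  stopifnot(coverage > 0)
  set.seed(seed)
  rl <- sm$read_length
  out <- vector("list", length(haplotypes))
  frag_counter <- 0L
  for (g in seq_along(haplotypes)) {
    pair <- haplotypes[[g]]
    h1 <- pair[[1L]]
    h2 <- pair[[2L]]
    contig <- h1$contig
    L <- h1$core_end - h1$core_start + 1L
    n_frag <- max(0L, round(coverage * (L + sm$frag_mean - 1) / (2 * rl)))
    if (n_frag == 0L) {
      warning("region ", contig, ":", h1$core_start, "-", h1$core_end,
              " received zero fragments at coverage ", coverage)
      next
    }
    hseq <- c(h1$seq, h2$seq)
    hlen <- nchar(hseq)
    hrp <- list(h1$rp, h2$rp)
    hirr <- list(hap_irregular_cumsum(h1), hap_irregular_cumsum(h2))
    # core offsets in haplotype coordinates (pad carries no variants)
    core_off <- c(h1$core_start - h1$rp[1L] + 1L,
                  h2$core_start - h2$rp[1L] + 1L)
    core_len_h <- hlen - core_off -
      c(h1$rp[length(h1$rp)] - h1$core_end,
        h2$rp[length(h2$rp)] - h2$core_end) + 1L
    chunks <- split(seq_len(n_frag),
                    ceiling(seq_len(n_frag) / 150000L))
    reg_out <- vector("list", length(chunks))
    for (ci in seq_along(chunks)) {
      nf <- length(chunks[[ci]])
      fl <- round(stats::rnorm(nf, sm$frag_mean, sm$frag_sd))
      while (any(fl < rl)) {
        bad <- fl < rl
        fl[bad] <- round(stats::rnorm(sum(bad), sm$frag_mean, sm$frag_sd))
      }
      hap <- sample.int(2L, nf, replace = TRUE)
      lo <- pmax(1L, core_off[hap] - fl + 1L)
      hi <- pmin(hlen[hap] - fl + 1L, core_off[hap] + core_len_h[hap] - 1L)
      hi <- pmax(hi, lo)
      s <- lo + floor(stats::runif(nf) * (hi - lo + 1L))
      if (!is_flat_gc(sm)) {
        frag_seq <- substring(hseq[hap], s, s + fl - 1L)
        gc <- Biostrings::letterFrequency(
          Biostrings::DNAStringSet(frag_seq), "GC", as.prob = TRUE)[, 1L]
        mx <- max(sm$gc_bias$mult)
        keep <- stats::runif(nf) < gc_multiplier(sm, gc) / mx
        # resample rejected fragments until the count is restored
        while (any(!keep)) {
          nb <- sum(!keep)
          fl2 <- round(stats::rnorm(nb, sm$frag_mean, sm$frag_sd))
          fl2[fl2 < rl] <- rl
          hap2 <- sample.int(2L, nb, replace = TRUE)
          lo2 <- pmax(1L, core_off[hap2] - fl2 + 1L)
          hi2 <- pmax(pmin(hlen[hap2] - fl2 + 1L,
                           core_off[hap2] + core_len_h[hap2] - 1L), lo2)
          s2 <- lo2 + floor(stats::runif(nb) * (hi2 - lo2 + 1L))
          fs2 <- substring(hseq[hap2], s2, s2 + fl2 - 1L)
          gc2 <- Biostrings::letterFrequency(
            Biostrings::DNAStringSet(fs2), "GC", as.prob = TRUE)[, 1L]
          ok2 <- stats::runif(nb) < gc_multiplier(sm, gc2) / mx
          idx <- which(!keep)
          fl[idx[ok2]] <- fl2[ok2]
          hap[idx[ok2]] <- hap2[ok2]
          s[idx[ok2]] <- s2[ok2]
          keep[idx[ok2]] <- TRUE
        }
      }
      # read spans in haplotype coordinates: left read and right read
      a_left <- s
      a_right <- s + fl - rl
      fwd <- stats::runif(nf) < sm$strand_balance
      # read1 sits at the fragment 5' end: left end for forward fragments
      r1_start <- ifelse(fwd, a_left, a_right)
      r2_start <- ifelse(fwd, a_right, a_left)
      r1_rev <- !fwd
      r2_rev <- fwd
      qname <- paste0(sample_id, ".", g, ".",
                      frag_counter + seq_len(nf))
      starts <- c(r1_start, r2_start)
      revs <- c(r1_rev, r2_rev)
      haps <- c(hap, hap)
      seqs <- substring(hseq[haps], starts, starts + rl - 1L)
      # alignment: fast path when the span crosses no indel breakpoint
      pos <- integer(2L * nf)
      cig <- character(2L * nf)
      ends <- starts + rl - 1L
      n_irr <- integer(2L * nf)
      for (hh in 1:2) {
        m <- haps == hh
        if (!any(m)) next
        before <- ifelse(starts[m] > 1L, hirr[[hh]][pmax(starts[m] - 1L, 1L)],
                         0L)
        n_irr[m] <- hirr[[hh]][ends[m]] - before
      }
      simple <- n_irr == 0L
      cig[simple] <- paste0(rl, "M")
      for (hh in 1:2) {
        m <- simple & haps == hh
        if (any(m)) pos[m] <- hrp[[hh]][starts[m]]
      }
      irr_idx <- which(!simple)
      if (length(irr_idx)) {
        # reads sharing (haplotype, start) have identical alignments:
        # derive each distinct one once
        key <- haps[irr_idx] * 1e9 + starts[irr_idx]
        uk <- which(!duplicated(key))
        map <- match(key, key[uk])
        upos <- integer(length(uk))
        ucig <- character(length(uk))
        for (t in seq_along(uk)) {
          i <- irr_idx[uk[t]]
          dc <- derive_cigar(hrp[[haps[i]]][starts[i]:(starts[i] + rl - 1L)])
          upos[t] <- dc$pos
          ucig[t] <- dc$cigar
        }
        pos[irr_idx] <- upos[map]
        cig[irr_idx] <- ucig[map]
      }
      # qualities (cycles x reads): cycle order is reversed for
      # reverse-strand reads, whose first sequenced base is the rightmost
      nr <- 2L * nf
      qm <- stats::rnorm(nr * rl, sd = sm$qual_profile$sd)
      dim(qm) <- c(rl, nr)
      qm <- qm + sm$qual_profile$mean  # recycles down each column
      qm <- pmin(41L, pmax(2L, as.integer(qm + 0.5)))
      dim(qm) <- c(rl, nr)
      if (any(revs)) qm[, revs] <- qm[rl:1L, revs, drop = FALSE]
      seqs <- inject_errors(seqs, qm, sm$error_scale)
      quals <- qual_strings(qm)
      df <- data.frame(
        qname = c(qname, qname),
        contig = contig,
        pos = pos,
        cigar = cig,
        seq = seqs,
        qual = quals,
        is_read1 = rep(c(TRUE, FALSE), each = nf),
        is_reverse = revs,
        mate_pos = c(pos[(nf + 1L):(2L * nf)], pos[seq_len(nf)]),
        isize = 0L,
        fragment_id = c(qname, qname),
        stringsAsFactors = FALSE
      )
      frag_counter <- frag_counter + nf
      reg_out[[ci]] <- df
    }
    out[[g]] <- do.call(rbind, reg_out)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) stop("no reads simulated")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a complete artificial normal sample
#'
#' Plants the germline background, simulates reads at the requested
#' coverage, and writes the coordinate-sorted indexed BAM plus the germline
#' truth VCF. Deterministic under a fixed seed.
#'
#' @param ref,regions reference and target regions.
#' @param sm,mm sequencing and mutation models.
#' @param coverage requested mean depth.
#' @param seed integer seed driving both planting and read simulation.
#' @param out_dir output directory (created if needed).
#' @param sample_id sample name; files are `<sample_id>.normal.bam` and
#'   `<sample_id>.germline.vcf`.
#' @param write_bam set `FALSE` to skip BAM writing and keep reads only in
#'   memory (useful for large in-memory pipelines).
#' @param keep_reads keep the read table in the returned object.
#' @return an object of class `normal_sample`: `sample_id`, `bam`,
#'   `germline_vcf`, `germline` (variant table), `coverage`, `seed`, and
#'   optionally `reads`.
#' @export
make_normal_sample <- function(ref, regions, sm = default_sequencing_model(),
                               mm = default_mutation_model(), coverage,
                               seed = 1L, out_dir = tempdir(),
                               sample_id = "sample1", write_bam = TRUE,
                               keep_reads = !write_bam) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pad <- as.integer(ceiling(sm$frag_mean + 6 * sm$frag_sd))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, 2L)
  pg <- plant_germline(ref, regions, mm, seed = sub_seeds[1L], pad = pad)
  reads <- simulate_reads(pg$haplotypes, sm, coverage, seed = sub_seeds[2L],
                          sample_id = sample_id)
  bam <- NULL
  if (write_bam) {
    bam <- file.path(out_dir, paste0(sample_id, ".normal.bam"))
    write_alignments(reads, bam, ref)
  }
  vcf <- file.path(out_dir, paste0(sample_id, ".germline.vcf"))
  gl <- pg$variants
  gl$allele <- NULL
  write_truth_vcf(gl, vcf, ref = ref)
  res <- list(sample_id = sample_id, bam = bam, germline_vcf = vcf,
              germline = gl, coverage = coverage, seed = seed,
              haplotypes = pg$haplotypes)
  if (keep_reads) res$reads <- reads
  class(res) <- "normal_sample"
  res
}

#' @export
print.normal_sample <- function(x, ...) {
  cat("<normal_sample> ", x$sample_id, "\n",
      " coverage: ", x$coverage, "x, seed ", x$seed, "\n",
      " germline variants: ", nrow(x$germline), "\n",
      " bam: ", if (is.null(x$bam)) "(in memory)" else x$bam, "\n",
      sep = "")
  invisible(x)
}
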