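# Allele counting from aligned reads: the package's own pileup, used to
# verify that planted/spiked variants are really present in the BAM at the
# expected allele fraction. Tests cross-check the SNV path against an
# independent htslib pileup.

# count support for one variant among reads known to overlap it
.count_support <- function(reads, ridx, contig, p, refa, alta, vtype) {
  ridx <- ridx[reads$contig[ridx] == contig]
  if (length(ridx) == 0L) {
    return(c(depth = 0L, alt = 0L))
  }
  simple <- grepl("^[0-9]+M$", reads$cigar[ridx])
  qoff <- query_offsets_at(reads$pos[ridx], reads$cigar[ridx], p, simple)
  if (vtype == "SNV") {
    elig <- !is.na(qoff)
    base <- substr(reads$seq[ridx[elig]], qoff[elig], qoff[elig])
    return(c(depth = sum(elig), alt = sum(base == alta)))
  }
  dlen <- abs(nchar(refa) - nchar(alta))
  depth <- 0L
  alt <- 0L
  for (k in seq_along(ridx)) {
    row <- ridx[k]
    if (is.na(qoff[k])) {
      # anchor deleted or not aligned in this read; still overlapping
      depth <- depth + 1L
      next
    }
    depth <- depth + 1L
    rp <- cigar_to_refpos(reads$cigar[row], reads$pos[row])
    qa <- qoff[k]
    n <- length(rp)
    if (qa >= n) next
    if (vtype == "INS") {
      # insertion evidence: unaligned bases immediately after the anchor
      run <- 0L
      j <- qa + 1L
      while (j <= n && is.na(rp[j])) {
        run <- run + 1L
        j <- j + 1L
      }
      if (run == dlen || (run > 0L && j > n)) alt <- alt + 1L
    } else {
      # deletion evidence: next aligned base jumps the deleted span
      j <- qa + 1L
      while (j <= n && is.na(rp[j])) j <- j + 1L
      if (j <= n && rp[j] == p + dlen + 1L) alt <- alt + 1L
    }
  }
  c(depth = depth, alt = alt)
}

#' Measure allele fractions of variants from aligned reads
#'
#' For each variant, counts reads whose alignment covers the site (depth)
#' and reads carrying the alternate allele: the matching base for SNVs, an
#' I operation immediately after the anchor for insertions, a D jump over
#' the deleted span for deletions.
#'
#' @param x a read table or a BAM path.
#' @param variants a [variant_records()] table (or spec table with
#'   `contig`/`pos`/`ref`/`alt`/`vtype` columns).
#' @return `data.frame` with `depth`, `alt_count` and `vaf` per variant.
#' @export
pileup_vaf <- function(x, variants) {
  reads <- if (is.character(x)) read_alignments(x) else x
  n <- nrow(variants)
  depth <- integer(n)
  altc <- integer(n)
  if (n > 0L) {
    span <- nchar(variants$ref) - 1L
    ref_end <- reads$pos + cigar_ref_width(reads$cigar) - 1L
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(variants$pos, variants$pos + span),
      IRanges::IRanges(reads$pos, ref_end))
    by_var <- split(S4Vectors::subjectHits(hits),
                    factor(S4Vectors::queryHits(hits), levels = seq_len(n)))
    for (i in seq_len(n)) {
      cnt <- .count_support(reads, by_var[[i]], variants$contig[i],
                            variants$pos[i], variants$ref[i],
                            variants$alt[i], variants$vtype[i])
      depth[i] <- cnt[["depth"]]
      altc[i] <- cnt[["alt"]]
    }
  }
  data.frame(contig = variants$contig, pos = variants$pos,
             vtype = variants$vtype, depth = depth, alt_count = altc,
             vaf = ifelse(depth > 0L, altc / depth, NA_real_),
             stringsAsFactors = FALSE)
}

#' Mean per-base depth of a BAM over target regions
#'
#' @param bam indexed BAM path.
#' @param regions target [GenomicRanges::GRanges].
#' @return mean depth (reads covering a base, M/D operations) across all
#'   region bases.
#' @export
bam_mean_depth <- function(bam, regions) {
  ga <- GenomicAlignments::readGAlignments(bam)
  cvg <- GenomicAlignments::coverage(ga)
  tot <- 0
  nb <- 0
  for (i in seq_along(regions)) {
    ctg <- as.character(GenomicRanges::seqnames(regions)[i])
    v <- IRanges::Views(cvg[[ctg]], GenomicRanges::start(regions)[i],
                        GenomicRanges::end(regions)[i])
    tot <- tot + sum(sum(v))
    nb <- nb + sum(IRanges::width(v))
  }
  tot / nb
}
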