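# Standard-format I/O: FASTA references, BED target regions, truth/caller
# VCFs and SAM/BAM alignments, behind small domain-typed wrappers used by the
# simulator, the spike-in editor and the benchmark.
#
# Coordinate conventions: BED is 0-based half-open on disk and converted to
# 1-based closed GRanges on load; VCF and BAM positions are 1-based
# throughout.

#' Load a reference genome from FASTA
#'
#' Reads every record, uppercases the sequence and validates the alphabet.
#' A `.fai` index is created next to the file when possible (ignored for
#' write-protected directories).
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet], one entry per contig, in file
#'   order. Contig names are the first whitespace-delimited word of each
#'   header.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate contig name(s) in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) stop("empty sequence in ", path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- Biostrings::letterFrequency(seqs, letters = "ACGTN")
  if (any(bad != Biostrings::width(seqs))) {
    stop("reference contains letters outside A/C/G/T/N")
  }
  try(suppressWarnings(Rsamtools::indexFa(path)), silent = TRUE)
  seqs
}

# substring of a contig as a plain character string (1-based closed)
ref_slice <- function(ref, contig, start, end) {
  i <- match(contig, names(ref))
  if (is.na(i)) stop("unknown contig: ", contig)
  as.character(Biostrings::subseq(ref[[i]], start, end))
}

contig_length <- function(ref, contig) {
  i <- match(contig, names(ref))
  if (is.na(i)) stop("unknown contig: ", contig)
  Biostrings::width(ref)[i]
}

#' Load target regions from BED
#'
#' BED intervals (0-based half-open) are converted to 1-based closed
#' coordinates, validated against the reference, sorted, and overlapping or
#' adjacent intervals are merged so the region set forms a partition for
#' coverage accounting.
#'
#' @param path BED file with at least chrom/start/end columns; `track`,
#'   `browser` and `#` lines are skipped.
#' @param ref reference as returned by [load_reference()].
#' @return a [GenomicRanges::GRanges] sorted by (contig, start).
#' @export
load_regions <- function(path, ref) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no intervals in ", path)
  fields <- strsplit(lines, "\t")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop("BED line ", lineno[i], ": fewer than 3 columns")
    }
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e)) {
      stop("BED line ", lineno[i], ": non-numeric start/end")
    }
    if (s >= e) {
      stop("BED line ", lineno[i], ": start >= end (", f[2L], " >= ", f[3L], ")")
    }
    if (!f[1L] %in% names(ref)) {
      stop("BED line ", lineno[i], ": unknown contig '", f[1L], "'")
    }
    if (e > contig_length(ref, f[1L])) {
      stop("BED line ", lineno[i], ": interval end ", e,
           " exceeds contig length ", contig_length(ref, f[1L]))
    }
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- vapply(fields, function(f) as.numeric(f[2L]), 0)
  end0 <- vapply(fields, function(f) as.numeric(f[3L]), 0)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    seqlengths = structure(Biostrings::width(ref), names = names(ref))
  )
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

write_bed <- function(regions, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- variant records -------------------------------------------------------

#' Construct a table of variant records
#'
#' The common variant currency of the package: one row per allele with
#' 1-based position, REF/ALT strings, an optional variant allele fraction,
#' the variant type and its origin (germline or somatic).
#'
#' @param contig,pos,ref,alt vectors defining the alleles.
#' @param vaf variant allele fraction in `[0, 1]`, `NA` when unknown.
#' @param vtype `"SNV"`, `"INS"` or `"DEL"`; inferred from allele lengths
#'   when missing.
#' @param origin `"germline"` or `"somatic"` (`NA` when unknown).
#' @return a `data.frame` with class `variant_records`.
#' @export
variant_records <- function(contig = character(), pos = integer(),
                            ref = character(), alt = character(),
                            vaf = NA_real_, vtype = NA_character_,
                            origin = NA_character_) {
  n <- length(pos)
  df <- data.frame(
    contig = as.character(contig),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    vaf = rep_len(as.numeric(vaf), n),
    vtype = rep_len(as.character(vtype), n),
    origin = rep_len(as.character(origin), n),
    stringsAsFactors = FALSE
  )
  if (n > 0L) {
    if (any(!nzchar(df$ref)) || any(!nzchar(df$alt))) {
      stop("ref and alt alleles must be non-empty")
    }
    miss <- is.na(df$vtype)
    df$vtype[miss] <- infer_vtype(df$ref[miss], df$alt[miss])
    snv <- df$vtype == "SNV"
    if (any(snv & (nchar(df$ref) != 1L | nchar(df$alt) != 1L))) {
      stop("SNV records must have single-base ref and alt")
    }
    if (any(!is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1))) {
      stop("vaf must lie in [0, 1]")
    }
  }
  class(df) <- c("variant_records", "data.frame")
  df
}

infer_vtype <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt),
         ifelse(nchar(ref) == 1L, "SNV", "MNP"),
         ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}

# check records against the reference sequence; returns logical vector
ref_consistent <- function(records, ref) {
  vapply(seq_len(nrow(records)), function(i) {
    ctg <- records$contig[i]
    p <- records$pos[i]
    r <- records$ref[i]
    if (!ctg %in% names(ref)) return(FALSE)
    if (p < 1L || p + nchar(r) - 1L > contig_length(ref, ctg)) return(FALSE)
    identical(ref_slice(ref, ctg, p, p + nchar(r) - 1L), r)
  }, logical(1L))
}

## ---- VCF -------------------------------------------------------------------

#' Write a truth VCF
#'
#' Emits a minimal VCF v4.2 with `INFO` keys `VAF` (observed variant allele
#' fraction), `VTYPE` (`SNV`/`INS`/`DEL`) and `ORIGIN` (`germline`/`somatic`).
#' Records are sorted by (contig, pos); the file round-trips losslessly
#' through [read_vcf()].
#'
#' @param records a [variant_records()] table.
#' @param path output path.
#' @param ref optional reference; when supplied every record's REF allele is
#'   checked against it and a mismatch is an error.
#' @export
write_truth_vcf <- function(records, path, ref = NULL) {
  if (!is.null(ref) && nrow(records) > 0L) {
    ok <- ref_consistent(records, ref)
    if (any(!ok)) {
      stop("record(s) inconsistent with reference at: ",
           paste(records$contig[!ok], records$pos[!ok],
                 sep = ":", collapse = ", "))
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=deepspike",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Observed variant allele fraction\">",
    "##INFO=<ID=VTYPE,Number=1,Type=String,Description=\"Variant type: SNV, INS or DEL\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Variant origin: germline or somatic\">"
  )
  if (!is.null(ref)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(ref),
                          Biostrings::width(ref)))
  } else if (nrow(records) > 0L) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", unique(records$contig)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(records) > 0L) {
    o <- order(records$contig, records$pos)
    rec <- records[o, , drop = FALSE]
    info <- paste0(
      ifelse(is.na(rec$vaf), "", paste0("VAF=", format(rec$vaf, digits = 10,
                                                       scientific = FALSE,
                                                       trim = TRUE), ";")),
      "VTYPE=", rec$vtype,
      ifelse(is.na(rec$origin), "", paste0(";ORIGIN=", rec$origin))
    )
    body <- paste(rec$contig, rec$pos, ".", rec$ref, rec$alt, ".", "PASS",
                  info, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant-record table
#'
#' Multi-allelic lines are split into one record per ALT allele. The variant
#' allele fraction is taken from `INFO/VAF` when present, else from `INFO/AF`
#' (per-allele), else left `NA` — caller VCFs without a VAF annotation are
#' accepted.
#'
#' @param path VCF v4.x file (plain or bgzipped).
#' @return a [variant_records()] table.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e))
  )
  vcf <- VariantAnnotation::expand(vcf)
  n <- length(vcf)
  if (n == 0L) {
    return(variant_records())
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  vaf <- rep(NA_real_, n)
  if ("VAF" %in% colnames(info)) {
    vaf <- suppressWarnings(as.numeric(info$VAF))
  } else if ("AF" %in% colnames(info)) {
    af <- info$AF
    if (is.list(af) || methods::is(af, "List")) {
      af <- vapply(af, function(x) if (length(x)) as.numeric(x[1L]) else NA_real_,
                   numeric(1L))
    }
    vaf <- suppressWarnings(as.numeric(af))
  }
  vtype <- rep(NA_character_, n)
  if ("VTYPE" %in% colnames(info)) vtype <- as.character(info$VTYPE)
  origin <- rep(NA_character_, n)
  if ("ORIGIN" %in% colnames(info)) origin <- as.character(info$ORIGIN)
  variant_records(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    vaf = vaf, vtype = vtype, origin = origin
  )
}

## ---- SAM/BAM ---------------------------------------------------------------

#' Read aligned reads from BAM (or SAM)
#'
#' @param path indexed or unindexed BAM; plain SAM is converted on the fly.
#' @return a `data.frame` with one row per read: `qname`, `contig`, `pos`,
#'   `cigar`, `seq`, `qual` (plain strings, Phred+33), `is_read1`,
#'   `is_reverse`, `mate_pos`, `isize`, `fragment_id`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, tmp, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mpos", "isize",
             "seq", "qual")
  )
  res <- Rsamtools::scanBam(path, param = p)[[1L]]
  flag <- res$flag
  data.frame(
    qname = res$qname,
    contig = as.character(res$rname),
    pos = res$pos,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    is_read1 = bitwAnd(flag, 64L) > 0L,
    is_reverse = bitwAnd(flag, 16L) > 0L,
    mate_pos = res$mpos,
    isize = res$isize,
    fragment_id = res$qname,
    stringsAsFactors = FALSE
  )
}

#' Write aligned reads to a coordinate-sorted, indexed BAM
#'
#' Reads are validated (CIGAR query width must equal sequence and quality
#' length; every fragment must consist of exactly one read-1/read-2 pair)
#' before writing; offending reads are reported by name. Mate position and
#' template-length fields are recomputed from the pair so they stay
#' consistent after read editing.
#'
#' @param reads a read table as produced by the simulator or
#'   [read_alignments()].
#' @param path output BAM path (`.bam`).
#' @param ref reference used for the `@SQ` header lines.
#' @return the BAM path, invisibly; a `.bai` index is written alongside.
#' @export
write_alignments <- function(reads, path, ref) {
  stopifnot(nrow(reads) > 0L)
  qw <- cigar_query_width(reads$cigar)
  bad <- qw != nchar(reads$seq) | nchar(reads$seq) != nchar(reads$qual)
  if (any(bad)) {
    stop("CIGAR/sequence length mismatch for read(s): ",
         paste(utils::head(reads$qname[bad], 5L), collapse = ", "))
  }
  tab <- table(reads$fragment_id)
  if (any(tab != 2L)) {
    stop("fragment(s) without exactly one read pair: ",
         paste(utils::head(names(tab)[tab != 2L], 5L), collapse = ", "))
  }
  o <- order(reads$fragment_id, !reads$is_read1)
  r <- reads[o, , drop = FALSE]
  i1 <- seq(1L, nrow(r), by = 2L)
  i2 <- i1 + 1L
  if (any(!r$is_read1[i1]) || any(r$is_read1[i2])) {
    stop("fragment(s) whose two reads are not a read1/read2 pair")
  }
  ends <- r$pos + cigar_ref_width(r$cigar) - 1L
  # recompute mate/template fields pairwise
  mpos <- integer(nrow(r))
  mpos[i1] <- r$pos[i2]
  mpos[i2] <- r$pos[i1]
  left <- pmin(r$pos[i1], r$pos[i2])
  right <- pmax(ends[i1], ends[i2])
  tl <- right - left + 1L
  tlen <- integer(nrow(r))
  tlen[i1] <- ifelse(r$pos[i1] <= r$pos[i2], tl, -tl)
  tlen[i2] <- -tlen[i1]
  mrev <- logical(nrow(r))
  mrev[i1] <- r$is_reverse[i2]
  mrev[i2] <- r$is_reverse[i1]
  flag <- 1L + 2L +
    16L * r$is_reverse + 32L * mrev +
    64L * r$is_read1 + 128L * !r$is_read1
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref), Biostrings::width(ref)))
  lines <- paste(r$qname, flag, r$contig, r$pos, 60L, r$cigar, "=",
                 mpos, tlen, r$seq, r$qual, sep = "\t")
  sam <- tempfile(fileext = ".sam")
  con <- file(sam, open = "wt")
  writeLines(hdr, con)
  writeLines(lines, con)
  close(con)
  tmp <- tempfile()
  bam0 <- Rsamtools::asBam(sam, tmp, overwrite = TRUE,
                           indexDestination = FALSE)
  dest <- sub("\\.bam$", "", path)
  out <- Rsamtools::sortBam(bam0, dest)
  Rsamtools::indexBam(out)
  unlink(c(sam, bam0))
  invisible(out)
}

#' Export reads as gzipped paired FASTQ
#'
#' Optional output for users who want to push simulated fragments through a
#' real aligner. Reverse-strand reads are reverse-complemented back to
#' sequenced orientation.
#' @param reads read table.
#' @param r1_path,r2_path output `.fastq.gz` paths.
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  emit <- function(rr, path) {
    o <- order(rr$fragment_id)
    rr <- rr[o, , drop = FALSE]
    seqs <- rr$seq
    quals <- rr$qual
    rev <- rr$is_reverse
    if (any(rev)) {
      seqs[rev] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rev])))
      quals[rev] <- vapply(quals[rev], function(q) {
        intToUtf8(rev(utf8ToInt(q)))
      }, "")
    }
    con <- gzfile(path, open = "wt")
    writeLines(paste0("@", rr$qname, "\n", seqs, "\n+\n", quals), con)
    close(con)
  }
  emit(reads[reads$is_read1, , drop = FALSE], r1_path)
  emit(reads[!reads$is_read1, , drop = FALSE], r2_path)
  invisible(c(r1_path, r2_path))
}
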