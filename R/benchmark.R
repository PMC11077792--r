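# Benchmarking caller VCFs against the spiked truth: allele normalization,
# exact matching with germline exclusion, TPR/PPV/FDR with stratification,
# reproducible fragment-level BAM downsampling, and the train/test split
# protocol.

#' Normalize variant records (trim + left-align)
#'
#' Applies the standard parsimony/left-alignment procedure: shared suffix
#' bases are trimmed (extending with the reference base to the left when an
#' allele would empty, which shifts indels left through repeats), then
#' shared prefix bases are trimmed. Idempotent; SNVs already minimal are
#' unchanged. Records whose REF allele disagrees with the reference are
#' flagged in the returned `ref_ok` column and should be excluded from
#' matching.
#'
#' @param records a [variant_records()] table.
#' @param ref reference from [load_reference()].
#' @return the records, normalized, with a logical `ref_ok` column.
#' @export
normalize_variants <- function(records, ref) {
  n <- nrow(records)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ctg <- records$contig[i]
    p <- records$pos[i]
    r <- records$ref[i]
    a <- records$alt[i]
    if (!ctg %in% names(ref) ||
        p + nchar(r) - 1L > contig_length(ref, ctg) ||
        ref_slice(ref, ctg, p, p + nchar(r) - 1L) != r) {
      ok[i] <- FALSE
      next
    }
    repeat {
      nr <- nchar(r)
      na <- nchar(a)
      if (nr > 0L && na > 0L &&
          substr(r, nr, nr) == substr(a, na, na)) {
        if (nr == 1L && na == 1L) break
        r <- substr(r, 1L, nr - 1L)
        a <- substr(a, 1L, na - 1L)
        if (nchar(r) == 0L || nchar(a) == 0L) {
          if (p == 1L) {  # cannot extend left past the contig start
            b <- ref_slice(ref, ctg, p, p)
            r <- paste0(r, b)
            a <- paste0(a, b)
            break
          }
          p <- p - 1L
          b <- ref_slice(ref, ctg, p, p)
          r <- paste0(b, r)
          a <- paste0(b, a)
        }
      } else {
        break
      }
    }
    while (nchar(r) >= 2L && nchar(a) >= 2L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    records$pos[i] <- p
    records$ref[i] <- r
    records$alt[i] <- a
  }
  records$vtype <- infer_vtype(records$ref, records$alt)
  records$ref_ok <- ok
  records
}

variant_key <- function(records) {
  paste(records$contig, records$pos, records$ref, records$alt, sep = ":")
}

#' Matching configuration
#'
#' @param mode `"tumor_only"` or `"paired"`. In paired mode the matched
#'   normal's call set (or the germline truth) must be supplied so its
#'   variants can be subtracted from the tumor calls.
#' @param scope `"SNV"`, `"INDEL"` or `"both"`: when not `"both"`, truth
#'   and calls outside the scope are dropped before matching.
#' @param germline germline [variant_records()] to exclude from the calls.
#' @param normal_calls matched-normal call set (paired mode).
#' @param normalize left-align and trim alleles before matching (needs
#'   `ref` at match time).
#' @return an object of class `match_config`.
#' @export
match_config <- function(mode = c("tumor_only", "paired"),
                         scope = c("both", "SNV", "INDEL"),
                         germline = NULL, normal_calls = NULL,
                         normalize = TRUE) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (mode == "paired" && is.null(germline) && is.null(normal_calls)) {
    stop("paired mode requires a matched-normal call set or germline list")
  }
  structure(list(mode = mode, scope = scope, germline = germline,
                 normal_calls = normal_calls, normalize = normalize),
            class = "match_config")
}

.in_scope <- function(records, scope) {
  if (scope == "both") return(rep(TRUE, nrow(records)))
  if (scope == "SNV") records$vtype == "SNV"
  else records$vtype %in% c("INS", "DEL")
}

#' Match caller output against the spiked truth
#'
#' Both sets are normalized (when configured), calls equal to a germline
#' variant (or present in the matched-normal call set) are removed, the
#' variant scope filter is applied to both sides, duplicate calls are
#' collapsed, and truth/calls are matched on the exact
#' (contig, pos, ref, alt) key; each truth record matches at most one call.
#'
#' @param truth truth [variant_records()] (the successfully inserted
#'   variants).
#' @param calls caller [variant_records()] (e.g. from [read_vcf()]).
#' @param cfg a [match_config()].
#' @param ref reference, required when `cfg$normalize` is `TRUE`.
#' @return an object of class `match_result` with `tp` (truth rows matched,
#'   carrying the call VAF in `call_vaf`), `fp` (unmatched calls), `fn`
#'   (unmatched truth).
#' @export
match_calls <- function(truth, calls, cfg = match_config(), ref = NULL) {
  if (cfg$normalize) {
    if (is.null(ref)) stop("normalization requires the reference")
    truth <- normalize_variants(truth, ref)
    if (any(!truth$ref_ok)) {
      warning(sum(!truth$ref_ok), " truth record(s) inconsistent with the ",
              "reference were excluded")
      truth <- truth[truth$ref_ok, , drop = FALSE]
    }
    calls <- normalize_variants(calls, ref)
    calls <- calls[calls$ref_ok, , drop = FALSE]
  }
  excl_keys <- character(0)
  if (!is.null(cfg$germline) && nrow(cfg$germline) > 0L) {
    g <- cfg$germline
    if (cfg$normalize) {
      g <- normalize_variants(g, ref)
      g <- g[g$ref_ok, , drop = FALSE]
    }
    excl_keys <- c(excl_keys, variant_key(g))
  }
  if (!is.null(cfg$normal_calls) && nrow(cfg$normal_calls) > 0L) {
    nc <- cfg$normal_calls
    if (cfg$normalize) {
      nc <- normalize_variants(nc, ref)
      nc <- nc[nc$ref_ok, , drop = FALSE]
    }
    excl_keys <- c(excl_keys, variant_key(nc))
  }
  calls <- calls[!variant_key(calls) %in% excl_keys, , drop = FALSE]
  truth <- truth[.in_scope(truth, cfg$scope), , drop = FALSE]
  calls <- calls[.in_scope(calls, cfg$scope), , drop = FALSE]
  ck <- variant_key(calls)
  if (anyDuplicated(ck)) {
    message("collapsed ", sum(duplicated(ck)), " duplicate call record(s)")
    calls <- calls[!duplicated(ck), , drop = FALSE]
    ck <- variant_key(calls)
  }
  tk <- variant_key(truth)
  matched <- tk %in% ck
  tp <- truth[matched, , drop = FALSE]
  if (nrow(tp) > 0L) {
    tp$call_vaf <- calls$vaf[match(variant_key(tp), ck)]
  } else {
    tp$call_vaf <- numeric(0)
  }
  structure(list(tp = tp,
                 fp = calls[!ck %in% tk, , drop = FALSE],
                 fn = truth[!matched, , drop = FALSE],
                 cfg = cfg),
            class = "match_result")
}

.safe_div <- function(a, b) if (b > 0) a / b else NA_real_

.metric_row <- function(tp, fp, fn) {
  data.frame(tp = tp, fp = fp, fn = fn,
             tpr = .safe_div(tp, tp + fn),
             ppv = .safe_div(tp, tp + fp),
             fdr = .safe_div(fp, tp + fp))
}

#' Compute TPR / PPV / FDR from a match result or raw counts
#'
#' TPR = TP/(TP+FN), PPV = TP/(TP+FP), FDR = FP/(TP+FP) = 1 - PPV. Empty
#' denominators yield `NA`, never 0/0. Given a [match_calls()] result,
#' metrics are additionally stratified by variant type and by truth VAF bin
#' (default edges 0.1/0.5/1/2/5%, covering the low-fraction range; false
#' positives enter a VAF bin only when the caller reported a VAF).
#'
#' @param x a `match_result`, or the TP count.
#' @param fp,fn counts, when `x` is given as a count.
#' @param vaf_bins bin edges as fractions.
#' @return object of class `benchmark_metrics`: `overall` (one-row
#'   data.frame) and `strata` (long data.frame, empty strata omitted).
#' @export
compute_metrics <- function(x, fp = NULL, fn = NULL,
                            vaf_bins = c(0.001, 0.005, 0.01, 0.02, 0.05)) {
  if (is.numeric(x)) {
    stopifnot(!is.null(fp), !is.null(fn), x >= 0, fp >= 0, fn >= 0)
    out <- list(overall = .metric_row(x, fp, fn),
                strata = data.frame())
    class(out) <- "benchmark_metrics"
    return(out)
  }
  stopifnot(inherits(x, "match_result"))
  overall <- .metric_row(nrow(x$tp), nrow(x$fp), nrow(x$fn))
  strata <- list()
  for (vt in unique(c(x$tp$vtype, x$fn$vtype, x$fp$vtype))) {
    row <- .metric_row(sum(x$tp$vtype == vt), sum(x$fp$vtype == vt),
                       sum(x$fn$vtype == vt))
    row <- cbind(data.frame(stratum = "vtype", level = vt), row)
    strata[[length(strata) + 1L]] <- row
  }
  edges <- sort(unique(c(0, vaf_bins, 1)))
  lab <- paste0("(", utils::head(edges, -1L) * 100, "%,",
                utils::tail(edges, -1L) * 100, "%]")
  binof <- function(v) {
    ifelse(is.na(v), NA_integer_,
           findInterval(v, edges, left.open = TRUE, rightmost.closed = TRUE))
  }
  tpb <- binof(x$tp$vaf)
  fnb <- binof(x$fn$vaf)
  fpb <- binof(x$fp$vaf)
  for (b in sort(unique(stats::na.omit(c(tpb, fnb, fpb))))) {
    row <- .metric_row(sum(tpb == b, na.rm = TRUE),
                       sum(fpb == b, na.rm = TRUE),
                       sum(fnb == b, na.rm = TRUE))
    row <- cbind(data.frame(stratum = "vaf_bin", level = lab[b]), row)
    strata[[length(strata) + 1L]] <- row
  }
  strata <- if (length(strata)) do.call(rbind, strata) else data.frame()
  out <- list(overall = overall, strata = strata)
  class(out) <- "benchmark_metrics"
  out
}

#' @export
print.benchmark_metrics <- function(x, ...) {
  cat("<benchmark_metrics>\n")
  print(x$overall, row.names = FALSE)
  if (nrow(x$strata)) {
    cat("strata:\n")
    print(x$strata, row.names = FALSE)
  }
  invisible(x)
}

## ---- downsampling ----------------------------------------------------------

#' Downsample reads at the fragment level
#'
#' Each fragment (both mates together) is retained independently with
#' probability `fraction`; mate pairs are never orphaned and the same seed
#' reproduces the same subset exactly.
#'
#' @param reads read table.
#' @param fraction retention probability in `(0, 1]`.
#' @param seed integer seed.
#' @return the retained read table.
#' @export
downsample_reads <- function(reads, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  set.seed(seed)
  uf <- unique(reads$fragment_id)
  keep <- uf[stats::runif(length(uf)) < fraction]
  reads[reads$fragment_id %in% keep, , drop = FALSE]
}

#' Downsample a BAM reproducibly
#'
#' @param bam input BAM.
#' @param out output BAM path.
#' @param fraction retention probability in `(0, 1]`.
#' @param seed integer seed.
#' @param ref reference for the output header.
#' @return the output BAM path, invisibly.
#' @export
downsample_bam <- function(bam, out, fraction, seed = 1L, ref) {
  reads <- read_alignments(bam)
  kept <- downsample_reads(reads, fraction, seed)
  write_alignments(kept, out, ref)
}

#' Coverage-titration schedule
#'
#' The retained-read fractions used for depth titration: 2-8% in steps of
#' 2%, then 20-80% in steps of 20%.
#' @return numeric vector of fractions.
#' @export
downsample_schedule <- function() {
  c(seq(2, 8, by = 2), seq(20, 80, by = 20)) / 100
}

## ---- train/test split ------------------------------------------------------

#' Deterministic train/test split by sample composition
#'
#' Samples are labelled by somatic composition (`"snv_only"` or
#' `"snv_indel"`); within each composition the lexicographically first
#' `design$train[comp]` samples form the training set and the remainder the
#' test set. The default design takes 7 of each composition for training
#' (paper-scale: 14 train / 6 test from a 10+10 cohort).
#'
#' @param sample_ids character vector.
#' @param composition parallel vector of composition labels.
#' @param design list with a named `train` vector of per-composition counts.
#' @return object of class `split_plan`: `training_ids`, `test_ids`.
#' @export
make_split <- function(sample_ids, composition,
                       design = list(train = c(snv_only = 7L,
                                               snv_indel = 7L))) {
  stopifnot(length(sample_ids) == length(composition),
            !anyDuplicated(sample_ids))
  train <- character(0)
  test <- character(0)
  for (comp in names(design$train)) {
    ids <- sort(sample_ids[composition == comp])
    k <- design$train[[comp]]
    if (length(ids) < k) {
      stop("insufficient samples of composition '", comp, "': have ",
           length(ids), ", need ", k, " for training")
    }
    train <- c(train, ids[seq_len(k)])
    test <- c(test, ids[-seq_len(k)])
  }
  other <- sample_ids[!composition %in% names(design$train)]
  test <- c(test, sort(other))
  structure(list(training_ids = train, test_ids = test),
            class = "split_plan")
}

## ---- report ----------------------------------------------------------------

#' Render a benchmark report as TSV + JSON
#'
#' @param entries list of entries, each a list with `sample`, `caller`,
#'   `mode`, `scope` and `metrics` (a [compute_metrics()] object).
#' @param out_prefix paths `<out_prefix>.tsv` and `<out_prefix>.json` are
#'   written.
#' @return data.frame of the long-format report rows, invisibly.
#' @export
render_report <- function(entries, out_prefix) {
  stopifnot(length(entries) >= 1L)
  rows <- lapply(entries, function(e) {
    m <- e$metrics
    base <- data.frame(sample = e$sample, caller = e$caller, mode = e$mode,
                       scope = e$scope, stringsAsFactors = FALSE)
    overall <- cbind(base, data.frame(stratum = "overall", level = "overall"),
                     m$overall)
    if (nrow(m$strata)) {
      rbind(overall, cbind(base[rep(1L, nrow(m$strata)), , drop = FALSE],
                           m$strata))
    } else {
      overall
    }
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, paste0(out_prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, paste0(out_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(df)
}
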