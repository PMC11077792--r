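# Parametric sequencing-error and mutational models. These are documented
# parametric stand-ins for models learned from real instrument data: users
# who know their platform supply parameters through a plain-text YAML config
# instead of a learned model file.

#' Construct a sequencing model
#'
#' Describes the read geometry and error behaviour of a paired-end
#' sequencing run: read length, fragment-length distribution (normal,
#' truncated at the read length), a per-cycle quality profile from which
#' substitution errors are drawn at the Phred-implied rate
#' \eqn{10^{-q/10}}, an optional GC coverage-bias curve, and the
#' forward-strand probability of a fragment.
#'
#' @param read_length read length in bp.
#' @param frag_mean,frag_sd fragment length mean and SD in bp; fragments are
#'   resampled below `read_length`.
#' @param qual_start,qual_end mean Phred quality at the first and last cycle;
#'   intermediate cycles interpolate linearly (default Q37 decaying to Q30).
#' @param qual_sd per-cycle Phred SD; drawn qualities are clipped to
#'   `[2, 41]`.
#' @param gc_bias `data.frame(gc, mult)` piecewise-linear coverage
#'   multiplier over fragment GC fraction; normalised to mean 1 over uniform
#'   GC. `NULL` (default) means flat (no bias).
#' @param strand_balance probability that a fragment is forward-oriented.
#' @param error_scale multiplier on the Phred-implied substitution rate;
#'   `0` gives an error-free instrument (useful for exact pileup checks).
#' @return an object of class `sequencing_model`.
#' @export
sequencing_model <- function(read_length = 150L, frag_mean = 350, frag_sd = 50,
                             qual_start = 37, qual_end = 30, qual_sd = 3,
                             gc_bias = NULL, strand_balance = 0.5,
                             error_scale = 1) {
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("read_length must be >= 1")
  if (frag_mean < read_length) stop("frag_mean must be >= read_length")
  if (frag_sd < 0) stop("frag_sd must be >= 0")
  if (strand_balance < 0 || strand_balance > 1) {
    stop("strand_balance must lie in [0, 1]")
  }
  if (error_scale < 0) stop("error_scale must be >= 0")
  if (is.null(gc_bias)) {
    gc_bias <- data.frame(gc = c(0, 1), mult = c(1, 1))
  }
  if (!all(c("gc", "mult") %in% names(gc_bias))) {
    stop("gc_bias needs columns 'gc' and 'mult'")
  }
  if (any(gc_bias$mult < 0)) stop("gc_bias multipliers must be >= 0")
  o <- order(gc_bias$gc)
  gc_bias <- gc_bias[o, , drop = FALSE]
  if (gc_bias$gc[1L] > 0 || gc_bias$gc[nrow(gc_bias)] < 1) {
    stop("gc_bias curve must cover [0, 1]")
  }
  # normalise to mean 1 over uniform GC (trapezoid integral)
  gx <- gc_bias$gc
  gy <- gc_bias$mult
  area <- sum(diff(gx) * (utils::head(gy, -1) + utils::tail(gy, -1)) / 2)
  if (area <= 0) stop("gc_bias curve integrates to zero")
  gc_bias$mult <- gy / area
  qprof <- seq(qual_start, qual_end, length.out = read_length)
  m <- structure(
    list(read_length = read_length, frag_mean = frag_mean, frag_sd = frag_sd,
         qual_profile = list(mean = qprof, sd = qual_sd),
         gc_bias = gc_bias, strand_balance = strand_balance,
         error_scale = error_scale),
    class = "sequencing_model"
  )
  m
}

#' Default sequencing model
#'
#' 150 bp paired-end reads, 350 +/- 50 bp fragments, per-cycle quality
#' decaying Q37 to Q30, flat GC bias, balanced strands.
#' @return a [sequencing_model()].
#' @export
default_sequencing_model <- function() sequencing_model()

#' Substitution-error probability implied by a Phred score
#'
#' @param q Phred quality (vectorised).
#' @param model optional [sequencing_model()] whose `error_scale` multiplies
#'   the Phred rate.
#' @return `error_scale * 10^(-q/10)`.
#' @export
subst_rate <- function(q, model = NULL) {
  scale <- if (is.null(model)) 1 else model$error_scale
  scale * 10^(-q / 10)
}

gc_multiplier <- function(model, gc) {
  stats::approx(model$gc_bias$gc, model$gc_bias$mult, xout = gc,
                rule = 2)$y
}

is_flat_gc <- function(model) {
  all(abs(model$gc_bias$mult - 1) < 1e-12)
}

#' Construct a mutational model for the germline background
#'
#' Governs how many background (germline) variants are planted per bp, the
#' SNV/insertion/deletion mix, the indel length distribution (truncated
#' geometric), the fraction of heterozygous sites and the
#' transition/transversion ratio used to pick SNV alternate alleles.
#'
#' The default type mix (89.24% SNV, 5.21% INS, 5.55% DEL) reflects the
#' composition of germline backgrounds typical of a normal human sample; the
#' default rate of 0.016 variants/bp yields roughly 3,000 background
#' variants on a ~186 kb three-gene panel.
#'
#' @param rate germline variants per bp of target.
#' @param type_probs named probabilities over `SNV`, `INS`, `DEL`; must sum
#'   to 1.
#' @param indel_geom_p geometric length parameter for indels.
#' @param max_indel_len truncation of the indel length distribution, bp.
#' @param het_fraction probability that a planted variant is heterozygous
#'   (expected VAF 0.5); the rest are homozygous (VAF 1.0). Default 1:
#'   every background variant is planted at 50% allele fraction.
#' @param ts_tv transition/transversion ratio for SNV alternate alleles.
#' @return an object of class `mutation_model`.
#' @export
mutation_model <- function(rate = 0.016,
                           type_probs = c(SNV = 0.8924, INS = 0.0521,
                                          DEL = 0.0555),
                           indel_geom_p = 0.3, max_indel_len = 10L,
                           het_fraction = 1.0, ts_tv = 2.0) {
  if (rate < 0) stop("rate must be >= 0")
  if (!all(c("SNV", "INS", "DEL") %in% names(type_probs))) {
    stop("type_probs needs entries SNV, INS and DEL")
  }
  type_probs <- type_probs[c("SNV", "INS", "DEL")]
  if (any(type_probs < 0)) stop("type_probs must be >= 0")
  if (abs(sum(type_probs) - 1) > 1e-9) {
    stop("type_probs must sum to 1 (got ", sum(type_probs), ")")
  }
  if (indel_geom_p <= 0 || indel_geom_p > 1) {
    stop("indel_geom_p must lie in (0, 1]")
  }
  max_indel_len <- as.integer(max_indel_len)
  if (max_indel_len < 1L) stop("max_indel_len must be >= 1")
  if (het_fraction < 0 || het_fraction > 1) {
    stop("het_fraction must lie in [0, 1]")
  }
  if (ts_tv <= 0) stop("ts_tv must be > 0")
  structure(
    list(rate = rate, type_probs = type_probs, indel_geom_p = indel_geom_p,
         max_indel_len = max_indel_len, het_fraction = het_fraction,
         ts_tv = ts_tv),
    class = "mutation_model"
  )
}

#' Default mutational model
#' @return a [mutation_model()] with the documented defaults.
#' @export
default_mutation_model <- function() mutation_model()

# truncated geometric on 1..max_len
sample_indel_len <- function(n, p, max_len) {
  probs <- stats::dgeom(0:(max_len - 1L), p)
  sample.int(max_len, n, replace = TRUE, prob = probs)
}

# SNV alternate alleles honouring the ts/tv ratio
sample_snv_alt <- function(refb, ts_tv) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  n <- length(refb)
  p_ts <- ts_tv / (ts_tv + 1)
  is_ts <- stats::runif(n) < p_ts
  alt <- character(n)
  alt[is_ts] <- transition[refb[is_ts]]
  if (any(!is_ts)) {
    tv <- which(!is_ts)
    for (i in tv) {
      opts <- setdiff(BASES, c(refb[i], transition[[refb[i]]]))
      alt[i] <- opts[sample.int(2L, 1L)]
    }
  }
  # reference N or other: any base
  bad <- !refb %in% BASES
  if (any(bad)) alt[bad] <- BASES[sample.int(4L, sum(bad), replace = TRUE)]
  alt
}

#' Load a model from a plain-text YAML config
#'
#' The config must carry `kind: sequencing` or `kind: mutation`; any other
#' key overrides the corresponding constructor default, and unknown keys are
#' an error. Invariants are re-validated by the constructor, which names the
#' offending key.
#'
#' @param path YAML file.
#' @return a [sequencing_model()] or [mutation_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  kind <- cfg$kind
  if (is.null(kind) || !kind %in% c("sequencing", "mutation")) {
    stop("config must set kind: sequencing or kind: mutation")
  }
  cfg$kind <- NULL
  ctor <- if (kind == "sequencing") sequencing_model else mutation_model
  known <- names(formals(ctor))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown model key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$type_probs)) cfg$type_probs <- unlist(cfg$type_probs)
  if (!is.null(cfg$gc_bias)) cfg$gc_bias <- as.data.frame(cfg$gc_bias)
  do.call(ctor, cfg)
}

#' @export
print.sequencing_model <- function(x, ...) {
  cat("<sequencing_model>\n",
      " read_length: ", x$read_length, " bp\n",
      " fragments:   ", x$frag_mean, " +/- ", x$frag_sd, " bp\n",
      " quality:     Q", round(x$qual_profile$mean[1]), " -> Q",
      round(x$qual_profile$mean[x$read_length]),
      " (sd ", x$qual_profile$sd, ")\n",
      " gc_bias:     ", if (is_flat_gc(x)) "flat" else "curved", "\n",
      " error_scale: ", x$error_scale, "\n", sep = "")
  invisible(x)
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("<mutation_model>\n",
      " rate:        ", x$rate, " variants/bp\n",
      " type_probs:  SNV ", x$type_probs[["SNV"]],
      ", INS ", x$type_probs[["INS"]],
      ", DEL ", x$type_probs[["DEL"]], "\n",
      " indels:      geometric(p=", x$indel_geom_p, ") truncated at ",
      x$max_indel_len, " bp\n",
      " het_fraction:", x$het_fraction, "\n", sep = "")
  invisible(x)
}
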