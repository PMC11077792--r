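# CIGAR / coordinate-map utilities shared by the read simulator and the
# spike-in editor. The central representation is `rp`, an integer vector
# giving, for every query base of a read, the 1-based reference position it
# is aligned to (NA for inserted or soft-clipped bases). All CIGARs are
# derived from such vectors, so M/I/D/S bookkeeping stays consistent by
# construction.

BASES <- c("A", "C", "G", "T")

#' Derive alignment position and CIGAR from a per-base reference map
#'
#' @param rp integer vector: reference position of each query base, NA where
#'   the base does not align (insertion); leading/trailing NA runs become
#'   soft clips, internal NA runs insertions, jumps > 1 deletions.
#' @return list with `pos` (leftmost aligned reference position) and `cigar`.
#' @keywords internal
derive_cigar <- function(rp) {
  n <- length(rp)
  al <- which(!is.na(rp))
  if (length(al) == 0L) {
    stop("read aligns to no reference base")
  }
  first <- al[1L]
  last <- al[length(al)]
  ops <- character(8L)
  lens <- integer(8L)
  k <- 0L
  push <- function(op, len) {
    if (len <= 0L) return(invisible())
    if (k > 0L && ops[k] == op) {
      lens[k] <<- lens[k] + len
    } else {
      k <<- k + 1L
      ops[k] <<- op
      lens[k] <<- len
    }
    invisible()
  }
  push("S", first - 1L)
  core <- rp[first:last]
  rl <- rle(is.na(core))
  seg_start <- cumsum(c(1L, rl$lengths[-length(rl$lengths)]))
  prev_ref <- NA_integer_
  for (s in seq_along(rl$lengths)) {
    seg <- core[seg_start[s]:(seg_start[s] + rl$lengths[s] - 1L)]
    if (rl$values[s]) {
      push("I", length(seg))
    } else {
      if (!is.na(prev_ref)) {
        gap <- seg[1L] - prev_ref - 1L
        if (gap < 0L) stop("non-monotone reference map")
        push("D", gap)
      }
      d <- diff(seg)
      if (length(d) && any(d != 1L)) {
        if (any(d < 1L)) stop("non-monotone reference map")
        br <- which(d != 1L)
        starts <- c(1L, br + 1L)
        ends <- c(br, length(seg))
        for (j in seq_along(starts)) {
          if (j > 1L) push("D", seg[starts[j]] - seg[ends[j - 1L]] - 1L)
          push("M", ends[j] - starts[j] + 1L)
        }
      } else {
        push("M", length(seg))
      }
      prev_ref <- seg[length(seg)]
    }
  }
  push("S", n - last)
  list(pos = rp[first],
       cigar = paste0(lens[seq_len(k)], ops[seq_len(k)], collapse = ""))
}

#' Expand a CIGAR into a per-query-base reference map (inverse of
#' `derive_cigar`).
#' @keywords internal
cigar_to_refpos <- function(cigar, pos) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1L]]
  out <- integer(sum(lens[ops %in% c("M", "I", "S", "=", "X")]))
  qi <- 0L
  ref <- pos
  for (j in seq_along(ops)) {
    op <- ops[j]
    len <- lens[j]
    if (op %in% c("M", "=", "X")) {
      out[(qi + 1L):(qi + len)] <- ref:(ref + len - 1L)
      qi <- qi + len
      ref <- ref + len
    } else if (op %in% c("I", "S")) {
      out[(qi + 1L):(qi + len)] <- NA_integer_
      qi <- qi + len
    } else if (op %in% c("D", "N")) {
      ref <- ref + len
    } else {
      stop("unsupported CIGAR op: ", op)
    }
  }
  out
}

# Reference width consumed by a vector of CIGARs (vectorised, C under the
# hood).
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

cigar_query_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
}

# Query offsets of reference position `p` for a set of reads known to
# overlap p. Simple all-M CIGARs take the arithmetic fast path; the rest walk
# their CIGAR. Returns NA where p falls in a deletion.
query_offsets_at <- function(pos, cigar, p, simple = NULL) {
  if (is.null(simple)) simple <- grepl("^[0-9]+M$", cigar)
  qoff <- rep(NA_integer_, length(pos))
  if (any(simple)) {
    w <- as.integer(sub("M$", "", cigar[simple]))
    q <- p - pos[simple] + 1L
    qoff[simple] <- ifelse(q >= 1L & q <= w, q, NA_integer_)
  }
  irr <- which(!simple)
  if (length(irr)) {
    # reads sharing (cigar, pos) have identical offsets: walk each once
    key <- paste0(cigar[irr], "@", pos[irr])
    uk <- which(!duplicated(key))
    uoff <- vapply(uk, function(j) {
      i <- irr[j]
      m <- match(p, cigar_to_refpos(cigar[i], pos[i]))
      if (is.na(m)) NA_integer_ else m
    }, integer(1L))
    qoff[irr] <- uoff[match(key, key[uk])]
  }
  qoff
}
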