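# Recombination signal (RS) detection.
#
# An RS is a conserved heptamer, a 12- or 23-bp spacer, and a nonamer. In
# the orientation written here ("forward"), the heptamer's first base is the
# one adjacent to the coding segment it serves:
#   <coding segment> CACAGTG <spacer> ACAAAAACC        (e.g. 3' of a V gene)
# An RS serving the 5' side of a segment (J genes, the 5' side of D genes)
# is the reverse complement of this layout and is reported as a minus-strand
# hit whose mirrored coordinates place the heptamer immediately 5' of the
# segment.

RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"

# Vectorized per-position mismatch counts of `pattern` along `chars`
# (character vector of the sequence). Returns integer vector of length
# nchar(seq) - w + 1. N never matches.
pattern_mismatch_profile <- function(chars, pattern) {
  w <- nchar(pattern)
  p <- seq_chars(pattern)
  n <- length(chars)
  if (n < w) return(integer(0L))
  m <- length(chars) - w + 1L
  mm <- integer(m)
  for (k in seq_len(w)) {
    mm <- mm + as.integer(chars[k:(k + m - 1L)] != p[k])
  }
  mm
}

#' Scan a sequence for recombination signals
#'
#' Finds all positions, on both strands, where the heptamer (consensus
#' `CACAGTG`) and nonamer (consensus `ACAAAAACC`) each lie within the given
#' mismatch maxima and the spacer between them is within +/-1 bp of the
#' spacer class. The score is the total mismatch count.
#'
#' For plus-strand hits `heptamer_start` is the 5'-most base of the heptamer
#' and the served coding segment ends at `heptamer_start - 1`. For
#' minus-strand hits `heptamer_start` is the forward-axis position of the
#' heptamer base adjacent to the coding segment, i.e. the segment starts at
#' `heptamer_start + 1`.
#'
#' @param seq Sequence to scan.
#' @param spacer_class 12 or 23.
#' @param max_heptamer_mm,max_nonamer_mm Mismatch maxima.
#' @param strands Strands to scan (default both).
#' @return data.frame: heptamer_start, spacer_class, spacer_length, strand,
#'   heptamer_mismatches, nonamer_mismatches, total_score; sorted by
#'   position then strand then spacer_length.
#' @export
scan_rss <- function(seq, spacer_class = c(23L, 12L), max_heptamer_mm = 2L,
                     max_nonamer_mm = 3L, strands = c("+", "-")) {
  spacer_class <- as.integer(spacer_class[1L])
  stopifnot(spacer_class %in% c(12L, 23L))
  s <- as_seq_string(seq)
  n <- nchar(s)
  min_len <- 7L + spacer_class - 1L + 9L
  if (n < min_len) stop("sequence shorter than minimal RS span")
  out <- list()
  for (strand in strands) {
    str_seq <- if (strand == "+") s else revcomp(s)
    chars <- seq_chars(str_seq)
    hmm <- pattern_mismatch_profile(chars, RSS_HEPTAMER)
    nmm <- pattern_mismatch_profile(chars, RSS_NONAMER)
    hpos <- which(hmm <= max_heptamer_mm)
    if (!length(hpos)) next
    for (spacer in spacer_class + (-1L:1L)) {
      npos <- hpos + 7L + spacer
      ok <- npos >= 1L & npos <= length(nmm)
      keep <- ok
      keep[ok] <- nmm[npos[ok]] <= max_nonamer_mm
      if (!any(keep)) next
      hp <- hpos[keep]
      hm <- hmm[hp]
      nm <- nmm[npos[keep]]
      # map to forward axis: heptamer_start is the coding-adjacent base
      fwd <- if (strand == "+") hp else n - hp + 1L
      out[[length(out) + 1L]] <- data.frame(
        heptamer_start = fwd, spacer_class = spacer_class,
        spacer_length = spacer, strand = strand,
        heptamer_mismatches = hm, nonamer_mismatches = nm,
        total_score = hm + nm, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(heptamer_start = integer(), spacer_class = integer(),
                      spacer_length = integer(), strand = character(),
                      heptamer_mismatches = integer(),
                      nonamer_mismatches = integer(), total_score = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$heptamer_start, res$strand, res$spacer_length), ]
  rownames(res) <- NULL
  res
}

# Evaluate a putative RS at a fixed position (no thresholding): used by the
# gene finders, which know where the RS must sit and record however degraded
# it is. `heptamer_start` follows the scan_rss coordinate convention for the
# given strand. Returns the best (lowest total mismatch) spacer in
# spacer_class +/- 1.
evaluate_rss_at <- function(seq, heptamer_start, spacer_class, strand = "+") {
  s <- as_seq_string(seq)
  n <- nchar(s)
  if (strand == "+") {
    pos <- heptamer_start
    str_seq <- s
  } else {
    str_seq <- revcomp(s)
    pos <- n - heptamer_start + 1L
  }
  best <- NULL
  for (spacer in spacer_class + (-1L:1L)) {
    hep_end <- pos + 6L
    non_start <- pos + 7L + spacer
    non_end <- non_start + 8L
    if (pos < 1L || non_end > n) next
    hm <- hamming(substring(str_seq, pos, hep_end), RSS_HEPTAMER)
    nm <- hamming(substring(str_seq, non_start, non_end), RSS_NONAMER)
    cand <- list(heptamer_start = heptamer_start, spacer_class = spacer_class,
                 spacer_length = spacer, strand = strand,
                 heptamer_mismatches = hm, nonamer_mismatches = nm,
                 total_score = hm + nm, found = TRUE)
    if (is.null(best) || cand$total_score < best$total_score) best <- cand
  }
  best %||% list(heptamer_start = heptamer_start, spacer_class = spacer_class,
                 spacer_length = NA_integer_, strand = strand,
                 heptamer_mismatches = NA_integer_,
                 nonamer_mismatches = NA_integer_,
                 total_score = NA_integer_, found = FALSE)
}
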