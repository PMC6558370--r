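# Cross-species comparison: ungapped percent-identity segments (the
# percentage-identity-plot view of co-linearity), GC profiling, and
# Table-style annotation summaries.

#' Ungapped local-identity segments between two sequences
#'
#' k-mer seeded, ungapped-extended local matches on both strands, merged
#' per diagonal — the machinery behind a percentage identity plot (pip).
#' Segments shorter than `min_len` or below `min_identity` are dropped.
#' N never matches, so an assembly gap in either sequence breaks the
#' homology line into separate segments.
#'
#' @param query,target Sequences.
#' @param min_len Minimum segment length (bp).
#' @param min_identity Minimum percent identity.
#' @param k Seed width.
#' @param step Seed sampling stride along the query.
#' @param max_mismatch_run Extension stops after this many consecutive
#'   mismatches (the trailing mismatch run is trimmed).
#' @return data.frame: qstart, qend, tstart, tend, strand, pct_id, sorted
#'   by qstart.
#' @export
pip_segments <- function(query, target, min_len = 100L, min_identity = 50,
                         k = 12L, step = 4L, max_mismatch_run = 10L) {
  q <- as_seq_string(query)
  t_fwd <- as_seq_string(target)
  stopifnot(nchar(q) > 0L, nchar(t_fwd) > 0L)
  out <- list()
  qch <- seq_chars(q)
  for (strand in c("+", "-")) {
    t_or <- if (strand == "+") t_fwd else revcomp(t_fwd)
    tch <- seq_chars(t_or)
    nq <- length(qch); ntg <- length(tch)
    offs <- seq(1L, max(nq - k + 1L, 1L), by = step)
    kmers <- substring(q, offs, offs + k - 1L)
    okk <- !grepl("N", kmers, fixed = TRUE) & nchar(kmers) == k
    offs <- offs[okk]; kmers <- kmers[okk]
    if (!length(offs)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
    hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(t_or))
    nh <- S4Vectors::elementNROWS(hits)
    if (sum(nh) == 0L) next
    idx <- rep.int(seq_along(nh), nh)
    tpos <- unlist(IRanges::start(hits), use.names = FALSE)
    qpos <- offs[idx]
    diag <- tpos - qpos
    o <- order(diag, qpos)
    diag <- diag[o]; qpos <- qpos[o]
    grp <- cumsum(c(1L, diff(diag) != 0L | diff(qpos) > (k + step) * 4L))
    for (g in unique(grp)) {
      sel <- grp == g
      d <- diag[sel][1L]
      qa <- min(qpos[sel]); qb <- max(qpos[sel]) + k - 1L
      # ungapped extension outward, trimming trailing mismatch runs
      ext <- function(pos, dir) {
        run <- 0L
        last_good <- pos
        p <- pos + dir
        while (p >= 1L && p <= nq && p + d >= 1L && p + d <= ntg) {
          a <- qch[p]; b <- tch[p + d]
          if (a != "N" && a == b) {
            run <- 0L
            last_good <- p
          } else {
            run <- run + 1L
            if (run >= max_mismatch_run) break
          }
          p <- p + dir
        }
        last_good
      }
      qa <- ext(qa, -1L)
      qb <- ext(qb, 1L)
      seg_q <- qch[qa:qb]
      seg_t <- tch[(qa + d):(qb + d)]
      len <- qb - qa + 1L
      if (len < min_len) next
      pid <- 100 * sum(seg_q == seg_t & seg_q != "N") / len
      if (pid < min_identity) next
      ta <- qa + d; tb <- qb + d
      if (strand == "-") {
        ta2 <- nchar(t_fwd) - tb + 1L
        tb2 <- nchar(t_fwd) - ta + 1L
        ta <- ta2; tb <- tb2
      }
      out[[length(out) + 1L]] <- data.frame(
        qstart = qa, qend = qb, tstart = ta, tend = tb, strand = strand,
        pct_id = pid, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(qstart = integer(), qend = integer(), tstart = integer(),
                      tend = integer(), strand = character(), pct_id = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # merge overlapping hits per (strand, diagonal)
  key <- ifelse(res$strand == "+", res$tstart - res$qstart, res$tstart + res$qend)
  ord <- order(res$strand, key, res$qstart)
  res <- res[ord, , drop = FALSE]
  key <- key[ord]
  merged <- list()
  for (i in seq_len(nrow(res))) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$strand == res$strand[i] &&
        last$key == key[i] && res$qstart[i] <= last$qend + 1L) {
      last$qend <- max(last$qend, res$qend[i])
      last$tstart <- min(last$tstart, res$tstart[i])
      last$tend <- max(last$tend, res$tend[i])
      last$pct_id <- max(last$pct_id, res$pct_id[i])
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- c(as.list(res[i, ]), key = key[i])
    }
  }
  res <- do.call(rbind, lapply(merged, function(x) {
    data.frame(qstart = x$qstart, qend = x$qend, tstart = x$tstart,
               tend = x$tend, strand = x$strand, pct_id = x$pct_id,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$qstart), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Windowed GC profile
#'
#' @param seq Sequence.
#' @param window Window size (bp).
#' @return data.frame: start, gc (fraction over non-N bases; `NA` for
#'   windows that are entirely N). Attribute `global_gc` carries the
#'   whole-sequence value.
#' @export
gc_profile <- function(seq, window = 1000L) {
  stopifnot(window >= 1L)
  s <- as_seq_string(seq)
  n <- nchar(s)
  starts <- seq(1L, n, by = window)
  ch <- seq_chars(s)
  gcv <- vapply(starts, function(st) {
    en <- min(st + window - 1L, n)
    w <- ch[st:en]
    denom <- sum(w != "N")
    if (denom == 0L) NA_real_ else sum(w %in% c("G", "C")) / denom
  }, numeric(1L))
  out <- data.frame(start = starts, gc = gcv)
  attr(out, "global_gc") <- gc_fraction(s)
  out
}
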