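#' Read a genome assembly from FASTA
#'
#' Reads scaffold sequences, normalizes residues to uppercase and maps IUPAC
#' ambiguity codes other than N to N (draft assemblies often contain stray
#' ambiguity codes; they are treated as unknown bases, with a warning).
#'
#' @param fasta_path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] over the alphabet A,C,G,T,N.
#'   Record order is preserved.
#' @export
read_assembly <- function(fasta_path) {
  stopifnot(file.exists(fasta_path))
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) == 0L) stop("no sequences in ", fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(ss) <- ids
  chars <- Biostrings::uniqueLetters(ss)
  odd <- setdiff(chars, c("A", "C", "G", "T", "N"))
  if (length(odd)) {
    warning("ambiguity codes mapped to N: ", paste(odd, collapse = ", "))
    s <- vapply(as.character(ss), function(x) {
      gsub("[^ACGTN]", "N", toupper(x))
    }, character(1L))
    ss <- Biostrings::DNAStringSet(s)
    names(ss) <- ids
  }
  ss
}

#' Detect N-gap runs in a scaffold
#'
#' @param seq A single sequence (character, DNAString, or length-1
#'   DNAStringSet).
#' @param min_run Minimum run length (bp) for a run of N to count as an
#'   assembly gap.
#' @return A data.frame with columns `start`, `end` (1-based, inclusive) and
#'   `length`, sorted by start. Maximal runs only.
#' @export
detect_gaps <- function(seq, min_run = 10L) {
  stopifnot(min_run >= 1L)
  s <- as_seq_string(seq)
  m <- gregexpr(sprintf("N{%d,}", as.integer(min_run)), s)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len - 1L, length = len)
}

#' Length of a 1-based closed genomic interval
#'
#' Coordinates throughout the package are 1-based and fully closed
#' (GenBank-style), so the length of `[start, end]` is `end - start + 1`.
#'
#' @param start,end 1-based positions, `end >= start >= 1`.
#' @return Interval length in bp.
#' @export
region_length <- function(start, end) {
  stopifnot(all(start >= 1L))
  if (any(end < start)) stop("end < start")
  as.integer(end - start + 1L)
}

#' Translate a spliced coding sequence
#'
#' Splices the given exon intervals out of a scaffold, reverse-complements
#' for minus-strand genes, and translates with the standard code. Internal
#' stops are rendered as `*`; a trailing partial codon is dropped (flagged).
#'
#' @param exons Two-column matrix (or data.frame) of exon `start`,`end`
#'   intervals on the forward axis, non-overlapping, in forward order.
#' @param strand `"+"` or `"-"`.
#' @param seq The scaffold sequence.
#' @param gaps Optional gap table from [detect_gaps()]; exons overlapping a
#'   gap mark the result incomplete.
#' @return Character scalar protein with attributes `incomplete` (logical)
#'   and `partial_codon` (logical).
#' @export
translate_cds <- function(exons, strand = "+", seq, gaps = NULL) {
  s <- as_seq_string(seq)
  ex <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(ex) <- "integer"
  if (any(ex[, 1L] < 1L) || any(ex[, 2L] > nchar(s))) {
    stop("exon outside sequence bounds")
  }
  if (any(ex[, 2L] < ex[, 1L])) stop("exon end < start")
  ex <- ex[order(ex[, 1L]), , drop = FALSE]
  incomplete <- FALSE
  if (!is.null(gaps) && nrow(gaps)) {
    for (i in seq_len(nrow(ex))) {
      if (any(gaps$start <= ex[i, 2L] & gaps$end >= ex[i, 1L])) {
        incomplete <- TRUE
      }
    }
  }
  spliced <- paste0(substring(s, ex[, 1L], ex[, 2L]), collapse = "")
  if (identical(strand, "-")) spliced <- revcomp(spliced)
  partial <- (nchar(spliced) %% 3L) != 0L
  prot <- translate_string(spliced)
  attr(prot, "incomplete") <- incomplete
  attr(prot, "partial_codon") <- partial
  prot
}

#' Order scaffolds by exact terminal overlaps
#'
#' Greedy chaining of scaffolds whose 3' end exactly matches another
#' scaffold's 5' start over at least `min_overlap` bp, the situation seen
#' when short bridging scaffolds tie two larger ones into one locus.
#' Overlap detection is exact-match only.
#'
#' @param scaffolds Named [Biostrings::DNAStringSet] (or named character
#'   vector) of scaffold sequences.
#' @param min_overlap Minimum exact terminal overlap (bp).
#' @return An object of class `scaffold_layout`: list with `chains` (list of
#'   data.frames: scaffold, orientation, overlap_with_prev), `unplaced`
#'   (character), `merged_lengths` (bp per chain) and `sequences`.
#' @export
stitch_scaffolds <- function(scaffolds, min_overlap = 100L) {
  if (inherits(scaffolds, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(scaffolds), names(scaffolds))
  } else {
    seqs <- scaffolds
  }
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  ids <- names(seqs)
  n <- length(ids)
  # best exact suffix(i)/prefix(j) overlap >= min_overlap
  best_overlap <- function(a, b) {
    lmax <- min(nchar(a), nchar(b)) - 1L
    for (L in rev(seq_len(lmax))) {
      if (L < min_overlap) break
      if (substring(a, nchar(a) - L + 1L, nchar(a)) == substring(b, 1L, L)) {
        return(L)
      }
    }
    0L
  }
  ov <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) ov[i, j] <- best_overlap(seqs[[i]], seqs[[j]])
  }
  succ <- rep(NA_character_, n); names(succ) <- ids
  pred <- rep(NA_character_, n); names(pred) <- ids
  for (i in seq_len(n)) {
    cand <- which(ov[i, ] > 0L)
    if (length(cand) > 1L) {
      top <- cand[ov[i, cand] == max(ov[i, cand])]
      if (length(top) > 1L) {
        stop("ambiguous overlap: 3' end of ", ids[i], " matches ",
             paste(ids[top], collapse = ", "), " equally")
      }
      cand <- top
    }
    if (length(cand) == 1L) succ[i] <- ids[cand]
  }
  for (j in names(succ)[!is.na(succ)]) {
    tgt <- succ[[j]]
    if (!is.na(pred[[tgt]])) {
      stop("ambiguous overlap: 5' start of ", tgt, " matches ",
           pred[[tgt]], " and ", j)
    }
    pred[[tgt]] <- j
  }
  heads <- ids[is.na(pred) & !is.na(succ)]
  chains <- list()
  used <- character()
  for (h in heads) {
    ord <- h
    while (!is.na(succ[[ord[length(ord)]]])) {
      nxt <- succ[[ord[length(ord)]]]
      if (nxt %in% ord) stop("circular overlap chain at ", nxt)
      ord <- c(ord, nxt)
    }
    ovl <- c(0L, vapply(seq_along(ord)[-1L], function(k) {
      ov[ord[k - 1L], ord[k]]
    }, integer(1L)))
    chains[[length(chains) + 1L]] <- data.frame(
      scaffold = ord, orientation = "+", overlap_with_prev = ovl,
      stringsAsFactors = FALSE)
    used <- c(used, ord)
  }
  unplaced <- setdiff(ids, used)
  merged <- vapply(chains, function(ch) {
    sum(nchar(seqs[ch$scaffold])) - sum(ch$overlap_with_prev)
  }, numeric(1L))
  structure(list(chains = chains, unplaced = unplaced,
                 merged_lengths = as.integer(merged), sequences = seqs,
                 min_overlap = as.integer(min_overlap)),
            class = "scaffold_layout")
}

#' @export
print.scaffold_layout <- function(x, ...) {
  cat("Scaffold layout:", length(x$chains), "chain(s),",
      length(x$unplaced), "unplaced\n")
  for (k in seq_along(x$chains)) {
    cat(sprintf("  chain %d (%d bp merged): %s\n", k, x$merged_lengths[k],
                paste(x$chains[[k]]$scaffold, collapse = " -> ")))
  }
  if (length(x$unplaced)) cat("  unplaced:", paste(x$unplaced, collapse = ", "), "\n")
  invisible(x)
}

#' Merge a stitched chain into a single sequence
#'
#' @param layout A `scaffold_layout`.
#' @param chain Chain index.
#' @return Character scalar of the merged sequence.
#' @export
merge_chain <- function(layout, chain = 1L) {
  ch <- layout$chains[[chain]]
  out <- layout$sequences[[ch$scaffold[1L]]]
  for (k in seq_len(nrow(ch))[-1L]) {
    s <- layout$sequences[[ch$scaffold[k]]]
    out <- paste0(out, substring(s, ch$overlap_with_prev[k] + 1L, nchar(s)))
  }
  out
}

#' Write a scaffold layout as AGP v2.1
#'
#' Each chain becomes one AGP object; overlapped portions are attributed to
#' the earlier scaffold, so component coordinates tile the object exactly.
#'
#' @param layout A `scaffold_layout` from [stitch_scaffolds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(layout, path) {
  rows <- list()
  for (k in seq_along(layout$chains)) {
    ch <- layout$chains[[k]]
    obj <- paste0("chain", k)
    pos <- 0L
    for (i in seq_len(nrow(ch))) {
      id <- ch$scaffold[i]
      len <- nchar(layout$sequences[[id]])
      comp_beg <- ch$overlap_with_prev[i] + 1L
      seg <- len - ch$overlap_with_prev[i]
      rows[[length(rows) + 1L]] <- data.frame(
        object = obj, object_beg = pos + 1L, object_end = pos + seg,
        part_number = i, component_type = "W", component_id = id,
        component_beg = comp_beg, component_end = len, orientation = "+",
        stringsAsFactors = FALSE)
      pos <- pos + seg
    }
  }
  for (id in layout$unplaced) {
    len <- nchar(layout$sequences[[id]])
    rows[[length(rows) + 1L]] <- data.frame(
      object = id, object_beg = 1L, object_end = len, part_number = 1L,
      component_type = "W", component_id = id, component_beg = 1L,
      component_end = len, orientation = "+", stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Whole-sequence GC fraction
#' @param seq Sequence.
#' @return G+C over non-N length; NA if no non-N bases.
#' @keywords internal
gc_fraction <- function(seq) {
  s <- as_seq_string(seq)
  ch <- seq_chars(s)
  denom <- sum(ch != "N")
  if (denom == 0L) return(NA_real_)
  sum(ch %in% c("G", "C")) / denom
}
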