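# V subgroup classification: pairwise nucleotide identity over the
# V-region, single-linkage clustering at the >75% threshold, and
# ortholog-aware nomenclature.

#' Percent nucleotide identity between two sequences
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch -1, and an
#' affine gap costing 5 for the first base and 1 for each additional base;
#' identity is the fraction of matching columns among aligned columns,
#' excluding end-gap overhangs from the denominator (draft gene calls may
#' truncate termini).
#'
#' @param a,b Nucleotide sequences (character scalars, A/C/G/T).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- as_seq_string(a); b <- as_seq_string(b)
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  .align_identity_batch(a, b)
}

# Global alignment of many patterns against one subject under the package
# scoring scheme, returning percent identities. For PairwiseAlignments,
# nchar() is the number of aligned columns excluding end-gap overhangs
# (internal gap columns included) and nmatch() the matching columns, which
# is exactly the identity definition used here.
.align_identity_batch <- function(patterns, subject) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  cols <- Biostrings::nchar(al)
  ifelse(cols > 0L, 100 * Biostrings::nmatch(al) / cols, 0)
}

#' Symmetric percent-identity matrix
#'
#' @param seqs Named character vector of V-region sequences.
#' @return Symmetric matrix with 100 on the diagonal.
#' @export
identity_matrix <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 1L, !is.null(names(seqs)))
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) {
    for (j in 2:n) {
      ids <- .align_identity_batch(unname(seqs[seq_len(j - 1L)]), seqs[[j]])
      m[seq_len(j - 1L), j] <- m[j, seq_len(j - 1L)] <- ids
    }
  }
  m
}

#' Cluster V genes into subgroups by identity threshold
#'
#' Single-linkage components of the graph whose edges join genes with
#' identity strictly greater than `threshold` ("more than 75%"): if A-B and
#' B-C each exceed the threshold, A, B and C share a subgroup even if A-C
#' does not. Subgroups are numbered by the position of their 5'-most
#' member, so the result is invariant under input-order permutation.
#'
#' @param genes Either a named character vector of V-region sequences, or a
#'   list of V `gene_model`s carrying `vexon_seq`.
#' @param threshold Percent identity threshold (strict inequality).
#' @param starts Optional numeric vector of genomic starts (for ordering);
#'   taken from the models when `genes` is a model list.
#' @param idm Optional precomputed identity matrix.
#' @return data.frame: gene, subgroup (integer), with attribute
#'   `identity_matrix`.
#' @export
cluster_subgroups <- function(genes, threshold = 75, starts = NULL, idm = NULL) {
  if (is.list(genes) && length(genes) && inherits(genes[[1L]], "gene_model")) {
    seqs <- stats::setNames(
      vapply(genes, function(m) m$vexon_seq, character(1L)),
      vapply(genes, `[[`, character(1L), "name"))
    starts <- starts %||% vapply(genes, gene_start, numeric(1L))
  } else {
    seqs <- genes
  }
  stopifnot(length(seqs) >= 1L)
  if (is.null(idm)) idm <- identity_matrix(seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (idm[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  if (is.null(starts)) starts <- seq_len(n)
  first_start <- vapply(unique(comp), function(cc) min(starts[comp == cc]), numeric(1L))
  rank <- match(comp, unique(comp)[order(first_start)])
  out <- data.frame(gene = names(seqs), subgroup = rank, stringsAsFactors = FALSE)
  out <- out[order(starts), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "identity_matrix") <- idm
  out
}

#' Name subgroups after their best-matching reference subgroup
#'
#' A subgroup inherits the name of the reference subgroup of its
#' best-identity reference hit, provided that identity exceeds the
#' threshold. Multi-member subgroups name their genes `<name>S<k>` with `k`
#' in genomic order; single-member subgroups use the bare name. Subgroups
#' with no qualifying reference receive sequential provisional numbers
#' after the last reference number.
#'
#' @param assignment Output of [cluster_subgroups()] (ordered by genomic
#'   position).
#' @param seqs Named character vector of the same genes' V-region
#'   sequences.
#' @param references A `reference_library` whose V records carry
#'   `subgroup` names like `TRBV12`.
#' @param threshold Identity threshold for inheriting a reference name.
#' @return `assignment` with columns `name`, `best_ref`, `ref_identity`.
#' @export
assign_nomenclature <- function(assignment, seqs, references, threshold = 75) {
  vrefs <- ref_subset(references, "V")
  stopifnot(length(vrefs$records) >= 1L)
  ref_names <- vapply(vrefs$records, function(r) r$subgroup %||% r$name, character(1L))
  ref_vexon <- vapply(vrefs$records, function(r) {
    if (!is.null(r$leader_len)) {
      s <- r$leader_len + r$intron_len + 1L
      substring(r$seq, s, s + r$vexon_len - 1L)
    } else r$seq
  }, character(1L))
  sgs <- sort(unique(assignment$subgroup))
  claimed <- character()
  sg_name <- character(length(sgs))
  ref_numbers <- suppressWarnings(as.integer(sub("^\\D+", "", ref_names)))
  next_prov <- max(c(ref_numbers, 0L), na.rm = TRUE) + 1L
  # gene x reference identity, one vectorized alignment call per gene
  gid <- matrix(NA_real_, nrow(assignment), length(ref_vexon),
                dimnames = list(assignment$gene, NULL))
  for (g in assignment$gene) {
    gid[g, ] <- .align_identity_batch(unname(ref_vexon), seqs[[g]])
  }
  for (k in seq_along(sgs)) {
    members <- assignment$gene[assignment$subgroup == sgs[k]]
    sub <- gid[members, , drop = FALSE]
    best_id <- max(sub)
    best_refs <- ref_names[unique(which(sub == best_id, arr.ind = TRUE)[, 2L])]
    best_ref <- sort(best_refs)[1L]
    if (best_id > threshold) {
      nm <- best_ref
      if (nm %in% claimed) {
        other <- sgs[which(sg_name[seq_len(k - 1L)] == nm)[1L]]
        stop("two subgroups claim reference name ", nm,
             ": subgroups ", other, " and ", sgs[k])
      }
      claimed <- c(claimed, nm)
    } else {
      nm <- paste0("TRBV", next_prov)
      next_prov <- next_prov + 1L
    }
    sg_name[k] <- nm
    assignment$best_ref[assignment$subgroup == sgs[k]] <- best_ref
    assignment$ref_identity[assignment$subgroup == sgs[k]] <- best_id
  }
  assignment$name <- NA_character_
  for (k in seq_along(sgs)) {
    idx <- which(assignment$subgroup == sgs[k])
    if (length(idx) > 1L) {
      assignment$name[idx] <- paste0(sg_name[k], "S", seq_along(idx))
    } else {
      assignment$name[idx] <- sg_name[k]
    }
  }
  assignment
}
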