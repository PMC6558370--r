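# IMGT-style functionality classification.
#
# Labels: F (functional), ORF (open reading frame with an altered conserved
# feature), P (pseudogene), nd (sequence too incomplete to call). Severity
# is ordered nd > P > ORF > F: incompleteness dominates everything, a
# crippling coding lesion dominates a conserved-feature alteration.
#
# The criteria: (a) presence of the leader sequence (V genes); (b) proper
# recombination signals; (c) conserved GT/AG splice dinucleotides; (d)
# coding-region length within the expected range; (e) absence of
# frameshifts and stop codons.

#' Default expected coding-region length ranges (bp)
#'
#' The length criterion is stated qualitatively in locus annotation
#' practice; these defaults bracket the canonical segment sizes and are
#' config-exposed.
#' @export
default_expected_lengths <- function() {
  list(V = c(280L, 310L), D = c(10L, 20L), J = c(40L, 60L), C = c(500L, 560L))
}

#' Find the FGXG motif in a protein
#'
#' The Phe-Gly-X-Gly tetrapeptide conserved in functional J segments.
#'
#' @param protein Amino-acid string (20-letter alphabet plus `*`).
#' @return 1-based position of the first F-G-any-G occurrence, or `NA` if
#'   absent.
#' @export
check_fgxg <- function(protein) {
  m <- regexpr("FG.G", protein)
  if (m[1L] == -1L) NA_integer_ else as.integer(m[1L])
}

# RS functional threshold: a "proper" RS has heptamer <= 1 and nonamer <= 2
# mismatches from consensus. A detected-but-worse RS is an ORF-level
# conserved-feature alteration, not a pseudogenizing lesion.
.rs_proper <- function(rs, max_hept = 1L, max_non = 2L) {
  if (is.null(rs) || !isTRUE(rs$found %||% TRUE)) return(FALSE)
  if (is.na(rs$heptamer_mismatches %||% NA) || is.na(rs$nonamer_mismatches %||% NA)) {
    return(FALSE)
  }
  rs$heptamer_mismatches <= max_hept && rs$nonamer_mismatches <= max_non
}

#' Classify one gene model as F / ORF / P / nd
#'
#' @param model A `gene_model` (from the finders in this package).
#' @param seq The scaffold sequence the model's coordinates refer to.
#' @param expected_lengths Per-type coding length ranges, as
#'   [default_expected_lengths()].
#' @param gaps Optional precomputed gap table for `seq`.
#' @return List with `label` and `reasons` (character vector of codes from
#'   NO_LEADER, RS_DEFECT, SPLICE_DEFECT, BAD_LENGTH, FRAMESHIFT,
#'   STOP_CODON, MOTIF_ABSENT, INCOMPLETE).
#' @export
classify_gene <- function(model, seq, expected_lengths = default_expected_lengths(),
                          gaps = NULL) {
  if (!model$type %in% c("V", "D", "J", "C", "TRY", "FLANK")) {
    stop("unknown gene type: ", model$type)
  }
  s <- as_seq_string(seq)
  n <- nchar(s)
  if (is.null(gaps)) gaps <- detect_gaps(s)
  ex <- model$exons
  # nd dominates: split/incomplete models, exons over gaps or off the end
  incomplete <- any(c("incomplete", "split_by_gap") %in% model$flags) ||
    any(ex[, 1L] < 1L) || any(ex[, 2L] > n)
  if (!incomplete && nrow(gaps)) {
    for (i in seq_len(nrow(ex))) {
      if (any(gaps$start <= ex[i, 2L] & gaps$end >= ex[i, 1L])) incomplete <- TRUE
    }
  }
  if (incomplete) {
    return(list(label = "nd", reasons = "INCOMPLETE"))
  }
  p_reasons <- character()
  orf_reasons <- character()
  type <- model$type
  oriented <- function(iv) {
    sub <- substring(s, iv[1L], iv[2L])
    if (model$strand == "-") revcomp(sub) else sub
  }

  if (type == "V") {
    # coding exon (V-exon) is the 3'-most exon in coding order
    if (nrow(ex) < 2L || "no_leader" %in% model$flags) {
      p_reasons <- c(p_reasons, "NO_LEADER")
    }
    vx_iv <- if (nrow(ex) >= 2L) {
      if (model$strand == "+") ex[nrow(ex), ] else ex[1L, ]
    } else ex[1L, ]
    vx <- oriented(vx_iv)
    if (any(c("no_donor", "no_acceptor") %in% model$flags)) {
      p_reasons <- c(p_reasons, "SPLICE_DEFECT")
    }
    ref_len <- model$ref_coding_length %||% nchar(vx)
    if ((nchar(vx) %% 3L) != (ref_len %% 3L)) {
      p_reasons <- c(p_reasons, "FRAMESHIFT")
    }
    if (grepl("*", translate_string(vx), fixed = TRUE)) {
      p_reasons <- c(p_reasons, "STOP_CODON")
    }
    if (!.rs_proper(model$rss$v_rs)) orf_reasons <- c(orf_reasons, "RS_DEFECT")
    rng <- expected_lengths$V
    if (nchar(vx) < rng[1L] || nchar(vx) > rng[2L]) {
      orf_reasons <- c(orf_reasons, "BAD_LENGTH")
    }
  } else if (type == "D") {
    len <- ex[1L, 2L] - ex[1L, 1L] + 1L
    if (!.rs_proper(model$rss$d5_rs) || !.rs_proper(model$rss$d3_rs)) {
      orf_reasons <- c(orf_reasons, "RS_DEFECT")
    }
    rng <- expected_lengths$D
    if (len < rng[1L] || len > rng[2L]) orf_reasons <- c(orf_reasons, "BAD_LENGTH")
  } else if (type == "J") {
    if ("no_donor" %in% model$flags) p_reasons <- c(p_reasons, "SPLICE_DEFECT")
    len <- ex[1L, 2L] - ex[1L, 1L] + 1L
    off <- len %% 3L
    prot <- translate_string(substring(s, ex[1L, 1L] + off, ex[1L, 2L]))
    if (grepl("*", prot, fixed = TRUE)) p_reasons <- c(p_reasons, "STOP_CODON")
    if (!.rs_proper(model$rss$j_rs)) orf_reasons <- c(orf_reasons, "RS_DEFECT")
    rng <- expected_lengths$J
    if (len < rng[1L] || len > rng[2L]) orf_reasons <- c(orf_reasons, "BAD_LENGTH")
    # FGXG absence is a conserved-feature alteration, not a pseudogene call
    if (is.na(check_fgxg(prot)) || "fgxg_absent" %in% model$flags) {
      orf_reasons <- c(orf_reasons, "MOTIF_ABSENT")
    }
  } else if (type == "C") {
    if (any(c("no_donor", "no_acceptor") %in% model$flags)) {
      p_reasons <- c(p_reasons, "SPLICE_DEFECT")
    }
    spliced <- paste0(vapply(seq_len(nrow(ex)), function(i) {
      substring(s, ex[i, 1L], ex[i, 2L])
    }, character(1L)), collapse = "")
    if (model$strand == "-") spliced <- revcomp(spliced)
    prot <- translate_string(spliced)
    body <- substring(prot, 1L, nchar(prot) - 1L)  # terminal stop is canonical
    if (grepl("*", body, fixed = TRUE)) p_reasons <- c(p_reasons, "STOP_CODON")
    ref_len <- model$ref_coding_length %||% nchar(spliced)
    if ((nchar(spliced) %% 3L) != (ref_len %% 3L)) {
      p_reasons <- c(p_reasons, "FRAMESHIFT")
    }
    rng <- expected_lengths$C
    if (nchar(spliced) < rng[1L] || nchar(spliced) > rng[2L]) {
      orf_reasons <- c(orf_reasons, "BAD_LENGTH")
    }
  } else {  # TRY / FLANK: single-exon; only an intact frame is required
    cds <- oriented(ex[1L, ])
    prot <- translate_string(cds)
    body <- substring(prot, 1L, nchar(prot) - 1L)
    if (type == "TRY" && grepl("*", body, fixed = TRUE)) {
      p_reasons <- c(p_reasons, "STOP_CODON")
    }
  }

  if (length(p_reasons)) {
    list(label = "P", reasons = unique(c(p_reasons, orf_reasons)))
  } else if (length(orf_reasons)) {
    list(label = "ORF", reasons = unique(orf_reasons))
  } else {
    list(label = "F", reasons = character())
  }
}

#' Classify every gene on a locus map
#'
#' @param map A `locus_map` (single-scaffold).
#' @param seq The scaffold sequence.
#' @param expected_lengths As [classify_gene()].
#' @return The map with `functionality` and `reasons` set on each gene.
#' @export
classify_locus <- function(map, seq, expected_lengths = default_expected_lengths()) {
  s <- as_seq_string(seq)
  gaps <- detect_gaps(s)
  for (i in seq_along(map$genes)) {
    call <- classify_gene(map$genes[[i]], s, expected_lengths, gaps = gaps)
    map$genes[[i]]$functionality <- call$label
    map$genes[[i]]$reasons <- call$reasons
  }
  map
}
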