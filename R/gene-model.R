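# Gene models and locus maps: the containers shared by the annotation,
# functionality, subgroup and comparative stages.

#' Construct a gene model
#'
#' A typed gene segment (V, D, J, C, TRY or FLANK) with its exons on the
#' forward coordinate axis, strand, attached recombination-signal (RS)
#' evaluations, homology evidence and flags.
#'
#' @param name Gene name.
#' @param type One of `"V"`, `"D"`, `"J"`, `"C"`, `"TRY"`, `"FLANK"`.
#' @param exons Two-column integer matrix of `start`,`end` intervals (forward
#'   axis, ascending). For V genes the rows are leader exon then V-exon in
#'   forward order (coding order is reversed on the minus strand).
#' @param strand `"+"` or `"-"`.
#' @param scaffold Scaffold id the coordinates refer to.
#' @param rss Named list of RS evaluations (roles `v_rs`, `d5_rs`, `d3_rs`,
#'   `j_rs`), each a list with `heptamer_start`, `spacer_class`,
#'   `heptamer_mismatches`, `nonamer_mismatches`, `spacer_length`, `strand`,
#'   `found`.
#' @param homology List with `ref` (best reference id) and `identity`
#'   (percent), or NULL.
#' @param flags Character vector drawn from `split_by_gap`,
#'   `duplicate_region`, `incomplete`, `no_leader`, `no_donor`,
#'   `no_acceptor`, `fgxg_absent`, `overlap_shared_rs`,
#'   `exclude_candidate`.
#' @param extra Named list of extra fields (e.g. `subgroup`, `cluster`,
#'   `ref_coding_length`, `fgxg`).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(name, type, exons, strand = "+", scaffold = NA_character_,
                       rss = list(), homology = NULL, flags = character(),
                       extra = list()) {
  type <- match.arg(type, c("V", "D", "J", "C", "TRY", "FLANK"))
  ex <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(ex) <- "integer"
  colnames(ex) <- c("start", "end")
  ex <- ex[order(ex[, 1L]), , drop = FALSE]
  structure(c(list(name = name, type = type, exons = ex, strand = strand,
                   scaffold = scaffold, rss = rss, homology = homology,
                   flags = unique(flags)), extra),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s [%s] %s:%d-%d (%s), %d exon(s)%s\n",
              x$name, x$type, x$scaffold %||% "?", gene_start(x), gene_end(x),
              x$strand, nrow(x$exons),
              if (length(x$flags)) paste0(" flags=", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' @export
gene_start <- function(model) min(model$exons[, 1L])

#' @export
gene_end <- function(model) max(model$exons[, 2L])

#' Spliced coding length of a gene model (bp)
#' @param model A `gene_model`.
#' @param coding_only For V genes, use only the V-exon (the coding-region
#'   length criterion applies to the V-exon, not the leader).
#' @export
coding_length <- function(model, coding_only = TRUE) {
  ex <- model$exons
  if (model$type == "V" && coding_only && nrow(ex) == 2L) {
    # V-exon is the 3'-most exon in coding order
    ex <- if (model$strand == "+") ex[nrow(ex), , drop = FALSE] else ex[1L, , drop = FALSE]
  }
  sum(ex[, 2L] - ex[, 1L] + 1L)
}

#' Assemble a locus map
#'
#' @param label Species/assembly label.
#' @param genes List of `gene_model`s (any order; stored sorted by start).
#' @param gaps Gap table from [detect_gaps()].
#' @param scaffold Scaffold id.
#' @param seq_length Scaffold length (bp).
#' @param artifacts Data.frame of artifact flags (may be empty).
#' @return Object of class `locus_map`.
#' @export
locus_map <- function(label, genes, gaps = NULL, scaffold = NA_character_,
                      seq_length = NA_integer_, artifacts = NULL) {
  ord <- order(vapply(genes, gene_start, numeric(1L)))
  genes <- genes[ord]
  structure(list(label = label, genes = genes,
                 gaps = gaps %||% data.frame(start = integer(), end = integer(),
                                             length = integer()),
                 scaffold = scaffold, seq_length = seq_length,
                 clusters = list(),
                 artifacts = artifacts %||% data.frame()),
            class = "locus_map")
}

#' @export
print.locus_map <- function(x, ...) {
  types <- vapply(x$genes, `[[`, character(1L), "type")
  cat(sprintf("<locus_map> %s: %d genes (%s), %d cluster(s), %d gap(s)\n",
              x$label, length(x$genes),
              paste(sprintf("%s:%d", names(table(types)), table(types)),
                    collapse = " "),
              length(x$clusters), nrow(x$gaps)))
  invisible(x)
}

#' @export
summary.locus_map <- function(object, ...) {
  df <- locus_map_table(object)
  cat("Locus map:", object$label, "\n")
  print(utils::head(df, 50L))
  if (nrow(df) > 50L) cat("...", nrow(df) - 50L, "more genes\n")
  invisible(df)
}

#' Flatten a locus map to a gene table
#'
#' @param map A `locus_map`.
#' @return data.frame: name, type, start, end, strand, n_exons, functionality,
#'   reasons, flags, subgroup, cluster, best_ref, identity.
#' @export
locus_map_table <- function(map) {
  g <- map$genes
  getc <- function(f, d) vapply(g, function(m) as.character(m[[f]] %||% d), character(1L))
  data.frame(
    name = getc("name", NA),
    type = getc("type", NA),
    start = vapply(g, gene_start, numeric(1L)),
    end = vapply(g, gene_end, numeric(1L)),
    strand = getc("strand", "+"),
    n_exons = vapply(g, function(m) nrow(m$exons), integer(1L)),
    functionality = getc("functionality", "nd"),
    reasons = vapply(g, function(m) paste(m$reasons %||% character(), collapse = ","), character(1L)),
    flags = vapply(g, function(m) paste(m$flags, collapse = ","), character(1L)),
    subgroup = getc("subgroup", NA),
    cluster = vapply(g, function(m) as.integer(m$cluster %||% NA_integer_), integer(1L)),
    best_ref = vapply(g, function(m) as.character((m$homology %||% list(ref = NA))$ref %||% NA), character(1L)),
    identity = vapply(g, function(m) as.numeric((m$homology %||% list(identity = NA))$identity %||% NA), numeric(1L)),
    stringsAsFactors = FALSE)
}

#' Write a locus map (or truth annotation) as GFF3
#'
#' One `gene` feature per gene model plus one `exon` feature per exon, with
#' the functionality call in the `functionality` attribute. Coordinates are
#' 1-based closed, matching the rest of the package.
#'
#' @param map A `locus_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(map, path) {
  recs <- list()
  for (m in map$genes) {
    gid <- m$name
    attrs <- c(sprintf("ID=%s", gid),
               sprintf("Name=%s", gid),
               sprintf("gene_type=%s", m$type),
               sprintf("functionality=%s", m$functionality %||% "nd"))
    if (!is.null(m$reasons) && length(m$reasons)) {
      attrs <- c(attrs, sprintf("reasons=%s", paste(m$reasons, collapse = "|")))
    }
    if (length(m$flags)) attrs <- c(attrs, sprintf("flags=%s", paste(m$flags, collapse = "|")))
    if (!is.null(m$subgroup)) attrs <- c(attrs, sprintf("subgroup=%s", m$subgroup))
    if (!is.null(m$cluster)) attrs <- c(attrs, sprintf("cluster=%s", m$cluster))
    recs[[length(recs) + 1L]] <- sprintf(
      "%s\tcamlocus\tgene\t%d\t%d\t.\t%s\t.\t%s",
      map$scaffold %||% map$label, gene_start(m), gene_end(m), m$strand,
      paste(attrs, collapse = ";"))
    for (i in seq_len(nrow(m$exons))) {
      recs[[length(recs) + 1L]] <- sprintf(
        "%s\tcamlocus\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        map$scaffold %||% map$label, m$exons[i, 1L], m$exons[i, 2L],
        m$strand, gid, i, gid)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(unlist(recs), con)
  invisible(path)
}

#' Read a GFF3 written by [write_gff3()] back into gene models
#'
#' Uses rtracklayer for parsing; reconstructs the same in-memory annotation
#' (round-trip identity over names, types, coordinates, strands,
#' functionality and flags).
#'
#' @param path GFF3 path.
#' @param label Label for the resulting map.
#' @return A `locus_map`.
#' @export
read_gff3 <- function(path, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  genes <- list()
  scaf <- as.character(GenomicRanges::seqnames(gr))[1L] %||% NA_character_
  gene_idx <- which(is_gene)
  for (k in gene_idx) {
    gid <- md$ID[k]
    parent <- vapply(md$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, character(1L))
    ex_rows <- which(md$type == "exon" & parent == gid)
    ex <- cbind(start = GenomicRanges::start(gr)[ex_rows],
                end = GenomicRanges::end(gr)[ex_rows])
    flags <- md$flags[k]
    flags <- if (is.na(flags %||% NA)) character() else strsplit(flags, "|", fixed = TRUE)[[1L]]
    reasons <- md$reasons[k] %||% NA
    reasons <- if (is.na(reasons)) character() else strsplit(reasons, "|", fixed = TRUE)[[1L]]
    genes[[length(genes) + 1L]] <- gene_model(
      name = gid, type = md$gene_type[k], exons = ex,
      strand = as.character(GenomicRanges::strand(gr))[k],
      scaffold = as.character(GenomicRanges::seqnames(gr))[k],
      flags = flags,
      extra = list(functionality = md$functionality[k],
                   reasons = reasons,
                   subgroup = md$subgroup[k] %||% NA_character_))
  }
  locus_map(label = label, genes = genes, scaffold = scaf)
}
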