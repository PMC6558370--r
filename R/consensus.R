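# Annotation summaries (per-subgroup gene/pseudogene counts) and the
# two-out-of-three species consensus ("virtual") locus map.

# Parse one transcribed summary-table cell like "1", "2 (P)", "1 (P) + 1",
# "1 + 1 (nd)", "1 (ORF)", "1 (TRBV9 P)", "(TRBV5S2)" or "-".
.parse_count_cell <- function(cell) {
  cell <- trimws(cell)
  out <- list(n = 0L, p = 0L, nd = 0L, orf = 0L, note = NA_character_)
  if (cell %in% c("-", "–", "")) return(out)
  if (grepl("^\\(", cell)) {  # e.g. "(TRBV5S2)": counted under another subgroup
    out$note <- gsub("[()]", "", cell)
    return(out)
  }
  for (term in strsplit(cell, "+", fixed = TRUE)[[1L]]) {
    term <- trimws(term)
    m <- regmatches(term, regexec("^(\\d+)\\s*(?:\\((.+)\\))?$", term))[[1L]]
    if (!length(m)) stop("cannot parse table cell: ", cell)
    k <- as.integer(m[2L])
    out$n <- out$n + k
    mark <- trimws(m[3L])
    if (nzchar(mark)) {
      if (mark == "P") out$p <- out$p + k
      else if (mark == "nd") out$nd <- out$nd + k
      else if (mark == "ORF") out$orf <- out$orf + k
      else if (grepl("P$", mark)) {  # e.g. "TRBV9 P": renamed gene, still P
        out$p <- out$p + k
        out$note <- mark
      } else out$note <- mark
    }
  }
  out
}

#' Read a transcribed per-subgroup summary table
#'
#' Reads the TSV transcription of a published per-subgroup gene-count table
#' (cells like `"1 (P) + 1"`), including its verbatim `TOTAL` row, into
#' per-subgroup counts. The printed totals are preserved separately so any
#' arithmetic tension between the table body and its printed totals is
#' carried, not reconciled.
#'
#' @param path TSV path; defaults to the table shipped with the package.
#' @return data.frame in long form: subgroup, species, n, p, nd, orf, note;
#'   attribute `printed_totals` (named numeric) carries the verbatim TOTAL
#'   row if present.
#' @export
read_subgroup_table <- function(path = system.file("extdata",
                                                   "trbv_subgroup_table.tsv",
                                                   package = "camlocus")) {
  raw <- read_tsv(path)
  species <- setdiff(colnames(raw), "subgroup")
  total_row <- raw$subgroup == "TOTAL"
  printed <- NULL
  if (any(total_row)) {
    printed <- stats::setNames(
      as.numeric(unlist(raw[total_row, species, drop = TRUE])), species)
    raw <- raw[!total_row, , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(raw))) {
    for (sp in species) {
      pc <- .parse_count_cell(raw[[sp]][i])
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = raw$subgroup[i], species = sp, n = pc$n, p = pc$p,
        nd = pc$nd, orf = pc$orf, note = pc$note, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "printed_totals") <- printed
  out
}

#' Summarize V-gene annotation per subgroup and species
#'
#' Accepts either the long-form fixture table from
#' [read_subgroup_table()] or a (named) list of classified `locus_map`s.
#' Totals are column sums of the per-subgroup rows; if the fixture carries
#' printed totals, they are kept alongside and any mismatch is flagged
#' (`totals_consistent`), never silently reconciled. The functional
#' percentage is `(total - P - nd) / total`, rounded to the nearest integer
#' percent (the denominator includes nd genes).
#'
#' @param x Long-form count table or list of `locus_map`s.
#' @return Object of class `summary_table`: list with `by_subgroup` (wide
#'   data.frame), `totals`, `printed_totals`, `totals_consistent`,
#'   `pseudogenes`, `nd`, `functional_pct`, `n_subgroups` (camel-style:
#'   subgroups with at least one gene in a non-human species; all-species
#'   subgroup counts are in `subgroups_by_species`).
#' @export
summarize_annotation <- function(x) {
  if (is.list(x) && !is.data.frame(x) && length(x) &&
      inherits(x[[1L]], "locus_map")) {
    rows <- list()
    for (k in seq_along(x)) {
      map <- x[[k]]
      sp <- names(x)[k] %||% map$label
      v <- map$genes[vapply(map$genes, function(m) m$type == "V", logical(1L))]
      sg <- vapply(v, function(m) as.character(m$subgroup %||% m$subgroup_ref %||% m$name),
                   character(1L))
      lab <- vapply(v, function(m) m$functionality %||% "nd", character(1L))
      for (s in unique(sg)) {
        sel <- sg == s
        rows[[length(rows) + 1L]] <- data.frame(
          subgroup = s, species = sp, n = sum(sel),
          p = sum(lab[sel] == "P"), nd = sum(lab[sel] == "nd"),
          orf = sum(lab[sel] == "ORF"), note = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    x <- if (length(rows)) do.call(rbind, rows) else
      data.frame(subgroup = character(), species = character(),
                 n = integer(), p = integer(), nd = integer(),
                 orf = integer(), note = character(),
                 stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x),
            all(c("subgroup", "species", "n", "p", "nd") %in% colnames(x)))
  species <- unique(x$species)
  printed <- attr(x, "printed_totals")
  totals <- vapply(species, function(sp) sum(x$n[x$species == sp]), numeric(1L))
  pseudo <- vapply(species, function(sp) sum(x$p[x$species == sp]), numeric(1L))
  ndc <- vapply(species, function(sp) sum(x$nd[x$species == sp]), numeric(1L))
  fpct <- round(100 * (totals - pseudo - ndc) / pmax(totals, 1L))
  fpct[totals == 0] <- NA_real_
  sg_by_sp <- vapply(species, function(sp) {
    sum(tapply(x$n[x$species == sp], x$subgroup[x$species == sp], sum) > 0)
  }, numeric(1L))
  camel_sp <- setdiff(species, "human")
  n_sg <- if (length(camel_sp)) {
    camel <- x[x$species %in% camel_sp, , drop = FALSE]
    sum(tapply(camel$n, camel$subgroup, sum) > 0)
  } else sum(tapply(x$n, x$subgroup, sum) > 0)
  wide <- if (nrow(x)) {
    stats::reshape(x[, c("subgroup", "species", "n")],
                   idvar = "subgroup", timevar = "species",
                   direction = "wide")
  } else x
  consistent <- if (is.null(printed)) NA else
    stats::setNames(abs(printed[species] - totals) < 0.5, species)
  structure(list(by_subgroup = x, wide = wide, totals = totals,
                 printed_totals = printed, totals_consistent = consistent,
                 pseudogenes = pseudo, nd = ndc, functional_pct = fpct,
                 n_subgroups = n_sg, subgroups_by_species = sg_by_sp),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat("Per-species V-gene summary\n")
  df <- data.frame(species = names(x$totals), total = x$totals,
                   pseudogenes = x$pseudogenes, nd = x$nd,
                   functional_pct = x$functional_pct, row.names = NULL)
  print(df)
  cat("Subgroups (non-human species):", x$n_subgroups, "\n")
  if (!is.null(x$printed_totals)) {
    bad <- names(which(!x$totals_consistent))
    if (length(bad)) {
      cat("Note: printed totals disagree with column sums for:",
          paste(bad, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Read the three-species per-gene functionality table
#'
#' @param path TSV path; defaults to the table shipped with the package
#'   (gene, subgroup, then one functionality column per species; `-` marks
#'   absence).
#' @return data.frame.
#' @export
read_three_species_table <- function(path = system.file(
  "extdata", "trbv_functionality_three_species.tsv", package = "camlocus")) {
  read_tsv(path)
}

#' Build the two-out-of-three consensus (virtual) locus map
#'
#' A gene enters the consensus if it is present in at least two of the
#' three species; its consensus functionality is the label shared by at
#' least two species. Label disagreements among the species carrying the
#' gene always produce a variation note; a gene present in only one
#' species is excluded from the consensus and listed as unconfirmed.
#'
#' @param maps Either a data.frame with columns `gene` and one label column
#'   per species (`-` = absent), or a named list of exactly three
#'   classified `locus_map`s with reconciled gene names.
#' @return Object of class `consensus_map`: list with `consensus`
#'   (data.frame: gene, per-species labels, present_in, label, note) and
#'   `unconfirmed`.
#' @export
consensus_locus_map <- function(maps) {
  if (is.data.frame(maps)) {
    df <- maps
    species <- setdiff(colnames(df), c("gene", "subgroup"))
  } else {
    if (length(maps) != 3L) stop("exactly 3 species maps are required")
    species <- names(maps) %||% vapply(maps, `[[`, character(1L), "label")
    genes <- unique(unlist(lapply(maps, function(m) {
      vapply(m$genes[vapply(m$genes, function(g) g$type == "V", logical(1L))],
             `[[`, character(1L), "name")
    })))
    df <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (k in seq_along(maps)) {
      lab <- rep("-", length(genes))
      vg <- maps[[k]]$genes
      for (g in vg) {
        if (g$type == "V" && g$name %in% genes) {
          lab[match(g$name, genes)] <- g$functionality %||% "nd"
        }
      }
      df[[species[k]]] <- lab
    }
  }
  if (length(species) != 3L) stop("exactly 3 species columns are required")
  labs <- as.matrix(df[, species, drop = FALSE])
  present <- labs != "-"
  n_present <- rowSums(present)
  consensus_label <- character(nrow(df))
  note <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    ll <- labs[i, present[i, ]]
    tab <- sort(table(ll), decreasing = TRUE)
    if (length(tab) && tab[1L] >= 2L) {
      consensus_label[i] <- names(tab)[1L]
    } else {
      consensus_label[i] <- "nd"
      if (n_present[i] >= 2L) {
        note[i] <- paste0("no majority label (",
                          paste(sprintf("%s:%s", species[present[i, ]], ll),
                                collapse = ", "), ")")
      }
    }
    if (n_present[i] >= 2L && length(unique(ll)) > 1L && is.na(note[i])) {
      minority <- species[present[i, ]][ll != consensus_label[i]]
      note[i] <- paste0(consensus_label[i], " by 2/3; ",
                        paste(sprintf("%s in %s",
                                      ll[ll != consensus_label[i]], minority),
                              collapse = ", "))
    }
  }
  out <- data.frame(gene = df$gene, stringsAsFactors = FALSE)
  for (sp in species) out[[sp]] <- df[[sp]]
  out$present_in <- n_present
  out$label <- consensus_label
  out$note <- note
  consensus <- out[n_present >= 2L, , drop = FALSE]
  unconfirmed <- out[n_present == 1L, , drop = FALSE]
  rownames(consensus) <- rownames(unconfirmed) <- NULL
  structure(list(consensus = consensus, unconfirmed = unconfirmed,
                 species = species),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("<consensus_map> %d consensus genes (>=2 of %d species), %d unconfirmed\n",
              nrow(x$consensus), length(x$species), nrow(x$unconfirmed)))
  noted <- x$consensus[!is.na(x$consensus$note), , drop = FALSE]
  if (nrow(noted)) {
    cat("Variation notes:\n")
    for (i in seq_len(nrow(noted))) {
      cat(sprintf("  %s: %s\n", noted$gene[i], noted$note[i]))
    }
  }
  invisible(x)
}
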