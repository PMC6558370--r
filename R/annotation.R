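# Gene finding on scaffolds: seeded homology placement of reference
# templates, signal (RS / splice-site) validation at the projected
# positions, D-J-C cluster assembly and assembly-artifact flagging.

# ---- seeded homology placement -------------------------------------------
#
# k-mer seeding with diagonal voting: exact k-mers taken from each reference
# template are matched against the scaffold (Biostrings::matchPDict); seed
# hits sharing a (reference, diagonal) accumulate votes, nearby diagonals
# (small indels) are clustered, and each surviving placement is scored by
# ungapped percent identity over the reference's identity region.

.template_kmers <- function(seq, k, step) {
  n <- nchar(seq)
  if (n < k) return(data.frame(offset = integer(), kmer = character()))
  offs <- seq(1L, n - k + 1L, by = step)
  data.frame(offset = offs, kmer = substring(seq, offs, offs + k - 1L),
             stringsAsFactors = FALSE)
}

# Place templates on one strand-oriented sequence string.
# Returns data.frame: ref (index into refs$records), tstart (position of
# template base 1 on the oriented axis), votes, identity.
.place_templates <- function(oriented_seq, refs, k = 11L, step = 4L,
                             min_votes = 5L, min_identity = 60,
                             id_region = NULL) {
  n <- nchar(oriented_seq)
  seeds <- lapply(seq_along(refs$records), function(i) {
    km <- .template_kmers(refs$records[[i]]$seq, k, step)
    if (nrow(km)) km$ref <- i
    km
  })
  seeds <- do.call(rbind, seeds[vapply(seeds, nrow, integer(1L)) > 0L])
  if (is.null(seeds) || !nrow(seeds)) return(NULL)
  keep <- !grepl("N", seeds$kmer, fixed = TRUE)
  seeds <- seeds[keep, , drop = FALSE]
  if (!nrow(seeds)) return(NULL)
  subject <- Biostrings::DNAString(oriented_seq)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$kmer))
  hits <- Biostrings::matchPDict(pd, subject)
  starts <- IRanges::start(hits)
  nh <- S4Vectors::elementNROWS(hits)
  if (sum(nh) == 0L) return(NULL)
  idx <- rep.int(seq_along(nh), nh)
  hit_pos <- unlist(starts, use.names = FALSE)
  diag <- hit_pos - seeds$offset[idx] + 1L
  ref <- seeds$ref[idx]
  tab <- stats::aggregate(list(votes = rep(1L, length(diag))),
                          by = list(ref = ref, diag = diag), FUN = sum)
  out <- list()
  for (r in unique(tab$ref)) {
    sub <- tab[tab$ref == r, , drop = FALSE]
    sub <- sub[order(sub$diag), , drop = FALSE]
    # cluster diagonals within 3 bp (indel tolerance)
    grp <- cumsum(c(1L, diff(sub$diag) > 3L))
    for (g in unique(grp)) {
      rows <- sub[grp == g, , drop = FALSE]
      total_votes <- sum(rows$votes)
      if (total_votes < min_votes) next
      rows <- rows[order(-rows$votes, rows$diag), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        ref = r, tstart = rows$diag[1L], votes = total_votes,
        alt_tstart = if (nrow(rows) > 1L) rows$diag[2L] else NA_integer_)
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  # identity over the reference's identity region at the placement; when a
  # second diagonal is supported (small indel), a position matches if it
  # matches under either diagonal
  res$identity <- vapply(seq_len(nrow(res)), function(i) {
    rec <- refs$records[[res$ref[i]]]
    reg <- if (is.null(id_region)) c(1L, nchar(rec$seq)) else id_region(rec)
    a <- seq_chars(substring(rec$seq, reg[1L], reg[2L]))
    gs <- res$tstart[i] + reg[1L] - 1L
    ge <- res$tstart[i] + reg[2L] - 1L
    if (gs < 1L || ge > n) return(0)
    b <- seq_chars(substring(oriented_seq, gs, ge))
    ok <- a == b
    if (!is.na(res$alt_tstart[i])) {
      gs2 <- res$alt_tstart[i] + reg[1L] - 1L
      ge2 <- res$alt_tstart[i] + reg[2L] - 1L
      if (gs2 >= 1L && ge2 <= n) {
        ok <- ok | (a == seq_chars(substring(oriented_seq, gs2, ge2)))
      }
    }
    100 * sum(ok) / length(a)
  }, numeric(1L))
  res <- res[res$identity >= min_identity, , drop = FALSE]
  if (!nrow(res)) return(NULL)
  # dedupe placements whose identity regions overlap: best identity wins,
  # ties to the lexicographically smallest reference name
  res$name <- vapply(res$ref, function(r) refs$records[[r]]$name, character(1L))
  spans <- t(vapply(seq_len(nrow(res)), function(i) {
    rec <- refs$records[[res$ref[i]]]
    c(res$tstart[i], res$tstart[i] + nchar(rec$seq) - 1L)
  }, numeric(2L)))
  res <- res[order(spans[, 1L]), , drop = FALSE]
  spans <- spans[order(spans[, 1L]), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  i <- 1L
  while (i <= nrow(res)) {
    if (!keep[i]) { i <- i + 1L; next }
    j <- i + 1L
    while (j <= nrow(res) && spans[j, 1L] <= spans[i, 2L] - 20L) {
      pick <- if (res$identity[j] > res$identity[i]) j
      else if (res$identity[j] < res$identity[i]) i
      else if (res$name[j] < res$name[i]) j else i
      drop <- if (pick == i) j else i
      keep[drop] <- FALSE
      if (drop == i) break
      j <- j + 1L
    }
    i <- i + 1L
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Pick the boundary offset whose RS evaluation is best; the projected
# position (offset 0) wins unless an alternative beats it by >= margin
# mismatches, so degraded-but-in-place signals are not displaced by chance
# near-matches while true 1-2 bp indels still shift the boundary.
.refine_rss_offset <- function(seq, heptamer_start, spacer_class, strand,
                               offsets = c(0L, -1L, 1L), margin = 2L) {
  score0 <- evaluate_rss_at(seq, heptamer_start, spacer_class, strand)$total_score
  score0 <- if (is.na(score0 %||% NA)) Inf else score0
  best_off <- 0L
  best <- score0
  for (off in setdiff(offsets, 0L)) {
    ev <- evaluate_rss_at(seq, heptamer_start + off, spacer_class, strand)
    sc <- ev$total_score %||% NA
    if (!isTRUE(ev$found) || is.na(sc)) next
    if (sc <= score0 - margin && sc < best) {
      best <- sc
      best_off <- off
    }
  }
  best_off
}

# Map an interval on the oriented (possibly reverse-complemented) axis back
# to the forward axis.
.to_forward <- function(iv, n, strand) {
  if (strand == "+") return(iv)
  c(n - iv[2L] + 1L, n - iv[1L] + 1L)
}

# ---- V genes --------------------------------------------------------------

#' Find V genes by seeded homology plus signal validation
#'
#' Candidate placements come from k-mer seeded homology to the reference V
#' library on both strands; for each accepted candidate the leader exon,
#' donor/acceptor splice dinucleotides and the 23-spacer RS abutting the
#' V-exon 3' end are evaluated at their projected positions (the RS
#' position is refined within +/-2 bp to absorb draft-assembly indels) and
#' recorded on the model. Degraded signals are flagged, not discarded, so
#' downstream classification can call P/ORF with reasons.
#'
#' @param assembly Named DNAStringSet (or named character vector) of
#'   scaffolds.
#' @param references A `reference_library` (only `type == "V"` records are
#'   used); each must carry `leader_len`, `intron_len`, `vexon_len`.
#' @param min_identity Minimum percent identity over the V-exon.
#' @return List of `gene_model`s (type V), sorted by scaffold and start.
#' @export
find_v_genes <- function(assembly, references, min_identity = 60) {
  vrefs <- ref_subset(references, "V")
  if (!length(vrefs$records)) stop("reference V library is empty")
  if (!inherits(assembly, "DNAStringSet")) {
    assembly <- Biostrings::DNAStringSet(vapply(assembly, as_seq_string, character(1L)))
  }
  models <- list()
  for (sc in seq_along(assembly)) {
    scaf_id <- names(assembly)[sc] %||% paste0("seq", sc)
    fwd <- as.character(assembly[[sc]])
    n <- nchar(fwd)
    gaps <- detect_gaps(fwd)
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") fwd else revcomp(fwd)
      pl <- .place_templates(oriented, vrefs, min_identity = min_identity,
                             id_region = function(rec) {
                               s <- rec$leader_len + rec$intron_len + 1L
                               c(s, s + rec$vexon_len - 1L)
                             })
      if (is.null(pl)) next
      for (i in seq_len(nrow(pl))) {
        rec <- vrefs$records[[pl$ref[i]]]
        t0 <- pl$tstart[i]
        leader <- c(t0, t0 + rec$leader_len - 1L)
        vx <- c(t0 + rec$leader_len + rec$intron_len,
                t0 + rec$leader_len + rec$intron_len + rec$vexon_len - 1L)
        if (leader[1L] < 1L || vx[2L] + 2L > n) next
        flags <- character()
        # refine the V-exon 3' end against the abutting 23-RS; the projected
        # position is kept unless a nearby offset is better by >=2
        # mismatches (absorbs real indels without chasing chance matches)
        vx[2L] <- vx[2L] + .refine_rss_offset(oriented, vx[2L] + 1L, 23L, "+",
                                              offsets = c(0L, -1L, 1L, -2L, 2L))
        rs_or <- evaluate_rss_at(oriented, vx[2L] + 1L, 23L, "+")
        donor <- substring(oriented, leader[2L] + 1L, leader[2L] + 2L)
        acceptor <- substring(oriented, vx[1L] - 2L, vx[1L] - 1L)
        if (donor != "GT") flags <- c(flags, "no_donor")
        if (acceptor != "AG") flags <- c(flags, "no_acceptor")
        # forward-axis mapping
        ex_fwd <- rbind(.to_forward(leader, n, strand), .to_forward(vx, n, strand))
        rs <- rs_or
        rs$strand <- strand
        rs$heptamer_start <- if (strand == "+") vx[2L] + 1L else n - vx[2L]
        vexon_fwd <- .to_forward(vx, n, strand)
        if (nrow(gaps) && any(gaps$start <= max(ex_fwd[, 2L]) &
                              gaps$end >= min(ex_fwd[, 1L]))) {
          flags <- c(flags, "incomplete")
        }
        models[[length(models) + 1L]] <- gene_model(
          name = sprintf("V@%s:%d", scaf_id, min(ex_fwd[, 1L])), type = "V",
          exons = ex_fwd, strand = strand, scaffold = scaf_id,
          rss = list(v_rs = rs),
          homology = list(ref = rec$name, identity = pl$identity[i]),
          flags = flags,
          extra = list(ref_coding_length = rec$vexon_len,
                       vexon = vexon_fwd,
                       vexon_seq = substring(oriented, vx[1L], vx[2L]),
                       subgroup_ref = rec$subgroup %||% rec$name))
      }
    }
  }
  .sort_models(models)
}

.sort_models <- function(models) {
  if (!length(models)) return(models)
  ord <- order(vapply(models, `[[`, character(1L), "scaffold"),
               vapply(models, gene_start, numeric(1L)))
  models[ord]
}

# ---- D genes --------------------------------------------------------------

#' Find D gene candidates from flanking recombination signals
#'
#' A D segment is a short stretch bounded by an inward-facing 12-spacer RS
#' on its 5' side and a 23-spacer RS on its 3' side (forward strand). Both
#' signals must pass the scan maxima. Candidates sharing an RS motif are
#' reported and flagged.
#'
#' @param seq Sequence to scan.
#' @param max_d_length Maximum segment length (bp).
#' @param max_heptamer_mm,max_nonamer_mm Scan maxima, as [scan_rss()].
#' @param scaffold Scaffold id recorded on the models.
#' @return List of `gene_model`s (type D).
#' @export
find_d_genes <- function(seq, max_d_length = 25L, max_heptamer_mm = 2L,
                         max_nonamer_mm = 3L, scaffold = NA_character_) {
  s <- as_seq_string(seq)
  if (nchar(s) < 2L * (7L + 11L + 9L) + 1L) return(list())
  rs12 <- scan_rss(s, 12L, max_heptamer_mm, max_nonamer_mm, strands = "-")
  rs23 <- scan_rss(s, 23L, max_heptamer_mm, max_nonamer_mm, strands = "+")
  if (!nrow(rs12) || !nrow(rs23)) return(list())
  # one signal per heptamer position: spacer +/-1 variants collapse to the
  # best-scoring one
  best_per_pos <- function(df) {
    df <- df[order(df$heptamer_start, df$total_score, df$spacer_length), ]
    df[!duplicated(df$heptamer_start), , drop = FALSE]
  }
  rs12 <- best_per_pos(rs12)
  rs23 <- best_per_pos(rs23)
  models <- list()
  used_rs <- list()
  for (i in seq_len(nrow(rs12))) {
    seg_start <- rs12$heptamer_start[i] + 1L
    after <- rs23[rs23$heptamer_start > seg_start &
                  rs23$heptamer_start <= seg_start + max_d_length, , drop = FALSE]
    for (j in seq_len(nrow(after))) {
      seg_end <- after$heptamer_start[j] - 1L
      models[[length(models) + 1L]] <- gene_model(
        name = sprintf("D@%d", seg_start), type = "D",
        exons = cbind(seg_start, seg_end), strand = "+", scaffold = scaffold,
        rss = list(d5_rs = as.list(rs12[i, ]), d3_rs = as.list(after[j, ])))
      used_rs[[length(used_rs) + 1L]] <- c(rs12$heptamer_start[i],
                                           after$heptamer_start[j])
    }
  }
  if (length(models) > 1L) {
    mats <- do.call(rbind, used_rs)
    shared <- duplicated(mats[, 1L]) | duplicated(mats[, 1L], fromLast = TRUE) |
      duplicated(mats[, 2L]) | duplicated(mats[, 2L], fromLast = TRUE)
    for (k in which(shared)) {
      models[[k]]$flags <- unique(c(models[[k]]$flags, "overlap_shared_rs"))
    }
  }
  .sort_models(models)
}

# ---- J genes --------------------------------------------------------------

#' Find J genes by homology plus 12-RS and donor validation
#'
#' J exons are placed by seeded homology to the reference J library; each
#' model records the 12-spacer RS immediately 5' of the exon, the GT donor
#' at the 3' exon boundary, and whether the translation (in the frame fixed
#' by the donor) contains the FGXG motif. Motif absence is recorded on the
#' model; classification happens downstream.
#'
#' @param seq Sequence to scan (forward-strand J genes).
#' @param references A `reference_library` with `type == "J"` records.
#' @param min_identity Minimum percent identity over the exon.
#' @param scaffold Scaffold id recorded on the models.
#' @return List of `gene_model`s (type J).
#' @export
find_j_genes <- function(seq, references, min_identity = 60,
                         scaffold = NA_character_) {
  jrefs <- ref_subset(references, "J")
  if (!length(jrefs$records)) return(list())
  s <- as_seq_string(seq)
  n <- nchar(s)
  pl <- .place_templates(s, jrefs, k = 11L, step = 1L, min_votes = 3L,
                         min_identity = min_identity)
  if (is.null(pl)) return(list())
  gaps <- detect_gaps(s)
  models <- list()
  for (i in seq_len(nrow(pl))) {
    rec <- jrefs$records[[pl$ref[i]]]
    ex <- c(pl$tstart[i], pl$tstart[i] + nchar(rec$seq) - 1L)
    len <- ex[2L] - ex[1L] + 1L
    if (len < 30L || len > 70L) next
    if (ex[1L] < 4L || ex[2L] + 2L > n) next
    flags <- character()
    # refine the exon 5' boundary against the abutting 12-RS (minus strand
    # orientation: heptamer_start is the base immediately before the exon)
    ex[1L] <- ex[1L] + .refine_rss_offset(s, ex[1L] - 1L, 12L, "-",
                                          offsets = c(0L, -1L, 1L))
    rs <- evaluate_rss_at(s, ex[1L] - 1L, 12L, "-")
    donor <- substring(s, ex[2L] + 1L, ex[2L] + 2L)
    if (donor != "GT") flags <- c(flags, "no_donor")
    # frame fixed by the donor: last complete codon ends at the exon end
    off <- (ex[2L] - ex[1L] + 1L) %% 3L
    prot <- translate_string(substring(s, ex[1L] + off, ex[2L]))
    fg <- check_fgxg(prot)
    if (is.na(fg)) flags <- c(flags, "fgxg_absent")
    if (nrow(gaps) && any(gaps$start <= ex[2L] & gaps$end >= ex[1L])) {
      flags <- c(flags, "incomplete")
    }
    models[[length(models) + 1L]] <- gene_model(
      name = sprintf("J@%d", ex[1L]), type = "J",
      exons = cbind(ex[1L], ex[2L]), strand = "+", scaffold = scaffold,
      rss = list(j_rs = rs),
      homology = list(ref = rec$name, identity = pl$identity[i]),
      flags = flags,
      extra = list(ref_coding_length = nchar(rec$seq), protein = prot,
                   fgxg = fg))
  }
  .sort_models(models)
}

# ---- C genes --------------------------------------------------------------

#' Find C genes by homology-seeded 4-exon placement
#'
#' Places the reference C template (4 exons, known offsets) by seeded
#' homology, projects the exon structure, validates the GT/AG dinucleotides
#' at every junction and attaches the spliced translation. Models whose
#' exons overlap N-gaps or run past the scaffold end are flagged
#' incomplete.
#'
#' @param assembly Named DNAStringSet or named character vector.
#' @param references A `reference_library` with `type == "C"` records
#'   (fields `exon_starts`, `exon_lens`).
#' @param min_identity Minimum percent identity over the spliced exons.
#' @return List of `gene_model`s (type C).
#' @export
find_c_genes <- function(assembly, references, min_identity = 70) {
  crefs <- ref_subset(references, "C")
  if (!length(crefs$records)) stop("reference C library is empty")
  if (!inherits(assembly, "DNAStringSet")) {
    assembly <- Biostrings::DNAStringSet(vapply(assembly, as_seq_string, character(1L)))
  }
  models <- list()
  for (sc in seq_along(assembly)) {
    scaf_id <- names(assembly)[sc] %||% paste0("seq", sc)
    s <- as.character(assembly[[sc]])
    n <- nchar(s)
    gaps <- detect_gaps(s)
    pl <- .place_templates(s, crefs, min_votes = 5L, min_identity = min_identity,
                           id_region = function(rec) c(rec$exon_starts[1L],
                                                       rec$exon_starts[1L] + rec$exon_lens[1L] - 1L))
    if (is.null(pl)) next
    for (i in seq_len(nrow(pl))) {
      rec <- crefs$records[[pl$ref[i]]]
      t0 <- pl$tstart[i]
      ex <- cbind(t0 + rec$exon_starts - 1L,
                  t0 + rec$exon_starts + rec$exon_lens - 2L)
      flags <- character()
      if (ex[1L, 1L] < 1L) next
      clipped <- ex[, 1L] <= n
      if (!all(clipped)) {
        ex <- ex[clipped, , drop = FALSE]
        flags <- c(flags, "incomplete")
      }
      if (any(ex[, 2L] > n)) {
        ex[, 2L] <- pmin(ex[, 2L], n)
        flags <- c(flags, "incomplete")
      }
      nex <- nrow(ex)
      for (e in seq_len(nex)) {
        if (e < nex) {
          don <- substring(s, ex[e, 2L] + 1L, ex[e, 2L] + 2L)
          if (don != "GT") flags <- c(flags, "no_donor")
        }
        if (e > 1L) {
          acc <- substring(s, ex[e, 1L] - 2L, ex[e, 1L] - 1L)
          if (acc != "AG") flags <- c(flags, "no_acceptor")
        }
      }
      if (nrow(gaps)) {
        for (e in seq_len(nex)) {
          if (any(gaps$start <= ex[e, 2L] & gaps$end >= ex[e, 1L])) {
            flags <- c(flags, "incomplete")
          }
        }
      }
      prot <- translate_cds(ex, "+", s, gaps = gaps)
      models[[length(models) + 1L]] <- gene_model(
        name = sprintf("C@%s:%d", scaf_id, ex[1L, 1L]), type = "C",
        exons = ex, strand = "+", scaffold = scaf_id,
        homology = list(ref = rec$name, identity = pl$identity[i]),
        flags = unique(flags),
        extra = list(protein = as.character(prot),
                     ref_coding_length = sum(rec$exon_lens)))
    }
  }
  .sort_models(models)
}

# ---- TRY and flank genes --------------------------------------------------

#' Find TRY-like (or flanking marker) genes by homology only
#'
#' TRY genes do not rearrange and carry no RS; they are detected purely by
#' homology to the reference library.
#'
#' @param assembly Named DNAStringSet or named character vector.
#' @param references A `reference_library`.
#' @param type `"TRY"` or `"FLANK"`.
#' @param min_identity Minimum percent identity.
#' @return List of `gene_model`s.
#' @export
find_homology_genes <- function(assembly, references, type = "TRY",
                                min_identity = 70) {
  trefs <- ref_subset(references, type)
  if (!length(trefs$records)) return(list())
  if (!inherits(assembly, "DNAStringSet")) {
    assembly <- Biostrings::DNAStringSet(vapply(assembly, as_seq_string, character(1L)))
  }
  models <- list()
  for (sc in seq_along(assembly)) {
    scaf_id <- names(assembly)[sc] %||% paste0("seq", sc)
    s <- as.character(assembly[[sc]])
    n <- nchar(s)
    pl <- .place_templates(s, trefs, min_votes = 5L, min_identity = min_identity)
    if (is.null(pl)) next
    for (i in seq_len(nrow(pl))) {
      rec <- trefs$records[[pl$ref[i]]]
      ex <- c(pl$tstart[i], pl$tstart[i] + nchar(rec$seq) - 1L)
      if (ex[1L] < 1L || ex[2L] > n) next
      models[[length(models) + 1L]] <- gene_model(
        name = rec$name, type = type, exons = cbind(ex[1L], ex[2L]),
        strand = "+", scaffold = scaf_id,
        homology = list(ref = rec$name, identity = pl$identity[i]),
        extra = list(ref_coding_length = nchar(rec$seq)))
    }
  }
  .sort_models(models)
}

# ---- cluster assembly -----------------------------------------------------

#' Group D, J and C models into D-J-C clusters
#'
#' Scans the position-sorted gene models for maximal runs matching the order
#' D, J+, C and numbers them 5' to 3'. Runs missing their D or C (e.g.
#' truncated by an assembly gap) yield `complete = FALSE` clusters.
#'
#' @param map A `locus_map` (or list of gene models).
#' @return List of `djc_cluster` objects (ordinal, d_gene, j_genes, c_gene,
#'   complete).
#' @export
assemble_clusters <- function(map) {
  genes <- if (inherits(map, "locus_map")) map$genes else .sort_models(map)
  djc <- genes[vapply(genes, function(m) m$type %in% c("D", "J", "C"), logical(1L))]
  clusters <- list()
  cur <- list(d = NULL, j = list(), c = NULL)
  flush <- function() {
    if (is.null(cur$d) && !length(cur$j) && is.null(cur$c)) return()
    ord <- length(clusters) + 1L
    clusters[[ord]] <<- structure(
      list(ordinal = ord, d_gene = cur$d, j_genes = cur$j, c_gene = cur$c,
           complete = !is.null(cur$d) && !is.null(cur$c) &&
             length(cur$j) >= 6L && length(cur$j) <= 7L),
      class = "djc_cluster")
    cur <<- list(d = NULL, j = list(), c = NULL)
  }
  for (m in djc) {
    if (m$type == "D") {
      if (!is.null(cur$d) || length(cur$j) || !is.null(cur$c)) flush()
      cur$d <- m
    } else if (m$type == "J") {
      if (!is.null(cur$c)) flush()
      cur$j[[length(cur$j) + 1L]] <- m
    } else {  # C
      if (!is.null(cur$c)) flush()
      cur$c <- m
      flush()
    }
  }
  flush()
  clusters
}

#' @export
print.djc_cluster <- function(x, ...) {
  cat(sprintf("<djc_cluster> #%d: D=%s, %d J gene(s), C=%s (%s)\n",
              x$ordinal,
              if (is.null(x$d_gene)) "-" else x$d_gene$name,
              length(x$j_genes),
              if (is.null(x$c_gene)) "-" else x$c_gene$name,
              if (x$complete) "complete" else "incomplete"))
  invisible(x)
}

# ---- duplicate-region artifacts -------------------------------------------

#' Flag exactly duplicated regions that contain gene models
#'
#' Finds pairs of non-overlapping, exactly identical regions of at least
#' `min_len` bp that each contain at least one gene model — the signature
#' of a local assembly redundancy. Genes inside either copy are flagged
#' `duplicate_region`; genes in the 3'-most copy are additionally marked
#' `exclude_candidate`.
#'
#' @param map A `locus_map`.
#' @param seq The scaffold sequence.
#' @param min_len Minimum duplicated length (bp).
#' @param anchor_k Anchor k-mer width used to seed repeat detection.
#' @return data.frame of flag pairs (start1, end1, start2, end2, length);
#'   the map's genes are annotated via the returned attribute
#'   `flagged_genes` (names). The input map is not modified.
#' @export
flag_duplicate_regions <- function(map, seq, min_len = 200L, anchor_k = 32L) {
  s <- as_seq_string(seq)
  n <- nchar(s)
  empty <- data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      length = integer())
  if (n < 2L * min_len) return(empty)
  k <- min(anchor_k, min_len)
  offs <- seq_len(n - k + 1L)
  km <- substring(s, offs, offs + k - 1L)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  dup[grepl("N", km, fixed = TRUE)] <- FALSE
  cand <- which(dup)
  if (!length(cand)) return(empty)
  groups <- split(cand, km[cand])
  pairs <- list()
  for (g in groups) {
    if (length(g) < 2L) next
    cmb <- utils::combn(g, 2L)
    for (cix in seq_len(ncol(cmb))) {
      pairs[[length(pairs) + 1L]] <- cmb[, cix]
    }
  }
  if (!length(pairs)) return(empty)
  pm <- unique(do.call(rbind, pairs))
  diagv <- pm[, 2L] - pm[, 1L]
  reps <- list()
  ch <- seq_chars(s)
  for (d in unique(diagv)) {
    ps <- sort(pm[diagv == d, 1L])
    grp <- cumsum(c(1L, diff(ps) > k))
    for (gg in unique(grp)) {
      run <- ps[grp == gg]
      a <- min(run)
      b <- max(run) + k - 1L
      # extend to maximal exact match
      while (a > 1L && a + d - 1L >= 1L && (a + d) <= n + 1L &&
             a - 1L + d >= 1L && ch[a - 1L] == ch[a - 1L + d] &&
             ch[a - 1L] != "N") a <- a - 1L
      while (b < n && b + d <= n && ch[b + 1L] == ch[b + 1L + d] &&
             ch[b + 1L] != "N") b <- b + 1L
      len <- b - a + 1L
      if (len >= min_len && d >= len) {  # require non-overlapping copies
        reps[[length(reps) + 1L]] <- c(a, b, a + d, b + d, len)
      }
    }
  }
  if (!length(reps)) return(empty)
  rm_ <- unique(do.call(rbind, reps))
  res <- data.frame(start1 = rm_[, 1L], end1 = rm_[, 2L], start2 = rm_[, 3L],
                    end2 = rm_[, 4L], length = rm_[, 5L])
  res <- res[order(res$start1), , drop = FALSE]
  rownames(res) <- NULL
  # keep only repeats where both copies contain a gene model
  genes <- if (inherits(map, "locus_map")) map$genes else map
  if (length(genes)) {
    gs <- vapply(genes, gene_start, numeric(1L))
    ge <- vapply(genes, gene_end, numeric(1L))
    gn <- vapply(genes, `[[`, character(1L), "name")
    in_copy <- function(a, b) gs >= a & ge <= b
    keep <- logical(nrow(res))
    flagged <- character()
    excl <- character()
    for (i in seq_len(nrow(res))) {
      c1 <- in_copy(res$start1[i], res$end1[i])
      c2 <- in_copy(res$start2[i], res$end2[i])
      keep[i] <- any(c1) && any(c2)
      if (keep[i]) {
        flagged <- unique(c(flagged, gn[c1 | c2]))
        excl <- unique(c(excl, gn[c2]))  # 3'-most copy
      }
    }
    res <- res[keep, , drop = FALSE]
    attr(res, "flagged_genes") <- flagged
    attr(res, "exclude_candidates") <- excl
  }
  rownames(res) <- NULL
  res
}

# ---- whole-locus annotation ----------------------------------------------

#' Annotate a scaffold (or assembly) end to end
#'
#' Runs the V, J, C, TRY and flank finders, restricts D calls to the region
#' immediately upstream of each J cluster (D segments are too short for
#' homology, and cryptic RS pairs occur by chance in ~300 kb of sequence;
#' anchoring D calls to homology-confirmed J clusters mirrors how D-J-C
#' units are annotated against a reference locus in practice), assembles
#' D-J-C clusters, optionally scans for duplicated-region artifacts, and
#' returns a `locus_map`.
#'
#' @param assembly Named DNAStringSet or named character vector (one or more
#'   scaffolds).
#' @param references A `reference_library`.
#' @param label Label for the map.
#' @param min_identity_v Minimum V identity (percent).
#' @param d_window Width (bp) of the D search window upstream of each J
#'   cluster.
#' @param scan_duplicates Whether to run [flag_duplicate_regions()].
#' @return A `locus_map` with genes, clusters, gaps and artifacts.
#' @export
annotate_locus <- function(assembly, references, label = "assembly",
                           min_identity_v = 60, d_window = 800L,
                           scan_duplicates = TRUE) {
  if (!inherits(assembly, "DNAStringSet")) {
    if (is.character(assembly) && is.null(names(assembly))) {
      assembly <- stats::setNames(assembly, paste0("seq", seq_along(assembly)))
    }
    assembly <- Biostrings::DNAStringSet(vapply(assembly, as_seq_string, character(1L)))
  }
  v <- find_v_genes(assembly, references, min_identity = min_identity_v)
  c_genes <- find_c_genes(assembly, references)
  try_genes <- find_homology_genes(assembly, references, "TRY")
  flank_genes <- find_homology_genes(assembly, references, "FLANK")
  all_models <- list()
  all_gaps <- list()
  for (sc in seq_along(assembly)) {
    scaf_id <- names(assembly)[sc]
    s <- as.character(assembly[[sc]])
    gaps <- detect_gaps(s)
    if (nrow(gaps)) {
      gaps$scaffold <- scaf_id
      all_gaps[[length(all_gaps) + 1L]] <- gaps
    }
    j <- find_j_genes(s, references, scaffold = scaf_id)
    d <- list()
    if (length(j)) {
      js <- vapply(j, gene_start, numeric(1L))
      grp <- cumsum(c(1L, diff(sort(js)) > 2000L))
      for (g in unique(grp)) {
        first_j <- min(sort(js)[grp == g])
        win <- c(max(1L, first_j - d_window), first_j)
        sub <- substring(s, win[1L], win[2L])
        dc <- find_d_genes(sub, scaffold = scaf_id)
        if (length(dc)) {
          scores <- vapply(dc, function(m) {
            (m$rss$d5_rs$total_score %||% 99) + (m$rss$d3_rs$total_score %||% 99)
          }, numeric(1L))
          best <- dc[[order(scores, vapply(dc, gene_start, numeric(1L)))[1L]]]
          best$exons <- best$exons + win[1L] - 1L
          best$rss$d5_rs$heptamer_start <- best$rss$d5_rs$heptamer_start + win[1L] - 1L
          best$rss$d3_rs$heptamer_start <- best$rss$d3_rs$heptamer_start + win[1L] - 1L
          best$name <- sprintf("D@%s:%d", scaf_id, gene_start(best))
          d[[length(d) + 1L]] <- best
        }
      }
    }
    sc_models <- c(
      v[vapply(v, function(m) m$scaffold == scaf_id, logical(1L))],
      d, j,
      c_genes[vapply(c_genes, function(m) m$scaffold == scaf_id, logical(1L))],
      try_genes[vapply(try_genes, function(m) m$scaffold == scaf_id, logical(1L))],
      flank_genes[vapply(flank_genes, function(m) m$scaffold == scaf_id, logical(1L))])
    all_models <- c(all_models, sc_models)
  }
  gaps_df <- if (length(all_gaps)) do.call(rbind, all_gaps) else NULL
  map <- locus_map(label = label, genes = .sort_models(all_models),
                   gaps = gaps_df,
                   scaffold = if (length(assembly) == 1L) names(assembly) else NA_character_,
                   seq_length = sum(Biostrings::width(assembly)))
  # cluster-ordinal naming for D/J/C
  map$clusters <- assemble_clusters(map)
  renames <- list()
  for (cl in map$clusters) {
    if (!is.null(cl$d_gene)) renames[[cl$d_gene$name]] <- paste0("TRBD", cl$ordinal)
    for (ji in seq_along(cl$j_genes)) {
      renames[[cl$j_genes[[ji]]$name]] <- paste0("TRBJ", cl$ordinal, "-", ji)
    }
    if (!is.null(cl$c_gene)) renames[[cl$c_gene$name]] <- paste0("TRBC", cl$ordinal)
  }
  if (length(renames)) {
    for (i in seq_along(map$genes)) {
      nm <- map$genes[[i]]$name
      if (!is.null(renames[[nm]])) map$genes[[i]]$name <- renames[[nm]]
    }
    map$clusters <- assemble_clusters(map)
  }
  if (scan_duplicates && length(assembly) == 1L) {
    art <- flag_duplicate_regions(map, as.character(assembly[[1L]]))
    map$artifacts <- art
    flagged <- attr(art, "flagged_genes") %||% character()
    excl <- attr(art, "exclude_candidates") %||% character()
    for (i in seq_along(map$genes)) {
      nm <- map$genes[[i]]$name
      if (nm %in% flagged) {
        map$genes[[i]]$flags <- unique(c(map$genes[[i]]$flags, "duplicate_region"))
      }
      if (nm %in% excl) {
        map$genes[[i]]$flags <- unique(c(map$genes[[i]]$flags, "exclude_candidate"))
      }
    }
  }
  map
}
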