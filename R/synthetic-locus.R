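# Synthetic TRB-like locus generator with planted ground truth.
#
# The generated locus mirrors the architecture of a camelid-style TRB locus:
# a 5' flanking marker gene, a pool of V genes (leader exon + intron +
# V-exon + 23-spacer RS) interspersed with TRY-like protease genes (a block
# after the first V and one before the first D-J-C cluster), three in-tandem
# D-J-C clusters (one D flanked by 12/23-spacer RSs, six or seven J genes
# each with a 12-spacer RS and an FGXG-encoding exon, one 4-exon C gene),
# one inverted V gene 3' of the clusters, and a 3' flanking marker.
# Every planted gene carries a truth record (coordinates, strand, subgroup,
# functionality label, lesion), so annotation, classification, clustering
# and nomenclature all have a recoverable answer.

#' Configuration for the synthetic locus generator
#'
#' @param n_v_genes Total V genes (the 3'-most one is planted in inverted
#'   orientation after the D-J-C clusters).
#' @param n_subgroups Number of V subgroups; members of one subgroup derive
#'   from a common ancestor.
#' @param subgroup_divergence Substitutions/site between subgroup ancestors
#'   (each ancestor is the archetype mutated at this rate; pairwise
#'   between-subgroup identity lands well below the 75% subgroup threshold).
#' @param within_subgroup_divergence Substitutions/site between a subgroup
#'   ancestor and its members (pairwise within-subgroup identity stays well
#'   above 75%).
#' @param n_djc_clusters Number of D-J-C clusters.
#' @param j_per_cluster J genes per cluster, each in `{6, 7}`; recycled to
#'   `n_djc_clusters`.
#' @param n_try_genes TRY-like genes; all but one are placed in a block
#'   after the first V gene, the last one before cluster 1.
#' @param pseudogene_rate Per-V-gene probability of planting a lesion.
#' @param lesion_mix Named weights over `stop`, `frameshift`, `splice`,
#'   `rs_defect`. The first three plant label P; `rs_defect` plants label
#'   ORF (an intact reading frame with an altered conserved RS).
#' @param gap_rate Expected N-gap runs per 100 kb of intergenic sequence.
#' @param gc_target GC fraction of intergenic sequence.
#' @param v_spacing Range (bp) of intergenic spacing between V-region genes.
#' @param seed Integer seed; a single global random stream drives all
#'   sampling in fixed (configuration) order.
#' @return An object of class `locus_config`.
#' @export
locus_config <- function(n_v_genes = 33L, n_subgroups = 26L,
                         subgroup_divergence = 0.35,
                         within_subgroup_divergence = 0.05,
                         n_djc_clusters = 3L, j_per_cluster = c(6L, 7L, 6L),
                         n_try_genes = 5L, pseudogene_rate = 0.2,
                         lesion_mix = c(stop = 1, frameshift = 1,
                                        splice = 1, rs_defect = 1),
                         gap_rate = 0, gc_target = 0.45,
                         v_spacing = c(6500, 8500), seed = 1L) {
  stopifnot(n_v_genes >= 0L, n_subgroups >= 0L,
            n_subgroups <= max(n_v_genes, 1L) || n_v_genes == 0L,
            pseudogene_rate >= 0, pseudogene_rate <= 1,
            subgroup_divergence >= 0, subgroup_divergence <= 1,
            within_subgroup_divergence >= 0, within_subgroup_divergence <= 1,
            gc_target > 0, gc_target < 1, gap_rate >= 0,
            n_djc_clusters >= 0L)
  if (n_v_genes > 0L && n_subgroups > n_v_genes) {
    stop("n_subgroups must not exceed n_v_genes")
  }
  j_per_cluster <- as.integer(j_per_cluster)
  if (n_djc_clusters > 0L) {
    j_per_cluster <- rep_len(j_per_cluster, n_djc_clusters)
    stopifnot(all(j_per_cluster %in% c(6L, 7L)))
  }
  stopifnot(all(names(lesion_mix) %in% c("stop", "frameshift", "splice", "rs_defect")),
            all(lesion_mix >= 0), sum(lesion_mix) > 0)
  structure(list(n_v_genes = as.integer(n_v_genes),
                 n_subgroups = as.integer(n_subgroups),
                 subgroup_divergence = subgroup_divergence,
                 within_subgroup_divergence = within_subgroup_divergence,
                 n_djc_clusters = as.integer(n_djc_clusters),
                 j_per_cluster = j_per_cluster,
                 n_try_genes = as.integer(n_try_genes),
                 pseudogene_rate = pseudogene_rate,
                 lesion_mix = lesion_mix, gap_rate = gap_rate,
                 gc_target = gc_target, v_spacing = v_spacing,
                 seed = as.integer(seed)),
            class = "locus_config")
}

# ---- structural constants of the generated gene templates -----------------

V_LEADER_LEN <- 48L    # ATG + 15 codons; multiple of 3 so the V-exon is frame 0
V_INTRON_LEN <- 90L
V_EXON_LEN <- 294L     # inside the expected V coding range 280-310
J_EXON_LEN <- 48L
D_SEGMENT <- "GGGACAGGGGGCTG"
C_EXON_LENS <- c(288L, 130L, 107L, 12L)  # spliced CDS 537 bp = 178 aa + stop
C_INTRON_LENS <- c(150L, 120L, 100L)
TRY_CODONS <- 233L     # ATG + 231 codons + stop = 699 bp
FLANK_LEN <- 600L

# ---- mutation helpers (all draw from the global RNG stream) ---------------

# Substitute positions of `s` at `rate`, never touching `protect` positions.
# If `coding` (list of template-relative intervals in coding order, frame 0)
# is given, substitutions creating an in-frame stop codon are skipped.
mutate_seq <- function(s, rate, protect = integer(), coding = NULL) {
  if (rate <= 0) return(s)
  ch <- seq_chars(s)
  n <- length(ch)
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, protect)
  if (!length(hit)) return(s)
  coding_pos <- NULL
  if (!is.null(coding)) {
    coding_pos <- unlist(lapply(coding, function(iv) seq(iv[1L], iv[2L])))
  }
  for (p in hit) {
    new <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    old <- ch[p]
    ch[p] <- new
    if (!is.null(coding_pos)) {
      ci <- match(p, coding_pos)
      if (!is.na(ci)) {
        cod_idx <- (ci - 1L) %/% 3L
        cod_pos <- coding_pos[(cod_idx * 3L + 1L):(cod_idx * 3L + 3L)]
        if (codon_table[[paste0(ch[cod_pos], collapse = "")]] == "*") {
          ch[p] <- old  # skip substitutions that would plant a stop
        }
      }
    }
  }
  paste0(ch, collapse = "")
}

# Mutate a consensus RS element with light noise bounded within the
# functional band (heptamer <=1 mismatch, nonamer <=2), so intended-F genes
# keep a proper RS.
noisy_rss <- function(spacer_class, gc, rate = 0.05) {
  mut_capped <- function(cons, cap) {
    ch <- seq_chars(cons)
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit) > cap) hit <- hit[seq_len(cap)]
    for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste0(ch, collapse = "")
  }
  paste0(mut_capped(RSS_HEPTAMER, 1L), random_dna(spacer_class, gc),
         mut_capped(RSS_NONAMER, 2L))
}

#' Plant a pseudogenizing lesion in a gene sequence
#'
#' @param gene_sequence Character scalar (the gene, template orientation).
#' @param mode One of `"stop"` (replace one sense codon with a stop, in
#'   frame), `"frameshift"` (delete 1 bp in the exon), `"splice"` (break a
#'   GT donor or AG acceptor dinucleotide), `"rs_defect"` (mutate 3 heptamer
#'   positions).
#' @param seed Optional integer seed; `NULL` draws from the current stream.
#' @param elements Named list locating the targeted elements in
#'   `gene_sequence`: `exon` (start,end; frame 0 at its start), `donor`
#'   (start,end of the GT), `acceptor` (start,end of the AG), `heptamer`
#'   (start,end of the RS heptamer). Defaults treat the whole string as one
#'   frame-0 exon.
#' @return List with `seq` (mutated sequence) and `lesion` (descriptor:
#'   mode, position, detail).
#' @export
pseudogenize <- function(gene_sequence, mode = c("stop", "frameshift", "splice", "rs_defect"),
                         seed = NULL, elements = list(exon = c(1L, nchar(gene_sequence)))) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- gene_sequence
  if (mode == "stop") {
    ex <- elements$exon
    if (is.null(ex)) stop("mode target absent: no exon")
    n_codons <- (ex[2L] - ex[1L] + 1L) %/% 3L
    if (n_codons < 2L) stop("mode target absent: exon too short")
    starts <- ex[1L] + 3L * (seq_len(n_codons) - 1L)
    sense <- which(vapply(starts, function(p) {
      codon_table[[substring(s, p, p + 2L)]] != "*"
    }, logical(1L)))
    sense <- setdiff(sense, 1L)  # never the initiation codon
    if (!length(sense)) stop("mode target absent: no sense codon")
    k <- if (length(sense) == 1L) sense else sample(sense, 1L)
    stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
    pos <- starts[k]
    s <- paste0(substring(s, 1L, pos - 1L), stop_codon,
                substring(s, pos + 3L, nchar(s)))
    lesion <- list(mode = "stop", position = pos, detail = stop_codon)
  } else if (mode == "frameshift") {
    ex <- elements$exon
    if (is.null(ex) || ex[2L] - ex[1L] < 6L) stop("mode target absent: no exon")
    pos <- sample(seq(ex[1L] + 3L, ex[2L] - 3L), 1L)
    s <- paste0(substring(s, 1L, pos - 1L), substring(s, pos + 1L, nchar(s)))
    lesion <- list(mode = "frameshift", position = pos, detail = "del1")
  } else if (mode == "splice") {
    tgt <- if (!is.null(elements$donor) && !is.null(elements$acceptor)) {
      sample(c("donor", "acceptor"), 1L)
    } else if (!is.null(elements$donor)) "donor"
    else if (!is.null(elements$acceptor)) "acceptor"
    else stop("mode target absent: no splice site")
    iv <- elements[[tgt]]
    pos <- iv[1L]
    old <- substring(s, pos, pos)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substring(s, pos, pos) <- new
    lesion <- list(mode = "splice", position = pos,
                   detail = paste0(tgt, ":", old, ">", new))
  } else {  # rs_defect
    iv <- elements$heptamer
    if (is.null(iv)) stop("mode target absent: no heptamer")
    pos <- sort(sample(seq(iv[1L], iv[2L]), 3L))
    ch <- seq_chars(s)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    s <- paste0(ch, collapse = "")
    lesion <- list(mode = "rs_defect", position = pos[1L],
                   detail = paste(pos, collapse = ","))
  }
  list(seq = s, lesion = lesion)
}

# ---- reference (ancestor) construction ------------------------------------

# Build the ancestral gene templates. Everything is drawn from the current
# RNG stream, so generate_locus() and reference_library() agree for a seed.
.make_ancestors <- function(config) {
  gc <- config$gc_target
  arch_leader <- paste0("ATG", random_codons(15L, gc))
  arch_intron <- paste0("GT", random_dna(V_INTRON_LEN - 4L, gc), "AG")
  arch_vexon <- random_codons(V_EXON_LEN / 3L, gc)
  v_anc <- vector("list", config$n_subgroups)
  for (i in seq_len(config$n_subgroups)) {
    v_anc[[i]] <- list(
      leader = mutate_seq(arch_leader, config$subgroup_divergence,
                          protect = 1:3, coding = list(c(1L, V_LEADER_LEN))),
      intron = mutate_seq(arch_intron, config$subgroup_divergence,
                          protect = c(1:2, (V_INTRON_LEN - 1L):V_INTRON_LEN)),
      vexon = mutate_seq(arch_vexon, config$subgroup_divergence,
                         coding = list(c(1L, V_EXON_LEN))))
  }
  # J ancestor: 16 codons, FGXG planted at codons 9-12 (FGQG)
  j_exon <- paste0(random_codons(8L, gc), "TTTGGCCAGGGC", random_codons(4L, gc))
  # C ancestor: spliced CDS then cut into 4 exons joined by GT..AG introns
  c_cds <- paste0(random_codons(178L, gc), "TGA")
  c_ex <- character(4L)
  off <- 0L
  for (i in 1:4) {
    c_ex[i] <- substring(c_cds, off + 1L, off + C_EXON_LENS[i])
    off <- off + C_EXON_LENS[i]
  }
  c_introns <- vapply(C_INTRON_LENS, function(L) {
    paste0("GT", random_dna(L - 4L, gc), "AG")
  }, character(1L))
  try_anc <- lapply(seq_len(max(config$n_try_genes, 0L)), function(i) {
    paste0("ATG", random_codons(TRY_CODONS - 2L, gc), "TGA")
  })
  flank5 <- random_dna(FLANK_LEN, gc)
  flank3 <- random_dna(FLANK_LEN, gc)
  list(v = v_anc, j_exon = j_exon, c_exons = c_ex, c_introns = c_introns,
       try_genes = try_anc, flank5 = flank5, flank3 = flank3)
}

# Assemble a reference library object from ancestors, using genomic-order
# subgroup ranks so reference names match planted names.
.make_reference_library <- function(anc, sg_rank, config) {
  recs <- list()
  add <- function(name, type, seq, meta = list()) {
    recs[[length(recs) + 1L]] <<- c(list(name = name, type = type, seq = seq), meta)
  }
  for (i in seq_along(anc$v)) {
    a <- anc$v[[i]]
    add(paste0("TRBV", sg_rank[i]), "V",
        paste0(a$leader, a$intron, a$vexon),
        list(leader_len = V_LEADER_LEN, intron_len = V_INTRON_LEN,
             vexon_len = V_EXON_LEN, subgroup = paste0("TRBV", sg_rank[i])))
  }
  add("TRBJ", "J", anc$j_exon, list(exon_len = J_EXON_LEN))
  c_tmpl <- paste0(anc$c_exons[1L], anc$c_introns[1L], anc$c_exons[2L],
                   anc$c_introns[2L], anc$c_exons[3L], anc$c_introns[3L],
                   anc$c_exons[4L])
  ex_start <- cumsum(c(1L, utils::head(C_EXON_LENS, -1L) + C_INTRON_LENS))
  add("TRBC", "C", c_tmpl,
      list(exon_starts = ex_start, exon_lens = C_EXON_LENS))
  add("TRBD", "D", D_SEGMENT, list())
  for (i in seq_along(anc$try_genes)) {
    add(paste0("TRY", i), "TRY", anc$try_genes[[i]], list())
  }
  add("MOXD2", "FLANK", anc$flank5, list())
  add("EPHB6", "FLANK", anc$flank3, list())
  structure(list(records = recs), class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  types <- vapply(x$records, `[[`, character(1L), "type")
  cat("<reference_library>", length(x$records), "references (",
      paste(sprintf("%s:%d", names(table(types)), table(types)), collapse = " "),
      ")\n")
  invisible(x)
}

#' Subset a reference library by gene type
#' @param refs A `reference_library`.
#' @param type Gene type.
#' @export
ref_subset <- function(refs, type) {
  keep <- vapply(refs$records, function(r) r$type == type, logical(1L))
  structure(list(records = refs$records[keep]), class = "reference_library")
}

#' Write a reference library as FASTA with metadata headers
#'
#' Headers follow `name|type=V|key=value|...`; [read_reference_library()]
#' restores the object.
#' @param refs A `reference_library`.
#' @param path Output path.
#' @export
write_reference_library <- function(refs, path) {
  lines <- unlist(lapply(refs$records, function(r) {
    meta <- r[setdiff(names(r), c("name", "seq"))]
    kv <- vapply(names(meta), function(k) {
      paste0(k, "=", paste(meta[[k]], collapse = ","))
    }, character(1L))
    c(paste0(">", r$name, "|", paste(kv, collapse = "|")), r$seq)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference library written by [write_reference_library()]
#' @param path FASTA path with metadata headers.
#' @export
read_reference_library <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  recs <- lapply(seq_along(ss), function(i) {
    hdr <- strsplit(names(ss)[i], "|", fixed = TRUE)[[1L]]
    rec <- list(name = hdr[1L], seq = as.character(ss[[i]]))
    for (kv in hdr[-1L]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      val <- strsplit(p[2L], ",", fixed = TRUE)[[1L]]
      num <- suppressWarnings(as.integer(val))
      rec[[p[1L]]] <- if (!anyNA(num)) num else val
    }
    rec
  })
  structure(list(records = recs), class = "reference_library")
}

#' Reference library for a configuration
#'
#' Reproduces exactly the ancestor library used by [generate_locus()] for
#' the same configuration (same seed, same draw order).
#' @param config A `locus_config`.
#' @export
reference_library <- function(config) {
  generate_locus(config)$references
}

# ---- the generator --------------------------------------------------------

#' Generate a synthetic TRB-like locus with planted truth
#'
#' @param config A [locus_config()].
#' @return Object of class `synthetic_locus`: list with `sequence`
#'   (character scalar), `truth` (data.frame: name, type, subgroup, strand,
#'   start, end, exons "s-e;s-e" in forward order, label, lesion_mode,
#'   lesion_pos), `references` (a `reference_library`), `lesions` (truth
#'   rows carrying lesions) and `config`.
#' @export
generate_locus <- function(config) {
  stopifnot(inherits(config, "locus_config"))
  set.seed(config$seed)
  gc <- config$gc_target
  anc <- .make_ancestors(config)

  # -- plan V membership and order ------------------------------------------
  n_v <- config$n_v_genes
  n_sg <- config$n_subgroups
  sg_sizes <- integer(0)
  v_order_sg <- integer(0)
  inverted_sg <- NA_integer_
  if (n_v > 0L) {
    sg_sizes <- rep(1L, n_sg)
    extras <- n_v - n_sg
    i <- 1L
    while (extras > 0L) {
      sg_sizes[i] <- sg_sizes[i] + 1L
      i <- if (i == n_sg) 1L else i + 1L
      extras <- extras - 1L
    }
    singletons <- which(sg_sizes == 1L)
    inverted_sg <- if (length(singletons)) singletons[length(singletons)] else n_sg
    pool <- rep(seq_len(n_sg), sg_sizes)
    pool <- pool[-match(inverted_sg, pool)]  # one copy reserved for the 3' end
    v_order_sg <- if (length(pool)) sample(pool) else integer(0)
  }
  placed_order <- c(v_order_sg, if (n_v > 0L) inverted_sg)
  sg_rank <- integer(n_sg)
  if (n_sg > 0L) {
    first_seen <- unique(placed_order)
    sg_rank[first_seen] <- seq_along(first_seen)
    unseen <- setdiff(seq_len(n_sg), first_seen)
    if (length(unseen)) sg_rank[unseen] <- seq(length(first_seen) + 1L, n_sg)
  }
  refs <- .make_reference_library(anc, sg_rank, config)

  # -- sequence assembly ----------------------------------------------------
  parts <- character(0)
  pos <- 0L
  add <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    start <- pos + 1L
    pos <<- pos + nchar(s)
    c(start, pos)
  }
  intergenic <- function(len) {
    len <- as.integer(len)
    s <- random_dna(len, gc)
    if (config$gap_rate > 0 && stats::runif(1L) < config$gap_rate * len / 1e5) {
      gl <- as.integer(stats::runif(1L, 100, 800))
      if (gl + 2L < len) {
        at <- as.integer(stats::runif(1L, 1, len - gl))
        s <- paste0(substring(s, 1L, at), strrep("N", gl),
                    substring(s, at + gl + 1L, len))
      }
    }
    add(s)
    invisible(NULL)
  }

  truth <- list()
  record <- function(name, type, subgroup, strand, exons, label,
                     lesion_mode = NA_character_, lesion_pos = NA_integer_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      name = name, type = type, subgroup = subgroup, strand = strand,
      start = min(exons[, 1L]), end = max(exons[, 2L]),
      exons = paste(sprintf("%d-%d", exons[, 1L], exons[, 2L]), collapse = ";"),
      label = label, lesion_mode = lesion_mode, lesion_pos = lesion_pos,
      stringsAsFactors = FALSE)
  }

  draw_lesion <- function() {
    if (stats::runif(1L) >= config$pseudogene_rate) return(NA_character_)
    sample(names(config$lesion_mix), 1L, prob = config$lesion_mix)
  }

  sg_member_count <- integer(n_sg)
  v_name <- function(sg) {
    sg_member_count[sg] <<- sg_member_count[sg] + 1L
    if (sg_sizes[sg] > 1L) {
      paste0("TRBV", sg_rank[sg], "S", sg_member_count[sg])
    } else paste0("TRBV", sg_rank[sg])
  }

  # Build one V gene (template orientation), apply divergence + optional
  # lesion, return list(seq, rel: template-relative feature coords, label,
  # lesion).
  build_v <- function(sg) {
    a <- anc$v[[sg]]
    leader <- mutate_seq(a$leader, config$within_subgroup_divergence,
                         protect = 1:3, coding = list(c(1L, V_LEADER_LEN)))
    intron <- mutate_seq(a$intron, config$within_subgroup_divergence,
                         protect = c(1:2, (V_INTRON_LEN - 1L):V_INTRON_LEN))
    vexon <- mutate_seq(a$vexon, config$within_subgroup_divergence,
                        coding = list(c(1L, V_EXON_LEN)))
    rs <- noisy_rss(23L, gc)
    g <- paste0(leader, intron, vexon, rs)
    vx_start <- V_LEADER_LEN + V_INTRON_LEN + 1L
    vx_end <- vx_start + V_EXON_LEN - 1L
    rel <- list(leader = c(1L, V_LEADER_LEN),
                donor = c(V_LEADER_LEN + 1L, V_LEADER_LEN + 2L),
                acceptor = c(vx_start - 2L, vx_start - 1L),
                vexon = c(vx_start, vx_end),
                heptamer = c(vx_end + 1L, vx_end + 7L))
    mode <- draw_lesion()
    lesion <- NULL
    if (!is.na(mode)) {
      res <- pseudogenize(g, mode, elements = list(
        exon = rel$vexon, donor = rel$donor, acceptor = rel$acceptor,
        heptamer = rel$heptamer))
      g <- res$seq
      lesion <- res$lesion
      if (mode == "frameshift") {
        # everything 3' of the deleted base shifts left by one
        shift <- function(iv) ifelse(iv > res$lesion$position, iv - 1L, iv)
        rel <- lapply(rel, shift)
      }
    }
    label <- if (is.null(lesion)) "F" else if (lesion$mode == "rs_defect") "ORF" else "P"
    list(seq = g, rel = rel, label = label, lesion = lesion)
  }

  place_v <- function(sg, inverted = FALSE) {
    b <- build_v(sg)
    L <- nchar(b$seq)
    if (!inverted) {
      span <- add(b$seq)
      ex <- rbind(span[1L] - 1L + b$rel$leader, span[1L] - 1L + b$rel$vexon)
      strand <- "+"
    } else {
      span <- add(revcomp(b$seq))
      flip <- function(iv) c(span[1L] + L - iv[2L], span[1L] + L - iv[1L])
      ex <- rbind(flip(b$rel$vexon), flip(b$rel$leader))
      strand <- "-"
    }
    record(v_name(sg), "V", paste0("TRBV", sg_rank[sg]), strand, ex, b$label,
           lesion_mode = if (is.null(b$lesion)) NA_character_ else b$lesion$mode,
           lesion_pos = if (is.null(b$lesion)) NA_integer_ else
             span[1L] - 1L + b$lesion$position)
    invisible(NULL)
  }

  place_try <- function(i) {
    g <- mutate_seq(anc$try_genes[[i]], 0.03, protect = 1:3,
                    coding = list(c(1L, nchar(anc$try_genes[[i]]) - 3L)))
    span <- add(g)
    record(paste0("TRY", i), "TRY", NA_character_, "+",
           rbind(span), "F")
    invisible(NULL)
  }

  place_cluster <- function(ord, n_j) {
    # D with 12-RS upstream (inverted orientation) and 23-RS downstream
    add(revcomp(noisy_rss(12L, gc)))
    d_span <- add(D_SEGMENT)
    add(noisy_rss(23L, gc))
    record(paste0("TRBD", ord), "D", NA_character_, "+", rbind(d_span), "F")
    intergenic(round(stats::runif(1L, 450, 650)))
    for (j in seq_len(n_j)) {
      add(revcomp(noisy_rss(12L, gc)))
      j_exon <- mutate_seq(anc$j_exon, 0.08, protect = 25:36,
                           coding = list(c(1L, J_EXON_LEN)))
      j_span <- add(j_exon)
      add("GT")
      record(paste0("TRBJ", ord, "-", j), "J", NA_character_, "+",
             rbind(j_span), "F")
      intergenic(round(stats::runif(1L, 90, 160)))
    }
    intergenic(round(stats::runif(1L, 600, 900)))
    c_ex <- lapply(anc$c_exons, function(e) {
      mutate_seq(e, 0.02)  # light species-level divergence; frame guarded below
    })
    spliced <- paste0(unlist(c_ex), collapse = "")
    # guard: re-generate any stop introduced upstream of the final codon
    prot <- translate_string(spliced)
    if (grepl("\\*", substring(prot, 1L, nchar(prot) - 1L))) {
      c_ex <- anc$c_exons
    }
    ex <- matrix(0L, 4L, 2L)
    for (i in 1:4) {
      sp <- add(c_ex[[i]])
      ex[i, ] <- sp
      if (i < 4L) add(paste0("GT", random_dna(C_INTRON_LENS[i] - 4L, gc), "AG"))
    }
    record(paste0("TRBC", ord), "C", NA_character_, "+", ex, "F")
    invisible(NULL)
  }

  # ---- layout -------------------------------------------------------------
  intergenic(1500L)
  sp5 <- add(anc$flank5)
  record("MOXD2", "FLANK", NA_character_, "+", rbind(sp5), "F")
  intergenic(round(stats::runif(1L, 2000, 3000)))

  n_try <- config$n_try_genes
  try_head <- if (n_try > 1L) seq_len(n_try - 1L) else integer(0)
  try_tail <- if (n_try >= 1L) n_try else integer(0)

  for (k in seq_along(v_order_sg)) {
    place_v(v_order_sg[k])
    intergenic(round(stats::runif(1L, config$v_spacing[1L], config$v_spacing[2L])))
    if (k == 1L) {
      for (t in try_head) {
        place_try(t)
        intergenic(round(stats::runif(1L, 1500, 2500)))
      }
    }
  }
  if (length(try_tail)) {
    place_try(try_tail)
    intergenic(round(stats::runif(1L, 1500, 2500)))
  }
  for (cl in seq_len(config$n_djc_clusters)) {
    place_cluster(cl, config$j_per_cluster[cl])
    intergenic(round(stats::runif(1L, 2000, 3000)))
  }
  if (n_v > 0L) {
    place_v(inverted_sg, inverted = TRUE)
    intergenic(round(stats::runif(1L, 2000, 3000)))
  }
  sp3 <- add(anc$flank3)
  record("EPHB6", "FLANK", NA_character_, "+", rbind(sp3), "F")
  intergenic(1500L)

  sequence <- paste0(parts, collapse = "")
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(sequence = sequence, truth = truth, references = refs,
                 lesions = truth[!is.na(truth$lesion_mode), , drop = FALSE],
                 config = config),
            class = "synthetic_locus")
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf("<synthetic_locus> %d bp, %d planted genes (%d lesioned), seed %d\n",
              nchar(x$sequence), nrow(x$truth), nrow(x$lesions),
              x$config$seed))
  invisible(x)
}

#' Parse truth exon strings into coordinate matrices
#' @param truth_row One row of a truth data.frame.
#' @return Two-column integer matrix.
#' @export
truth_exons <- function(truth_row) {
  ivs <- strsplit(truth_row$exons, ";", fixed = TRUE)[[1L]]
  m <- do.call(rbind, lapply(strsplit(ivs, "-", fixed = TRUE), as.integer))
  colnames(m) <- c("start", "end")
  m
}

#' Fragment a locus into overlapping or gapped scaffolds
#'
#' Emulates draft-assembly fragmentation: the locus is cut into
#' `n_scaffolds` pieces whose breakpoints avoid genes (policies `overlap`,
#' `n_gap`) or deliberately split one gene's exon (`split_gene`).
#'
#' @param locus A `synthetic_locus` (or character sequence).
#' @param truth Truth data.frame (defaults to `locus$truth`).
#' @param n_scaffolds Number of scaffolds.
#' @param overlap Shared bp between adjacent scaffolds (policy `overlap`).
#' @param gap_policy `"overlap"` (adjacent scaffolds share `overlap` bp),
#'   `"n_gap"` (a chunk between scaffolds is dropped, an unknown gap), or
#'   `"split_gene"` (one breakpoint falls inside a gene exon; that gene is
#'   marked `nd`).
#' @return List with `scaffolds` (named character vector), `truth`
#'   (remapped truth with `scaffold` column) and `breakpoints`.
#' @export
fragment_assembly <- function(locus, truth = NULL, n_scaffolds = 3L,
                              overlap = 200L,
                              gap_policy = c("overlap", "n_gap", "split_gene")) {
  gap_policy <- match.arg(gap_policy)
  if (inherits(locus, "synthetic_locus")) {
    truth <- truth %||% locus$truth
    seq <- locus$sequence
  } else {
    seq <- as_seq_string(locus)
    truth <- truth %||% data.frame()
  }
  n <- nchar(seq)
  stopifnot(n_scaffolds >= 1L)
  if (n_scaffolds == 1L) {
    tr <- truth
    if (nrow(tr)) tr$scaffold <- "scaffold_1"
    return(list(scaffolds = c(scaffold_1 = seq), truth = tr,
                breakpoints = integer(0)))
  }
  stopifnot(overlap < n %/% n_scaffolds)
  targets <- round(seq_len(n_scaffolds - 1L) * n / n_scaffolds)
  clearance <- if (gap_policy == "n_gap") as.integer(overlap) else 0L
  blocked <- function(p) {
    nrow(truth) && any(truth$start <= p & truth$end >= (p - clearance))
  }
  bps <- integer(0)
  for (t in targets) {
    p <- t
    while (p < n && blocked(p)) p <- p + 1L
    if (blocked(p)) {
      p <- t
      while (p > 1L && blocked(p)) p <- p - 1L
    }
    if (blocked(p)) stop("impossible breakpoint request: no intergenic position")
    bps <- c(bps, p)
  }
  split_target <- NA_character_
  if (gap_policy == "split_gene") {
    if (!nrow(truth)) stop("impossible breakpoint request: no genes to split")
    mid <- truth[truth$type %in% c("V", "J", "C", "TRY", "D"), , drop = FALSE]
    tgt <- mid[which.min(abs((mid$start + mid$end) / 2 - targets[1L])), ]
    ex <- truth_exons(tgt)
    bps[1L] <- as.integer((ex[1L, 1L] + ex[1L, 2L]) %/% 2L)
    split_target <- tgt$name
  }
  starts <- c(1L, bps + 1L)
  ends <- c(bps, n)
  if (gap_policy == "overlap") {
    starts[-1L] <- pmax(1L, starts[-1L] - as.integer(overlap))
  } else if (gap_policy == "n_gap") {
    drop <- as.integer(overlap)
    ends[-length(ends)] <- pmax(starts[-length(starts)] - 1L + 1L,
                                ends[-length(ends)] - drop)
  }
  scaffolds <- stats::setNames(
    substring(seq, starts, ends),
    paste0("scaffold_", seq_len(n_scaffolds)))
  out_truth <- list()
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      row <- truth[i, ]
      hit <- which(starts <= row$start & ends >= row$end)
      if (length(hit)) {
        k <- hit[1L]
        off <- starts[k] - 1L
        ex <- truth_exons(row) - off
        row$start <- row$start - off
        row$end <- row$end - off
        row$exons <- paste(sprintf("%d-%d", ex[, 1L], ex[, 2L]), collapse = ";")
        row$scaffold <- names(scaffolds)[k]
        out_truth[[length(out_truth) + 1L]] <- row
      } else {
        # gene split across scaffolds (or lost in an n_gap): keep the piece
        # on the scaffold holding its 5' end, mark functionality undefinable
        k <- which(starts <= row$start & ends >= row$start)
        k <- if (length(k)) k[length(k)] else 1L
        off <- starts[k] - 1L
        ex <- truth_exons(row)
        ex[, 2L] <- pmin(ex[, 2L], ends[k])
        ex <- ex[ex[, 1L] <= ends[k], , drop = FALSE]
        ex <- ex - off
        row$start <- max(1L, row$start - off)
        row$end <- max(ex[, 2L])
        row$exons <- paste(sprintf("%d-%d", ex[, 1L], ex[, 2L]), collapse = ";")
        row$label <- "nd"
        row$scaffold <- names(scaffolds)[k]
        out_truth[[length(out_truth) + 1L]] <- row
      }
    }
  }
  tr <- if (length(out_truth)) do.call(rbind, out_truth) else truth
  rownames(tr) <- NULL
  list(scaffolds = scaffolds, truth = tr, breakpoints = bps,
       split_gene = split_target)
}
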