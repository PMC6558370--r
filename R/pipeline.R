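# End-to-end orchestration: simulate -> annotate -> classify -> subgroup ->
# tree -> compare -> consensus, with a serialized configuration, audit log
# and checksummed artifacts.

#' Build a pipeline run configuration
#'
#' @param stages Character vector of stages to run, in fixed order from
#'   `simulate`, `annotate`, `classify`, `subgroup`, `tree`, `compare`,
#'   `consensus`, `summarize`.
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level seed; per-stage seeds are derived by fixed offsets
#'   so stage-level re-runs stay reproducible.
#' @param locus Optional `locus_config` for the simulate stage (its seed is
#'   overridden by the derived stage seed).
#' @param assembly_fasta,references_fasta Input paths when not simulating.
#' @param thresholds Named list of threshold overrides
#'   (`min_identity_v`, `subgroup_threshold`, `bootstrap_reps`,
#'   `pip_min_len`, `pip_min_identity`, `expected_lengths`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "annotate", "classify",
                                  "subgroup", "tree", "summarize"),
                       out_dir = tempfile("camlocus_run_"), seed = 1L,
                       locus = NULL, assembly_fasta = NULL,
                       references_fasta = NULL, thresholds = list()) {
  all_stages <- c("simulate", "annotate", "classify", "subgroup", "tree",
                  "compare", "consensus", "summarize")
  stages <- all_stages[all_stages %in% stages]
  if (!length(stages)) stop("nothing to do: no stages enabled")
  defaults <- list(min_identity_v = 60, subgroup_threshold = 75,
                   bootstrap_reps = 100L, pip_min_len = 100L,
                   pip_min_identity = 50)
  for (nm in names(thresholds)) defaults[[nm]] <- thresholds[[nm]]
  structure(list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
                 locus = locus, assembly_fasta = assembly_fasta,
                 references_fasta = references_fasta,
                 thresholds = defaults),
            class = "run_config")
}

.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, annotate = 202L, classify = 303L,
               subgroup = 404L, tree = 505L, compare = 606L,
               consensus = 707L, summarize = 808L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the annotation pipeline
#'
#' Executes the enabled stages in order, writes every artifact (FASTA,
#' GFF3, TSV, newick, YAML config) under `config$out_dir` with md5
#' checksums, and returns a run report. Identical config and seed give
#' byte-identical artifacts.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`: per-stage counts (genes found,
#'   clusters, subgroups, tree length, consensus size), artifact paths and
#'   checksums, and the thresholds actually used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  note("seed: ", config$seed)
  for (nm in names(th)) {
    note("threshold ", nm, ": ",
         paste(utils::capture.output(utils::str(th[[nm]], give.head = FALSE)),
               collapse = " "))
  }
  artifacts <- character()
  emit <- function(path) artifacts <<- c(artifacts, path)
  report <- list(stages = config$stages, seed = config$seed, thresholds = th)

  sim <- NULL
  assembly <- NULL
  refs <- NULL
  if ("simulate" %in% config$stages) {
    lc <- config$locus %||% locus_config()
    lc$seed <- .stage_seed(config$seed, "simulate")
    note("simulate: seed ", lc$seed, ", n_v_genes ", lc$n_v_genes)
    sim <- generate_locus(lc)
    assembly <- Biostrings::DNAStringSet(stats::setNames(sim$sequence, "locus"))
    refs <- sim$references
    fa <- file.path(config$out_dir, "locus.fasta")
    Biostrings::writeXStringSet(assembly, fa)
    emit(fa)
    truth_map <- locus_map("truth", .truth_models(sim$truth), scaffold = "locus")
    tg <- file.path(config$out_dir, "truth.gff3")
    write_gff3(truth_map, tg)
    emit(tg)
    rf <- file.path(config$out_dir, "references.fasta")
    write_reference_library(refs, rf)
    emit(rf)
    report$simulate <- list(locus_bp = nchar(sim$sequence),
                            planted_genes = nrow(sim$truth),
                            lesions = nrow(sim$lesions))
  } else if (any(c("annotate", "classify", "subgroup") %in% config$stages)) {
    if (is.null(config$assembly_fasta) || is.null(config$references_fasta)) {
      stop("stage annotate: missing input (assembly_fasta/references_fasta)")
    }
    assembly <- read_assembly(config$assembly_fasta)
    refs <- read_reference_library(config$references_fasta)
  }

  map <- NULL
  if ("annotate" %in% config$stages) {
    map <- annotate_locus(assembly, refs, label = "pipeline",
                          min_identity_v = th$min_identity_v)
    note("annotate: ", length(map$genes), " gene models, ",
         length(map$clusters), " clusters")
    report$annotate <- list(genes = length(map$genes),
                            clusters = length(map$clusters),
                            gaps = nrow(map$gaps))
  }
  if ("classify" %in% config$stages) {
    if (is.null(map)) stop("stage classify: missing input (no annotation)")
    map <- classify_locus(map, as.character(assembly[[1L]]))
    labs <- table(vapply(map$genes, function(m) m$functionality, character(1L)))
    note("classify: ", paste(sprintf("%s=%d", names(labs), labs), collapse = " "))
    report$classify <- as.list(labs)
  }
  subgroups <- NULL
  if ("subgroup" %in% config$stages) {
    if (is.null(map)) stop("stage subgroup: missing input (no annotation)")
    vmods <- map$genes[vapply(map$genes, function(m) m$type == "V", logical(1L))]
    if (length(vmods)) {
      subgroups <- cluster_subgroups(vmods, threshold = th$subgroup_threshold)
      seqs <- stats::setNames(vapply(vmods, `[[`, character(1L), "vexon_seq"),
                              vapply(vmods, `[[`, character(1L), "name"))
      subgroups <- assign_nomenclature(subgroups, seqs, refs,
                                       threshold = th$subgroup_threshold)
      # adopt the ortholog-aware names and subgroup ids on the map
      for (i in seq_along(map$genes)) {
        hit <- match(map$genes[[i]]$name, subgroups$gene)
        if (!is.na(hit)) {
          map$genes[[i]]$subgroup <- sub("S\\d+$", "", subgroups$name[hit])
          map$genes[[i]]$name <- subgroups$name[hit]
        }
      }
      st <- file.path(config$out_dir, "subgroups.tsv")
      write_tsv(subgroups, st)
      emit(st)
      note("subgroup: ", length(unique(subgroups$subgroup)), " subgroups")
      report$subgroup <- list(n_subgroups = length(unique(subgroups$subgroup)),
                              n_genes = nrow(subgroups))
    }
  }
  if (!is.null(map)) {
    gff <- file.path(config$out_dir, "annotation.gff3")
    write_gff3(map, gff)
    emit(gff)
    tsv <- file.path(config$out_dir, "annotation.tsv")
    write_tsv(locus_map_table(map), tsv)
    emit(tsv)
  }
  if ("tree" %in% config$stages) {
    if (is.null(map)) stop("stage tree: missing input (no annotation)")
    vmods <- map$genes[vapply(map$genes, function(m) m$type == "V", logical(1L))]
    if (length(vmods) >= 3L) {
      seqs <- stats::setNames(vapply(vmods, `[[`, character(1L), "vexon_seq"),
                              vapply(vmods, `[[`, character(1L), "name"))
      # equal-length ungapped V-exon set: alignment-free columns
      if (length(unique(nchar(seqs))) == 1L) {
        aln <- seqs
      } else {
        L <- min(nchar(seqs))
        aln <- substring(seqs, 1L, L)
      }
      tr <- bootstrap_support(aln, reps = th$bootstrap_reps,
                              seed = .stage_seed(config$seed, "tree"))
      nw <- file.path(config$out_dir, "v_genes.nwk")
      ape::write.tree(tr, nw)
      emit(nw)
      tl <- tree_length(tr)
      note("tree: ", length(tr$tip.label), " tips, length ", sprintf("%.8f", tl))
      report$tree <- list(tips = length(tr$tip.label),
                          tree_length = tl,
                          tree_length_printed = sprintf("%.8f", tl))
    }
  }
  if ("summarize" %in% config$stages && !is.null(map)) {
    smap <- list(pipeline = map)
    summ <- summarize_annotation(smap)
    st <- file.path(config$out_dir, "summary.tsv")
    write_tsv(summ$by_subgroup, st)
    emit(st)
    report$summarize <- list(total = unname(summ$totals[1L]),
                             pseudogenes = unname(summ$pseudogenes[1L]),
                             functional_pct = unname(summ$functional_pct[1L]))
  }
  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  yaml::write_yaml(list(stages = config$stages, seed = config$seed,
                        thresholds = th), cfg_path)
  emit(cfg_path)
  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  report$artifacts <- data.frame(path = artifacts,
                                 md5 = unname(tools::md5sum(artifacts)),
                                 stringsAsFactors = FALSE)
  report$log <- log_lines
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("camlocus pipeline run (seed ", x$seed, ")\n", sep = "")
  for (st in x$stages) {
    if (!is.null(x[[st]])) {
      vals <- vapply(x[[st]], function(v) paste(format(v), collapse = ","),
                     character(1L))
      cat(sprintf("  %-9s %s\n", st,
                  paste(sprintf("%s=%s", names(vals), vals), collapse = " ")))
    }
  }
  cat("  artifacts:", nrow(x$artifacts), "files\n")
  invisible(x)
}

# Truth rows -> gene models (for GFF output and recovery comparisons).
.truth_models <- function(truth) {
  lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    gene_model(name = row$name, type = row$type, exons = truth_exons(row),
               strand = row$strand,
               scaffold = row$scaffold %||% "locus",
               extra = list(functionality = row$label,
                            subgroup = row$subgroup))
  })
}
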