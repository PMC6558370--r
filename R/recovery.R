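# Comparison of an annotation against planted truth: exact-coordinate
# precision/recall per gene type and functionality-label agreement.

#' Compare an annotated locus map against planted truth
#'
#' Detection is scored at exact-coordinate level: a detected model matches
#' a truth record when type, strand and every exon interval coincide.
#' Label agreement is scored over matched V/D/J/C genes against the planted
#' functionality labels.
#'
#' @param map A classified `locus_map`.
#' @param truth Truth data.frame from [generate_locus()] (or remapped by
#'   [fragment_assembly()]).
#' @param types Gene types to score.
#' @return List: `per_type` (data.frame with truth_n, detected_n,
#'   true_positives, precision, recall per type), `precision`, `recall`
#'   (micro-averaged over `types`), `label_matches`, `label_total`,
#'   `label_agreement`, `mismatches` (data.frame of label disagreements,
#'   with the recorded RS scores for post-hoc inspection).
#' @export
recovery_stats <- function(map, truth, types = c("V", "D", "J", "C")) {
  truth <- truth[truth$type %in% types, , drop = FALSE]
  models <- map$genes[vapply(map$genes, function(m) m$type %in% types, logical(1L))]
  key_model <- vapply(models, function(m) {
    paste0(m$type, "/", m$strand, "/",
           paste(sprintf("%d-%d", m$exons[, 1L], m$exons[, 2L]), collapse = ";"))
  }, character(1L))
  key_truth <- vapply(seq_len(nrow(truth)), function(i) {
    paste0(truth$type[i], "/", truth$strand[i], "/", truth$exons[i])
  }, character(1L))
  matched_model <- match(key_model, key_truth)
  per_type <- do.call(rbind, lapply(types, function(tp) {
    t_idx <- truth$type == tp
    m_idx <- vapply(models, function(m) m$type == tp, logical(1L))
    tp_n <- sum(!is.na(matched_model[m_idx]))
    data.frame(type = tp, truth_n = sum(t_idx), detected_n = sum(m_idx),
               true_positives = tp_n,
               precision = if (sum(m_idx)) tp_n / sum(m_idx) else NA_real_,
               recall = if (sum(t_idx)) tp_n / sum(t_idx) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  # label agreement: exact matches, plus best same-type overlap for models
  # whose coordinates shifted (e.g. frameshift lesions move an exon edge)
  label_match <- matched_model
  t_used <- stats::na.omit(matched_model)
  for (mi in which(is.na(label_match))) {
    m <- models[[mi]]
    cand <- which(truth$type == m$type & truth$strand == m$strand &
                  truth$start <= gene_end(m) & truth$end >= gene_start(m) &
                  !(seq_len(nrow(truth)) %in% t_used))
    if (length(cand)) {
      ov <- pmin(truth$end[cand], gene_end(m)) - pmax(truth$start[cand], gene_start(m))
      label_match[mi] <- cand[which.max(ov)]
      t_used <- c(t_used, label_match[mi])
    }
  }
  label_rows <- which(!is.na(label_match))
  mismatches <- list()
  n_match_label <- 0L
  for (mi in label_rows) {
    ti <- label_match[mi]
    got <- models[[mi]]$functionality %||% "nd"
    want <- truth$label[ti]
    if (identical(got, want)) {
      n_match_label <- n_match_label + 1L
    } else {
      rs <- models[[mi]]$rss
      rs_desc <- paste(vapply(names(rs), function(r) {
        sprintf("%s:h%s/n%s", r,
                rs[[r]]$heptamer_mismatches %||% NA,
                rs[[r]]$nonamer_mismatches %||% NA)
      }, character(1L)), collapse = " ")
      mismatches[[length(mismatches) + 1L]] <- data.frame(
        gene = truth$name[ti], type = truth$type[ti], planted = want,
        called = got,
        reasons = paste(models[[mi]]$reasons %||% character(), collapse = ","),
        rs_scores = rs_desc,
        lesion = truth$lesion_mode[ti], stringsAsFactors = FALSE)
    }
  }
  list(per_type = per_type,
       precision = sum(per_type$true_positives) / max(sum(per_type$detected_n), 1L),
       recall = sum(per_type$true_positives) / max(sum(per_type$truth_n), 1L),
       label_matches = n_match_label,
       label_total = length(label_rows),
       truth_total = nrow(truth),
       label_agreement = if (length(label_rows)) n_match_label / length(label_rows)
       else NA_real_,
       # strict agreement: an undetected planted gene counts against it
       label_agreement_vs_truth = if (nrow(truth)) n_match_label / nrow(truth)
       else NA_real_,
       mismatches = if (length(mismatches)) do.call(rbind, mismatches)
       else data.frame())
}
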