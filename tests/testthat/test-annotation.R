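test_that("every planted gene is recovered at exact coordinates", {
  sim <- small_sim()
  map <- small_map()
  rs <- recovery_stats(map, sim$truth)
  expect_equal(rs$precision, 1)
  expect_equal(rs$recall, 1)
  expect_equal(rs$label_agreement, 1)
  # the inverted 3'-most V gene is reported on the minus strand
  v <- map$genes[vapply(map$genes, function(m) m$type == "V", logical(1))]
  strands <- vapply(v, `[[`, character(1), "strand")
  starts <- vapply(v, gene_start, numeric(1))
  expect_equal(strands[which.max(starts)], "-")
})

test_that("find_v_genes returns nothing on gene-free sequence", {
  sim <- small_sim()
  expect_length(find_v_genes(c(bare = random_dna_str(5000, seed = 2)),
                             sim$references), 0L)
})

test_that("find_d_genes pairs inward-facing 12/23 signals", {
  set.seed(21)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  rss12 <- paste0("CACAGTG", random_dna_str(12), "ACAAAAACC")
  rss23 <- paste0("CACAGTG", random_dna_str(23), "ACAAAAACC")
  dseg <- "GGGACAGGGGGCTG"
  s <- paste0(random_dna_str(80), rc(rss12), dseg, rss23, random_dna_str(80))
  d <- find_d_genes(s)
  expect_length(d, 1L)
  expect_equal(unname(d[[1]]$exons[1, ]), c(81L + 28L, 81L + 28L + 13L))

  # a lone signal yields no D candidate
  s2 <- paste0(random_dna_str(80), rss23, random_dna_str(80))
  expect_length(find_d_genes(s2), 0L)

  # two 23-RS sharing one 12-RS: both candidates, flagged
  s3 <- paste0(random_dna_str(80), rc(rss12), "GGGACA", rss23,
               "GGGC", rss23, random_dna_str(60))
  d3 <- find_d_genes(s3, max_d_length = 60)
  expect_gte(length(d3), 2L)
  expect_true(all(vapply(d3, function(m) "overlap_shared_rs" %in% m$flags,
                         logical(1))))
})

test_that("find_j_genes records the FGXG motif state", {
  sim <- small_sim()
  jref <- NULL
  for (r in sim$references$records) if (r$type == "J") jref <- r
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  rss12 <- paste0("CACAGTG", random_dna_str(12), "ACAAAAACC")
  mk_locus <- function(exon) {
    paste0(random_dna_str(100), rc(rss12), exon, "GT", random_dna_str(100))
  }
  set.seed(31)
  j1 <- find_j_genes(mk_locus(jref$seq), sim$references)
  expect_length(j1, 1L)
  expect_false("fgxg_absent" %in% j1[[1]]$flags)
  expect_false(is.na(j1[[1]]$fgxg))

  # replace the planted FGQG codons (9-12) so the protein reads FGLS
  exon_fgls <- paste0(substr(jref$seq, 1, 24), "TTTGGCCTGAGC",
                      substr(jref$seq, 37, 48))
  j2 <- find_j_genes(mk_locus(exon_fgls), sim$references)
  expect_length(j2, 1L)
  expect_true("fgxg_absent" %in% j2[[1]]$flags)

  # planted J count per cluster matches the configuration
  map <- small_map()
  expect_equal(vapply(map$clusters, function(cl) length(cl$j_genes), integer(1)),
               c(6L, 7L))
})

test_that("find_c_genes projects the 4-exon structure and translation", {
  sim <- small_sim()
  map <- small_map()
  cs <- map$genes[vapply(map$genes, function(m) m$type == "C", logical(1))]
  expect_length(cs, 2L)
  for (cm in cs) {
    expect_equal(nrow(cm$exons), 4L)
    truth_row <- sim$truth[sim$truth$name == cm$name, ]
    expect_equal(unname(cm$exons), unname(truth_exons(truth_row)))
    # spliced product: 178 residues plus the terminal stop
    expect_equal(nchar(cm$protein), 179L)
    expect_equal(substr(cm$protein, 179, 179), "*")
    expect_false(grepl("*", substr(cm$protein, 1, 178), fixed = TRUE))
  }
  # C gene running past the scaffold end is flagged incomplete
  trunc_at <- gene_start(cs[[1]]) + 350L
  trunc <- substr(sim$sequence, 1, trunc_at)
  c_tr <- find_c_genes(c(sc = trunc), sim$references)
  expect_true(length(c_tr) >= 1L)
  expect_true("incomplete" %in% c_tr[[length(c_tr)]]$flags)
})

test_that("assemble_clusters groups D, J+, C runs and flags losses", {
  map <- small_map()
  expect_length(map$clusters, 2L)
  expect_true(all(vapply(map$clusters, `[[`, logical(1), "complete")))
  expect_length(assemble_clusters(list()), 0L)

  # masking the second C gene with N leaves cluster 2 incomplete
  sim <- small_sim()
  c2 <- sim$truth[sim$truth$name == "TRBC2", ]
  s2 <- sim$sequence
  substr(s2, c2$start, c2$end) <- strrep("N", c2$end - c2$start + 1)
  map2 <- annotate_locus(s2, sim$references, label = "masked",
                         scan_duplicates = FALSE)
  expect_length(map2$clusters, 2L)
  expect_false(map2$clusters[[2]]$complete)
})

test_that("duplicated regions containing genes are flagged, 3' copy excluded", {
  sim <- small_sim()
  tr <- sim$truth
  j4 <- tr[tr$name == "TRBJ1-4", ]
  block <- substr(sim$sequence, j4$start - 120, j4$start + 194)  # 315 bp
  s <- paste0(sim$sequence, block, random_dna_str(500, seed = 4))
  map <- annotate_locus(s, sim$references, label = "dup")
  art <- map$artifacts
  expect_gte(nrow(art), 1L)
  expect_true(any(art$length >= 315L))
  dup_genes <- Filter(function(m) "duplicate_region" %in% m$flags, map$genes)
  expect_gte(length(dup_genes), 2L)
  excl <- Filter(function(m) "exclude_candidate" %in% m$flags, map$genes)
  expect_gte(length(excl), 1L)
  # the exclude candidate is the 3'-most copy
  expect_gte(min(vapply(excl, gene_start, numeric(1))), nchar(sim$sequence))

  # no duplicates in the clean locus
  clean <- flag_duplicate_regions(small_map(), sim$sequence)
  expect_equal(nrow(clean), 0L)
})

test_that("maximal exact repeats match a substring-occurrence oracle", {
  set.seed(17)
  base <- random_dna_str(1500)
  rep_block <- random_dna_str(260)
  s <- paste0(substr(base, 1, 500), rep_block, substr(base, 501, 1000),
              rep_block, substr(base, 1001, 1500))
  # gene models inside both copies so the filter keeps the repeat
  g1 <- gene_model("g1", "TRY", cbind(520, 700), scaffold = "s")
  g2 <- gene_model("g2", "TRY", cbind(1280, 1460), scaffold = "s")
  res <- flag_duplicate_regions(list(g1, g2), s, min_len = 200)
  expect_equal(nrow(res), 1L)
  # oracle: every min_len-window of copy 1 recurs at the reported offset
  off <- res$start2[1] - res$start1[1]
  for (p in seq(res$start1[1], res$end1[1] - 199, by = 37)) {
    expect_identical(substr(s, p, p + 199), substr(s, p + off, p + off + 199))
  }
  # maximality: extending one base in either direction breaks identity
  expect_false(substr(s, res$start1[1] - 1, res$start1[1] - 1) ==
                 substr(s, res$start2[1] - 1, res$start2[1] - 1))
  expect_false(substr(s, res$end1[1] + 1, res$end1[1] + 1) ==
                 substr(s, res$end2[1] + 1, res$end2[1] + 1))
})

test_that("rs_defect lesions do not break gene detection", {
  cfg <- locus_config(n_v_genes = 6, n_subgroups = 6, n_djc_clusters = 1,
                      pseudogene_rate = 1,
                      lesion_mix = c(stop = 0, frameshift = 0, splice = 0,
                                     rs_defect = 1),
                      v_spacing = c(600, 900), seed = 12)
  sim <- generate_locus(cfg)
  map <- annotate_locus(sim$sequence, sim$references, label = "orf",
                        scan_duplicates = FALSE)
  map <- classify_locus(map, sim$sequence)
  rs <- recovery_stats(map, sim$truth)
  expect_equal(rs$recall, 1)
  v_labels <- vapply(Filter(function(m) m$type == "V", map$genes),
                     `[[`, character(1), "functionality")
  expect_true(all(v_labels == "ORF"))
})
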