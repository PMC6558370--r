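test_that("a flanks-only configuration yields just the two marker genes", {
  cfg <- locus_config(n_v_genes = 0, n_djc_clusters = 0, n_try_genes = 0,
                      seed = 9)
  sim <- generate_locus(cfg)
  expect_equal(nrow(sim$truth), 2L)
  expect_setequal(sim$truth$type, "FLANK")
})

test_that("generation is byte-identical for a fixed seed", {
  cfg <- locus_config(n_v_genes = 5, n_subgroups = 4, n_djc_clusters = 1,
                      n_try_genes = 2, pseudogene_rate = 0.3,
                      v_spacing = c(500, 700), seed = 77)
  a <- generate_locus(cfg)
  b <- generate_locus(cfg)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$truth, b$truth)
  expect_identical(reference_library(cfg)$records, a$references$records)
})

test_that("planted truth slices carry the expected signals", {
  sim <- small_sim()
  s <- sim$sequence
  vs <- sim$truth[sim$truth$type == "V" & sim$truth$strand == "+", ]
  for (i in seq_len(nrow(vs))) {
    ex <- truth_exons(vs[i, ])
    # donor GT after the leader exon, acceptor AG before the V-exon
    expect_equal(substr(s, ex[1, 2] + 1, ex[1, 2] + 2), "GT")
    expect_equal(substr(s, ex[2, 1] - 2, ex[2, 1] - 1), "AG")
    # planted 23-RS heptamer abuts the V-exon 3' end (at most 1 mismatch)
    hep <- substr(s, ex[2, 2] + 1, ex[2, 2] + 7)
    expect_lte(sum(strsplit(hep, "")[[1]] !=
                     strsplit("CACAGTG", "")[[1]]), 1L)
  }
  # the 3'-most V gene is inverted
  v_all <- sim$truth[sim$truth$type == "V", ]
  expect_equal(v_all$strand[which.max(v_all$start)], "-")
})

test_that("subgroup identity structure brackets the 75% threshold", {
  cfg <- locus_config(n_v_genes = 33, n_subgroups = 26,
                      pseudogene_rate = 0, v_spacing = c(700, 1000),
                      seed = 101)
  sim <- generate_locus(cfg)
  vs <- sim$truth[sim$truth$type == "V", ]
  expect_equal(nrow(vs), 33L)
  expect_true(all(vs$label == "F"))
  get_vexon <- function(row) {
    ex <- truth_exons(row)
    iv <- if (row$strand == "+") ex[2, ] else ex[1, ]
    sub <- substr(sim$sequence, iv[1], iv[2])
    if (row$strand == "-")
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    sub
  }
  seqs <- vapply(seq_len(nrow(vs)), function(i) get_vexon(vs[i, ]), character(1))
  names(seqs) <- vs$name
  idm <- identity_matrix(seqs)
  same_sg <- outer(vs$subgroup, vs$subgroup, "==")
  diag(same_sg) <- NA
  expect_gt(min(idm[same_sg & !is.na(same_sg)]), 75)
  expect_lt(max(idm[!same_sg & !is.na(same_sg)]), 75)
})

test_that("intergenic GC tracks the configured target", {
  cfg <- locus_config(n_v_genes = 20, n_subgroups = 18, pseudogene_rate = 0,
                      v_spacing = c(5000, 6000), seed = 55)
  sim <- generate_locus(cfg)
  expect_gte(nchar(sim$sequence), 1e5)
  covered <- rep(FALSE, nchar(sim$sequence))
  for (i in seq_len(nrow(sim$truth))) {
    covered[sim$truth$start[i]:sim$truth$end[i]] <- TRUE
  }
  inter <- strsplit(sim$sequence, "")[[1]][!covered]
  gc <- sum(inter %in% c("G", "C")) / length(inter)
  expect_lt(abs(gc - cfg$gc_target), 0.02)
})

test_that("pseudogenize plants exactly the requested lesion", {
  set.seed(8)
  exon <- paste0("ATG", paste(rep("GCT", 20), collapse = ""))  # no stops
  les <- pseudogenize(exon, "stop")
  prot <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(les$seq))), "")[[1]]
  expect_equal(sum(prot == "*"), 1L)

  donor_seq <- paste0(exon, "GTAAGT")
  les2 <- pseudogenize(donor_seq, "splice",
                       elements = list(donor = c(nchar(exon) + 1, nchar(exon) + 2)))
  expect_false(substr(les2$seq, nchar(exon) + 1, nchar(exon) + 2) == "GT")

  les3 <- pseudogenize(exon, "frameshift")
  expect_equal(nchar(les3$seq), nchar(exon) - 1L)
  # translation differs downstream of the lesion (oracle: translate both)
  tr_before <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(exon, 1, 60))))
  tr_after <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(les3$seq, 1, 60))))
  expect_false(tr_before == tr_after)

  rs <- paste0("CACAGTG", random_dna_str(23), "ACAAAAACC")
  les4 <- pseudogenize(rs, "rs_defect", elements = list(heptamer = c(1, 7)))
  expect_gte(sum(strsplit(substr(les4$seq, 1, 7), "")[[1]] !=
                   strsplit("CACAGTG", "")[[1]]), 3L)

  expect_error(pseudogenize(exon, "splice", elements = list(exon = c(1, 63))),
               "target absent")
})

test_that("fragmentation policies behave and stitching inverts overlap mode", {
  sim <- small_sim()
  fr1 <- fragment_assembly(sim, n_scaffolds = 1)
  expect_equal(unname(fr1$scaffolds[1]), sim$sequence)
  expect_identical(fr1$truth$exons, sim$truth$exons)

  fr <- fragment_assembly(sim, n_scaffolds = 3, overlap = 200,
                          gap_policy = "overlap")
  lay <- stitch_scaffolds(fr$scaffolds, min_overlap = 150)
  expect_equal(length(lay$chains), 1L)
  expect_equal(lay$chains[[1]]$scaffold, names(fr$scaffolds))
  expect_equal(lay$merged_lengths[1], nchar(sim$sequence))
  expect_identical(merge_chain(lay, 1), sim$sequence)

  fr2 <- fragment_assembly(sim, n_scaffolds = 3, overlap = 100,
                           gap_policy = "split_gene")
  expect_false(is.na(fr2$split_gene))
  expect_equal(fr2$truth$label[fr2$truth$name == fr2$split_gene], "nd")
  others <- fr2$truth[fr2$truth$name != fr2$split_gene, ]
  expect_identical(others$label,
                   sim$truth$label[match(others$name, sim$truth$name)])
})

test_that("remapped truth coordinates still point at the planted genes", {
  sim <- small_sim()
  fr <- fragment_assembly(sim, n_scaffolds = 3, overlap = 200,
                          gap_policy = "overlap")
  for (i in seq_len(nrow(fr$truth))) {
    row <- fr$truth[i, ]
    orig <- sim$truth[sim$truth$name == row$name, ]
    sc <- fr$scaffolds[[row$scaffold]]
    expect_identical(substr(sc, row$start, row$end),
                     substr(sim$sequence, orig$start, orig$end))
  }
})
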