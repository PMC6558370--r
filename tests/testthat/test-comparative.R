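test_that("self-comparison yields one full-length 100% segment", {
  s <- random_dna_str(10000, seed = 61)
  seg <- pip_segments(s, s)
  main <- seg[seg$strand == "+" & seg$qstart == 1, ]
  expect_equal(nrow(main), 1L)
  expect_equal(main$qend, 10000L)
  expect_equal(main$tstart, 1L)
  expect_equal(main$pct_id, 100)
})

test_that("self-comparison covers every non-N position", {
  set.seed(62)
  s <- paste0(random_dna_str(3000), strrep("N", 400), random_dna_str(3000))
  seg <- pip_segments(s, s)
  plus <- seg[seg$strand == "+" & seg$tstart == seg$qstart, ]
  covered <- rep(FALSE, nchar(s))
  for (i in seq_len(nrow(plus))) covered[plus$qstart[i]:plus$qend[i]] <- TRUE
  non_n <- strsplit(s, "")[[1]] != "N"
  expect_true(all(covered[non_n]))
})

test_that("a shared diverged block is found near its planted identity", {
  set.seed(63)
  block <- random_dna_str(500)
  mut <- strsplit(block, "")[[1]]
  hit <- sample(500, 25)  # 95% identity
  mut[hit] <- vapply(mut[hit], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  q <- paste0(random_dna_str(2000), block, random_dna_str(2000))
  t_ <- paste0(random_dna_str(1500), paste(mut, collapse = ""), random_dna_str(2500))
  seg <- pip_segments(q, t_, min_len = 200, min_identity = 80)
  ov <- seg[seg$qstart <= 2200 & seg$qend >= 2300, ]
  expect_gte(nrow(ov), 1L)
  expect_lt(abs(ov$pct_id[1] - 95), 2)
})

test_that("an N gap in the target splits the homology line", {
  set.seed(64)
  s <- random_dna_str(6000)
  gapped <- paste0(substr(s, 1, 2500), strrep("N", 1000), substr(s, 3501, 6000))
  seg <- pip_segments(s, gapped, min_len = 200)
  expect_gte(nrow(seg), 2L)
  expect_true(any(seg$qend <= 2600) && any(seg$qstart >= 3400))
})

test_that("gc_profile reports per-window and global GC, NA for all-N", {
  expect_true(all(gc_profile(strrep("GC", 500), window = 100)$gc == 1))
  p <- gc_profile(strrep("ATGC", 250), window = 100)
  expect_equal(attr(p, "global_gc"), 0.5)
  pn <- gc_profile(paste0(strrep("A", 100), strrep("N", 100)), window = 100)
  expect_true(is.na(pn$gc[2]))
  expect_equal(pn$gc[1], 0)
})

test_that("summaries from locus maps equal the lesion-ledger tallies", {
  cfg <- locus_config(n_v_genes = 8, n_subgroups = 8, n_djc_clusters = 1,
                      pseudogene_rate = 0.5, v_spacing = c(600, 900),
                      seed = 71)
  sim <- generate_locus(cfg)
  map <- annotate_locus(sim$sequence, sim$references, label = "sum",
                        scan_duplicates = FALSE)
  map <- classify_locus(map, sim$sequence)
  s <- summarize_annotation(list(synth = map))
  truth_v <- sim$truth[sim$truth$type == "V", ]
  expect_equal(unname(s$totals["synth"]), nrow(truth_v))
  expect_equal(unname(s$pseudogenes["synth"]), sum(truth_v$label == "P"))
  expect_equal(unname(s$functional_pct["synth"]),
               round(100 * sum(truth_v$label %in% c("F", "ORF")) / nrow(truth_v)))
})

test_that("an empty map summarizes to zeros", {
  m <- locus_map("empty", list())
  s <- summarize_annotation(list(empty = m))
  expect_true(is.data.frame(s$by_subgroup))
  expect_equal(sum(s$by_subgroup$n), 0)
})

test_that("the consensus rule is permutation-invariant and 2-of-3 stable", {
  fx <- read_three_species_table()
  c1 <- consensus_locus_map(fx)
  fx2 <- fx[, c("gene", "subgroup", "ferus", "bactrianus", "dromedarius")]
  c2 <- consensus_locus_map(fx2)
  expect_equal(setNames(c2$consensus$label, c2$consensus$gene),
               setNames(c1$consensus$label, c1$consensus$gene))

  # flipping one species cannot change a consensus backed by the other two
  fx3 <- fx
  stopifnot(fx3$ferus[fx3$gene == "TRBV2"] == "F",
            fx3$bactrianus[fx3$gene == "TRBV2"] == "F")
  fx3$dromedarius[fx3$gene == "TRBV2"] <- "P"
  c3 <- consensus_locus_map(fx3)
  expect_equal(c3$consensus$label[c3$consensus$gene == "TRBV2"], "F")
  expect_false(is.na(c3$consensus$note[c3$consensus$gene == "TRBV2"]))

  # a gene present in one species only is excluded but listed
  fx4 <- fx
  fx4$ferus[fx4$gene == "TRBV2"] <- "-"
  fx4$bactrianus[fx4$gene == "TRBV2"] <- "-"
  c4 <- consensus_locus_map(fx4)
  expect_false("TRBV2" %in% c4$consensus$gene)
  expect_true("TRBV2" %in% c4$unconfirmed$gene)

  expect_error(consensus_locus_map(fx[, 1:4]), "exactly 3")
})

test_that("summary totals equal column sums for every species", {
  s <- summarize_annotation(read_subgroup_table())
  for (sp in names(s$totals)) {
    expect_equal(unname(s$totals[sp]),
                 sum(s$by_subgroup$n[s$by_subgroup$species == sp]))
  }
})
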