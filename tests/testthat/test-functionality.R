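# Lesion a specific planted V gene in the small locus and re-classify.
lesioned_call <- function(edit) {
  sim <- small_sim()
  v <- sim$truth[sim$truth$type == "V" & sim$truth$strand == "+", ][2, ]
  ex <- truth_exons(v)
  s <- edit(sim$sequence, ex)
  map <- annotate_locus(s, sim$references, label = "les",
                        scan_duplicates = FALSE)
  map <- classify_locus(map, s)
  hit <- Filter(function(m) m$type == "V" && gene_start(m) >= ex[1, 1] - 5 &&
                  gene_end(m) <= ex[2, 2] + 5, map$genes)
  expect_length(hit, 1L)
  list(label = hit[[1]]$functionality, reasons = hit[[1]]$reasons)
}

test_that("an in-frame stop in the V-exon gives P with STOP_CODON", {
  call <- lesioned_call(function(s, ex) {
    pos <- ex[2, 1] + 30  # codon 11 of the V-exon (frame 0)
    substr(s, pos, pos + 2) <- "TAA"
    s
  })
  expect_equal(call$label, "P")
  expect_true("STOP_CODON" %in% call$reasons)
})

test_that("a broken donor site gives P with SPLICE_DEFECT", {
  call <- lesioned_call(function(s, ex) {
    substr(s, ex[1, 2] + 1, ex[1, 2] + 1) <- "A"  # GT -> AT
    s
  })
  expect_equal(call$label, "P")
  expect_true("SPLICE_DEFECT" %in% call$reasons)
})

test_that("an intact frame with anomalous V-exon length is ORF", {
  sim <- small_sim()
  map <- small_map()
  v <- Filter(function(m) m$type == "V" && m$strand == "+", map$genes)[[2]]
  narrow <- default_expected_lengths()
  narrow$V <- c(200L, 290L)  # the planted 294 bp V-exon is now anomalous
  call <- classify_gene(v, sim$sequence, expected_lengths = narrow)
  expect_equal(call$label, "ORF")
  expect_true("BAD_LENGTH" %in% call$reasons)
})

test_that("a gene split by an assembly gap is nd with INCOMPLETE", {
  call <- lesioned_call(function(s, ex) {
    substr(s, ex[2, 1] + 50, ex[2, 1] + 80) <- strrep("N", 31)
    s
  })
  expect_equal(call$label, "nd")
  expect_equal(call$reasons, "INCOMPLETE")
})

test_that("lesion-free planted genes are F with empty reasons", {
  sim <- small_sim()
  map <- small_map()
  for (m in map$genes) {
    if (m$type %in% c("V", "D", "J", "C")) {
      expect_equal(m$functionality, "F")
      expect_length(m$reasons, 0L)
    }
  }
})

test_that("classification is deterministic and respects severity order", {
  sim <- small_sim()
  map <- small_map()
  v <- Filter(function(m) m$type == "V" && m$strand == "+", map$genes)[[1]]
  c1 <- classify_gene(v, sim$sequence)
  c2 <- classify_gene(v, sim$sequence)
  expect_identical(c1, c2)

  # an ORF-level defect plus a stop codon moves the label to P, not back
  s <- sim$sequence
  ex <- v$exons
  substr(s, ex[2, 1] + 30, ex[2, 1] + 32) <- "TAA"
  v_orf <- v
  v_orf$rss$v_rs$heptamer_mismatches <- 3L  # ORF-level RS defect
  call <- classify_gene(v_orf, s)
  expect_equal(call$label, "P")
  expect_true(all(c("STOP_CODON", "RS_DEFECT") %in% call$reasons))

  # a gap overlap dominates everything
  substr(s, ex[2, 1] + 60, ex[2, 1] + 90) <- strrep("N", 31)
  call_nd <- classify_gene(v_orf, s)
  expect_equal(call_nd$label, "nd")
})

test_that("check_fgxg finds the first F-G-x-G and misses FGLS", {
  expect_equal(check_fgxg("NTEAFFGQGTRLTVL"), 6L)
  expect_true(is.na(check_fgxg("NTEAFFGLSTRLTVL")))
  expect_equal(check_fgxg("FGAG"), 1L)
  # sliding 4-mer oracle on random proteins
  set.seed(23)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:20) {
    p <- paste(sample(aas, 40, TRUE), collapse = "")
    oracle <- NA_integer_
    for (i in 1:37) {
      w <- substr(p, i, i + 3)
      if (substr(w, 1, 2) == "FG" && substr(w, 4, 4) == "G") {
        oracle <- i
        break
      }
    }
    expect_identical(check_fgxg(p), oracle)
  }
})

test_that("each lesion mode recovers its planted label exactly", {
  modes <- list(stop = "P", frameshift = "P", splice = "P", rs_defect = "ORF")
  for (mode in names(modes)) {
    mix <- c(stop = 0, frameshift = 0, splice = 0, rs_defect = 0)
    mix[mode] <- 1
    cfg <- locus_config(n_v_genes = 5, n_subgroups = 5, n_djc_clusters = 1,
                        n_try_genes = 0, pseudogene_rate = 1, lesion_mix = mix,
                        v_spacing = c(600, 900), seed = 61)
    sim <- generate_locus(cfg)
    map <- annotate_locus(sim$sequence, sim$references, label = mode,
                          scan_duplicates = FALSE)
    map <- classify_locus(map, sim$sequence)
    rs <- recovery_stats(map, sim$truth)
    expect_equal(rs$label_agreement, 1,
                 label = paste("label agreement for mode", mode))
    expect_true(all(sim$lesions$label == modes[[mode]]))
  }
})
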