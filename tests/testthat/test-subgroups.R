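test_that("pairwise identity matches hand counts and the DP oracle", {
  set.seed(33)
  a <- random_dna_str(300)
  expect_equal(pairwise_identity(a, a), 100)

  b20 <- random_dna_str(20)
  mut <- strsplit(b20, "")[[1]]
  for (p in c(3, 8, 13, 18)) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  expect_equal(pairwise_identity(b20, paste(mut, collapse = "")), 80)

  # one internal 3 bp deletion: identity over aligned columns, < 100
  s <- random_dna_str(60)
  del <- paste0(substr(s, 1, 30), substr(s, 34, 60))
  got <- pairwise_identity(s, del)
  expect_lt(got, 100)
  expect_equal(got, oracle_global_identity(s, del))

  # DP oracle agreement on random short pairs with indels
  for (rep in 1:8) {
    x <- random_dna_str(40)
    y <- strsplit(random_dna_str(40), "")[[1]]
    xx <- strsplit(x, "")[[1]]
    take <- runif(40) > 0.15
    y <- paste(ifelse(runif(40) > 0.2, xx, y)[take], collapse = "")
    expect_equal(pairwise_identity(x, y), oracle_global_identity(x, y),
                 tolerance = 1e-9)
  }
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("pairwise identity is symmetric", {
  set.seed(34)
  for (rep in 1:5) {
    a <- random_dna_str(50 + rep)
    b <- random_dna_str(60)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("single-linkage clustering follows the stated identity graph", {
  seqs <- c(A = "ACGT", B = "ACGT", C = "ACGT", D = "ACGT")  # placeholders
  idm <- matrix(50, 4, 4, dimnames = list(names(seqs), names(seqs)))
  diag(idm) <- 100
  idm["A", "B"] <- idm["B", "A"] <- 90
  idm["B", "C"] <- idm["C", "B"] <- 80
  idm["A", "C"] <- idm["C", "A"] <- 60
  asg <- cluster_subgroups(seqs, threshold = 75, idm = idm)
  sg <- setNames(asg$subgroup, asg$gene)
  expect_equal(sg[["A"]], sg[["B"]])
  expect_equal(sg[["B"]], sg[["C"]])
  expect_false(sg[["D"]] == sg[["A"]])

  # identity exactly at the threshold does not merge (strict >)
  idm2 <- matrix(50, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  diag(idm2) <- 100
  idm2["X", "Y"] <- idm2["Y", "X"] <- 75
  asg2 <- cluster_subgroups(c(X = "ACGT", Y = "ACGT"), threshold = 75, idm = idm2)
  expect_equal(length(unique(asg2$subgroup)), 2L)
})

test_that("planted subgroups are recovered exactly", {
  cfg <- locus_config(n_v_genes = 33, n_subgroups = 26, pseudogene_rate = 0,
                      v_spacing = c(700, 1000), seed = 101)
  sim <- generate_locus(cfg)
  map <- annotate_locus(sim$sequence, sim$references, label = "sg",
                        scan_duplicates = FALSE)
  vm <- Filter(function(m) m$type == "V", map$genes)
  asg <- cluster_subgroups(vm)
  expect_equal(length(unique(asg$subgroup)), 26L)
  # partition agrees with the planted membership (match genes by start)
  truth_v <- sim$truth[sim$truth$type == "V", ]
  starts <- vapply(vm, gene_start, numeric(1))
  planted <- truth_v$subgroup[match(starts[match(asg$gene,
    vapply(vm, `[[`, character(1), "name"))], truth_v$start)]
  expect_false(any(is.na(planted)))
  # one-to-one correspondence between inferred and planted subgroups
  expect_equal(length(unique(paste(asg$subgroup, planted))), 26L)
})

test_that("clustering is invariant under input order permutation", {
  sim <- small_sim()
  map <- small_map()
  vm <- Filter(function(m) m$type == "V", map$genes)
  asg1 <- cluster_subgroups(vm)
  set.seed(9)
  asg2 <- cluster_subgroups(vm[sample(seq_along(vm))])
  expect_equal(asg1[order(asg1$gene), ], asg2[order(asg2$gene), ],
               ignore_attr = TRUE)
})

test_that("raising the threshold never merges subgroups", {
  map <- small_map()
  vm <- Filter(function(m) m$type == "V", map$genes)
  idm <- identity_matrix(setNames(
    vapply(vm, `[[`, character(1), "vexon_seq"),
    vapply(vm, `[[`, character(1), "name")))
  counts <- vapply(c(40, 60, 75, 85, 95, 99.5), function(th) {
    length(unique(cluster_subgroups(vm, threshold = th, idm = idm)$subgroup))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("nomenclature inherits reference subgroup names", {
  sim <- small_sim()
  map <- small_map()
  vm <- Filter(function(m) m$type == "V", map$genes)
  asg <- cluster_subgroups(vm)
  seqs <- setNames(vapply(vm, `[[`, character(1), "vexon_seq"),
                   vapply(vm, `[[`, character(1), "name"))
  named <- assign_nomenclature(asg, seqs, sim$references)
  # planted names recovered 100%: compare by coordinates
  starts <- vapply(vm, gene_start, numeric(1))[match(named$gene, names(seqs))]
  truth_v <- sim$truth[sim$truth$type == "V", ]
  expect_equal(named$name, truth_v$name[match(starts, truth_v$start)])
  # multimember subgroups use S-numbering in genomic order; singles are bare
  multi <- named$name[grepl("S\\d+$", named$name)]
  expect_true(all(table(sub("S\\d+$", "", multi)) > 1))

  # two subgroups claiming the same reference name is an error
  refs1 <- sim$references
  v1 <- Filter(function(r) r$type == "V", refs1$records)[[1]]
  solo <- list(records = c(list(v1),
                           Filter(function(r) r$type != "V", refs1$records)))
  class(solo) <- "reference_library"
  idm <- attr(asg, "identity_matrix")
  expect_error(assign_nomenclature(asg, seqs, solo, threshold = 10),
               "claim")
})
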