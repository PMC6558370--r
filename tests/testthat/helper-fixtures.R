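# Shared fixtures, built once per test run. Everything is generated in
# code; no binary data.

.fixture_cache <- new.env(parent = emptyenv())

# A small lesion-free locus used across annotation/functionality tests.
small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- locus_config(n_v_genes = 8L, n_subgroups = 6L, n_djc_clusters = 2L,
                        j_per_cluster = c(6L, 7L), n_try_genes = 3L,
                        pseudogene_rate = 0, v_spacing = c(700, 1000),
                        seed = 42L)
    .fixture_cache$small <- generate_locus(cfg)
  }
  .fixture_cache$small
}

small_map <- function() {
  if (is.null(.fixture_cache$small_map)) {
    sim <- small_sim()
    map <- annotate_locus(sim$sequence, sim$references, label = "small")
    .fixture_cache$small_map <- classify_locus(map, sim$sequence)
  }
  .fixture_cache$small_map
}

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

random_dna_str <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force affine-gap global aligner (oracle for pairwise_identity on
# short strings): gap of length L costs open + L * extend, first gap base
# included via open = 4, extend = 1 to mirror the package scheme.
oracle_global_identity <- function(a, b, match = 1, mismatch = -1,
                                   open = 4, extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  for (i in 1:n) X[i + 1, 1] <- -(open + extend * i)
  for (j in 1:m) Y[1, j + 1] <- -(open + extend * j)
  for (i in 1:n) for (j in 1:m) {
    s <- if (A[i] == B[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend, X[i, j + 1] - extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend, Y[i + 1, j] - extend)
  }
  # traceback for aligned strings
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  i <- n; j <- m
  pa <- character(); pb <- character()
  while (i > 0 || j > 0) {
    if (state == 1) {
      pa <- c(A[i], pa); pb <- c(B[j], pb)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1; j <- j - 1
      state <- which.max(prev)
    } else if (state == 2) {
      pa <- c(A[i], pa); pb <- c("-", pb)
      from_m <- M[i, j + 1] - open - extend
      from_x <- X[i, j + 1] - extend
      state <- if (from_m >= from_x) 1 else 2
      i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(B[j], pb)
      from_m <- M[i + 1, j] - open - extend
      from_y <- Y[i + 1, j] - extend
      state <- if (from_m >= from_y) 1 else 3
      j <- j - 1
    }
    if (i == 0 && j > 0) state <- 3
    if (j == 0 && i > 0) state <- 2
  }
  ga <- pa == "-"; gb <- pb == "-"
  L <- length(pa)
  lead_run <- function(g) if (g[1]) rle(g)$lengths[1] else 0L
  lead <- max(lead_run(ga), lead_run(gb))
  trail <- max(lead_run(rev(ga)), lead_run(rev(gb)))
  cols <- seq_len(L)
  cols <- cols[cols > lead & cols <= L - trail]
  100 * sum(pa[cols] == pb[cols] & !ga[cols]) / length(cols)
}
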