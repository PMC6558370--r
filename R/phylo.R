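# Distance phylogenetics: p-distance under complete gap deletion,
# neighbor-joining (Saitou-Nei agglomeration with the Q criterion), and
# nonparametric bootstrap support. Trees are returned as ape "phylo"
# objects so newick round-trips and plotting come for free; the algorithms
# themselves are implemented here (ape::nj serves as an independent
# cross-check in the test suite, never as the implementation).

#' p-distance matrix under complete gap deletion
#'
#' Every alignment column containing `-` or `N` in any row is removed
#' globally; the distance between two rows is the proportion of remaining
#' columns at which they differ (base differences per site).
#'
#' @param aln Named character vector of equal-length aligned sequences, or
#'   a character matrix (rows = taxa).
#' @return Symmetric numeric matrix with zero diagonal; attribute
#'   `retained_positions` gives the number of columns kept.
#' @export
p_distance_matrix <- function(aln) {
  m <- .aln_matrix(aln)
  keep <- colSums(m == "-" | m == "N") == 0L
  if (!any(keep)) {
    stop("complete deletion removed all ", ncol(m), " columns; 0 retained")
  }
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ]) / ncol(m)
    }
  }
  attr(d, "retained_positions") <- ncol(m)
  d
}

.aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    stopifnot(!is.null(rownames(aln)))
    return(aln)
  }
  stopifnot(is.character(aln), !is.null(names(aln)), length(aln) >= 2L)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) stop("aligned rows differ in length")
  m <- do.call(rbind, lapply(aln, function(s) seq_chars(toupper(s))))
  rownames(m) <- names(aln)
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q-matrix selection criterion and the
#' standard branch-length formulas. Ties in Q are broken deterministically
#' (lexicographically smallest pair of cluster labels). Negative branch
#' lengths are clamped to zero with the deficit moved to the sister branch
#' (so the joined pair's path length is preserved). The tree is unrooted
#' (basal trichotomy).
#'
#' @param dm Symmetric distance matrix with dimnames.
#' @return An [ape::phylo] tree; attribute `tree_length` is the sum of all
#'   branch lengths.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric")
  }
  n0 <- nrow(dm)
  stopifnot(n0 >= 3L, !is.null(rownames(dm)))
  labels <- rownames(dm)
  # each active cluster carries its newick subtree string
  nwk <- stats::setNames(labels, labels)
  d <- dm
  fmt <- function(x) sprintf("%.10g", x)
  total_len <- 0
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_lab <- apply(cand, 1L, function(ix) {
      paste(sort(rownames(d)[ix]), collapse = "\r")
    })
    pick <- cand[order(pair_lab)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- d[i, j]; vi <- 0 }
    if (vj < 0) { vi <- d[i, j]; vj <- 0 }
    total_len <- total_len + vi + vj
    new_lab <- paste0("(", rownames(d)[i], ",", rownames(d)[j], ")")
    new_nwk <- paste0("(", nwk[[rownames(d)[i]]], ":", fmt(vi), ",",
                      nwk[[rownames(d)[j]]], ":", fmt(vj), ")")
    duk <- (d[i, -c(i, j)] + d[j, -c(i, j)] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- d[keep, keep, drop = FALSE]
    d2 <- rbind(cbind(d2, duk), c(duk, 0))
    rownames(d2)[n - 1L] <- colnames(d2)[n - 1L] <- new_lab
    nwk[[new_lab]] <- new_nwk
    d <- d2
  }
  labs3 <- rownames(d)
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  total_len <- total_len + sum(v)
  newick <- paste0("(", nwk[[labs3[1L]]], ":", fmt(v[1L]), ",",
                   nwk[[labs3[2L]]], ":", fmt(v[2L]), ",",
                   nwk[[labs3[3L]]], ":", fmt(v[3L]), ");")
  tree <- ape::read.tree(text = newick)
  attr(tree, "tree_length") <- total_len
  tree
}

#' Total branch length of a tree
#' @param tree An `ape::phylo`.
#' @return Sum of branch lengths (printed to 8+ decimals by
#'   [format_tree_length()]).
#' @export
tree_length <- function(tree) sum(tree$edge.length)

#' @rdname tree_length
#' @export
format_tree_length <- function(tree) sprintf("%.8f", tree_length(tree))

# Unrooted splits of a tree: for each internal edge, the tip set on the far
# side from tip 1, canonicalized as a sorted, comma-joined label string.
.tree_splits <- function(tree) {
  nt <- length(tree$tip.label)
  if (is.null(tree$edge)) return(character())
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    out <- integer()
    for (k in kids) {
      if (k <= nt) out <- c(out, k) else out <- c(out, desc(k))
    }
    out
  }
  splits <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= nt) next
    tips <- desc(child)
    side <- sort(tree$tip.label[tips])
    other <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2L || length(other) < 2L) next  # trivial split
    anchor <- min(tree$tip.label)
    key <- if (anchor %in% side) paste(other, collapse = ",")
    else paste(side, collapse = ",")
    splits[as.character(child)] <- key
  }
  splits
}

#' Compare two unrooted tree topologies
#' @param a,b `ape::phylo` trees over the same tips.
#' @return TRUE if the non-trivial split sets coincide.
#' @export
same_topology <- function(a, b) {
  setequal(unname(.tree_splits(a)), unname(.tree_splits(b)))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Columns (after complete gap deletion) are resampled with replacement;
#' each replicate alignment yields an NJ tree, and the support of an
#' internal edge of the original tree is the percentage of replicates whose
#' tree contains the same split.
#'
#' @param aln As [p_distance_matrix()].
#' @param reps Number of replicates.
#' @param seed Integer seed (deterministic supports for a fixed seed).
#' @return The original NJ tree with `node.label` set to integer supports
#'   and attribute `supports` (named by split key).
#' @export
bootstrap_support <- function(aln, reps = 100L, seed = 1L) {
  if (reps < 1L) stop("reps must be >= 1")
  m <- .aln_matrix(aln)
  keep <- colSums(m == "-" | m == "N") == 0L
  if (!any(keep)) stop("complete deletion removed all columns")
  m <- m[, keep, drop = FALSE]
  base_tree <- nj_tree(p_distance_matrix(m))
  base_splits <- .tree_splits(base_tree)
  counts <- stats::setNames(numeric(length(base_splits)), unname(base_splits))
  set.seed(as.integer(seed))
  for (b in seq_len(reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_tree <- nj_tree(p_distance_matrix(m[, cols, drop = FALSE]))
    rs <- unname(.tree_splits(rep_tree))
    hit <- names(counts) %in% rs
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / reps)
  nt <- length(base_tree$tip.label)
  node_lab <- rep("", base_tree$Nnode)
  for (nd in names(base_splits)) {
    node_lab[as.integer(nd) - nt] <- as.character(support[[base_splits[[nd]]]])
  }
  base_tree$node.label <- node_lab
  attr(base_tree, "supports") <- support
  base_tree
}

#' Simulate a nucleotide alignment on a tree
#'
#' Jukes-Cantor-style simulation used for bootstrap sanity checks: a random
#' root sequence evolves along the tree, each branch substituting each site
#' with probability equal to the branch length (capped at 0.75).
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param n_sites Alignment length.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences.
#' @export
simulate_alignment <- function(tree, n_sites = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  nt <- length(tree$tip.label)
  root <- nt + 1L
  seqs <- vector("list", nt + tree$Nnode)
  seqs[[root]] <- sample(bases, n_sites, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]
    child <- ord$edge[e, 2L]
    p <- min(ord$edge.length[e], 0.75)
    s <- seqs[[parent]]
    hit <- which(stats::runif(n_sites) < p)
    if (length(hit)) {
      s[hit] <- vapply(s[hit], function(x) sample(setdiff(bases, x), 1L),
                       character(1L))
    }
    seqs[[child]] <- s
  }
  stats::setNames(vapply(seq_len(nt), function(i) paste0(seqs[[i]], collapse = ""),
                         character(1L)),
                  tree$tip.label)
}
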