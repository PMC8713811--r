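# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own code paths.

# Gotoh global alignment with affine gaps; a gap of length k costs
# open + k * ext (the same convention as the package's aligner).
gotoh_score <- function(a, b, mat, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) Ix[i + 1L, 1L] <- -(open + ext * i)
  for (j in seq_len(m)) Iy[1L, j + 1L] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1L, j + 1L] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - (open + ext),
                                Ix[i, j + 1L] - ext)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - (open + ext),
                                Iy[i + 1L, j] - ext)
    }
  }
  max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

blosum62_matrix <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Ordinary-least-squares branch lengths for a fixed topology, and the
# minimum-evolution (sum of OLS branch lengths) optimum over all unrooted
# topologies, by exhaustive enumeration.  Tractable for <= 6 taxa.
ols_tree_length <- function(tree, d) {
  labs <- tree$tip.label
  n <- length(labs)
  pairs <- t(combn(n, 2L))
  A <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (r in seq_len(nrow(pairs))) {
    np <- ape::nodepath(tree, pairs[r, 1L], pairs[r, 2L])
    for (k in seq_len(length(np) - 1L)) {
      e <- which((tree$edge[, 1L] == np[k] & tree$edge[, 2L] == np[k + 1L]) |
                   (tree$edge[, 1L] == np[k + 1L] & tree$edge[, 2L] == np[k]))
      A[r, e] <- 1
    }
  }
  dv <- d[cbind(labs[pairs[, 1L]], labs[pairs[, 2L]])]
  b <- qr.coef(qr(A), dv)
  sum(b)
}

me_best_topology <- function(d) {
  labs <- rownames(d)
  tops <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  lens <- vapply(tops, ols_tree_length, numeric(1), d = d)
  tops[[which.min(lens)]]
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Additive distance matrix from a random tree with strictly positive
# branch lengths.
random_additive <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.1, 1))
  list(tree = tr, d = cophenetic(tr))
}
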