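#' @include wcategory-package.R
NULL

alignment_matrix <- function(alignment) {
  if (methods::is(alignment, "AAStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (is.matrix(alignment)) return(alignment)
  if (!is.character(alignment) || is.null(names(alignment))) {
    wc_stop("alignment must be a named character vector, AAStringSet or character matrix")
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) wc_stop("aligned sequences must have equal lengths")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

GAP_CHARS <- c("-", ".")

#' Pairwise distances from an aligned set of protein sequences
#'
#' The distance between two sequences is the proportion of differing sites
#' over their mutually ungapped columns (pairwise deletion).  The Poisson
#' correction transforms p to `-ln(1 - p)`.
#'
#' @param alignment Named character vector, `AAStringSet` or character
#'   matrix of aligned sequences (>= 3, equal lengths).
#' @param correction `"NONE"` (p-distance) or `"POISSON"`.
#' @return Symmetric numeric matrix with zero diagonal and taxon labels as
#'   dimnames.
#' @export
pdistance <- function(alignment, correction = c("NONE", "POISSON")) {
  correction <- match.arg(correction)
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 3L) wc_stop("need at least 3 sequences")
  gap <- matrix(m %in% GAP_CHARS, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        wc_stop("no comparable (mutually ungapped) columns between ",
                rownames(m)[i], " and ", rownames(m)[j])
      }
      p <- mean(m[i, ok] != m[j, ok])
      if (correction == "POISSON") {
        if (p >= 1) wc_stop("Poisson correction undefined for p >= 1 (",
                            rownames(m)[i], " vs ", rownames(m)[j], ")")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) wc_stop("distance matrix must be square")
  if (is.null(rownames(d))) wc_stop("distance matrix must carry taxon labels")
  if (any(!is.finite(d))) wc_stop("distance matrix has non-finite entries")
  if (any(d < 0)) wc_stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) wc_stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) wc_stop("distance matrix diagonal must be zero")
  invisible(d)
}

fmt_bl <- function(x) sprintf("%.12g", max(0, x))

#' Neighbor-joining tree estimation
#'
#' Saitou-Nei agglomeration on the Q criterion with a deterministic
#' tie-break (the pair with the lowest active-node indices, in input label
#' order, wins).  Negative branch-length estimates are clamped to zero.
#'
#' @param d Symmetric distance matrix with taxon labels (>= 3 taxa).
#' @return An unrooted `phylo` tree (basal trifurcation).
#' @export
nj_tree <- function(d) {
  check_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) wc_stop("need at least 3 taxa")
  labels <- rownames(d)
  frags <- as.list(labels)        # newick fragment per active node
  D <- d
  active <- seq_len(n)            # creation-order indices, for tie-breaking

  while (length(frags) > 3L) {
    r <- length(frags)
    R <- rowSums(D)
    best <- NULL; bestQ <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in seq.int(i + 1L, r)) {
        Q <- (r - 2) * D[i, j] - R[i] - R[j]
        if (Q < bestQ - 1e-12) { bestQ <- Q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    frag <- sprintf("(%s:%s,%s:%s)", frags[[i]], fmt_bl(bi), frags[[j]], fmt_bl(bj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frags <- c(frags[keep], frag)
    active <- c(active[keep], max(active) + 1L)
  }

  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frags[[1L]], fmt_bl(v1), frags[[2L]], fmt_bl(v2),
                 frags[[3L]], fmt_bl(v3))
  ape::read.tree(text = nwk)
}

# Canonical key of the bipartition separating `tipset` from the rest:
# the side not containing the alphabetically first taxon, sorted and joined.
canonical_split <- function(tipset, all_labels) {
  ref <- sort(all_labels)[1L]
  side <- if (ref %in% tipset) setdiff(all_labels, tipset) else tipset
  paste(sort(side), collapse = "|")
}

# Non-trivial bipartitions of an unrooted phylo tree, as canonical keys.
tree_bipartitions <- function(tree) {
  labs <- tree$tip.label
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    tips <- labs[p]
    if (length(tips) <= 1L || length(tips) >= length(labs) - 1L) next
    keys <- c(keys, canonical_split(tips, labs))
  }
  unique(keys)
}

#' Bootstrap bipartition support for a neighbor-joining analysis
#'
#' Resamples alignment columns with replacement, recomputes
#' [pdistance()] + [nj_tree()] per replicate and tallies the non-trivial
#' bipartitions.  Identical seeds give identical results; the resampling
#' uses R's Mersenne-Twister generator, recorded in the output.
#'
#' @param alignment As in [pdistance()].
#' @param B Number of replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param correction Distance correction, see [pdistance()].
#' @return A `support_map`: list with `support` (named percentages in
#'   `[0, 100]` keyed by canonical bipartition), `B`, `seed`, `rng`,
#'   `taxa` and `tree` (the NJ tree on the original alignment).
#' @export
bootstrap_support <- function(alignment, B, seed = 1L,
                              correction = c("NONE", "POISSON")) {
  correction <- match.arg(correction)
  if (B < 1L) wc_stop("B must be at least 1")
  m <- alignment_matrix(alignment)
  main_tree <- nj_tree(pdistance(m, correction))
  set.seed(as.integer(seed))
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    tr <- nj_tree(pdistance(m[, cols, drop = FALSE], correction))
    for (k in tree_bipartitions(tr)) {
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  support <- setNames(vapply(keys, function(k) 100 * counts[[k]] / B, numeric(1)),
                      keys)
  structure(list(support = support, B = as.integer(B), seed = as.integer(seed),
                 rng = RNGkind()[1L], taxa = rownames(m), tree = main_tree),
            class = "support_map")
}

#' Bootstrap support for a clade
#'
#' Support of the bipartition separating `taxa` from the remaining taxa.
#' Trivial bipartitions (single taxon, or all but one) are present in every
#' tree and return 100; an unobserved bipartition returns 0.
#'
#' @param support A `support_map` from [bootstrap_support()].
#' @param taxa Non-empty proper subset of the taxon set.
#' @return Support percentage in `[0, 100]`.
#' @export
clade_support <- function(support, taxa) {
  stopifnot(inherits(support, "support_map"))
  taxa <- unique(taxa)
  if (!length(taxa)) wc_stop("taxon subset is empty")
  if (!all(taxa %in% support$taxa)) {
    wc_stop("unknown taxa: ", paste(setdiff(taxa, support$taxa), collapse = ", "))
  }
  if (length(taxa) >= length(support$taxa)) {
    wc_stop("taxon subset must be a proper subset of the taxon set")
  }
  if (length(taxa) == 1L || length(taxa) == length(support$taxa) - 1L) return(100)
  key <- canonical_split(taxa, support$taxa)
  unname(support$support[key] %||% 0) -> out
  if (is.na(out)) 0 else out
}

#' Annotate a tree's internal nodes with bootstrap supports
#'
#' @param support A `support_map`.
#' @param tree A `phylo` on the same taxa (default: the map's NJ tree).
#' @return The tree with `node.label` set to the rounded support of each
#'   internal node's bipartition (empty for trivial/root nodes).
#' @export
annotate_supports <- function(support, tree = support$tree) {
  stopifnot(inherits(support, "support_map"))
  labs <- tree$tip.label
  parts <- ape::prop.part(tree)
  node_lab <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    tips <- labs[parts[[k]]]
    if (length(tips) <= 1L || length(tips) >= length(labs) - 1L) next
    pct <- support$support[canonical_split(tips, labs)] %||% 0
    if (is.na(pct)) pct <- 0
    node_lab[k] <- as.character(round(pct))
  }
  tree$node.label <- node_lab
  tree
}

#' @export
print.support_map <- function(x, ...) {
  cat("<support_map>", length(x$taxa), "taxa, B =", x$B,
      ", seed =", x$seed, "(", x$rng, ")\n")
  s <- sort(x$support, decreasing = TRUE)
  for (k in head(names(s), 5L)) cat(sprintf("  %5.1f%%  %s\n", s[k], k))
  if (length(s) > 5L) cat("  ...", length(s) - 5L, "more bipartitions\n")
  invisible(x)
}

#' Support table as a data.frame
#'
#' @param support A `support_map`.
#' @return data.frame with columns `bipartition` and `support_pct`.
#' @export
support_table <- function(support) {
  stopifnot(inherits(support, "support_map"))
  s <- sort(support$support, decreasing = TRUE)
  data.frame(bipartition = names(s), support_pct = unname(s),
             stringsAsFactors = FALSE)
}
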