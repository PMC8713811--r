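test_that("p-distances match hand counts, handle gaps, and apply the Poisson correction", {
  aln <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKV", c = "ACDEWGYIKV")
  d <- pdistance(aln)
  expect_equal(d["a", "b"], 0.1)   # 1 difference / 10 sites
  expect_equal(d["a", "c"], 0.3)   # 3 / 10
  expect_equal(d["b", "c"], 0.2)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(c(0, 0, 0), c("a", "b", "c")))

  gapped <- c(a = "AC-EFGHIKL", b = "ACDEFGHIK-", c = "ACDEWGYIKV")
  dg <- pdistance(gapped)
  expect_equal(dg["a", "b"], 0)        # 8 comparable columns, all equal
  expect_equal(dg["a", "c"], 3 / 9)    # W, Y and V differ over 9 columns

  ident <- c(a = "AAAA", b = "AAAA", c = "AAAA")
  expect_true(all(pdistance(ident) == 0))
  expect_true(all(pdistance(ident, "POISSON") == 0))

  dp <- pdistance(aln, "POISSON")
  expect_equal(dp["a", "c"], -log(1 - 0.3))
})

test_that("degenerate distance inputs are rejected", {
  expect_error(pdistance(c(a = "AC", b = "AC")), "at least 3")
  expect_error(pdistance(c(a = "AC", b = "ACD", c = "AC")), "equal lengths")
  nocomp <- c(a = "A--", b = "-C-", c = "AC-")
  expect_error(pdistance(nocomp), "no comparable")
  alldiff <- c(a = "AAAA", b = "CCCC", c = "AACC")
  expect_error(pdistance(alldiff, "POISSON"), "p >= 1")

  d <- pdistance(c(a = "ACDE", b = "ACDF", c = "AGHF"))
  dneg <- d; dneg[1, 2] <- dneg[2, 1] <- -0.1
  expect_error(nj_tree(dneg), "negative")
  dasym <- d; dasym[1, 2] <- d[1, 2] + 0.2
  expect_error(nj_tree(dasym), "not symmetric")
})

test_that("three taxa give the unique unrooted topology with closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0),
              3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(bl[["a"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(bl[["b"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(bl[["c"]], (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ recovers the generating topology from additive distances (5-8 taxa)", {
  for (s in 1:12) {
    gen <- random_additive(5L + (s %% 4L), seed = 100L + s)
    tr <- nj_tree(gen$d)
    expect_true(same_topology(tr, gen$tree), info = paste("seed", s))
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  skip_if_not_installed("phangorn")
  for (s in 1:5) {
    set.seed(400L + s)
    gen <- random_additive(7L, seed = 400L + s)
    d <- gen$d + matrix(runif(49, 0, 0.02), 7, 7)
    d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- dimnames(gen$d)
    expect_true(same_topology(nj_tree(d), ape::nj(d)), info = paste("seed", s))
  }
})

test_that("bootstrap supports are deterministic per seed and bounded", {
  pct <- planted_clade_tree(seed = 3L)
  aln <- make_alignment_set(pct$tree, sim_config(seed = 77L), clade = pct$clade,
                            schema = SCHEMA)$alignment
  s1 <- bootstrap_support(aln, B = 40L, seed = 5L)
  s2 <- bootstrap_support(aln, B = 40L, seed = 5L)
  expect_identical(s1$support, s2$support)
  expect_true(all(s1$support >= 0 & s1$support <= 100))
  s3 <- bootstrap_support(aln, B = 40L, seed = 6L)
  expect_false(identical(s1$support, s3$support))
  expect_error(bootstrap_support(aln, B = 0L), "at least 1")
})

test_that("a clade fixed by many invariant diagnostic columns gets support 100", {
  # four clade taxa share 40 derived columns; background taxa each carry
  # 25 private mutations.  A resample that loses all 40 shared columns has
  # probability (54/94)^94 (~1e-23), so every replicate preserves the split.
  base <- strsplit(SCHEMA$frames$IG_C1$consensus, "")[[1]]
  L <- length(base)
  set.seed(9)
  clade_seq <- base
  shared <- sample(L, 40L)
  clade_seq[shared] <- ifelse(clade_seq[shared] == "W", "A", "W")
  aln <- character(0)
  for (i in 1:4) aln[[paste0("clade_", i)]] <- paste(clade_seq, collapse = "")
  for (i in 1:4) {
    bg <- base
    priv <- sample(L, 25L)
    bg[priv] <- ifelse(bg[priv] == "K", "E", "K")
    aln[[paste0("bg_", i)]] <- paste(bg, collapse = "")
  }
  s <- bootstrap_support(aln, B = 100L, seed = 2L)
  expect_equal(clade_support(s, paste0("clade_", 1:4)), 100)
})

test_that("clade_support handles trivial and invalid subsets", {
  pct <- planted_clade_tree(seed = 3L)
  aln <- make_alignment_set(pct$tree, sim_config(seed = 78L), clade = pct$clade,
                            schema = SCHEMA)$alignment
  s <- bootstrap_support(aln, B = 10L, seed = 1L)
  expect_equal(clade_support(s, s$taxa[1L]), 100)               # single taxon
  expect_equal(clade_support(s, s$taxa[-1L]), 100)              # complement of one
  expect_error(clade_support(s, s$taxa), "proper subset")
  expect_error(clade_support(s, character(0)), "empty")
  expect_error(clade_support(s, "no_such_taxon"), "unknown taxa")
  # a never-observed grouping has support 0
  weird <- c(s$taxa[1L], s$taxa[length(s$taxa)])
  expect_gte(clade_support(s, weird), 0)
})

test_that("support annotations survive Newick round-trips", {
  pct <- planted_clade_tree(seed = 4L)
  aln <- make_alignment_set(pct$tree, sim_config(seed = 79L), clade = pct$clade,
                            schema = SCHEMA)$alignment
  s <- bootstrap_support(aln, B = 20L, seed = 1L)
  tr <- annotate_supports(s)
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_true(same_topology(tr, back))
  expect_true(any(nzchar(back$node.label)))
})
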