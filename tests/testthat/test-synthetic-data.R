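test_that("identical configurations give byte-identical outputs", {
  cfg <- sim_config(seed = 33L, mu = 0.05)
  expect_identical(make_chain("WA", cfg, SCHEMA)$sequence,
                   make_chain("WA", cfg, SCHEMA)$sequence)
  b1 <- make_chains(sim_config(seed = 9L, counts = counts_per_class(2L)), SCHEMA)
  b2 <- make_chains(sim_config(seed = 9L, counts = counts_per_class(2L)), SCHEMA)
  expect_identical(b1$sequences, b2$sequences)

  pct <- planted_clade_tree(seed = 2L)
  a1 <- make_alignment_set(pct$tree, sim_config(seed = 4L), clade = pct$clade)
  a2 <- make_alignment_set(pct$tree, sim_config(seed = 4L), clade = pct$clade)
  expect_identical(a1$alignment, a2$alignment)
  a3 <- make_alignment_set(pct$tree, sim_config(seed = 5L), clade = pct$clade)
  expect_false(identical(a1$alignment, a3$alignment))
})

test_that("configuration bounds are enforced", {
  expect_error(sim_config(mu = 1.5), "mu")
  expect_error(sim_config(counts = c(WA = -1L)), "non-negative")
  expect_error(make_chain("HLA", sim_config()), "unknown chain class")
})

test_that("a noise-free b2m chain carries the planted Ig signature residues", {
  ch <- make_chain("B2M", sim_config(seed = 17L), SCHEMA)
  res <- strsplit(ch$sequence, "")[[1]]
  # single Ig domain: frame column == sequence position
  expect_equal(res[8L], "Y")
  expect_equal(res[37L], "L")
  expect_equal(res[55L], "L")
  expect_equal(res[57L], "F")
  expect_equal(res[61L], "W")
  expect_equal(nchar(ch$sequence), 94L)
  planted <- ch$truth$planted
  expect_setequal(planted$position, c(8L, 37L, 55L, 57L, 61L))
})

test_that("chains round-trip through the classifier and truth records score them", {
  for (lab in CLASSES6) {
    ch <- make_chain(lab, sim_config(seed = 55L), SCHEMA)
    call <- classify_sequences(setNames(ch$sequence, lab), SCHEMA)
    expect_equal(call$table$label, ch$truth$label, info = lab)
  }
})

test_that("multi-residue signature sets are sampled within their allowed sets", {
  # WA position 57 allows F or Y; over seeds both must occur and nothing else
  drawn <- vapply(1:30, function(s) {
    ch <- make_chain("WA", sim_config(seed = 6000L + s), SCHEMA)
    p <- ch$truth$planted
    p$residue[p$frame == "IG_C1" & p$position == 57L]
  }, character(1))
  expect_true(all(drawn %in% c("F", "Y")))
  expect_length(unique(drawn), 2L)
})

test_that("zero branch lengths copy the root state to every leaf", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  out <- make_alignment_set(tr, sim_config(seed = 1L), clade = character(0))
  cons <- SCHEMA$frames$IG_C1$consensus
  expect_true(all(out$alignment == cons))
})

test_that("the planted clade overwrites diagnostic columns on clade leaves only", {
  pct <- planted_clade_tree(seed = 8L)
  out <- make_alignment_set(pct$tree, sim_config(seed = 8L), clade = pct$clade)
  for (lab in pct$clade) {
    res <- strsplit(out$alignment[[lab]], "")[[1]]
    expect_equal(res[out$truth$columns], out$truth$residues, info = lab)
  }
  # background taxa do not all share the planted set
  bg <- setdiff(names(out$alignment), pct$clade)
  hits <- vapply(bg, function(lab) {
    res <- strsplit(out$alignment[[lab]], "")[[1]]
    all(res[out$truth$columns] == out$truth$residues)
  }, logical(1))
  expect_false(any(hits))
})

test_that("malformed trees are rejected", {
  expect_error(make_alignment_set("not a tree", sim_config()), "not a phylo")
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  trneg <- tr; trneg$edge.length[1L] <- -0.5
  expect_error(make_alignment_set(trneg, sim_config()), "negative branch")
  trnull <- tr; trnull$edge.length <- NULL
  expect_error(make_alignment_set(trnull, sim_config()), "no branch lengths")
  expect_error(make_alignment_set(tr, sim_config(), clade = "zz"), "not in tree")
})

test_that("simulated loci contain exactly the planted pairs", {
  loc1 <- make_locus_gff(1L, 0L, sim_config())
  expect_length(find_head_to_head_pairs(loc1$genes), 1L)
  loc0 <- make_locus_gff(0L, 4L, sim_config())
  expect_length(find_head_to_head_pairs(loc0$genes), 0L)
  loc <- make_locus_gff(3L, 5L, sim_config())
  p <- find_head_to_head_pairs(loc$genes)
  expect_length(p, 3L)
  found <- vapply(p, function(x) paste(x$alpha_candidate, x$beta_candidate),
                  character(1))
  expect_setequal(found, paste(loc$truth$pairs$alpha, loc$truth$pairs$beta))
  paired <- unlist(lapply(p, function(x) c(x$alpha_candidate, x$beta_candidate)))
  expect_length(intersect(paired, loc$truth$decoys), 0L)
})
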