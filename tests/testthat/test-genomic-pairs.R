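make_gene <- function(id, strand, start, exon_lens = c(258L, 282L, 90L, 60L),
                      introns = c(500L, 400L, 300L), contig = "ctg1") {
  glens <- if (strand == "-") rev(exon_lens) else exon_lens
  gintr <- if (strand == "-") rev(head(introns, length(exon_lens) - 1L))
           else head(introns, length(exon_lens) - 1L)
  exons <- matrix(0, length(glens), 2L)
  cur <- start
  for (k in seq_along(glens)) {
    exons[k, ] <- c(cur, cur + glens[k])
    cur <- cur + glens[k] + if (k < length(glens)) gintr[k] else 0L
  }
  gene_model(id, contig, strand, exons)
}

test_that("exon templates separate class II-type from class I gene structures", {
  wa <- make_gene("wa", "+", 0L)                                   # distal/Ig/TM/CY
  class1 <- make_gene("hla", "+", 0L, exon_lens = c(258L, 276L, 282L, 150L))
  one_exon <- gene_model("tiny", "ctg1", "+", matrix(c(0L, 282L), 1L))

  expect_true(match_exon_template(wa, "CLASS_II_TYPE")$match)
  expect_false(match_exon_template(wa, "CLASS_I")$match)
  expect_true(match_exon_template(class1, "CLASS_I")$match)
  expect_false(match_exon_template(class1, "CLASS_II_TYPE")$match)
  r <- match_exon_template(one_exon, "CLASS_II_TYPE")
  expect_false(r$match)
  expect_match(r$reasons[1L], "too few exons")
  # minus-strand genes are measured in transcription order
  wa_minus <- make_gene("wam", "-", 0L)
  expect_true(match_exon_template(wa_minus, "CLASS_II_TYPE")$match)
})

test_that("head-to-head detection requires facing 5' ends within the distance cap", {
  left <- make_gene("g_minus", "-", 1000L)
  gap_start <- gene_extent(left)[2L] + 2000L
  right <- make_gene("g_plus", "+", gap_start)
  pairs <- find_head_to_head_pairs(list(left, right))
  expect_length(pairs, 1L)
  expect_equal(pairs[[1L]]$alpha_candidate, "g_minus")
  expect_equal(pairs[[1L]]$beta_candidate, "g_plus")
  expect_equal(pairs[[1L]]$distance, 2000)

  # same strand: no pair
  same <- make_gene("g_plus2", "+", 1000L)
  expect_length(find_head_to_head_pairs(list(same, right)), 0L)
  # tail-to-tail (plus before minus): no pair
  expect_length(find_head_to_head_pairs(list(
    make_gene("p", "+", 1000L), make_gene("m", "-", 5000L))), 0L)
  # beyond max_distance: no pair
  far <- make_gene("g_far", "+", gene_extent(left)[2L] + 50000L)
  expect_length(find_head_to_head_pairs(list(left, far)), 0L)
  expect_length(find_head_to_head_pairs(list(left, far), max_distance = 1e6), 1L)
})

test_that("pair calls are invariant to input order and each gene pairs at most once", {
  loc <- make_locus_gff(3L, 5L, sim_config())
  p1 <- find_head_to_head_pairs(loc$genes)
  p2 <- find_head_to_head_pairs(rev(loc$genes))
  key <- function(p) sort(vapply(p, function(x)
    paste(x$alpha_candidate, x$beta_candidate), character(1)))
  expect_equal(key(p1), key(p2))
  ids <- unlist(lapply(p1, function(x) c(x$alpha_candidate, x$beta_candidate)))
  expect_false(any(duplicated(ids)))
})

test_that("mirroring coordinates and strands yields the mirrored pair set", {
  loc <- make_locus_gff(2L, 3L, sim_config())
  L <- max(vapply(loc$genes, function(g) gene_extent(g)[2L], numeric(1))) + 1000
  mirrored <- lapply(loc$genes, function(g) {
    gene_model(g$gene_id, g$contig, if (g$strand == "+") "-" else "+",
               cbind(L - g$exons[, 2L], L - g$exons[, 1L]))
  })
  p <- find_head_to_head_pairs(loc$genes)
  pm <- find_head_to_head_pairs(mirrored)
  key <- function(pp, swap = FALSE) sort(vapply(pp, function(x) {
    g <- c(x$alpha_candidate, x$beta_candidate)
    paste(sort(g), collapse = "~")
  }, character(1)))
  expect_equal(key(p), key(pm))
  expect_equal(vapply(p, `[[`, numeric(1), "distance"),
               vapply(pm, `[[`, numeric(1), "distance"))
})

test_that("gene models survive a GFF3 round-trip", {
  loc <- make_locus_gff(2L, 2L, sim_config())
  path <- tempfile(fileext = ".gff3")
  write_locus_gff(loc$genes, path)
  back <- read_locus_gff(path)
  expect_equal(length(back), length(loc$genes))
  orig <- loc$genes[order(vapply(loc$genes, `[[`, character(1), "gene_id"))]
  back <- back[order(vapply(back, `[[`, character(1), "gene_id"))]
  for (k in seq_along(orig)) {
    expect_equal(back[[k]]$gene_id, orig[[k]]$gene_id)
    expect_equal(back[[k]]$strand, orig[[k]]$strand)
    expect_equal(unname(back[[k]]$exons), unname(orig[[k]]$exons))
  }
  # and the pairs are identical before and after
  key <- function(p) sort(vapply(p, function(x)
    paste(x$alpha_candidate, x$beta_candidate), character(1)))
  expect_equal(key(find_head_to_head_pairs(back)),
               key(find_head_to_head_pairs(loc$genes)))
})

test_that("invalid gene models are rejected", {
  expect_error(gene_model("g", "c", "*", matrix(c(0, 10), 1L)), "strand")
  expect_error(gene_model("g", "c", "+", matrix(c(10, 5), 1L)), "inverted")
  expect_error(gene_model("g", "c", "+", rbind(c(0, 10), c(5, 20))), "overlapping")
})
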