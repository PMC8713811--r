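#' @include wcategory-package.R
NULL

#' Construct a gene model
#'
#' Coding-exon structure of one gene.  Coordinates are 0-based half-open on
#' the contig (the GFF3 readers/writers convert to and from 1-based closed
#' coordinates on disk).
#'
#' @param gene_id Gene identifier.
#' @param contig Contig/scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of coding-exon `(start, end)` intervals,
#'   0-based half-open, non-overlapping; stored sorted by coordinate.
#' @param labels Optional character vector of per-exon domain labels (in
#'   coordinate order).
#' @return A `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, labels = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] <= exons[, 1L])) wc_stop("empty or inverted exon interval")
  ord <- order(exons[, 1L])
  exons <- exons[ord, , drop = FALSE]
  if (!is.null(labels)) labels <- labels[ord]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    wc_stop("overlapping exons in gene ", gene_id)
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons, labels = labels),
            class = "gene_model")
}

gene_extent <- function(g) c(min(g$exons[, 1L]), max(g$exons[, 2L]))

# Exon lengths in transcription order (5' to 3').
exon_lengths_5to3 <- function(g) {
  len <- g$exons[, 2L] - g$exons[, 1L]
  if (g$strand == "-") rev(len) else len
}

#' @export
print.gene_model <- function(x, ...) {
  ext <- gene_extent(x)
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d coding exons\n", x$gene_id,
              x$contig, ext[1L], ext[2L], x$strand, nrow(x$exons)))
  invisible(x)
}

#' Default exon-length windows for template matching
#'
#' Length windows (bp) for the membrane-distal-domain exon and the Ig-like
#' domain exon; roughly 85-92 and 94 codons respectively.
#'
#' @return List with `distal` and `ig` two-element numeric vectors.
#' @export
default_exon_windows <- function() list(distal = c(250, 278), ig = c(280, 300))

in_window <- function(x, w) x >= w[1L] & x <= w[2L]

#' Match a gene against a class I or class II-type exon template
#'
#' A class II-type gene (conventional class II chains and the W-category
#' WA/WB genes) carries separate exons for the membrane-distal domain, the
#' Ig-like domain and the TM/CY region: at least three coding exons whose
#' first two fall in the distal- and Ig-length windows.  A class I gene
#' needs at least four coding exons, the first two in the distal window
#' (alpha1, alpha2) followed by an Ig-length exon (alpha3).
#'
#' @param gene A `gene_model` with >= 2 coding exons.
#' @param template `"CLASS_I"` or `"CLASS_II_TYPE"`.
#' @param windows Exon-length windows, see [default_exon_windows()].
#' @return List with `match` (logical) and `reasons` (character; why the
#'   template failed, empty on success).
#' @export
match_exon_template <- function(gene, template = c("CLASS_II_TYPE", "CLASS_I"),
                                windows = default_exon_windows()) {
  stopifnot(inherits(gene, "gene_model"))
  template <- match.arg(template)
  len <- exon_lengths_5to3(gene)
  if (length(len) < 2L) {
    return(list(match = FALSE, reasons = "too few exons"))
  }
  reasons <- character(0)
  if (template == "CLASS_II_TYPE") {
    if (length(len) < 3L) reasons <- c(reasons, "too few exons (need >= 3)")
    if (length(len) >= 1L && !in_window(len[1L], windows$distal)) {
      reasons <- c(reasons, sprintf("exon 1 length %d outside distal window", len[1L]))
    }
    if (length(len) >= 2L && !in_window(len[2L], windows$ig)) {
      reasons <- c(reasons, sprintf("exon 2 length %d outside Ig window", len[2L]))
    }
  } else {
    if (length(len) < 4L) reasons <- c(reasons, "too few exons (need >= 4)")
    for (k in 1:2) {
      if (length(len) >= k && !in_window(len[k], windows$distal)) {
        reasons <- c(reasons, sprintf("exon %d length %d outside distal window", k, len[k]))
      }
    }
    if (length(len) >= 3L && !in_window(len[3L], windows$ig)) {
      reasons <- c(reasons, sprintf("exon 3 length %d outside Ig window", len[3L]))
    }
  }
  list(match = length(reasons) == 0L, reasons = reasons)
}

#' Find head-to-head gene pairs
#'
#' A head-to-head (divergently transcribed) pair consists of two adjacent
#' genes on the same contig and opposite strands whose 5' ends face each
#' other across the intergenic gap: the minus-strand gene lies upstream (in
#' contig coordinates) of the plus-strand gene.  Candidate pairs are
#' matched greedily by smallest gap; each gene joins at most one pair.
#'
#' @param genes List of `gene_model`.
#' @param max_distance Maximum intergenic gap in bp (default 20000).
#' @return List of `pair_call`: each with `alpha_candidate` /
#'   `beta_candidate` (left and right gene ids; which chain each encodes is
#'   decided by sequence classification, not by the pair finder), `contig`,
#'   `distance` (bp) and `orientation = "head_to_head"`.
#' @export
find_head_to_head_pairs <- function(genes, max_distance = 20000) {
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_model")))
  cand <- list()
  for (contig in unique(vapply(genes, `[[`, character(1), "contig"))) {
    gs <- Filter(function(g) g$contig == contig, genes)
    starts <- vapply(gs, function(g) gene_extent(g)[1L], numeric(1))
    gs <- gs[order(starts)]
    if (length(gs) < 2L) next
    for (k in seq_len(length(gs) - 1L)) {
      left <- gs[[k]]; right <- gs[[k + 1L]]
      if (left$strand != "-" || right$strand != "+") next
      gap <- gene_extent(right)[1L] - gene_extent(left)[2L]
      if (gap < 0 || gap > max_distance) next
      cand[[length(cand) + 1L]] <- list(left = left$gene_id,
                                        right = right$gene_id,
                                        contig = contig, gap = gap)
    }
  }
  if (!length(cand)) return(list())
  used <- character(0)
  pairs <- list()
  for (p in cand[order(vapply(cand, `[[`, numeric(1), "gap"))]) {
    if (p$left %in% used || p$right %in% used) next
    used <- c(used, p$left, p$right)
    pairs[[length(pairs) + 1L]] <- structure(
      list(alpha_candidate = p$left, beta_candidate = p$right,
           contig = p$contig, distance = p$gap, orientation = "head_to_head"),
      class = "pair_call")
  }
  pairs
}

#' @export
print.pair_call <- function(x, ...) {
  cat(sprintf("<pair_call> %s <-||-> %s  (%s, gap %d bp)\n",
              x$alpha_candidate, x$beta_candidate, x$contig, as.integer(x$distance)))
  invisible(x)
}

#' Write gene models to a GFF3 file
#'
#' Internal 0-based half-open coordinates are emitted as 1-based closed
#' GFF3 `gene`/`CDS` features.
#'
#' @param genes List of `gene_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_gff <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    ext <- gene_extent(g)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = g$contig, start = ext[1L] + 1L, end = ext[2L], strand = g$strand,
      type = "gene", ID = g$gene_id, Parent = NA_character_,
      domain_label = NA_character_, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(g$exons))) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = g$contig, start = g$exons[k, 1L] + 1L, end = g$exons[k, 2L],
        strand = g$strand, type = "CDS",
        ID = sprintf("%s.cds%d", g$gene_id, k), Parent = g$gene_id,
        domain_label = if (is.null(g$labels)) NA_character_ else g$labels[k],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$domain_label <- df$domain_label
  S4Vectors::mcols(gr)$source <- "wcategory"
  S4Vectors::mcols(gr)$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Groups `CDS` features under their parent `gene` features and converts to
#' the package's internal 0-based half-open coordinates.
#'
#' @param path GFF3 path.
#' @return List of `gene_model`.
#' @export
read_locus_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  is_gene <- mc$type == "gene"
  parent <- vapply(seq_along(gr), function(i) {
    p <- mc$Parent[[i]]
    if (length(p) && nzchar(p[1L])) as.character(p[1L]) else NA_character_
  }, character(1))
  genes <- list()
  for (i in which(is_gene)) {
    gid <- as.character(mc$ID[i])
    cds <- which(mc$type == "CDS" & parent == gid)
    if (!length(cds)) next
    exons <- cbind(start = BiocGenerics::start(gr)[cds] - 1L,
                   end = BiocGenerics::end(gr)[cds])
    labels <- if ("domain_label" %in% colnames(mc)) {
      lab <- as.character(mc$domain_label[cds])
      if (all(is.na(lab))) NULL else lab
    } else NULL
    genes[[length(genes) + 1L]] <- gene_model(
      gid, as.character(GenomicRanges::seqnames(gr)[i]),
      as.character(BiocGenerics::strand(gr)[i]), exons, labels = labels)
  }
  genes
}
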