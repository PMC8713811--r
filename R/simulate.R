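#' @include schema.R
NULL

# Fixed cytoplasmic tail appended after the TM segment of anchored chains;
# hydrophilic so the hydropathy scan ends at the membrane anchor.
CY_TAIL <- "RKRSNSAEGSDQTLAP"

#' Simulation configuration
#'
#' One object collects every knob of the synthetic-data generator so that
#' identical configurations give byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param mu Point-mutation rate in `[0, 1]` applied to non-signature,
#'   non-invariant columns of generated chains.
#' @param counts Named non-negative integer vector of chains per class
#'   (names among the six chain classes).
#' @param randomize_signatures If `TRUE`, signature columns are overwritten
#'   with uniformly random residues instead of the class's diagnostic
#'   residues (used for null chains).
#' @param branch_scale Multiplier on branch lengths in the alignment
#'   simulator.
#' @param diagnostic_columns Ig-frame columns carrying the planted clade
#'   signal in [make_alignment_set()]; defaults to the b2m/WA-alpha2
#'   signature columns 8, 37, 55, 57, 61.
#' @param clade_residues Residues planted at `diagnostic_columns` on the
#'   designated clade (defaults Y, L, L, F, W: the b2m set).
#' @param pair_gap Intergenic gap (bp) inside a simulated head-to-head pair.
#' @param block_gap Gap (bp) between consecutive gene blocks; larger than
#'   the pair-finder's default `max_distance` so blocks never pair across.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, mu = 0,
                       counts = setNames(rep(1L, 6L), CHAIN_CLASSES),
                       randomize_signatures = FALSE,
                       branch_scale = 1,
                       diagnostic_columns = c(8L, 37L, 55L, 57L, 61L),
                       clade_residues = c("Y", "L", "L", "F", "W"),
                       pair_gap = 2000L, block_gap = 30000L) {
  if (mu < 0 || mu > 1) wc_stop("mu must lie in [0, 1]")
  if (any(counts < 0)) wc_stop("counts must be non-negative")
  if (!all(names(counts) %in% CHAIN_CLASSES)) {
    wc_stop("counts names must be chain classes")
  }
  if (length(diagnostic_columns) != length(clade_residues)) {
    wc_stop("diagnostic_columns and clade_residues lengths differ")
  }
  structure(list(seed = as.integer(seed), mu = mu, counts = counts,
                 randomize_signatures = randomize_signatures,
                 branch_scale = branch_scale,
                 diagnostic_columns = as.integer(diagnostic_columns),
                 clade_residues = clade_residues,
                 pair_gap = as.integer(pair_gap),
                 block_gap = as.integer(block_gap)),
            class = "sim_config")
}

mutate_residues <- function(res, mu, protect = integer(0)) {
  if (mu <= 0) return(res)
  idx <- setdiff(seq_along(res), protect)
  hit <- idx[stats::runif(length(idx)) < mu]
  for (i in hit) res[i] <- sample(setdiff(AA_STANDARD, res[i]), 1L)
  res
}

#' Generate one synthetic chain of a given class
#'
#' Concatenates the frame consensi dictated by the class's domain layout
#' (e.g. two distal domains + Ig + TM for a class I heavy chain, a single
#' Ig domain for b2m), overwrites the signature columns with the class's
#' diagnostic residues (sampling uniformly within multi-residue sets such
#' as F/Y57), applies the indel-region presence/absence of the class,
#' plants the class's TM glycines, and finally mutates the remaining
#' positions at rate `mu` (IgSF-invariant tryptophan/cysteine columns are
#' protected).  Fully deterministic given `config$seed`.
#'
#' @param label One of the six chain classes.
#' @param config A [sim_config()].
#' @param schema A `wcat_schema`.
#' @param chain_id Optional identifier.
#' @return List with `sequence`, `label`, `chain_id` and `truth` (planted
#'   residues, domain layout, seed).
#' @export
make_chain <- function(label, config = sim_config(), schema = default_schema(),
                       chain_id = label) {
  if (!label %in% CHAIN_CLASSES) wc_stop("unknown chain class: ", label)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- CLASS_LAYOUT[[label]]
  planted <- list()
  parts <- character(0)

  plant_frame <- function(frame_name) {
    fr <- schema$frames[[frame_name]]
    res <- str_residues(fr$consensus)
    protect <- integer(0)
    sigs <- schema$signatures[schema$signatures$frame == frame_name &
                                schema$signatures$chain_class == label, , drop = FALSE]
    for (i in seq_len(nrow(sigs))) {
      pos <- sigs$position[i]
      res[pos] <- if (config$randomize_signatures) sample(AA_STANDARD, 1L)
                  else sample(str_residues(sigs$allowed_residues[i]), 1L)
      protect <- c(protect, pos)
      planted[[length(planted) + 1L]] <<- data.frame(
        frame = frame_name, position = pos, residue = res[pos],
        stringsAsFactors = FALSE)
    }
    core <- schema$signatures[schema$signatures$frame == frame_name &
                                schema$signatures$chain_class == "IGSF_CORE", ]
    protect <- c(protect, core$position)
    if (config$randomize_signatures && nrow(core)) {
      res[core$position] <- sample(AA_STANDARD, nrow(core), replace = TRUE)
    }
    if (frame_name == "IG_C1") protect <- c(protect, schema$invariant_cysteine_positions)
    res <- mutate_residues(res, config$mu, protect)
    # class II-type chains lack the indel regions shared by class I and
    # W-category: delete those columns
    reg <- schema$indel_regions
    drop <- integer(0)
    for (k in seq_len(nrow(reg))) {
      if (reg$frame[k] == frame_name && label %in% reg$absent_in[[k]]) {
        drop <- c(drop, seq.int(reg$start_column[k], reg$end_column[k]))
      }
    }
    if (length(drop)) res <- res[-drop]
    paste(res, collapse = "")
  }

  for (fn in layout$distal) parts <- c(parts, plant_frame(fn))
  parts <- c(parts, plant_frame("IG_C1"))
  if (layout$tm) {
    fr <- schema$frames[["TM"]]
    res <- str_residues(fr$consensus)
    pat <- schema$tm_glycine_patterns[[label]] %||% integer(0)
    if (length(pat)) {
      res[pat] <- "G"
      planted[[length(planted) + 1L]] <- data.frame(
        frame = "TM", position = pat, residue = "G", stringsAsFactors = FALSE)
    }
    res <- mutate_residues(res, config$mu, protect = pat)
    parts <- c(parts, paste(res, collapse = ""), CY_TAIL)
  }

  list(sequence = paste(parts, collapse = ""), label = label,
       chain_id = chain_id,
       truth = list(label = label, planted = do.call(rbind, planted),
                    layout = layout, seed = config$seed, mu = config$mu))
}

#' Generate a panel of chains for all classes
#'
#' Calls [make_chain()] once per requested chain with a per-chain seed
#' derived from `config$seed` (class index * 1000 + replicate), so the
#' whole panel is reproducible and individual chains are re-derivable.
#'
#' @param config A [sim_config()]; `config$counts` sets chains per class.
#' @param schema A `wcat_schema`.
#' @return List with `sequences` (named character vector) and `truth`
#'   (data.frame chain_id/label/seed).
#' @export
make_chains <- function(config = sim_config(), schema = default_schema()) {
  sequences <- character(0)
  rows <- list()
  for (ci in seq_along(config$counts)) {
    label <- names(config$counts)[ci]
    for (r in seq_len(config$counts[[ci]])) {
      sub_seed <- config$seed + 1000L * ci + r
      cfg <- config; cfg$seed <- sub_seed
      id <- sprintf("%s_%03d", label, r)
      ch <- make_chain(label, cfg, schema, chain_id = id)
      sequences[[id]] <- ch$sequence
      rows[[length(rows) + 1L]] <- data.frame(chain_id = id, label = label,
                                              seed = sub_seed,
                                              stringsAsFactors = FALSE)
    }
  }
  list(sequences = sequences, truth = do.call(rbind, rows))
}

#' A tree with a planted clade, for alignment simulation
#'
#' Builds an unrooted tree containing a designated clade (default: three
#' WA-alpha2-like taxa plus one b2m-like taxon, mirroring the
#' WA-alpha2 + b2m clustering) next to a caterpillar of background taxa
#' with randomized branch lengths.
#'
#' @param n_background Number of background taxa (>= 3).
#' @param clade_labels Labels of the planted clade taxa.
#' @param seed RNG seed for the background branch lengths.
#' @return List with `tree` (a `phylo`) and `clade` (the planted labels).
#' @export
planted_clade_tree <- function(n_background = 8L,
                               clade_labels = c("WAa2_1", "WAa2_2", "WAa2_3", "b2m_1"),
                               seed = 1L) {
  stopifnot(n_background >= 3L, length(clade_labels) >= 2L)
  set.seed(as.integer(seed))
  bl <- function() sprintf("%.4f", stats::runif(1L, 0.05, 0.25))
  clade <- sprintf("%s:0.08", clade_labels[1L])
  for (lab in clade_labels[-1L]) {
    clade <- sprintf("(%s,%s:0.08):0.04", clade, lab)
  }
  bg <- sprintf("bg_1:%s", bl())
  for (k in seq.int(2L, n_background - 1L)) {
    bg <- sprintf("(%s,bg_%d:%s):%s", bg, k, bl(), bl())
  }
  nwk <- sprintf("(%s:0.12,%s:%s,bg_%d:%s);", clade, bg, bl(), n_background, bl())
  list(tree = ape::read.tree(text = nwk), clade = clade_labels)
}

#' Simulate an Ig-domain alignment along a tree with a planted clade signal
#'
#' Evolves the Ig C1-set consensus along the tree under a Poisson
#' uniform-replacement model: on a branch of length `b` each site
#' substitutes with probability `1 - exp(-b * branch_scale)` to a uniformly
#' chosen different residue.  The designated diagnostic columns of the
#' leaves inside the planted clade are then overwritten with the
#' clade-specific residues (shared derived states on the clade's stem).
#' Deterministic per `config$seed`.
#'
#' @param tree A binary `phylo` with non-negative branch lengths.
#' @param config A [sim_config()] (`diagnostic_columns`, `clade_residues`,
#'   `branch_scale`, `seed`).
#' @param clade Leaf labels of the planted clade (character vector; may be
#'   empty for a pure-drift alignment).
#' @param schema A `wcat_schema` supplying the Ig consensus.
#' @return List with `alignment` (named character vector, equal lengths),
#'   `truth` (clade, columns, residues, seed) and `tree`.
#' @export
make_alignment_set <- function(tree, config = sim_config(), clade = character(0),
                               schema = default_schema()) {
  if (!inherits(tree, "phylo")) wc_stop("malformed tree: not a phylo object")
  if (is.null(tree$edge.length)) wc_stop("malformed tree: no branch lengths")
  if (any(tree$edge.length < 0)) wc_stop("malformed tree: negative branch length")
  missing_clade <- setdiff(clade, tree$tip.label)
  if (length(missing_clade)) {
    wc_stop("clade taxa not in tree: ", paste(missing_clade, collapse = ", "))
  }
  set.seed(config$seed)
  cons <- str_residues(frame_consensus(schema, "IG_C1"))
  L <- length(cons)
  ntip <- length(tree$tip.label)
  tree_cw <- stats::reorder(tree, "cladewise")
  states <- vector("list", ntip + tree_cw$Nnode)
  root <- ntip + 1L
  states[[root]] <- cons
  for (e in seq_len(nrow(tree_cw$edge))) {
    parent <- tree_cw$edge[e, 1L]; child <- tree_cw$edge[e, 2L]
    b <- tree_cw$edge.length[e] * config$branch_scale
    s <- states[[parent]]
    p <- 1 - exp(-b)
    if (p > 0) {
      hit <- which(stats::runif(L) < p)
      for (i in hit) s[i] <- sample(setdiff(AA_STANDARD, s[i]), 1L)
    }
    states[[child]] <- s
  }
  aln <- vapply(seq_len(ntip), function(i) paste(states[[i]], collapse = ""),
                character(1))
  names(aln) <- tree_cw$tip.label
  for (lab in clade) {
    s <- str_residues(aln[[lab]])
    s[config$diagnostic_columns] <- config$clade_residues
    aln[[lab]] <- paste(s, collapse = "")
  }
  list(alignment = aln,
       truth = list(clade = clade, columns = config$diagnostic_columns,
                    residues = config$clade_residues, seed = config$seed),
       tree = tree)
}

#' Simulate a genomic locus with head-to-head gene pairs and decoys
#'
#' Emits `n_pairs` divergently transcribed gene pairs (a minus-strand gene
#' followed, across a `pair_gap` intergenic gap, by a plus-strand gene,
#' both with class II-type exon structure) plus decoy genes that must not
#' pair: same-strand neighbors, a distant facing gene, and genes with too
#' few exons.  Blocks are separated by `block_gap` (larger than the default
#' pairing distance).
#'
#' @param n_pairs,n_decoys Non-negative counts.
#' @param config A [sim_config()].
#' @return List with `genes` (list of `gene_model`) and `truth`
#'   (data.frame of planted pairs; decoy ids).
#' @export
make_locus_gff <- function(n_pairs, n_decoys, config = sim_config()) {
  stopifnot(n_pairs >= 0, n_decoys >= 0)
  contig <- "sim_locus_1"
  class2_exons <- c(258L, 282L, 90L, 60L)   # distal / Ig / TM / CY codons * 3
  introns <- c(500L, 400L, 300L)

  build_gene <- function(id, strand, start, exon_lens = class2_exons,
                         intr = introns) {
    # exon_lens in transcription order; genomic order reversed on minus strand
    glens <- if (strand == "-") rev(exon_lens) else exon_lens
    gintr <- if (strand == "-") rev(intr[seq_len(length(exon_lens) - 1L)])
             else intr[seq_len(length(exon_lens) - 1L)]
    exons <- matrix(0, nrow = length(glens), ncol = 2L)
    cur <- start
    for (k in seq_along(glens)) {
      exons[k, ] <- c(cur, cur + glens[k])
      cur <- cur + glens[k] + if (k < length(glens)) gintr[k] else 0L
    }
    list(gene = gene_model(id, contig, strand, exons), end = cur)
  }

  genes <- list()
  pair_rows <- list()
  cursor <- 1000L
  for (p in seq_len(n_pairs)) {
    left <- build_gene(sprintf("WA_sim_%02d", p), "-", cursor)
    cursor <- left$end + config$pair_gap
    right <- build_gene(sprintf("WB_sim_%02d", p), "+", cursor)
    cursor <- right$end + config$block_gap
    genes <- c(genes, list(left$gene, right$gene))
    pair_rows[[p]] <- data.frame(alpha = left$gene$gene_id,
                                 beta = right$gene$gene_id,
                                 gap = config$pair_gap, stringsAsFactors = FALSE)
  }
  decoy_ids <- character(0)
  for (d in seq_len(n_decoys)) {
    id <- sprintf("decoy_%02d", d)
    kind <- (d - 1L) %% 3L
    g <- if (kind == 2L) {
      build_gene(id, "+", cursor, exon_lens = 282L, intr = integer(0))
    } else if (kind == 1L) {
      build_gene(id, "-", cursor)   # distant facing gene: next block >> max_distance
    } else {
      build_gene(id, "+", cursor)   # same-strand neighbor
    }
    cursor <- g$end + config$block_gap
    genes <- c(genes, list(g$gene))
    decoy_ids <- c(decoy_ids, id)
  }
  list(genes = genes,
       truth = list(pairs = if (length(pair_rows)) do.call(rbind, pair_rows)
                            else data.frame(alpha = character(0), beta = character(0),
                                            gap = integer(0)),
                    decoys = decoy_ids))
}
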