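#' @include classifier.R
NULL

#' Pipeline run configuration
#'
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed driving every stochastic stage.
#' @param stages Stages to execute, in order, among `simulate`, `classify`,
#'   `interfaces`, `phylo`, `pairs`, `conserve`.  `classify`, `interfaces`,
#'   `phylo`, `pairs` and `conserve` consume the simulated bundle.
#' @param schema_path Optional path to a schema JSON (default: packaged
#'   schema).
#' @param tau Classifier margin threshold in `[0, 1]`.
#' @param min_score Confident-mapping threshold in `[0, 1]`.
#' @param max_distance Pairing distance cap in bp (> 0).
#' @param correction Distance correction (`"NONE"` or `"POISSON"`).
#' @param B Bootstrap replicates (>= 1).
#' @param mu Chain mutation rate in `[0, 1]`.
#' @param chains_per_class Chains per class for the simulated bundle.
#' @param n_pairs,n_decoys Simulated locus composition.
#' @return A `wcat_run_config`.
#' @export
run_config <- function(outdir, seed = 1L,
                       stages = c("simulate", "classify", "interfaces",
                                  "phylo", "pairs", "conserve"),
                       schema_path = NULL, tau = 0.15, min_score = 0.35,
                       max_distance = 20000, correction = "NONE", B = 100L,
                       mu = 0, chains_per_class = 3L, n_pairs = 3L,
                       n_decoys = 5L) {
  known <- c("simulate", "classify", "interfaces", "phylo", "pairs", "conserve")
  if (!length(stages)) wc_stop("no stages selected")
  if (!all(stages %in% known)) {
    wc_stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if (tau < 0 || tau > 1) wc_stop("tau outside [0, 1]")
  if (min_score < 0 || min_score > 1) wc_stop("min_score outside [0, 1]")
  if (max_distance <= 0) wc_stop("max_distance must be positive")
  if (B < 1) wc_stop("B must be at least 1")
  if (mu < 0 || mu > 1) wc_stop("mu outside [0, 1]")
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 schema_path = schema_path, tau = tau, min_score = min_score,
                 max_distance = max_distance, correction = correction,
                 B = as.integer(B), mu = mu,
                 chains_per_class = as.integer(chains_per_class),
                 n_pairs = as.integer(n_pairs), n_decoys = as.integer(n_decoys)),
            class = "wcat_run_config")
}

#' Load a run configuration from JSON
#'
#' @param path JSON file whose keys mirror the [run_config()] arguments.
#' @return A `wcat_run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) wc_stop("config file does not exist: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$outdir)) wc_stop("config must set 'outdir'")
  do.call(run_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    wc_stop("stage '", stage, "' failed: ", conditionMessage(e))
  })
}

#' Run the analysis pipeline on a simulated bundle
#'
#' Executes the requested stages in order: simulate a bundle (chains of
#' every class, an Ig-domain alignment with a planted WA-alpha2 + b2m-style
#' clade, and a genomic locus with head-to-head pairs), classify the
#' chains, type the interfaces of the first WA/WB pair, run the
#' bootstrap/NJ clade-support analysis, detect head-to-head pairs, and
#' profile alignment conservation.  All outputs are written under
#' `config$outdir` and summarized in a JSON report (`report.json`) that
#' records the seed and every stage's parameters; reruns with an identical
#' configuration give identical reports.
#'
#' @param config A `wcat_run_config` (or path to a JSON config).
#' @return The report, invisibly (also written to
#'   `file.path(config$outdir, "report.json")`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "wcat_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  schema <- if (is.null(config$schema_path)) default_schema()
            else load_schema(config$schema_path)

  report <- list(
    package = "wcategory",
    version = as.character(utils::packageVersion("wcategory")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "outdir")],
    stages = list())

  bundle <- NULL
  if ("simulate" %in% config$stages) {
    bundle <- stage_error("simulate", {
      cfg <- sim_config(seed = config$seed, mu = config$mu,
                        counts = setNames(rep(config$chains_per_class, 6L),
                                          CHAIN_CLASSES))
      chains <- make_chains(cfg, schema)
      pct <- planted_clade_tree(seed = config$seed)
      aln <- make_alignment_set(pct$tree, sim_config(seed = config$seed + 101L),
                                clade = pct$clade, schema = schema)
      locus <- make_locus_gff(config$n_pairs, config$n_decoys,
                              sim_config(seed = config$seed))
      Biostrings::writeXStringSet(Biostrings::AAStringSet(chains$sequences),
                                  file.path(config$outdir, "chains.faa"))
      Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$alignment),
                                  file.path(config$outdir, "ig_alignment.afa"))
      write_locus_gff(locus$genes, file.path(config$outdir, "locus.gff3"))
      jsonlite::write_json(
        list(chains = chains$truth, clade = aln$truth,
             pairs = locus$truth$pairs, decoys = locus$truth$decoys),
        file.path(config$outdir, "truth.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(chains = chains, alignment = aln, locus = locus)
    })
    report$stages$simulate <- list(
      n_chains = length(bundle$chains$sequences),
      alignment_taxa = length(bundle$alignment$alignment),
      n_genes = length(bundle$locus$genes))
  }
  needs_bundle <- intersect(config$stages,
                            c("classify", "interfaces", "phylo", "pairs", "conserve"))
  if (length(needs_bundle) && is.null(bundle)) {
    wc_stop("stage '", needs_bundle[1L], "' requires the simulate stage")
  }

  cls <- NULL
  if ("classify" %in% config$stages) {
    cls <- stage_error("classify", {
      res <- classify_sequences(bundle$chains$sequences, schema,
                                tau = config$tau, min_score = config$min_score)
      tab <- merge(res$table, bundle$chains$truth[, c("chain_id", "label")],
                   by = "chain_id", suffixes = c("", "_true"))
      write_tsv(tab, file.path(config$outdir, "calls.tsv"))
      res$truth_table <- tab
      res
    })
    conf <- with(cls$truth_table,
                 table(true = label_true,
                       predicted = factor(label, levels = c(CHAIN_CLASSES, "UNKNOWN"))))
    report$stages$classify <- list(
      n = nrow(cls$truth_table),
      accuracy = mean(cls$truth_table$label == cls$truth_table$label_true),
      confusion = as.data.frame(conf))
  }

  if ("interfaces" %in% config$stages) {
    rep_if <- stage_error("interfaces", {
      if (is.null(cls)) wc_stop("requires the classify stage")
      wa <- cls$calls[[with(cls$truth_table, chain_id[label == "WA"][1L])]]
      wb <- cls$calls[[with(cls$truth_table, chain_id[label == "WB"][1L])]]
      if (is.null(wa) || is.null(wb)) wc_stop("no WA/WB call available")
      ir <- evaluate_interfaces(wa, wb, schema)
      jsonlite::write_json(
        list(alpha = ir$alpha_id, beta = ir$beta_id,
             verdicts = lapply(ir$interfaces, function(e)
               list(verdict = e$verdict, weighted_match = e$fraction))),
        file.path(config$outdir, "interfaces.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      ir
    })
    report$stages$interfaces <- lapply(rep_if$interfaces, `[[`, "verdict")
  }

  if ("phylo" %in% config$stages) {
    sup <- stage_error("phylo", {
      s <- bootstrap_support(bundle$alignment$alignment, B = config$B,
                             seed = config$seed, correction = config$correction)
      ape::write.tree(annotate_supports(s),
                      file.path(config$outdir, "ig_nj.nwk"))
      write_tsv(support_table(s), file.path(config$outdir, "supports.tsv"))
      s
    })
    report$stages$phylo <- list(
      B = sup$B, seed = sup$seed, rng = sup$rng,
      correction = config$correction,
      planted_clade_support = clade_support(sup, bundle$alignment$truth$clade))
  }

  if ("pairs" %in% config$stages) {
    pc <- stage_error("pairs", {
      p <- find_head_to_head_pairs(bundle$locus$genes,
                                   max_distance = config$max_distance)
      df <- if (length(p)) do.call(rbind, lapply(p, function(x)
        data.frame(alpha_candidate = x$alpha_candidate,
                   beta_candidate = x$beta_candidate, contig = x$contig,
                   distance = x$distance, stringsAsFactors = FALSE)))
        else data.frame(alpha_candidate = character(0),
                        beta_candidate = character(0), contig = character(0),
                        distance = numeric(0))
      write_tsv(df, file.path(config$outdir, "pairs.tsv"))
      p
    })
    truth_pairs <- bundle$locus$truth$pairs
    found <- vapply(pc, function(x)
      paste(x$alpha_candidate, x$beta_candidate), character(1))
    planted <- paste(truth_pairs$alpha, truth_pairs$beta)
    report$stages$pairs <- list(
      n_found = length(pc),
      n_planted = nrow(truth_pairs),
      planted_recovered = sum(planted %in% found),
      decoys_paired = sum(vapply(pc, function(x)
        any(c(x$alpha_candidate, x$beta_candidate) %in%
              bundle$locus$truth$decoys), logical(1))))
  }

  if ("conserve" %in% config$stages) {
    prof <- stage_error("conserve", {
      p <- column_conservation(bundle$alignment$alignment)
      write_tsv(as.data.frame(p), file.path(config$outdir, "conservation.tsv"))
      p
    })
    report$stages$conserve <- list(
      columns = nrow(prof),
      mean_entropy_bits = mean(prof$entropy_bits, na.rm = TRUE),
      mean_modal_fraction = mean(prof$modal_fraction, na.rm = TRUE))
  }

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(report)
}

#' Print the pipeline's default configuration
#'
#' @return The default `wcat_run_config` for a placeholder output
#'   directory, invisibly (printed as JSON).
#' @export
default_run_config <- function() {
  cfg <- run_config(outdir = "wcat_out")
  cat(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, pretty = TRUE,
                       null = "null"), "\n")
  invisible(cfg)
}
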