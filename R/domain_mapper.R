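#' @include wcategory-package.R
NULL

.wc_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.wc_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .wc_env$BLOSUM62 <- e$BLOSUM62
  }
  .wc_env$BLOSUM62
}

#' Default alignment scoring for frame mapping
#'
#' Global affine-gap alignment against frame consensi uses a BLOSUM62 table
#' with gap opening 10 and gap extension 1 (a gap of length k costs
#' `10 + k`).
#'
#' @return A list with elements `matrix`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function() list(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1)

scoring_matrix <- function(scoring) {
  if (is.character(scoring$matrix)) {
    if (scoring$matrix != "BLOSUM62") wc_stop("unknown scoring matrix: ", scoring$matrix)
    blosum62()
  } else scoring$matrix
}

check_protein <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    wc_stop("sequence must be a single non-empty protein string")
  }
  res <- str_residues(sequence)
  bad <- setdiff(res, c(AA_STANDARD, "X"))
  if (length(bad)) wc_stop("non-standard residues in sequence: ", paste(bad, collapse = ","))
  invisible(res)
}

consensus_aastring <- function(frame) {
  key <- paste0("aas_", frame$name, "_", frame$consensus)
  if (is.null(.wc_env[[key]])) .wc_env[[key]] <- Biostrings::AAString(frame$consensus)
  .wc_env[[key]]
}

consensus_self_score <- function(frame, scoring) {
  key <- paste0("self_", frame$name, "_", frame$consensus)
  if (is.null(.wc_env[[key]])) {
    .wc_env[[key]] <- as.numeric(Biostrings::pairwiseAlignment(
      Biostrings::AAString(frame$consensus), Biostrings::AAString(frame$consensus),
      substitutionMatrix = scoring_matrix(scoring),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      type = "global", scoreOnly = TRUE))
  }
  .wc_env[[key]]
}

# Core aligner: aligns the full frame consensus (pattern) against
# `sequence[region]` (0-based half-open region), globally in the pattern and
# either globally or locally in the subject.  Returns a domain_hit.
align_frame_score <- function(sequence, frame, scoring, type, region = NULL) {
  if (is.null(region)) region <- c(0L, nchar(sequence))
  sub <- substr(sequence, region[1L] + 1L, region[2L])
  raw <- as.numeric(Biostrings::pairwiseAlignment(
    consensus_aastring(frame), Biostrings::AAString(sub),
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = type, scoreOnly = TRUE))
  max(0, min(1, raw / consensus_self_score(frame, scoring)))
}

align_frame <- function(sequence, frame, scoring, type, region = NULL,
                        chain_id = NA_character_) {
  n <- nchar(sequence)
  if (is.null(region)) region <- c(0L, n)
  sub <- substr(sequence, region[1L] + 1L, region[2L])
  aln <- Biostrings::pairwiseAlignment(
    consensus_aastring(frame), Biostrings::AAString(sub),
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = type)
  ap <- str_residues(as.character(Biostrings::alignedPattern(aln)))
  as_ <- str_residues(as.character(Biostrings::alignedSubject(aln)))
  pmap <- rep(NA_integer_, frame$length)
  pi <- 0L
  si <- region[1L] + Biostrings::start(Biostrings::subject(aln)) - 1L  # 0-based
  for (k in seq_along(ap)) {
    if (ap[k] != "-") {
      pi <- pi + 1L
      if (as_[k] != "-") pmap[pi] <- si
    }
    if (as_[k] != "-") si <- si + 1L
  }
  names(pmap) <- as.character(seq_len(frame$length) + frame$numbering_origin - 1L)
  qstart <- region[1L] + Biostrings::start(Biostrings::subject(aln)) - 1L
  qend <- region[1L] + Biostrings::end(Biostrings::subject(aln))
  raw <- as.numeric(Biostrings::score(aln))
  norm <- max(0, min(1, raw / consensus_self_score(frame, scoring)))
  structure(list(chain_id = chain_id, frame = frame$name,
                 query_interval = c(qstart, qend),
                 score_raw = raw, score = norm, position_map = pmap),
            class = "domain_hit")
}

#' Map a protein sequence onto a position frame
#'
#' Globally aligns `sequence` to the frame consensus with affine gap
#' penalties and returns the frame-column to query-index map plus an
#' alignment score normalized to `[0, 1]` by the consensus self-alignment
#' score (negative scores are clamped to 0).  Query indices are 0-based;
#' frame columns follow the frame's own 1-based numbering.
#'
#' @param sequence Protein string (standard residues, `X` tolerated).
#' @param frame A `wcat_frame` (an element of `schema$frames`).
#' @param scoring Scoring parameters, see [default_scoring()].
#' @return A `domain_hit`: list with `frame`, `query_interval` (0-based
#'   half-open), `score_raw`, `score` (normalized) and `position_map`
#'   (integer vector over frame columns, `NA` where a column is unmatched).
#' @export
map_to_frame <- function(sequence, frame, scoring = default_scoring()) {
  check_protein(sequence)
  stopifnot(inherits(frame, "wcat_frame"))
  if (nchar(sequence) < 0.4 * frame$length) {
    wc_stop("no confident mapping: sequence shorter than 40% of frame ", frame$name)
  }
  align_frame(sequence, frame, scoring, type = "global")
}

#' @export
print.domain_hit <- function(x, ...) {
  cat(sprintf("<domain_hit> %s  query [%d,%d)  score %.3f (%d/%d columns mapped)\n",
              x$frame, x$query_interval[1L], x$query_interval[2L], x$score,
              sum(!is.na(x$position_map)), length(x$position_map)))
  invisible(x)
}

# Residues observed at frame columns through a hit's position map.
observed_residues <- function(hit, sequence) {
  idx <- hit$position_map
  out <- rep(NA_character_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- substring(sequence, idx[ok] + 1L, idx[ok] + 1L)
  names(out) <- names(idx)
  out
}

# Sliding Kyte-Doolittle hydropathy scan downstream of a position.
# Returns the 0-based half-open interval spanned by all windows whose mean
# hydropathy reaches `threshold`, or NULL.
scan_tm <- function(sequence, from = 0L, window = 19L, threshold = 1.6) {
  res <- str_residues(sequence)
  kd <- unname(KYTE_DOOLITTLE[res])
  kd[is.na(kd)] <- 0
  n <- length(kd)
  if (n - from < window) return(NULL)
  means <- vapply(seq.int(from + 1L, n - window + 1L),
                  function(i) mean(kd[i:(i + window - 1L)]), numeric(1))
  pass <- which(means >= threshold)
  if (!length(pass)) return(NULL)
  starts <- from + pass - 1L           # 0-based starts
  c(min(starts), max(starts) + window)
}

#' Segment a protein chain into MHC-style domains
#'
#' Locates the membrane-proximal Ig-like C1-set domain by best frame
#' mapping, then walks upstream locating membrane-distal domains (at most
#' two), and finally scans downstream of the Ig domain for a transmembrane
#' segment with a sliding Kyte-Doolittle hydropathy window.  Signal peptides
#' are not modeled.
#'
#' @param sequence Protein string, length >= 80.
#' @param schema A `wcat_schema` supplying the frames.
#' @param min_score Confident-mapping threshold on the normalized alignment
#'   score (default 0.35, calibrated so that under 1% of shuffled consensi
#'   pass).
#' @param scoring See [default_scoring()].
#' @param chain_id Optional identifier recorded on the hits.
#' @return A `chain_architecture`: list with `domains` (ordered `domain_hit`
#'   list), `extracellular_domain_count`, `cptmcy_count` (0 or 1),
#'   `tm_interval` (0-based half-open or `NULL`) and `chain_id`.
#' @export
segment_chain <- function(sequence, schema, min_score = 0.35,
                          scoring = default_scoring(), chain_id = NA_character_) {
  check_protein(sequence)
  stopifnot(inherits(schema, "wcat_schema"))
  if (nchar(sequence) < 80L) wc_stop("sequence shorter than 80 residues")
  ig_frame <- schema$frames[["IG_C1"]]
  if (is.null(ig_frame)) wc_stop("schema defines no IG_C1 frame")

  ig <- align_frame(sequence, ig_frame, scoring, type = "global-local",
                    chain_id = chain_id)
  if (ig$score < min_score) {
    wc_stop("not MHC-like: no Ig C1 mapping above threshold (best score ",
            sprintf("%.3f", ig$score), ")")
  }

  distal_frames <- schema$frames[intersect(c("DISTAL_A1TYPE", "DISTAL_A2TYPE"),
                                           names(schema$frames))]
  distals <- list()
  region_end <- ig$query_interval[1L]
  while (length(distals) < 2L && region_end > 0L) {
    # cheap score-only pre-scan picks the frame; only the winner is aligned
    # in full for its position map
    pre <- numeric(0)
    for (fr in distal_frames) {
      if (region_end < 0.4 * fr$length) next
      pre[fr$name] <- align_frame_score(sequence, fr, scoring,
                                        type = "global-local",
                                        region = c(0L, region_end))
    }
    pre <- pre[pre >= min_score]
    if (!length(pre)) break
    cand <- lapply(names(pre), function(fn)
      align_frame(sequence, schema$frames[[fn]], scoring,
                  type = "global-local", region = c(0L, region_end),
                  chain_id = chain_id))
    # take the downstream-most confident hit so a second distal domain can
    # still be found upstream of it; break ties by score
    ends <- vapply(cand, function(h) h$query_interval[2L], numeric(1))
    scores <- vapply(cand, function(h) h$score, numeric(1))
    best <- cand[[order(-ends, -scores)[1L]]]
    distals <- c(list(best), distals)
    region_end <- best$query_interval[1L]
  }

  tm_interval <- scan_tm(sequence, from = ig$query_interval[2L])
  structure(list(chain_id = chain_id,
                 domains = c(distals, list(ig)),
                 extracellular_domain_count = length(distals) + 1L,
                 cptmcy_count = if (is.null(tm_interval)) 0L else 1L,
                 tm_interval = tm_interval),
            class = "chain_architecture")
}

#' @export
print.chain_architecture <- function(x, ...) {
  cat("<chain_architecture>", if (!is.na(x$chain_id)) x$chain_id else "",
      "\n  extracellular domains:", x$extracellular_domain_count,
      "| CP/TM/CY regions:", x$cptmcy_count, "\n")
  for (d in x$domains) {
    cat(sprintf("  %-14s [%d,%d) score %.3f\n", d$frame,
                d$query_interval[1L], d$query_interval[2L], d$score))
  }
  if (!is.null(x$tm_interval)) {
    cat(sprintf("  TM segment     [%d,%d)\n", x$tm_interval[1L], x$tm_interval[2L]))
  }
  invisible(x)
}

#' Summarize an assembled multi-chain molecule
#'
#' A class I molecule (heavy chain + b2m) has one CP/TM/CY region; a class
#' II-type molecule (alpha + beta chain) has two.
#'
#' @param ... `chain_architecture` objects, one per chain.
#' @return List with `n_chains`, `extracellular_domain_count` (summed over
#'   chains) and `cptmcy_count` (summed).
#' @export
assemble_molecule <- function(...) {
  chains <- list(...)
  stopifnot(length(chains) > 0L,
            all(vapply(chains, inherits, logical(1), "chain_architecture")))
  list(n_chains = length(chains),
       extracellular_domain_count =
         sum(vapply(chains, `[[`, integer(1), "extracellular_domain_count")),
       cptmcy_count = sum(vapply(chains, `[[`, integer(1), "cptmcy_count")))
}

#' Tabulate domain intervals and scores for a set of architectures
#'
#' @param architectures List of `chain_architecture`.
#' @return data.frame with one row per domain hit (plus TM rows), suitable
#'   for writing as TSV.
#' @export
architecture_table <- function(architectures) {
  rows <- lapply(architectures, function(a) {
    d <- do.call(rbind, lapply(a$domains, function(h) {
      data.frame(chain_id = a$chain_id, feature = h$frame,
                 start = h$query_interval[1L], end = h$query_interval[2L],
                 score = h$score, stringsAsFactors = FALSE)
    }))
    if (!is.null(a$tm_interval)) {
      d <- rbind(d, data.frame(chain_id = a$chain_id, feature = "TM_SEGMENT",
                               start = a$tm_interval[1L], end = a$tm_interval[2L],
                               score = NA_real_, stringsAsFactors = FALSE))
    }
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
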