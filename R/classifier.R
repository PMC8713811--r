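#' @include domain_mapper.R
NULL

#' Score a mapped domain against the signature schema
#'
#' For each chain class, the score is the weight of matched signatures over
#' the weight of signatures readable at non-gap columns of this domain's
#' frame.  Classes with no readable signature in the frame are flagged
#' (zero coverage) and scored 0; a warning is emitted when a class has
#' signatures in the frame but every one falls on a gapped column.
#'
#' @param hit A `domain_hit` with a confident mapping.
#' @param sequence The chain's protein string (the hit's query).
#' @param schema A `wcat_schema`.
#' @return Named numeric vector over the six chain classes, with attributes
#'   `readable_weight` (named vector; 0 marks zero coverage) and `evidence`
#'   (data.frame of per-signature observations).
#' @export
score_domain <- function(hit, sequence, schema) {
  stopifnot(inherits(hit, "domain_hit"), inherits(schema, "wcat_schema"))
  ev <- signature_evidence(hit, sequence, schema, classes = CHAIN_CLASSES)
  scores <- setNames(numeric(length(CHAIN_CLASSES)), CHAIN_CLASSES)
  readable <- scores
  for (cls in CHAIN_CLASSES) {
    rows <- ev[ev$chain_class == cls & ev$readable, , drop = FALSE]
    readable[cls] <- sum(rows$weight)
    if (readable[cls] > 0) scores[cls] <- sum(rows$weight[rows$matched]) / readable[cls]
  }
  defined <- table(factor(schema$signatures$chain_class[
    schema$signatures$frame == hit$frame], levels = CHAIN_CLASSES))
  starved <- CHAIN_CLASSES[defined > 0 & readable == 0]
  if (length(starved)) {
    warning("zero readable signature coverage in frame ", hit$frame,
            " for class(es): ", paste(starved, collapse = ", "), call. = FALSE)
  }
  attr(scores, "readable_weight") <- readable
  attr(scores, "evidence") <- ev
  scores
}

# Per-signature observations of one domain hit.
signature_evidence <- function(hit, sequence, schema, classes) {
  sigs <- schema$signatures[schema$signatures$frame == hit$frame &
                              schema$signatures$chain_class %in% classes, ,
                            drop = FALSE]
  if (!nrow(sigs)) {
    return(data.frame(source = character(0), frame = character(0),
                      position = integer(0), chain_class = character(0),
                      expected = character(0), observed = character(0),
                      readable = logical(0), matched = logical(0),
                      weight = numeric(0)))
  }
  obs <- observed_residues(hit, sequence)
  col <- as.character(sigs$position)
  observed <- unname(obs[col])
  readable <- !is.na(observed)
  matched <- readable & mapply(function(o, allowed) o %in% str_residues(allowed),
                               observed, sigs$allowed_residues)
  data.frame(source = "signature", frame = sigs$frame, position = sigs$position,
             chain_class = sigs$chain_class, expected = sigs$allowed_residues,
             observed = ifelse(readable, observed, NA_character_),
             readable = readable, matched = as.logical(matched),
             weight = sigs$weight, stringsAsFactors = FALSE)
}

# Glycine-spacing evidence for a class's TM pattern inside the detected
# hydrophobic segment.  The hydropathy scan yields an interval, not a
# column-level map, so the pattern is matched by the spacing between its
# glycine positions rather than by absolute frame columns.
tm_evidence <- function(architecture, sequence, schema, classes) {
  rows <- list()
  for (cls in classes) {
    pat <- schema$tm_glycine_patterns[[cls]]
    if (is.null(pat) || length(pat) < 2L) next
    spacing <- diff(sort(pat))
    readable <- TRUE
    matched <- FALSE
    if (architecture$cptmcy_count == 1L) {
      tm <- architecture$tm_interval
      seg <- str_residues(substr(sequence, tm[1L] + 1L, tm[2L]))
      g <- which(seg == "G")
      if (length(g) >= 2L) {
        gaps <- outer(g, g, `-`)
        matched <- all(spacing %in% gaps)
      }
    }
    rows[[cls]] <- data.frame(source = "tm_glycine", frame = "TM",
                              position = NA_integer_, chain_class = cls,
                              expected = paste0("G-spacing ", paste(spacing, collapse = ",")),
                              observed = NA_character_, readable = readable,
                              matched = matched, weight = 1,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Presence/absence evidence for distal indel-signature regions.
indel_evidence <- function(architecture, schema, classes) {
  reg <- schema$indel_regions
  if (!nrow(reg)) return(NULL)
  rows <- list()
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    hit <- Filter(function(h) h$frame == r$frame, architecture$domains)
    if (!length(hit)) next
    pmap <- hit[[1L]]$position_map
    cols <- as.character(seq.int(r$start_column, r$end_column))
    present <- mean(!is.na(pmap[cols])) >= 0.5
    for (cls in classes) {
      expects_present <- cls %in% r$present_in[[1L]]
      expects_absent <- cls %in% r$absent_in[[1L]]
      if (!expects_present && !expects_absent) next
      rows[[length(rows) + 1L]] <- data.frame(
        source = "indel_region", frame = r$frame, position = r$start_column,
        chain_class = cls,
        expected = if (expects_present) "region present" else "region absent",
        observed = if (present) "present" else "absent",
        readable = TRUE, matched = (expects_present == present),
        weight = 1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

architecture_allowed_classes <- function(architecture) {
  switch(as.character(architecture$extracellular_domain_count),
         "3" = "I_HEAVY", "1" = "B2M",
         "2" = c("IIA", "IIB", "WA", "WB"),
         character(0))
}

#' Classify a segmented chain into one of the six chain classes
#'
#' Combines (i) architecture gating — three extracellular domains restrict
#' the call to a class I heavy chain, one to b2m, two to the class II /
#' W-category chains; (ii) weighted signature scores over all mapped
#' domains; (iii) TM glycine patterns and distal indel-region
#' presence/absence as additive evidence.  The label is the arg-max class
#' if its margin over the runner-up reaches `tau`, else `UNKNOWN`.  When
#' gating leaves a single candidate class the margin is that class's score
#' itself.
#'
#' @param architecture A `chain_architecture` from [segment_chain()].
#' @param sequence The chain's protein string.
#' @param schema A `wcat_schema`.
#' @param tau Margin threshold (default 0.15).
#' @return A `chain_call`: list with `chain_id`, `label`, `margin`, `scores`
#'   (all six classes; classes incompatible with the architecture are
#'   reported but never labeled), `gated_classes`, `evidence` data.frame,
#'   `architecture`, `sequence`.
#' @export
classify_chain <- function(architecture, sequence, schema, tau = 0.15) {
  stopifnot(inherits(architecture, "chain_architecture"),
            inherits(schema, "wcat_schema"))
  check_protein(sequence)
  allowed <- architecture_allowed_classes(architecture)
  if (!length(allowed)) wc_stop("not MHC-like: unsupported domain count")

  ev <- list()
  for (hit in architecture$domains) {
    ev[[length(ev) + 1L]] <- signature_evidence(hit, sequence, schema, CHAIN_CLASSES)
  }
  ev[[length(ev) + 1L]] <- tm_evidence(architecture, sequence, schema, CHAIN_CLASSES)
  ev[[length(ev) + 1L]] <- indel_evidence(architecture, schema, CHAIN_CLASSES)
  ev <- do.call(rbind, Filter(Negate(is.null), ev))

  scores <- setNames(numeric(length(CHAIN_CLASSES)), CHAIN_CLASSES)
  for (cls in CHAIN_CLASSES) {
    rows <- ev[ev$chain_class == cls & ev$readable, , drop = FALSE]
    w <- sum(rows$weight)
    if (w > 0) scores[cls] <- sum(rows$weight[rows$matched]) / w
  }

  gated <- sort(scores[allowed], decreasing = TRUE)
  top <- names(gated)[1L]
  runner <- if (length(gated) > 1L) gated[2L] else 0
  margin <- unname(gated[1L] - runner)
  label <- if (margin >= tau) top else "UNKNOWN"
  structure(list(chain_id = architecture$chain_id, label = label,
                 margin = margin, scores = scores, gated_classes = allowed,
                 tau = tau, evidence = ev, architecture = architecture,
                 sequence = sequence),
            class = "chain_call")
}

#' @export
print.chain_call <- function(x, ...) {
  cat("<chain_call>", if (!is.na(x$chain_id)) x$chain_id else "", "->", x$label,
      sprintf("(margin %.3f)\n", x$margin))
  s <- sort(x$scores, decreasing = TRUE)
  cat("  scores:", paste(sprintf("%s=%.2f", names(s), s), collapse = " "), "\n")
  cat("  gated to:", paste(x$gated_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a set of chains
#'
#' Convenience wrapper: segments and classifies each sequence, mapping
#' chains that fail segmentation ("not MHC-like") to label `UNKNOWN`.
#'
#' @param sequences Named character vector or `AAStringSet`.
#' @param schema A `wcat_schema`.
#' @param tau Margin threshold, see [classify_chain()].
#' @param min_score Confident-mapping threshold, see [segment_chain()].
#' @return List with `calls` (list of `chain_call` or `NULL` for unmappable
#'   chains) and `table` (one row per chain: chain_id, label, margin, note).
#' @export
classify_sequences <- function(sequences, schema, tau = 0.15, min_score = 0.35) {
  if (methods::is(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("chain_%03d", seq_along(sequences))
  }
  calls <- vector("list", length(sequences))
  names(calls) <- names(sequences)
  rows <- lapply(names(sequences), function(id) {
    res <- tryCatch({
      arch <- segment_chain(sequences[[id]], schema, min_score = min_score,
                            chain_id = id)
      classify_chain(arch, sequences[[id]], schema, tau = tau)
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "chain_call")) {
      calls[[id]] <<- res
      data.frame(chain_id = id, label = res$label, margin = res$margin,
                 note = "", stringsAsFactors = FALSE)
    } else {
      data.frame(chain_id = id, label = "UNKNOWN", margin = NA_real_,
                 note = res, stringsAsFactors = FALSE)
    }
  })
  list(calls = calls, table = do.call(rbind, rows))
}

interface_names <- function() c("A1A2_B2M", "A1A2_A3", "A3_B2M")

get_hit <- function(call, frame) {
  hits <- Filter(function(h) h$frame == frame, call$architecture$domains)
  if (length(hits)) hits[[1L]] else NULL
}

observe_at <- function(call, frame, position) {
  hit <- get_hit(call, frame)
  if (is.null(hit)) return(NA_character_)
  unname(observed_residues(hit, call$sequence)[as.character(position)])
}

interface_check <- function(checks) {
  # checks: data.frame(frame, position, allowed, weight, observed)
  checks$readable <- !is.na(checks$observed)
  checks$matched <- checks$readable &
    mapply(function(o, a) !is.na(o) && o %in% str_residues(a),
           checks$observed, checks$allowed)
  checks
}

#' Type the three class I interdomain interfaces for an alpha/beta pair
#'
#' A class I molecule has three interdomain interfaces: alpha1alpha2/b2m,
#' alpha1alpha2/alpha3 and alpha3/b2m.  Each is typed from its diagnostic
#' residues: the alpha1alpha2/b2m interface from the alpha-chain Ig residues
#' L55, F/Y57, W61 plus the distal residues V30 (alpha1-type frame) and Q6,
#' A32, G35, D37 (alpha2-type frame); the alpha1alpha2/alpha3 interface from
#' the beta-chain Ig residue at position 61 (G is class I-like, the class II
#' diagnostic W61 is class II-like); the alpha3/b2m interface from the
#' beta-chain Ig P57 and alpha-chain Ig Y8.  An interface is
#' `CLASS_I_TYPE` when at least `min_frac` of its weighted class I
#' signatures match and the class II diagnostic (where one exists) is
#' absent, `CLASS_II_TYPE` when the class II diagnostic matches, and
#' `AMBIGUOUS` otherwise (including unreadable positions).
#'
#' @param alpha `chain_call` for the alpha-type chain (b2m, WA or IIA): a
#'   one- or two-domain chain whose Ig domain is alpha-type.
#' @param beta `chain_call` for the partner chain contributing the remaining
#'   distal and Ig domains (class I heavy chain, WB or IIB).
#' @param schema A `wcat_schema` (reserved for custom weights; the residue
#'   sets are fixed by the interface definitions).
#' @param min_frac Weighted match fraction required for `CLASS_I_TYPE`
#'   (default 2/3).
#' @return An `interface_report`: exactly three entries keyed
#'   `A1A2_B2M`, `A1A2_A3`, `A3_B2M`, each with `verdict`, `matched` and
#'   `unmatched` signature tables and the weighted match fraction.
#' @export
evaluate_interfaces <- function(alpha, beta, schema = default_schema(),
                                min_frac = 2 / 3) {
  stopifnot(inherits(alpha, "chain_call"), inherits(beta, "chain_call"))
  if (is.null(get_hit(alpha, "IG_C1")) || is.null(get_hit(beta, "IG_C1"))) {
    wc_stop("missing Ig mapping on alpha or beta chain")
  }
  if (alpha$architecture$extracellular_domain_count > 2L) {
    wc_stop("alpha chain must have one or two extracellular domains (b2m/WA/IIA-type)")
  }

  # V30 is read from whichever chain carries the alpha1-type distal domain
  # (the alpha chain for WA/IIA, the heavy chain for class I); the
  # alpha2-type distal residues likewise.
  from_either <- function(frame, position) {
    o <- observe_at(alpha, frame, position)
    if (is.na(o)) o <- observe_at(beta, frame, position)
    o
  }

  report <- list()

  c1 <- interface_check(data.frame(
    frame = c("IG_C1", "IG_C1", "IG_C1", "DISTAL_A1TYPE",
              "DISTAL_A2TYPE", "DISTAL_A2TYPE", "DISTAL_A2TYPE", "DISTAL_A2TYPE"),
    position = c(55L, 57L, 61L, 30L, 6L, 32L, 35L, 37L),
    allowed = c("L", "FY", "W", "V", "Q", "A", "G", "D"),
    weight = c(2, 2, 2, 1, 0.5, 2, 2, 2),
    observed = c(observe_at(alpha, "IG_C1", 55), observe_at(alpha, "IG_C1", 57),
                 observe_at(alpha, "IG_C1", 61), from_either("DISTAL_A1TYPE", 30),
                 from_either("DISTAL_A2TYPE", 6), from_either("DISTAL_A2TYPE", 32),
                 from_either("DISTAL_A2TYPE", 35), from_either("DISTAL_A2TYPE", 37)),
    stringsAsFactors = FALSE))
  w_read <- sum(c1$weight[c1$readable])
  frac1 <- if (w_read > 0) sum(c1$weight[c1$matched]) / w_read else 0
  report$A1A2_B2M <- list(
    verdict = if (w_read > 0 && frac1 >= min_frac) "CLASS_I_TYPE" else "AMBIGUOUS",
    fraction = frac1, matched = c1[c1$matched, ], unmatched = c1[!c1$matched, ])

  pos61 <- observe_at(beta, "IG_C1", 61)
  c2 <- interface_check(data.frame(
    frame = "IG_C1", position = 61L, allowed = "G", weight = 2,
    observed = pos61, stringsAsFactors = FALSE))
  report$A1A2_A3 <- list(
    verdict = if (is.na(pos61)) "AMBIGUOUS"
              else if (pos61 == "G") "CLASS_I_TYPE"
              else if (pos61 == "W") "CLASS_II_TYPE"
              else "AMBIGUOUS",
    fraction = if (isTRUE(pos61 == "G")) 1 else 0,
    matched = c2[c2$matched, ], unmatched = c2[!c2$matched, ])

  c3 <- interface_check(data.frame(
    frame = c("IG_C1", "IG_C1"), position = c(57L, 8L), allowed = c("P", "Y"),
    weight = c(2, 2),
    observed = c(observe_at(beta, "IG_C1", 57), observe_at(alpha, "IG_C1", 8)),
    stringsAsFactors = FALSE))
  w_read <- sum(c3$weight[c3$readable])
  frac3 <- if (w_read > 0) sum(c3$weight[c3$matched]) / w_read else 0
  report$A3_B2M <- list(
    verdict = if (w_read > 0 && frac3 >= min_frac) "CLASS_I_TYPE" else "AMBIGUOUS",
    fraction = frac3, matched = c3[c3$matched, ], unmatched = c3[!c3$matched, ])

  structure(list(alpha_id = alpha$chain_id, beta_id = beta$chain_id,
                 interfaces = report), class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat("<interface_report>", x$alpha_id, "+", x$beta_id, "\n")
  for (nm in names(x$interfaces)) {
    e <- x$interfaces[[nm]]
    cat(sprintf("  %-9s %-13s (weighted match %.2f)\n", nm, e$verdict, e$fraction))
  }
  invisible(x)
}
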