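#' Load and validate a signature schema
#'
#' A signature schema is the declarative description of everything the
#' classifier knows: canonical position frames (consensus residue per
#' column), diagnostic residue signatures with their chain-class
#' associations and weights, distal indel-signature regions, per-class
#' transmembrane glycine patterns, and the invariant Ig-superfamily
#' cysteine positions.  The packaged default schema
#' (`system.file("extdata", "default_schema.json", package = "wcategory")`)
#' encodes the residues that discriminate class I heavy chains, beta-2
#' microglobulin (b2m), class II alpha/beta and W-category WA/WB chains:
#' among them the b2m/WA-alpha2 tryptophan at Ig position 61, the class I
#' alpha3 / WB glycine at the same column, the IgSF-invariant tryptophan at
#' Ig position 37 (replaced by L37 in b2m and F/L37 in WA), the alpha3 P57
#' plus b2m/WA Y8 hydrogen-bond partners, and the distal-domain residues
#' V30, Q6, A32, G35 and D37.
#'
#' @param path Path to a schema JSON file.
#' @return An object of class `wcat_schema`: a list with elements `version`,
#'   `frames` (named list of `wcat_frame`), `signatures` (data.frame),
#'   `indel_regions` (data.frame), `tm_glycine_patterns` (named list of
#'   integer vectors) and `invariant_cysteine_positions`.
#' @seealso [default_schema()], [query_signatures()], [write_schema()]
#' @examples
#' schema <- default_schema()
#' query_signatures(schema, "IG_C1", 61)
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) wc_stop("schema file does not exist: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) wc_stop("schema parse failure: ", conditionMessage(e)))
  validate_schema(raw, path)
}

#' The packaged default signature schema
#'
#' @return A validated `wcat_schema` (see [load_schema()]).
#' @export
default_schema <- function() {
  load_schema(system.file("extdata", "default_schema.json",
                          package = "wcategory", mustWork = TRUE))
}

validate_schema <- function(raw, path = "<schema>") {
  bad <- function(...) wc_stop("schema validation failure in ", path, ": ", ...)
  for (key in c("frames", "signatures")) {
    if (is.null(raw[[key]]) || length(raw[[key]]) == 0L) bad("missing or empty '", key, "'")
  }

  frames <- list()
  for (fr in raw$frames) {
    if (is.null(fr$name) || is.null(fr$length) || is.null(fr$consensus)) {
      bad("frame entry missing name/length/consensus")
    }
    cons <- str_residues(fr$consensus)
    if (length(cons) != fr$length) {
      bad("frame ", fr$name, ": consensus has ", length(cons),
          " residues but declared length is ", fr$length)
    }
    if (!all(cons %in% AA_STANDARD)) {
      bad("frame ", fr$name, ": consensus contains non-standard residue ",
          paste(setdiff(cons, AA_STANDARD), collapse = ","))
    }
    frames[[fr$name]] <- structure(
      list(name = fr$name, length = as.integer(fr$length),
           consensus = fr$consensus,
           numbering_origin = as.integer(fr$numbering_origin %||% 1L)),
      class = "wcat_frame")
  }

  sigs <- do.call(rbind, lapply(raw$signatures, function(s) {
    data.frame(frame = s$frame, position = as.integer(s$position),
               allowed_residues = s$allowed_residues,
               chain_class = s$chain_class,
               role = s$role %||% "CORE",
               weight = as.numeric(s$weight %||% 1),
               stringsAsFactors = FALSE)
  }))
  for (i in seq_len(nrow(sigs))) {
    s <- sigs[i, ]
    fr <- frames[[s$frame]]
    if (is.null(fr)) bad("signature ", i, " (", s$chain_class, " ", s$frame, ":",
                         s$position, "): dangling frame reference '", s$frame, "'")
    if (s$position < fr$numbering_origin ||
        s$position > fr$numbering_origin + fr$length - 1L) {
      bad("signature ", i, " (", s$chain_class, "): position ", s$position,
          " outside frame ", s$frame)
    }
    res <- str_residues(s$allowed_residues)
    if (length(res) == 0L || !all(res %in% AA_STANDARD)) {
      bad("signature ", i, " (", s$chain_class, "): allowed_residues '",
          s$allowed_residues, "' not a non-empty set of standard residues")
    }
    if (!s$chain_class %in% ALL_CLASSES) bad("signature ", i, ": unknown chain class ", s$chain_class)
    if (!s$role %in% SIGNATURE_ROLES) bad("signature ", i, ": unknown role ", s$role)
    if (s$weight < 0) bad("signature ", i, ": negative weight")
  }
  key <- paste(sigs$frame, sigs$position, sigs$chain_class)
  if (anyDuplicated(key)) {
    bad("duplicate signature for (frame, position, chain_class): ",
        key[duplicated(key)][1L])
  }

  indels <- data.frame(frame = character(0), start_column = integer(0),
                       end_column = integer(0), provisional = logical(0))
  indels$present_in <- list(); indels$absent_in <- list()
  if (length(raw$indel_regions)) {
    indels <- do.call(rbind, lapply(raw$indel_regions, function(r) {
      d <- data.frame(frame = r$frame, start_column = as.integer(r$start_column),
                      end_column = as.integer(r$end_column),
                      provisional = isTRUE(r$provisional), stringsAsFactors = FALSE)
      d$present_in <- list(unlist(r$present_in))
      d$absent_in <- list(unlist(r$absent_in))
      d
    }))
    for (i in seq_len(nrow(indels))) {
      r <- indels[i, ]
      fr <- frames[[r$frame]]
      if (is.null(fr)) bad("indel region ", i, ": dangling frame reference '", r$frame, "'")
      if (r$start_column > r$end_column) bad("indel region ", i, ": start_column > end_column")
      if (r$start_column < fr$numbering_origin ||
          r$end_column > fr$numbering_origin + fr$length - 1L) {
        bad("indel region ", i, ": columns outside frame ", r$frame)
      }
      if (length(intersect(r$present_in[[1L]], r$absent_in[[1L]]))) {
        bad("indel region ", i, ": present_in and absent_in overlap")
      }
    }
  }

  tmg <- raw$tm_glycine_patterns %||% list()
  tmg_prov <- isTRUE(tmg$provisional)
  tmg$provisional <- NULL
  tmg <- lapply(tmg, function(x) as.integer(unlist(x)))
  tm_frame <- frames[["TM"]]
  for (cls in names(tmg)) {
    if (!cls %in% ALL_CLASSES) bad("tm_glycine_patterns: unknown chain class ", cls)
    if (is.null(tm_frame)) bad("tm_glycine_patterns given but no TM frame defined")
    if (any(tmg[[cls]] < 1L | tmg[[cls]] > tm_frame$length)) {
      bad("tm_glycine_patterns for ", cls, ": position outside TM frame")
    }
  }

  cys <- as.integer(unlist(raw$invariant_cysteine_positions %||% integer(0)))
  ig <- frames[["IG_C1"]]
  if (length(cys) && !is.null(ig) && any(cys < 1L | cys > ig$length)) {
    bad("invariant_cysteine_positions outside IG_C1 frame")
  }

  structure(list(version = raw$version %||% "unversioned",
                 frames = frames, signatures = sigs, indel_regions = indels,
                 tm_glycine_patterns = tmg,
                 tm_patterns_provisional = tmg_prov,
                 invariant_cysteine_positions = cys),
            class = "wcat_schema")
}

#' Write a schema back to JSON
#'
#' Round-trip companion of [load_schema()]: `load_schema(write_schema(s, f))`
#' reproduces `s` exactly.
#'
#' @param schema A `wcat_schema`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "wcat_schema"))
  frames <- lapply(unname(schema$frames), function(fr) {
    list(name = fr$name, length = fr$length, consensus = fr$consensus,
         numbering_origin = fr$numbering_origin)
  })
  sigs <- lapply(seq_len(nrow(schema$signatures)), function(i) {
    s <- schema$signatures[i, ]
    list(frame = s$frame, position = s$position,
         allowed_residues = s$allowed_residues, chain_class = s$chain_class,
         role = s$role, weight = s$weight)
  })
  indels <- lapply(seq_len(nrow(schema$indel_regions)), function(i) {
    r <- schema$indel_regions[i, ]
    list(frame = r$frame, start_column = r$start_column,
         end_column = r$end_column, present_in = I(r$present_in[[1L]]),
         absent_in = I(r$absent_in[[1L]]), provisional = r$provisional)
  })
  tmg <- schema$tm_glycine_patterns
  if (isTRUE(schema$tm_patterns_provisional)) tmg$provisional <- TRUE
  out <- list(version = schema$version, frames = frames, signatures = sigs,
              indel_regions = indels, tm_glycine_patterns = tmg,
              invariant_cysteine_positions = I(schema$invariant_cysteine_positions))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Query signatures at a frame column
#'
#' @param schema A `wcat_schema`.
#' @param frame Frame name (e.g. `"IG_C1"`).
#' @param position Frame column (1-based, in the frame's own numbering).
#' @return The subset of `schema$signatures` at that column (possibly with
#'   zero rows, e.g. for an out-of-range column).
#' @examples
#' # position 61 separates b2m/WA (W) from class I alpha3/WB (G) and IIB (W)
#' query_signatures(default_schema(), "IG_C1", 61)
#' @export
query_signatures <- function(schema, frame, position) {
  stopifnot(inherits(schema, "wcat_schema"))
  if (!frame %in% names(schema$frames)) wc_stop("unknown frame name: ", frame)
  out <- schema$signatures[schema$signatures$frame == frame &
                             schema$signatures$position == position, ]
  rownames(out) <- NULL
  out
}

frame_consensus <- function(schema, frame) {
  fr <- schema$frames[[frame]]
  if (is.null(fr)) wc_stop("unknown frame name: ", frame)
  fr$consensus
}

#' @export
print.wcat_schema <- function(x, ...) {
  cat("<wcat_schema> version", x$version, "\n")
  cat("  frames:", paste(sprintf("%s[%d]", names(x$frames),
                                 vapply(x$frames, `[[`, 1L, "length")),
                         collapse = ", "), "\n")
  cat("  signatures:", nrow(x$signatures), "over classes",
      paste(sort(unique(x$signatures$chain_class)), collapse = ", "), "\n")
  cat("  indel regions:", nrow(x$indel_regions),
      " | TM glycine patterns:", length(x$tm_glycine_patterns), "\n")
  invisible(x)
}

#' @export
print.wcat_frame <- function(x, ...) {
  cat("<wcat_frame>", x$name, "(", x$length, "columns, origin",
      x$numbering_origin, ")\n")
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}
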