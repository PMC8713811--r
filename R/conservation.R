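#' @include phylo.R
NULL

#' Per-column conservation profile of an alignment
#'
#' For every alignment column: the modal residue, the modal fraction (share
#' of non-gap residues equal to the mode) and the Shannon entropy in bits
#' over the residue frequencies.  Gaps are excluded column-wise (pairwise
#' deletion); all-gap columns are flagged and carry `NA` statistics.
#'
#' @param alignment Named character vector, `AAStringSet` or character
#'   matrix of >= 2 aligned sequences.
#' @return A `conservation_profile`: data.frame with columns `column`,
#'   `modal_residue`, `modal_fraction`, `entropy_bits`, `n_obs`, `all_gap`.
#' @export
column_conservation <- function(alignment) {
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2L) wc_stop("need at least 2 sequences")
  ncolm <- ncol(m)
  out <- data.frame(column = seq_len(ncolm), modal_residue = NA_character_,
                    modal_fraction = NA_real_, entropy_bits = NA_real_,
                    n_obs = 0L, all_gap = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncolm)) {
    col <- m[, j]
    col <- col[!col %in% GAP_CHARS]
    if (!length(col)) { out$all_gap[j] <- TRUE; next }
    tab <- table(col)
    freq <- as.numeric(tab) / length(col)
    out$modal_residue[j] <- names(tab)[which.max(tab)]
    out$modal_fraction[j] <- max(freq)
    out$entropy_bits[j] <- -sum(freq * log2(freq))
    out$n_obs[j] <- length(col)
  }
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Compare two conservation profiles at designated positions
#'
#' Pearson correlation of the modal fractions of the two profiles over a
#' shared set of positions (e.g. groove positions of the MHC ligand-binding
#' superstructure; the position list is user-supplied).
#'
#' @param p1,p2 `conservation_profile`s on a shared column coordinate frame.
#' @param positions At least 3 column indices present in both profiles.
#' @return Correlation in `[-1, 1]`, or `NA` with attribute
#'   `flag = "undefined"` and a warning when either profile is constant over
#'   the positions.
#' @export
compare_profiles <- function(p1, p2, positions) {
  stopifnot(inherits(p1, "conservation_profile"),
            inherits(p2, "conservation_profile"))
  positions <- as.integer(positions)
  if (length(positions) < 3L) wc_stop("need at least 3 positions")
  if (!all(positions %in% p1$column) || !all(positions %in% p2$column)) {
    wc_stop("positions outside the shared column frame")
  }
  x <- p1$modal_fraction[match(positions, p1$column)]
  y <- p2$modal_fraction[match(positions, p2$column)]
  if (anyNA(x) || anyNA(y)) wc_stop("all-gap column among the requested positions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant profile over the requested positions; correlation undefined",
            call. = FALSE)
    return(structure(NA_real_, flag = "undefined"))
  }
  stats::cor(x, y)
}
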