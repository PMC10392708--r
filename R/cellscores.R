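#' Raw marker-gene cell type scores
#'
#' The raw score of a cell type in a sample is the arithmetic mean of the
#' log2 expression of that type's marker genes. Markers absent from the
#' matrix are dropped with a warning; a cell type losing all of its
#' markers is an error.
#'
#' @param merged_log2 an [expr_matrix()] with `scale = "log2"` (typically
#'   the merged panel after [log2_transform()]).
#' @param map marker map: data.frame with `cell_type` and `gene` columns,
#'   or a named list of marker gene vectors.
#' @return Numeric matrix, cell type x sample.
#' @export
raw_cell_scores <- function(merged_log2, map) {
  stopifnot(inherits(merged_log2, "expr_matrix"))
  if (merged_log2$scale != "log2")
    stopf("expression must be on the log2 scale")
  ml <- if (is.data.frame(map)) marker_list(map) else map
  x <- merged_log2$values
  out <- matrix(NA_real_, length(ml), ncol(x),
                dimnames = list(names(ml), colnames(x)))
  for (ct in names(ml)) {
    present <- intersect(ml[[ct]], rownames(x))
    dropped <- setdiff(ml[[ct]], present)
    if (length(dropped))
      warnf("cell type '%s': dropping %d missing marker(s): %s", ct,
            length(dropped), paste(dropped, collapse = ", "))
    if (!length(present))
      stopf("cell type '%s' has no markers in the expression matrix", ct)
    out[ct, ] <- colMeans(x[present, , drop = FALSE])
  }
  out
}

#' Total tumor-infiltrating lymphocyte (TIL) score
#'
#' Per-sample average of the raw scores of the five TIL components
#' (B cells, T cells, CD45, macrophages, cytotoxic cells).
#'
#' @param raw raw score matrix from [raw_cell_scores()].
#' @return Named numeric vector, one TIL score per sample.
#' @export
til_score <- function(raw) {
  missing <- setdiff(TIL_COMPONENTS, rownames(raw))
  if (length(missing))
    stopf("TIL components missing from raw scores: %s",
          paste(missing, collapse = ", "))
  colMeans(raw[TIL_COMPONENTS, , drop = FALSE])
}

#' Relative (ratio) cell type scores
#'
#' The relative score of a cell type against a denominator is the
#' log2-space ratio: the raw score minus the denominator score, where
#' the denominator is the TIL composite or another cell subset's raw
#' score. Since raw scores are log2 averages, the difference is the log2
#' of the ratio of the marker geometric means.
#'
#' @param raw raw score matrix from [raw_cell_scores()].
#' @param til TIL vector from [til_score()].
#' @param pairs data.frame with columns `numerator` (a cell type) and
#'   `denominator` (`"TIL"` or a cell type), one row per requested
#'   relative score.
#' @return Numeric matrix, one row per pair (named
#'   `"numerator|denominator"`) x sample.
#' @export
relative_scores <- function(raw, til, pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("numerator", "denominator") %in% names(pairs)))
  out <- matrix(NA_real_, nrow(pairs), ncol(raw),
                dimnames = list(paste(pairs$numerator, pairs$denominator,
                                      sep = "|"),
                                colnames(raw)))
  for (i in seq_len(nrow(pairs))) {
    num <- pairs$numerator[i]; den <- pairs$denominator[i]
    if (!num %in% rownames(raw)) stopf("unknown cell type '%s'", num)
    d <- if (den == "TIL") til
    else if (den %in% rownames(raw)) raw[den, ]
    else stopf("unknown denominator '%s'", den)
    out[i, ] <- raw[num, ] - d
  }
  out
}

#' Center scores across the cohort
#'
#' Subtracts each row's cohort mean, so every (cell type, denominator)
#' row averages zero — the form used for cross-sample score comparisons.
#'
#' @param relative matrix of relative scores (rows = scores).
#' @return The row-centered matrix.
#' @export
center_scores <- function(relative) {
  if (ncol(relative) < 2) stopf("centering needs at least 2 samples")
  sweep(relative, 1, rowMeans(relative))
}

#' Compute the full cell score table
#'
#' Raw scores, TIL composite, relative scores for the requested pairs
#' (default: every cell type vs TIL, plus CD8 vs exhausted CD8), and the
#' centered relative scores.
#'
#' @inheritParams raw_cell_scores
#' @param pairs as in [relative_scores()]; NULL for the default set.
#' @return List of class `cell_scores`: `raw`, `til`, `relative`,
#'   `centered`, `pairs`.
#' @export
cell_scores <- function(merged_log2, map, pairs = NULL) {
  raw <- raw_cell_scores(merged_log2, map)
  til <- til_score(raw)
  if (is.null(pairs)) {
    pairs <- data.frame(numerator = rownames(raw), denominator = "TIL",
                        stringsAsFactors = FALSE)
    if (all(c("CD8 T cells", "exhausted CD8") %in% rownames(raw)))
      pairs <- rbind(pairs, data.frame(numerator = "CD8 T cells",
                                       denominator = "exhausted CD8"))
  }
  rel <- relative_scores(raw, til, pairs)
  structure(list(raw = raw, til = til, relative = rel,
                 centered = center_scores(rel), pairs = pairs),
            class = "cell_scores")
}

#' @export
print.cell_scores <- function(x, ...) {
  cat(sprintf("cell_scores: %d cell types, %d samples, %d relative scores\n",
              nrow(x$raw), ncol(x$raw), nrow(x$relative)))
  invisible(x)
}
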