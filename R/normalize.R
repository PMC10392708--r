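#' Rank candidate reference genes by geNorm expression stability
#'
#' Implements the geNorm stability measure on log2 expression: for each
#' candidate j, `M_j` is the mean over all other candidates k of the
#' sample SD of the pairwise log-ratio `A_jk = log2 x_j - log2 x_k`.
#' Candidates are eliminated one at a time (highest M first, ties broken
#' toward the later input position), yielding a stability ranking.
#' The pairwise variation `V(n, n+1)` is the sample SD, across samples,
#' of the change in the log2 normalization factor (mean of the top-n
#' candidates' log2 values) when the (n+1)-th ranked gene is added. The
#' selected reference set is the smallest `n >= min_refs` with
#' `V(n, n+1) < v_threshold`; if no n qualifies, all candidates are kept.
#'
#' @param log2_expr numeric matrix, candidate genes x samples, log2 scale.
#' @param min_refs minimum number of reference genes to keep (>= 2).
#' @param v_threshold pairwise-variation cutoff (geNorm convention 0.15).
#' @return A list of class `genorm_result`: `m_values` (first-round M per
#'   candidate, input order), `ranking` (genes, most to least stable),
#'   `pairwise_variation` (named vector, `V(n,n+1)` for n = 2..K-1),
#'   `selected` (final reference gene list).
#' @examples
#' x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 3, 4, 5), g3 = c(1, 1, 1, 1))
#' colnames(x) <- paste0("s", 1:4)
#' genorm_stability(x)$m_values
#' @export
genorm_stability <- function(log2_expr, min_refs = 3, v_threshold = 0.15) {
  if (!is.matrix(log2_expr) || nrow(log2_expr) < 3)
    stopf("geNorm needs at least 3 candidate genes")
  if (ncol(log2_expr) < 2) stopf("geNorm needs at least 2 samples")
  if (any(!is.finite(log2_expr))) stopf("log2 expression must be finite")
  if (is.null(rownames(log2_expr)))
    rownames(log2_expr) <- paste0("gene", seq_len(nrow(log2_expr)))
  genes <- rownames(log2_expr)

  m_of <- function(idx) {
    vapply(idx, function(j) {
      others <- setdiff(idx, j)
      mean(vapply(others, function(k)
        stats::sd(log2_expr[j, ] - log2_expr[k, ]), numeric(1)))
    }, numeric(1))
  }

  m_first <- m_of(seq_along(genes))
  names(m_first) <- genes

  remaining <- seq_along(genes)
  elim_order <- integer(0)
  while (length(remaining) > 2) {
    m <- m_of(remaining)
    # ties broken toward the later input position so a fully constant
    # matrix ranks candidates in input order
    worst <- remaining[max(which(m == max(m)))]
    elim_order <- c(elim_order, worst)
    remaining <- setdiff(remaining, worst)
  }
  ranking_idx <- c(remaining, rev(elim_order))
  ranking <- genes[ranking_idx]

  K <- length(genes)
  pv <- numeric(0)
  if (K >= 3) {
    nf <- function(n) colMeans(log2_expr[ranking_idx[seq_len(n)], ,
                                         drop = FALSE])
    pv <- vapply(2:(K - 1), function(n) stats::sd(nf(n + 1) - nf(n)),
                 numeric(1))
    names(pv) <- paste0("V", 2:(K - 1), "/", 3:K)
  }

  selected <- genes[ranking_idx]
  cand_n <- seq(2, K - 1)
  ok <- cand_n >= min_refs & pv < v_threshold
  if (any(ok)) selected <- ranking[seq_len(min(cand_n[ok]))]

  structure(list(m_values = m_first, ranking = ranking,
                 pairwise_variation = pv, selected = selected),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability ranking (most to least stable):\n ",
      paste(x$ranking, collapse = ", "), "\n")
  cat(sprintf("selected %d reference genes: %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Normalize raw counts to panel reference genes
#'
#' Per-sample scaling to the panel's reference (housekeeping) genes:
#' with `g_s` the geometric mean of the reference genes in sample s
#' (computed on counts + 0.5), the factor is
#' `f_s = mean(g) / g_s`, so samples with low reference content are
#' scaled up. All counts in the sample are multiplied by `f_s`.
#' Samples whose reference geometric mean falls below `qc_min` are
#' flagged as QC failures and excluded before the factors are computed.
#'
#' @param raw an [expr_matrix()] with `scale = "raw_counts"`.
#' @param refs character vector of reference gene names (subset of the
#'   matrix's genes), e.g. the `selected` slot of [genorm_stability()].
#' @param qc_min minimum reference geometric mean for a sample to pass
#'   QC.
#' @return An `expr_matrix` with `scale = "normalized"`; attributes
#'   `size_factors` (the applied `f_s`) and `qc_excluded` (names of
#'   dropped samples).
#' @export
housekeeping_normalize <- function(raw, refs, qc_min = 20) {
  stopifnot(inherits(raw, "expr_matrix"))
  if (raw$scale != "raw_counts") stopf("input must be raw counts")
  missing <- setdiff(refs, gene_names(raw))
  if (length(missing))
    stopf("reference genes not in matrix: %s",
          paste(missing, collapse = ", "))
  gm <- apply(raw$values[refs, , drop = FALSE] + 0.5, 2, geomean)
  fail <- gm < qc_min
  if (all(fail)) stopf("all samples failed reference-gene QC")
  if (any(fail))
    warnf("excluding %d sample(s) failing QC (reference geomean < %g): %s",
          sum(fail), qc_min, paste(names(gm)[fail], collapse = ", "))
  keep <- !fail
  f <- mean(gm[keep]) / gm[keep]
  out <- raw
  out$values <- sweep(raw$values[, keep, drop = FALSE], 2, f, `*`)
  out$scale <- "normalized"
  attr(out, "size_factors") <- f
  attr(out, "qc_excluded") <- names(gm)[fail]
  out
}

#' Merge two normalized panels via the common-probe geometric-mean ratio
#'
#' Scales the second panel onto the first using the ratio
#' `r = geomean(first common block) / geomean(second common block)`
#' computed over all common probes and all samples, multiplies every
#' value of the second panel by `r`, averages the common probes entrywise
#' across the two panels, and carries unique probes through (the second
#' panel's scaled by `r`). The merged gene set is the union.
#'
#' Entries that are nonpositive in either panel's common block are
#' excluded from the geometric means (with a warning); averaging of
#' common probes is done on the normalized linear scale.
#'
#' @param first,second normalized [expr_matrix()] objects over the same
#'   samples; `second` is the panel that gets rescaled.
#' @return A merged `expr_matrix` (`panel_id = "merged"`), with attribute
#'   `merge_ratio` = `r`.
#' @export
merge_panels <- function(first, second) {
  stopifnot(inherits(first, "expr_matrix"), inherits(second, "expr_matrix"))
  if (first$scale != "normalized" || second$scale != "normalized")
    stopf("both panels must be normalized before merging")
  if (!setequal(sample_names(first), sample_names(second)))
    stopf("panels have mismatched sample sets")
  second$values <- second$values[, sample_names(first), drop = FALSE]
  common <- intersect(gene_names(first), gene_names(second))
  if (!length(common)) stopf("no common probes between panels")
  cls1 <- structure(first$probe_class, names = gene_names(first))
  cls2 <- structure(second$probe_class, names = gene_names(second))
  if (!identical(unname(cls1[common]), unname(cls2[common])))
    stopf("common probes have conflicting probe classes")

  a <- first$values[common, , drop = FALSE]
  b <- second$values[common, , drop = FALSE]
  pos <- a > 0 & b > 0
  if (!any(pos)) stopf("no positive common-probe entries to form the ratio")
  if (!all(pos))
    warnf("%d nonpositive common-probe entries excluded from the ratio",
          sum(!pos))
  r <- geomean(a[pos]) / geomean(b[pos])

  scaled_b <- second$values * r
  uniq1 <- setdiff(gene_names(first), common)
  uniq2 <- setdiff(gene_names(second), common)
  merged <- rbind((a + scaled_b[common, , drop = FALSE]) / 2,
                  first$values[uniq1, , drop = FALSE],
                  scaled_b[uniq2, , drop = FALSE])
  out <- expr_matrix(merged,
                     probe_class = c(cls1[common], cls1[uniq1], cls2[uniq2]),
                     panel_id = "merged", scale = "normalized")
  attr(out, "merge_ratio") <- r
  out
}
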