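#' Per-gene two-group differential expression (Welch's t)
#'
#' For each gene on the merged log2 matrix, computes the log2 fold change
#' (mean of `group_a` minus mean of the reference `group_b`) and a
#' two-sided unequal-variance t p-value with Welch-Satterthwaite degrees
#' of freedom. Genes with zero variance in both groups and equal means
#' get p = 1.
#'
#' @param merged_log2 an [expr_matrix()] with `scale = "log2"`, or a
#'   numeric gene x sample matrix of log2 values.
#' @param groups factor/character of length `ncol`, two levels, labeling
#'   every sample.
#' @param ref which level is the baseline (group B); default the second
#'   level.
#' @param endogenous_only if TRUE (default) and an `expr_matrix` is
#'   supplied, housekeeping probes are dropped before testing.
#' @return A data.frame with columns `gene`, `log2fc`, `p_raw`.
#' @export
de_test <- function(merged_log2, groups, ref = NULL,
                    endogenous_only = TRUE) {
  if (inherits(merged_log2, "expr_matrix")) {
    if (merged_log2$scale != "log2")
      stopf("expression must be on the log2 scale")
    x <- merged_log2$values
    if (endogenous_only)
      x <- x[merged_log2$probe_class == "endogenous", , drop = FALSE]
  } else x <- as.matrix(merged_log2)
  groups <- as.factor(as.character(groups))
  if (length(groups) != ncol(x))
    stopf("labels must cover all %d samples", ncol(x))
  if (nlevels(groups) != 2) stopf("exactly two group levels required")
  ref <- ref %||% levels(groups)[2]
  if (!ref %in% levels(groups)) stopf("unknown reference group '%s'", ref)
  ga <- setdiff(levels(groups), ref)
  ia <- which(groups == ga); ib <- which(groups == ref)
  n1 <- length(ia); n2 <- length(ib)
  if (n1 < 2 || n2 < 2) stopf("each group needs at least 2 samples")

  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- rowSums((xa - m1)^2) / (n1 - 1)
  v2 <- rowSums((xb - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  tt <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate genes: no variance anywhere
  degen <- se2 == 0
  p[degen & lfc == 0] <- 1
  p[degen & lfc != 0] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  data.frame(gene = rownames(x), log2fc = unname(lfc),
             p_raw = unname(p), stringsAsFactors = FALSE)
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' FDR adjustment valid under arbitrary dependence: the step-up
#' Benjamini-Hochberg adjustment inflated by the harmonic-number factor
#' `c(m) = sum(1/i, i = 1..m)`.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @examples
#' adjust_by(c(0.01, 0.02, 0.04))  # 0.055 0.055 0.0733...
#' @export
adjust_by <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Classify differential expression results for a volcano plot
#'
#' Flags each gene `up` if `p_raw < p_thresh` and `log2fc > lfc_thresh`,
#' `down` if `p_raw < p_thresh` and `log2fc < -lfc_thresh`, else `ns`.
#'
#' @param results data.frame with `log2fc` and `p_raw` (as from
#'   [de_test()]).
#' @param p_thresh unadjusted p cutoff (default 0.05).
#' @param lfc_thresh absolute log2 fold-change cutoff (default 1).
#' @return The input with a `flag` column added.
#' @export
classify_volcano <- function(results, p_thresh = 0.05, lfc_thresh = 1) {
  if (p_thresh <= 0 || lfc_thresh <= 0) stopf("thresholds must be positive")
  sig <- results$p_raw < p_thresh
  results$flag <- ifelse(sig & results$log2fc > lfc_thresh, "up",
                  ifelse(sig & results$log2fc < -lfc_thresh, "down", "ns"))
  results
}

#' Run the full differential expression stage
#'
#' [de_test()] plus Benjamini-Yekutieli adjustment and volcano flags.
#'
#' @inheritParams de_test
#' @inheritParams classify_volcano
#' @return data.frame `gene`, `log2fc`, `p_raw`, `p_by`, `flag`, sorted
#'   by `p_raw`.
#' @export
run_de <- function(merged_log2, groups, ref = NULL, p_thresh = 0.05,
                   lfc_thresh = 1) {
  res <- de_test(merged_log2, groups, ref = ref)
  res$p_by <- adjust_by(res$p_raw)
  res <- classify_volcano(res, p_thresh, lfc_thresh)
  res[order(res$p_raw), c("gene", "log2fc", "p_raw", "p_by", "flag")]
}
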