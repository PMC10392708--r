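#' Construct an expression matrix
#'
#' Container for gene-by-sample values from a targeted expression panel.
#' Rows are probes (endogenous genes or housekeeping/reference genes),
#' columns are samples. The `scale` field tracks the processing state:
#' `"raw_counts"` (nonnegative integers straight off the instrument),
#' `"normalized"` (reference-gene scaled, linear scale), or `"log2"`.
#'
#' @param values numeric matrix with unique rownames (genes) and unique
#'   colnames (samples); finite, nonnegative for raw counts.
#' @param probe_class character vector, one of `"endogenous"` or
#'   `"housekeeping"` per gene (recycled if length 1).
#' @param panel_id single string identifying the panel / CodeSet.
#' @param scale one of `"raw_counts"`, `"normalized"`, `"log2"`.
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `probe_class`, `panel_id`, `scale`.
#' @examples
#' m <- matrix(rpois(20, 50), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' em <- expr_matrix(m, "endogenous", panel_id = "demo")
#' em
#' @export
expr_matrix <- function(values, probe_class, panel_id = "panel",
                        scale = c("raw_counts", "normalized", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene names in expression matrix")
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample names in expression matrix")
  if (any(!is.finite(values)))
    stopf("expression values must be finite")
  probe_class <- rep_len(as.character(probe_class), nrow(values))
  if (!all(probe_class %in% c("endogenous", "housekeeping")))
    stopf("probe_class must be 'endogenous' or 'housekeeping'")
  if (scale == "raw_counts" &&
      (any(values < 0) || any(values != round(values))))
    stopf("raw counts must be nonnegative integers")
  structure(
    list(values = values, probe_class = probe_class,
         panel_id = as.character(panel_id)[1], scale = scale),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [panel '%s', scale %s]\n",
              nrow(x$values), ncol(x$values), x$panel_id, x$scale))
  cat(sprintf("  endogenous: %d, housekeeping: %d\n",
              sum(x$probe_class == "endogenous"),
              sum(x$probe_class == "housekeeping")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_names <- function(em) rownames(em$values)
sample_names <- function(em) colnames(em$values)

#' Log2-transform an expression matrix
#'
#' Applies `log2(x + pseudocount)`. The pseudocount keeps zero counts
#' finite; 0.5 is the package-wide default used before any log or
#' geometric-mean computation on counts.
#'
#' @param em an [expr_matrix()] on a linear scale.
#' @param pseudocount nonnegative offset added before the log.
#' @return An `expr_matrix` with `scale = "log2"`.
#' @export
log2_transform <- function(em, pseudocount = 0.5) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale == "log2") stopf("matrix is already on the log2 scale")
  out <- em
  out$values <- log2(em$values + pseudocount)
  out$scale <- "log2"
  out
}

#' Write an expression matrix as CSV
#'
#' Plain-text dialect: a header comment line `# panel=<id> scale=<scale>`,
#' then columns `gene`, `probe_class`, and one column per sample.
#'
#' @param em an [expr_matrix()].
#' @param path output file path.
#' @export
write_expr_csv <- function(em, path) {
  stopifnot(inherits(em, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# panel=%s scale=%s", em$panel_id, em$scale), con)
  df <- data.frame(gene = gene_names(em), probe_class = em$probe_class,
                   em$values, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expr_csv()]
#'
#' @param path CSV file path.
#' @return An `expr_matrix`.
#' @export
read_expr_csv <- function(path) {
  header <- readLines(path, n = 1)
  panel_id <- "panel"; scale <- "raw_counts"
  if (startsWith(header, "#")) {
    kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
    for (item in kv) {
      p <- strsplit(item, "=", fixed = TRUE)[[1]]
      if (p[1] == "panel") panel_id <- p[2]
      if (p[1] == "scale") scale <- p[2]
    }
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), c("gene", "probe_class")),
                       drop = FALSE])
  rownames(vals) <- df$gene
  expr_matrix(vals, df$probe_class, panel_id = panel_id, scale = scale)
}
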