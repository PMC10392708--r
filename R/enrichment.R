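#' Read a GMT gene-set file
#'
#' Standard MSigDB exchange format: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within
#' a set are dropped; an empty file yields an empty collection with a
#' warning; a line with fewer than three fields is an error naming the
#' line.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warnf("empty GMT file: %s", path)
    return(list())
  }
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stopf("malformed GMT line %d: expected name, description, >=1 gene",
            i)
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' Hypergeometric overrepresentation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance within the universe: with `N` universe genes,
#' `K` set genes (after restriction to the universe), `n` query genes
#' and overlap `k`, the one-sided p-value is `P(X >= k)` for
#' `X ~ hypergeometric(N, K, n)`. Adjustment across sets is
#' Benjamini-Hochberg. Query and set genes outside the universe are
#' dropped.
#'
#' @param query character vector of genes of interest (e.g. the
#'   differentially expressed list).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector defining the testable gene space
#'   (e.g. the merged panel's endogenous genes).
#' @return data.frame sorted by p: `set`, `set_size` (K), `query_size`
#'   (n), `overlap` (k), `gene_ratio`, `p`, `p_adj`,
#'   `overlap_genes` (comma-joined).
#' @export
ora_test <- function(query, sets, universe) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (!length(query)) stopf("query is empty after universe intersection")
  N <- length(universe)
  n <- length(query)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    ov <- intersect(query, s)
    k <- length(ov); K <- length(s)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, query_size = n, overlap = k,
               gene_ratio = k / n, p = p,
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p), c("set", "set_size", "query_size", "overlap",
                             "gene_ratio", "p", "p_adj", "overlap_genes")]
  rownames(res) <- NULL
  res
}
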