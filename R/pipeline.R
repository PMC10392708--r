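#' Read a pipeline run configuration from YAML
#'
#' The file may contain a `synth:` block (fields of [synth_config()])
#' and top-level analysis settings (`p_thresh`, `lfc_thresh`,
#' `v_threshold`, `min_refs`, `qc_min`, `seed`).
#'
#' @param path YAML file path.
#' @return A list with `synth` (a `synth_config`) and the analysis
#'   settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  if (!is.null(y$seed)) synth_args$seed <- y$seed
  if (!is.null(synth_args$effect_map))
    synth_args$effect_map <- lapply(synth_args$effect_map, as.list)
  list(synth = do.call(synth_config, synth_args),
       p_thresh = y$p_thresh %||% 0.05,
       lfc_thresh = y$lfc_thresh %||% 1,
       v_threshold = y$v_threshold %||% 0.15,
       min_refs = y$min_refs %||% 3,
       qc_min = y$qc_min %||% 20)
}

# geNorm-select references among a panel's housekeeping genes, then
# normalize the panel to them.
normalize_panel <- function(panel, min_refs = 3, v_threshold = 0.15,
                            qc_min = 20, refs = NULL) {
  hk <- gene_names(panel)[panel$probe_class == "housekeeping"]
  if (is.null(refs)) {
    gn <- genorm_stability(log2(panel$values[hk, , drop = FALSE] + 0.5),
                           min_refs = min_refs, v_threshold = v_threshold)
    refs <- gn$selected
  } else gn <- NULL
  out <- housekeeping_normalize(panel, refs, qc_min = qc_min)
  attr(out, "genorm") <- gn
  attr(out, "refs") <- refs
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage: cohort generation, independent
#' reference-gene normalization of the two panels (geNorm selection
#' among each panel's housekeeping genes), panel merging, differential
#' expression by race with Benjamini-Yekutieli adjustment, cell type and
#' TIL-relative scoring, clinicopathologic group statistics, three-way
#' survival evaluation (continuous Cox, median split, Youden split) of
#' every relative score against both endpoints, and overrepresentation
#' analysis of the differentially expressed genes against the cell-type
#' marker sets. All randomness derives from the config's master seed, so
#' a rerun with the same config reproduces every output.
#'
#' @param config a [synth_config()], or the path of a YAML run config
#'   (see [read_run_config()]).
#' @param out optional output directory; when given, every stage writes
#'   its table there plus a `summary.json` report.
#' @param p_thresh,lfc_thresh volcano thresholds for [classify_volcano()].
#' @param v_threshold,min_refs geNorm settings per panel.
#' @param qc_min reference-geomean QC floor for sample exclusion.
#' @return List of class `tilscore_run`: `cohort`, `normalized` (both
#'   panels), `merged`, `de`, `scores`, `cohort_stats`, `survival`,
#'   `ora`, `summary`.
#' @export
run_pipeline <- function(config = synth_config(), out = NULL,
                         p_thresh = 0.05, lfc_thresh = 1,
                         v_threshold = 0.15, min_refs = 3, qc_min = 20) {
  if (is.character(config)) {
    rc <- read_run_config(config)
    return(run_pipeline(rc$synth, out = out, p_thresh = rc$p_thresh,
                        lfc_thresh = rc$lfc_thresh,
                        v_threshold = rc$v_threshold,
                        min_refs = rc$min_refs, qc_min = rc$qc_min))
  }
  stopifnot(inherits(config, "synth_config"))
  cohort <- synth_cohort(config)

  norm_a <- normalize_panel(cohort$panel_a, min_refs, v_threshold, qc_min)
  norm_b <- normalize_panel(cohort$panel_b, min_refs, v_threshold, qc_min)
  keep <- intersect(sample_names(norm_a), sample_names(norm_b))
  norm_a$values <- norm_a$values[, keep, drop = FALSE]
  norm_b$values <- norm_b$values[, keep, drop = FALSE]
  merged <- merge_panels(norm_a, norm_b)
  merged_log2 <- log2_transform(merged)
  clinical <- cohort$clinical[match(keep, cohort$clinical$sample), ]

  de <- run_de(merged_log2, clinical$race, ref = "CA",
               p_thresh = p_thresh, lfc_thresh = lfc_thresh)
  scores <- cell_scores(merged_log2, cohort$marker_map)

  stats_rows <- list()
  for (v in c("age_group", "psa_group", "gleason", "grade_group")) {
    tab <- table(clinical[[v]], clinical$race)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) >= 2 && all(colSums(tab) > 0)) {
      ft <- fisher_exact(as.matrix(tab))
      stats_rows[[length(stats_rows) + 1]] <-
        data.frame(variable = v, comparison = "AA vs CA",
                   method = "fisher", statistic = ft$statistic, p = ft$p)
    }
  }
  for (i in seq_len(nrow(scores$relative))) {
    nm <- rownames(scores$relative)[i]
    gt <- tryCatch(score_by_group(scores$relative[i, ], clinical$race),
                   error = function(e) NULL)
    if (!is.null(gt))
      stats_rows[[length(stats_rows) + 1]] <-
        data.frame(variable = nm, comparison = "AA vs CA",
                   method = gt$method, statistic = gt$statistic, p = gt$p)
  }
  cohort_stats <- do.call(rbind, stats_rows)

  surv_rows <- list()
  for (ep in c("bcr", "metastasis")) {
    tt <- clinical[[paste0("time_", ep)]]
    ee <- clinical[[paste0("event_", ep)]]
    for (i in seq_len(nrow(scores$relative))) {
      row <- survival_report_row(scores$relative[i, ], tt, ee,
                                 name = rownames(scores$relative)[i])
      row$endpoint <- ep
      surv_rows[[length(surv_rows) + 1]] <- row
    }
  }
  surv <- do.call(rbind, surv_rows)

  de_hits <- de$gene[de$p_raw < p_thresh]
  universe <- gene_names(merged_log2)[merged_log2$probe_class ==
                                        "endogenous"]
  ora <- if (length(intersect(de_hits, universe))) {
    ora_test(de_hits, marker_list(cohort$marker_map), universe)
  } else NULL

  summary <- list(
    seed = config$seed,
    n_samples = config$n_samples,
    n_samples_post_qc = length(keep),
    n_genes_merged = nrow(merged$values),
    refs_a = attr(norm_a, "refs"), refs_b = attr(norm_b, "refs"),
    merge_ratio = attr(merged, "merge_ratio"),
    n_de_raw = sum(de$p_raw < p_thresh),
    n_de_by = sum(de$p_by < 0.05),
    top_de = utils::head(de, 5),
    package_version = as.character(utils::packageVersion("tilscore")))

  res <- structure(
    list(cohort = cohort, normalized = list(a = norm_a, b = norm_b),
         merged = merged, de = de, scores = scores,
         cohort_stats = cohort_stats, survival = surv, ora = ora,
         summary = summary),
    class = "tilscore_run")

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_synth_cohort(cohort, file.path(out, "synth"))
    write_expr_csv(merged, file.path(out, "merged_counts.csv"))
    utils::write.table(de, file.path(out, "de_results.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.csv(
      data.frame(sample = colnames(scores$relative),
                 t(scores$relative), TIL = scores$til,
                 check.names = FALSE),
      file.path(out, "cell_scores.csv"), row.names = FALSE)
    utils::write.table(cohort_stats, file.path(out, "cohort_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(surv, file.path(out, "survival_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(ora))
      utils::write.table(ora, file.path(out, "ora_results.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.tilscore_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("tilscore pipeline run (seed %d)\n", s$seed))
  cat(sprintf("  samples: %d (%d post-QC), merged genes: %d\n",
              s$n_samples, s$n_samples_post_qc, s$n_genes_merged))
  cat(sprintf("  DE: %d genes at raw p < 0.05, %d at BY-adjusted < 0.05\n",
              s$n_de_raw, s$n_de_by))
  cat(sprintf("  survival report rows: %d\n", nrow(x$survival)))
  invisible(x)
}
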