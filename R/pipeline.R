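#' End-to-end pipeline configuration
#'
#' Bundles the per-stage parameters of the canonical workflow with their
#' defaults (Tweedie power 1.1, 25 expression bins, 100 control genes,
#' top-100 signature, FDR 0.05, Bonferroni 0.05, purity cutoff 0.8,
#' T-cell marker thresholds 3.0/3.5/2.5). All stage randomness derives
#' from `seed` by fixed per-stage offsets.
#'
#' @param anchor anchor gene symbol.
#' @param power Tweedie variance power.
#' @param top_n signature size.
#' @param n_bins pooled-expression bins.
#' @param n_controls control genes per signature gene.
#' @param fdr_max SCG FDR cutoff.
#' @param filter_threshold pooled-expression filter cutoff.
#' @param jackstraw_B jackstraw iterations.
#' @param use_weights apply dropout weights in the EDM stage.
#' @param min_cells per-patient minimum for the malignant meta-analysis.
#' @param seed master seed.
#' @export
pipeline_config <- function(anchor = "ANCHOR", power = 1.1, top_n = 100,
                            n_bins = 25, n_controls = 100, fdr_max = 0.05,
                            filter_threshold = 3, jackstraw_B = 1000,
                            use_weights = TRUE, min_cells = 30, seed = 1L) {
  as.list(environment())
}

#' Run the anchor co-expression workflow end to end
#'
#' Stages, in dependency order: pooled-expression QC filter, housekeeping
#' detection curves and reliability weights, malignant SCG discovery
#' (per-patient EDM + fixed-effect meta-analysis), binned-control
#' single-cell scoring, bulk projection of the signature, and — when bulk
#' data are supplied — the jackstraw association stage. Each stage's
#' table is written as TSV under `out_dir` together with a manifest
#' recording parameters, seeds and output checksums. A failure in any
#' stage halts the run with a stage-labeled error.
#'
#' @param sc_expr single-cell [expr_matrix()].
#' @param annotation cell annotation tibble.
#' @param config a [pipeline_config()].
#' @param housekeeping housekeeping gene symbols (optional; weights stage
#'   skipped when absent).
#' @param bulk_expr optional bulk [expr_matrix()].
#' @param out_dir optional output directory for stage TSVs + manifest.
#' @return list with `qc`, `pooled`, `weights`, `scg_stats`, `scg`,
#'   `score_sc`, `score_bulk`, `jackstraw`, `manifest`.
#' @export
run_pipeline <- function(sc_expr, annotation, config = pipeline_config(),
                         housekeeping = NULL, bulk_expr = NULL,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  res <- list(config = config)
  res$pooled <- stage("qc", compute_pooled_expression(sc_expr))
  res$qc <- stage("qc", filter_genes(sc_expr, res$pooled,
                                     threshold = config$filter_threshold,
                                     anchor = config$anchor))
  pooled_qc <- res$pooled[res$pooled$gene_id %in% rownames(res$qc), ]
  res$weights <- NULL
  if (!is.null(housekeeping)) {
    res$curves <- stage("weights",
                        fit_detection_curves(res$qc, housekeeping, pooled_qc))
    res$weights <- stage("weights",
                         compute_weights(res$qc, res$curves, pooled_qc))
  }
  cfg_edm <- edm_config(power = config$power, min_cells = config$min_cells,
                        use_weights = config$use_weights)
  res$scg_stats <- stage("scg",
    discover_scgs(res$qc, annotation, config$anchor,
                  cell_type = "malignant", weights = res$weights,
                  cfg = cfg_edm))
  res$scg <- stage("scg", select_scgs(res$scg_stats, top_n = config$top_n,
                                      fdr_max = config$fdr_max))
  bins <- stage("score", bin_genes(pooled_qc, n_bins = config$n_bins))
  res$score_sc <- stage("score",
    score_single_cell(res$qc, res$scg, bins,
                      n_controls = config$n_controls,
                      seed = config$seed + 101L))
  res$score_bulk <- NULL
  res$jackstraw <- NULL
  if (!is.null(bulk_expr)) {
    res$score_bulk <- stage("bulk_score", score_bulk(bulk_expr, res$scg))
    res$jackstraw <- stage("jackstraw",
      jackstraw_test(bulk_expr, z_transform(res$score_bulk),
                     B = config$jackstraw_B, seed = config$seed + 202L))
  }
  if (!is.null(out_dir)) {
    res$manifest <- write_pipeline_outputs(res, out_dir)
  }
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(as_tibble(as.data.frame(df)), p, progress = FALSE)
    paths[[name]] <<- p
  }
  put(res$pooled, "pooled_expression")
  put(res$scg_stats, "scg_stats")
  put(res$scg, "scg_top")
  put(res$score_sc, "score_single_cell")
  if (!is.null(res$score_bulk)) put(res$score_bulk, "score_bulk")
  if (!is.null(res$jackstraw)) put(res$jackstraw, "jackstraw")
  manifest <- list(
    package_version = as.character(utils::packageVersion("scganchor")),
    seed = res$config$seed,
    parameters = res$config,
    checksums = as.list(tools::md5sum(unlist(paths))))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  writeLines(format_manifest(manifest), manifest_path)
  manifest
}

# minimal flat YAML-ish rendering; values are atomic
format_manifest <- function(x, indent = 0) {
  pad <- strrep("  ", indent)
  unlist(purrr::imap(x, function(v, k) {
    if (is.list(v)) c(paste0(pad, k, ":"), format_manifest(v, indent + 1))
    else paste0(pad, k, ": ", paste(v, collapse = ", "))
  }))
}
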