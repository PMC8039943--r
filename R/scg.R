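#' Discover anchor-coexpressed genes for one cell type
#'
#' For malignant cells, the anchor association is fitted separately within
#' each patient contributing at least `cfg$min_cells` cells and the
#' per-patient coefficients are pooled by inverse-variance fixed-effect
#' meta-analysis; for every other cell type all cells of the type are
#' pooled into a single fit. BH FDRs are computed over the resulting
#' per-gene p-values.
#'
#' @param x single-cell [expr_matrix()] after QC.
#' @param annotation annotation tibble (see [read_annotations()]).
#' @param anchor anchor gene symbol.
#' @param cell_type one of the annotation cell types.
#' @param weights optional reliability weight matrix.
#' @param cfg an [edm_config()].
#' @return tibble with per-gene columns `gene_id`, `cell_type`, `beta`,
#'   `se`, `z`, `p`, `fdr` plus `k_studies` for the meta-analyzed case.
#' @export
discover_scgs <- function(x, annotation, anchor, cell_type = "malignant",
                          weights = NULL, cfg = edm_config()) {
  annotation <- validate_annotations(annotation)
  cells <- annotation$obs_id[annotation$cell_type == cell_type]
  cells <- intersect(cells, colnames(x))
  if (!length(cells)) abort(sprintf("no '%s' cells in the matrix", cell_type))
  if (cell_type == "malignant") {
    by_patient <- split(cells,
                        annotation$patient_id[match(cells, annotation$obs_id)])
    sizes <- lengths(by_patient)
    small <- names(sizes)[sizes < cfg$min_cells]
    if (length(small)) {
      inform(paste0("patients below min_cells excluded from meta-analysis: ",
                    paste(small, collapse = ", ")))
    }
    by_patient <- by_patient[sizes >= cfg$min_cells]
    if (!length(by_patient)) abort("no patient reaches min_cells")
    per <- purrr::imap(by_patient, function(cc, pid) {
      fit_all_genes(x, anchor, cells = cc, weights = weights, cfg = cfg) |>
        dplyr::mutate(patient_id = pid)
    })
    # vectorized inverse-variance pooling; identical to meta_fixed_effect()
    stats <- dplyr::bind_rows(per) |>
      dplyr::filter(is.finite(.data$beta), is.finite(.data$se),
                    .data$se > 0, .data$converged) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
                       se = 1 / sqrt(sum(1 / .data$se^2)),
                       k_studies = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(z = .data$beta / .data$se, p = 2 * pnorm(-abs(.data$z))) |>
      dplyr::select("gene_id", "beta", "se", "z", "p", "k_studies")
  } else {
    stats <- fit_all_genes(x, anchor, cells = cells, weights = weights,
                           cfg = cfg) |>
      dplyr::filter(is.na(.data$note) | .data$note == "non_convergence") |>
      dplyr::select("gene_id", "beta", "se", "z", "p")
  }
  stats |>
    dplyr::mutate(cell_type = cell_type, fdr = bh_fdr(.data$p),
                  .after = "gene_id")
}

#' Select the top anchor-coexpressed genes
#'
#' Keeps genes with a positive coefficient and FDR below `fdr_max`, ranks
#' them by ascending p-value (ties by descending |Z|, then gene symbol),
#' and truncates to `top_n`.
#'
#' @param stats association tibble from [discover_scgs()].
#' @param top_n signature size (default 100).
#' @param fdr_max FDR cutoff (default 0.05).
#' @return An `scg_set`: the ranked tibble (most significant first) with
#'   attributes `cell_type` and `top_n`. `scg_genes()` extracts the ranked
#'   symbols.
#' @export
select_scgs <- function(stats, top_n = 100, fdr_max = 0.05) {
  qual <- stats |>
    dplyr::filter(is.finite(.data$beta), .data$beta > 0,
                  is.finite(.data$fdr), .data$fdr < fdr_max) |>
    dplyr::arrange(.data$p, dplyr::desc(abs(.data$z)), .data$gene_id)
  if (!nrow(qual)) {
    abort(sprintf(
      "no qualifying genes (of %d tested: %d with beta > 0, min FDR %.3g)",
      nrow(stats), sum(stats$beta > 0, na.rm = TRUE),
      suppressWarnings(min(stats$fdr, na.rm = TRUE))))
  }
  if (nrow(qual) < top_n) {
    warn(sprintf("only %d genes qualify (top_n = %d); returning all",
                 nrow(qual), top_n))
  }
  out <- head(qual, top_n) |> dplyr::mutate(rank = dplyr::row_number())
  structure(out, class = c("scg_set", class(out)),
            cell_type = stats$cell_type[1] %||% NA_character_,
            top_n = top_n)
}

#' @rdname select_scgs
#' @param scg an `scg_set`.
#' @export
scg_genes <- function(scg) {
  if (inherits(scg, "scg_set") || is.data.frame(scg)) scg$gene_id
  else as.character(scg)
}

#' @export
print.scg_set <- function(x, ...) {
  cat(sprintf("<scg_set> %d anchor-coexpressed genes (%s cells)\n",
              nrow(x), attr(x, "cell_type")))
  NextMethod()
}
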