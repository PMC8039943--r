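#' Correct gene symbols against a reference map
#'
#' Applies a symbol correction map (e.g. alias -> approved HGNC symbol) to
#' the rownames of an expression matrix. Unmapped symbols pass through.
#' When a rename collides with an existing row, duplicates are collapsed
#' with [dedup_genes()] under `policy`.
#'
#' @param x an [expr_matrix()].
#' @param mapping data frame with columns `from`, `to` (one target per source).
#' @param policy collapse rule for collisions, see [dedup_genes()].
#' @return corrected [expr_matrix()].
#' @export
correct_symbols <- function(x, mapping,
                            policy = c("keep_max_total", "mean_aggregate")) {
  policy <- match.arg(policy)
  if (!all(c("from", "to") %in% names(mapping))) {
    abort("`mapping` needs columns 'from' and 'to'")
  }
  mapping <- dplyr::distinct(tibble(from = toupper(mapping$from),
                                    to = toupper(mapping$to)))
  multi <- mapping |> dplyr::count(.data$from) |> dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    abort(paste0("symbol map is one-to-many for: ",
                 paste(multi$from, collapse = ", ")))
  }
  if (!nrow(mapping)) return(x)
  genes <- rownames(x)
  idx <- match(genes, mapping$from)
  genes[!is.na(idx)] <- mapping$to[idx[!is.na(idx)]]
  m <- unclass(x)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    dedup_genes(m, policy = policy, scale_tag = expr_scale(x))
  } else {
    as_expr_matrix(m, expr_scale(x))
  }
}

#' Collapse duplicate gene rows
#'
#' `keep_max_total` retains, among rows sharing a symbol, the one with the
#' largest total expression (the single-cell convention of dropping
#' duplicate genes); `mean_aggregate` averages them (the microarray
#' probe-summarization convention).
#'
#' @param x matrix or [expr_matrix()] whose rownames may repeat.
#' @param policy `"keep_max_total"` or `"mean_aggregate"`.
#' @param scale_tag scale for the result when `x` is a bare matrix.
#' @return [expr_matrix()] with unique rownames, first-appearance order.
#' @export
dedup_genes <- function(x, policy = c("keep_max_total", "mean_aggregate"),
                        scale_tag = expr_scale(x)) {
  policy <- match.arg(policy)
  m <- unclass(as.matrix(x))
  genes <- rownames(m)
  if (is.null(genes)) abort("matrix must have gene rownames")
  if (!anyDuplicated(genes)) return(as_expr_matrix(m, scale_tag))
  keep_order <- unique(genes)
  if (policy == "keep_max_total") {
    tot <- rowSums(m, na.rm = TRUE)
    # stable: first row wins ties
    ord <- order(-tot, seq_along(tot))
    best <- ord[!duplicated(genes[ord])]
    out <- m[best[match(keep_order, genes[best])], , drop = FALSE]
  } else {
    out <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    out <- out[keep_order, , drop = FALSE]
  }
  rownames(out) <- keep_order
  as_expr_matrix(out, scale_tag)
}

#' Per-gene pooled expression
#'
#' Aggregates each gene over all observations on the linear TPM scale and
#' re-logs: `e_pooled = log2(mean(TPM) + 1)`. Single-cell values stored as
#' `log2(TPM/10 + 1)` are linearized as `TPM = 10 * (2^v - 1)`; bulk values
#' as `2^v - 1`. Missing bulk entries are excluded from the per-gene mean.
#'
#' @param x an [expr_matrix()] on a log2 scale.
#' @return tibble with columns `gene_id`, `e_pooled`.
#' @export
compute_pooled_expression <- function(x) {
  if (ncol(x) == 0) abort("zero observations")
  if (expr_scale(x) == "bulk_centered") {
    abort("pooled expression is undefined on centered values")
  }
  mult <- if (expr_scale(x) == "sc_log2_tpm10") 10 else 1
  lin <- mult * (2^unclass(x) - 1)
  tibble(gene_id = rownames(x),
         e_pooled = unname(log2(rowMeans(lin, na.rm = TRUE) + 1)))
}

#' Pooled-expression gene filter
#'
#' Excludes genes whose pooled expression falls below `threshold`
#' (default 3; the boundary value is retained). The anchor gene, when
#' given, is exempt and kept with a warning if it falls below threshold.
#'
#' @param x an [expr_matrix()].
#' @param pooled tibble from [compute_pooled_expression()] covering all genes.
#' @param threshold exclusion threshold in log2 units.
#' @param anchor optional anchor gene symbol, never filtered out.
#' @return filtered [expr_matrix()].
#' @export
filter_genes <- function(x, pooled = compute_pooled_expression(x),
                         threshold = 3, anchor = NULL) {
  ep <- pooled$e_pooled[match(rownames(x), pooled$gene_id)]
  if (anyNA(ep)) abort("`pooled` does not cover all genes in the matrix")
  keep <- ep >= threshold
  if (!is.null(anchor)) {
    anchor <- toupper(anchor)
    i <- match(anchor, rownames(x))
    if (is.na(i)) abort(sprintf("anchor gene '%s' absent from matrix", anchor))
    if (!keep[i]) {
      warn(sprintf("anchor '%s' has e_pooled %.3f < %g; retained anyway",
                   anchor, ep[i], threshold))
      keep[i] <- TRUE
    }
  }
  if (!any(keep)) abort("all genes removed by the pooled-expression filter")
  as_expr_matrix(unclass(x)[keep, , drop = FALSE], expr_scale(x))
}

#' Marker thresholds for T-cell subtype classification
#'
#' Log2-expression cutoffs: CD8 T cells need mean(CD8A, CD8B) above
#' `cd8_mean_min`; Tregs need mean(FOXP3, IL2RA) above `treg_mean_min`;
#' Th cells need CD4 above `cd4_min` with both FOXP3 and IL2RA below
#' `th_exclusion_max`.
#'
#' @param cd8_mean_min,treg_mean_min,cd4_min,th_exclusion_max nonnegative reals.
#' @export
marker_thresholds <- function(cd8_mean_min = 3.0, treg_mean_min = 3.5,
                              cd4_min = 3.0, th_exclusion_max = 2.5) {
  v <- c(cd8_mean_min, treg_mean_min, cd4_min, th_exclusion_max)
  if (any(v < 0)) abort("marker thresholds must be nonnegative")
  list(cd8_mean_min = cd8_mean_min, treg_mean_min = treg_mean_min,
       cd4_min = cd4_min, th_exclusion_max = th_exclusion_max)
}

#' Classify T cells into subtypes from surface markers
#'
#' Rules are applied in order CD8T, then CD4Treg, then CD4Th; the first
#' match wins and unmatched T cells become `"otherT"`. Non-T cells are
#' never touched. CD25 is expected under its approved symbol IL2RA (apply
#' [correct_symbols()] first). A missing marker gene is treated as
#' all-zero expression with a warning.
#'
#' @param x an [expr_matrix()] of raw log2 single-cell values.
#' @param annotation annotation tibble, see [read_annotations()].
#' @param thr thresholds from [marker_thresholds()].
#' @return annotation tibble with `t_subtype` filled in for T cells.
#' @export
classify_t_cells <- function(x, annotation, thr = marker_thresholds()) {
  annotation <- validate_annotations(annotation)
  markers <- c("CD8A", "CD8B", "FOXP3", "IL2RA", "CD4")
  get_row <- function(g) {
    if (g %in% rownames(x)) unclass(x)[g, ] else {
      warn(sprintf("marker gene '%s' missing; treated as 0", g))
      setNames(rep(0, ncol(x)), colnames(x))
    }
  }
  mk <- do.call(rbind, lapply(markers, get_row))
  rownames(mk) <- markers
  t_cells <- annotation$obs_id[annotation$cell_type == "T"]
  t_cells <- intersect(t_cells, colnames(x))
  if (!length(t_cells)) return(annotation)
  m <- mk[, t_cells, drop = FALSE]
  cd8 <- colMeans(m[c("CD8A", "CD8B"), , drop = FALSE]) > thr$cd8_mean_min
  treg <- colMeans(m[c("FOXP3", "IL2RA"), , drop = FALSE]) > thr$treg_mean_min
  th <- m["CD4", ] > thr$cd4_min &
    m["FOXP3", ] < thr$th_exclusion_max & m["IL2RA", ] < thr$th_exclusion_max
  sub <- rep("otherT", length(t_cells))
  sub[th] <- "CD4Th"
  sub[treg] <- "CD4Treg" # earlier rules override
  sub[cd8] <- "CD8T"
  annotation$t_subtype[match(t_cells, annotation$obs_id)] <- sub
  annotation
}
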