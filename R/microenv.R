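#' Cell-type-specific marker discovery
#'
#' A gene is a marker of a cell type when (1) its mean expression in that
#' type reaches `min_mean`, (2) its mean is at least `fold_vs_others`
#' times the largest mean among the other types, and (3) it is detected
#' (expression > 0) in at least `min_detect_frac` of the type's cells.
#' Genes qualifying for more than one type are assigned to none.
#'
#' @param x single-cell [expr_matrix()].
#' @param annotation annotation tibble.
#' @param min_mean minimum within-type mean (log2 units, default 2).
#' @param fold_vs_others fold over the best other type (default 4).
#' @param min_detect_frac minimum detection fraction (default 0.25).
#' @param group_by `"cell_type"` or `"t_subtype"` (T cells split into
#'   subtypes, other types kept).
#' @return A `marker_panel` tibble: `cell_type`, `gene_id`; parameters kept
#'   as attributes.
#' @export
find_markers <- function(x, annotation, min_mean = 2, fold_vs_others = 4,
                         min_detect_frac = 0.25, group_by = "cell_type") {
  annotation <- validate_annotations(annotation)
  ann <- annotation[match(colnames(x), annotation$obs_id), ]
  grp <- if (group_by == "t_subtype") {
    ifelse(ann$cell_type == "T", ann$t_subtype, ann$cell_type)
  } else ann$cell_type
  sizes <- table(grp)
  types <- names(sizes)[sizes >= 10]
  if (length(types) < 2) abort("need >= 2 cell types with >= 10 cells each")
  m <- unclass(x)
  means <- sapply(types, function(t) rowMeans(m[, grp == t, drop = FALSE]))
  detf <- sapply(types, function(t) rowMeans(m[, grp == t, drop = FALSE] > 0))
  hits <- sapply(types, function(t) {
    others <- means[, setdiff(types, t), drop = FALSE]
    best_other <- apply(others, 1, max)
    means[, t] >= min_mean &
      means[, t] >= fold_vs_others * best_other &
      detf[, t] >= min_detect_frac
  })
  multi <- rowSums(hits) > 1
  hits[multi, ] <- FALSE
  rows <- purrr::map(types, function(t) {
    g <- rownames(m)[hits[, t]]
    if (!length(g)) {
      warn(sprintf("no marker genes qualify for type '%s'", t))
      return(NULL)
    }
    tibble(cell_type = t, gene_id = g)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("marker_panel", class(out)),
            params = list(min_mean = min_mean, fold_vs_others = fold_vs_others,
                          min_detect_frac = min_detect_frac))
}

#' Immune/stromal metagenes from marker panels
#'
#' The metagene of a cell type in a bulk sample is the arithmetic mean of
#' the type's marker genes present in the bulk matrix; a metagene is
#' omitted (with a warning) when fewer than half its markers are present.
#' Duplicate marker entries and marker order do not affect the value.
#'
#' @param x bulk [expr_matrix()].
#' @param panel `marker_panel` tibble (columns `cell_type`, `gene_id`).
#' @return tibble: `obs_id`, `cell_type`, `value`, `n_markers_used`,
#'   `frac_markers_present`.
#' @export
compute_metagenes <- function(x, panel) {
  m <- unclass(x)
  rows <- panel |>
    dplyr::distinct(.data$cell_type, .data$gene_id) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_split()
  out <- purrr::map(rows, function(p) {
    t <- p$cell_type[1]
    present <- intersect(p$gene_id, rownames(m))
    frac <- length(present) / nrow(p)
    if (frac < 0.5 || !length(present)) {
      warn(sprintf("metagene '%s' omitted: %d/%d markers present",
                   t, length(present), nrow(p)))
      return(NULL)
    }
    tibble(obs_id = colnames(m), cell_type = t,
           value = unname(colMeans(m[present, , drop = FALSE], na.rm = TRUE)),
           n_markers_used = length(present), frac_markers_present = frac)
  })
  dplyr::bind_rows(out)
}

#' Correlate a signature score with cell-type metagenes
#'
#' Pearson product-moment correlation with Fisher-z 95% confidence
#' interval and two-sided p-value, per metagene, over the shared samples.
#'
#' @param score an `anchor_scores` tibble.
#' @param metagenes tibble from [compute_metagenes()].
#' @return A `metagene_cor` tibble: `cell_type`, `r`, `conf.low`,
#'   `conf.high`, `p`, `n`.
#' @export
correlate_score_metagenes <- function(score, metagenes) {
  joined <- dplyr::inner_join(score, metagenes, by = "obs_id")
  out <- joined |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 10) abort("need >= 10 shared samples per metagene")
      ct <- cor.test(d$score, d$value, method = "pearson")
      tibble(r = unname(ct$estimate), conf.low = ct$conf.int[1],
             conf.high = ct$conf.int[2], p = ct$p.value, n = nrow(d))
    }) |>
    dplyr::ungroup()
  structure(out, class = c("metagene_cor", class(out)))
}

#' Ligand-receptor crosstalk map from a signature gene set
#'
#' Intersects the source cell type's anchor-coexpressed genes with the
#' ligands of a curated ligand-receptor table (optionally restricted to a
#' cytokine/chemokine whitelist) and reports, for each ligand's receptor,
#' the cell types in which at least `min_frac` of cells express the
#' receptor above `expr_threshold`.
#'
#' @param scg an `scg_set` (source cell type's signature).
#' @param pairs ligand-receptor tibble from [read_lr_pairs()].
#' @param x single-cell [expr_matrix()].
#' @param annotation annotation tibble.
#' @param ligand_whitelist optional symbols restricting eligible ligands.
#' @param expr_threshold log2 expression above which a receptor counts as
#'   expressed (default 1).
#' @param min_frac minimum expressing fraction of a target type (default 0.1).
#' @param source_cell_type label recorded on the edges; defaults to the
#'   `scg_set`'s cell type.
#' @return tibble of edges: `ligand`, `receptor`, `source_cell_type`,
#'   `target_cell_type`, `receptor_evidence`.
#' @export
crosstalk_map <- function(scg, pairs, x, annotation, ligand_whitelist = NULL,
                          expr_threshold = 1, min_frac = 0.1,
                          source_cell_type = attr(scg, "cell_type")) {
  if (!nrow(pairs)) abort("empty ligand-receptor table")
  annotation <- validate_annotations(annotation)
  ligands <- intersect(toupper(scg_genes(scg)), pairs$ligand)
  if (!is.null(ligand_whitelist)) {
    ligands <- intersect(ligands, toupper(ligand_whitelist))
  }
  use <- pairs |> dplyr::filter(.data$ligand %in% ligands,
                                .data$receptor %in% rownames(x))
  if (!nrow(use)) return(tibble(ligand = character(), receptor = character(),
                                source_cell_type = character(),
                                target_cell_type = character(),
                                receptor_evidence = numeric()))
  ann <- annotation[match(colnames(x), annotation$obs_id), ]
  types <- unique(ann$cell_type)
  m <- unclass(x)
  out <- purrr::pmap(use, function(ligand, receptor, ...) {
    expr <- m[receptor, ] > expr_threshold
    frac <- vapply(types, function(t) mean(expr[ann$cell_type == t]),
                   numeric(1))
    keep <- which(frac >= min_frac)
    if (!length(keep)) return(NULL)
    tibble(ligand = ligand, receptor = receptor,
           source_cell_type = source_cell_type %||% NA_character_,
           target_cell_type = types[keep],
           receptor_evidence = unname(frac[keep]))
  })
  dplyr::bind_rows(out)
}
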