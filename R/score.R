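#' Bin genes by pooled expression
#'
#' Sorts genes by pooled expression (ties broken by gene symbol for
#' determinism) and splits them into `n_bins` contiguous equal-frequency
#' groups whose sizes differ by at most one; leftover genes go to the
#' lowest-expression bins.
#'
#' @param pooled tibble from [compute_pooled_expression()].
#' @param n_bins number of bins (default 25).
#' @return tibble with columns `gene_id`, `bin` (1 = lowest expression).
#' @export
bin_genes <- function(pooled, n_bins = 25) {
  n <- nrow(pooled)
  if (n < n_bins) abort(sprintf("%d genes < %d bins", n, n_bins))
  ord <- order(pooled$e_pooled, pooled$gene_id)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  tibble(gene_id = pooled$gene_id[ord],
         bin = rep(seq_len(n_bins), times = sizes))
}

new_anchor_scores <- function(obs_id, score, mode, scg_source, n_genes_used) {
  structure(tibble(obs_id = obs_id, score = unname(score)),
            class = c("anchor_scores", class(tibble())),
            mode = mode, scg_source = scg_source,
            n_genes_used = n_genes_used)
}

#' Binned-control signature score for single-cell data
#'
#' For each signature gene, `n_controls` control genes are sampled from the
#' gene's pooled-expression bin (excluding the gene itself; without
#' replacement when the bin holds at least `n_controls + 1` genes,
#' otherwise with replacement). The gene's expression in each cell is
#' centralized by the mean control expression in that cell, and the
#' per-cell score is the mean of the centralized values over the signature.
#' Controls are sampled once per signature gene and reused across cells.
#'
#' @param x single-cell [expr_matrix()].
#' @param scg an `scg_set` (or character vector of signature genes).
#' @param bins tibble from [bin_genes()] covering the matrix genes.
#' @param n_controls control genes per signature gene (default 100).
#' @param seed integer seed fixing the control draw.
#' @return An `anchor_scores` tibble (`obs_id`, `score`) with attributes
#'   `mode = "single_cell_control"`, `scg_source`, `n_genes_used`.
#' @export
score_single_cell <- function(x, scg, bins, n_controls = 100, seed = 1L) {
  genes <- scg_genes(scg)
  present <- genes %in% rownames(x) & genes %in% bins$gene_id
  if (any(!present)) {
    warn(sprintf("%d signature genes absent from matrix/bins; excluded",
                 sum(!present)))
    genes <- genes[present]
  }
  if (!length(genes)) abort("no signature genes available for scoring")
  m <- unclass(x)
  bin_of <- setNames(bins$bin, bins$gene_id)
  members <- split(bins$gene_id, bins$bin)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  centered <- matrix(0, length(genes), ncol(m))
  for (i in seq_along(genes)) {
    g <- genes[i]
    pool <- setdiff(members[[as.character(bin_of[[g]])]], g)
    pool <- intersect(pool, rownames(m))
    ctrl <- if (length(pool) >= n_controls) {
      sample(pool, n_controls)
    } else {
      sample(pool, n_controls, replace = TRUE)
    }
    centered[i, ] <- m[g, ] - colMeans(m[ctrl, , drop = FALSE])
  }
  new_anchor_scores(colnames(m), colMeans(centered),
                    mode = "single_cell_control",
                    scg_source = attr(scg, "cell_type") %||% NA_character_,
                    n_genes_used = length(genes))
}

#' Mean signature score for bulk data
#'
#' The bulk score is the per-sample mean of the available signature genes,
#' optionally after gene-wise mean-centering across samples (the microarray
#' convention).
#'
#' @param x bulk [expr_matrix()].
#' @param scg an `scg_set` or character vector of signature genes.
#' @param center mean-center each gene across samples before averaging.
#' @param force proceed when fewer than half the signature genes are present.
#' @return An `anchor_scores` tibble, `mode = "bulk_mean"`.
#' @export
score_bulk <- function(x, scg, center = FALSE, force = FALSE) {
  genes <- scg_genes(scg)
  present <- intersect(genes, rownames(x))
  if (length(present) < 10) {
    abort(sprintf("only %d signature genes present (< 10)", length(present)))
  }
  if (length(present) < 0.5 * length(genes) && !force) {
    abort(sprintf(
      "only %d/%d signature genes present (< 50%%); use force = TRUE",
      length(present), length(genes)))
  }
  m <- unclass(x)[present, , drop = FALSE]
  if (center) m <- m - rowMeans(m, na.rm = TRUE)
  new_anchor_scores(colnames(x), colMeans(m, na.rm = TRUE),
                    mode = "bulk_mean",
                    scg_source = attr(scg, "cell_type") %||% NA_character_,
                    n_genes_used = length(present))
}

#' Z-transform a signature score
#'
#' Centers and scales to mean 0 and (population) SD 1 across
#' observations, so `z_transform(c(1, 2, 3))` is `(-1.2247, 0, 1.2247)`.
#'
#' @param score an `anchor_scores` tibble (or numeric vector).
#' @return same shape as the input, standardized; a `z_transformed`
#'   attribute marks `anchor_scores` output.
#' @export
z_transform <- function(score) {
  v <- if (is.data.frame(score)) score$score else score
  if (length(v) < 2) abort("need >= 2 observations")
  s <- sqrt(mean((v - mean(v))^2))
  if (!is.finite(s) || s == 0) abort("zero-variance score")
  z <- (v - mean(v)) / s
  if (is.data.frame(score)) {
    score$score <- z
    attr(score, "z_transformed") <- TRUE
    score
  } else z
}

# save/restore .Random.seed so score sampling is seed-local
.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.anchor_scores <- function(x, ...) {
  cat(sprintf("<anchor_scores> %d observations, mode %s, %d genes\n",
              nrow(x), attr(x, "mode"), attr(x, "n_genes_used")))
  NextMethod()
}
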