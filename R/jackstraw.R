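#' Modified jackstraw association test against a signature score
#'
#' Associates every bulk-profiled gene with a fixed, Z-transformed
#' signature score. The observed statistic per gene is the absolute
#' Pearson correlation with the score; the null distribution pools, over
#' `B` iterations, the statistics of all genes after independently
#' permuting each gene's values across samples while the score is held
#' fixed. The permutation p-value uses the add-one estimator
#' `p = (1 + #null >= observed) / (1 + B * n_genes)`, so the smallest
#' attainable p is `1 / (1 + B * n_genes)` and 0 is never returned.
#' Direction comes from the unpermuted Pearson correlation and Bonferroni
#' adjustment multiplies by the number of genes.
#'
#' @param x bulk [expr_matrix()] (genes x samples).
#' @param score Z-transformed `anchor_scores` covering the samples of `x`.
#' @param B permutation iterations (>= 100; default 1000).
#' @param seed integer seed for the permutation stream.
#' @return A `jackstraw_result` tibble: `gene_id`, `stat`, `direction`,
#'   `p_perm`, `p_bonf`, `selected`.
#' @export
jackstraw_test <- function(x, score, B = 1000, seed = 1L) {
  if (B < 100) abort("B must be >= 100")
  v <- if (is.data.frame(score)) {
    setNames(score$score, score$obs_id)[colnames(x)]
  } else score[colnames(x)]
  if (anyNA(v)) abort("score does not cover all samples of the matrix")
  if (abs(mean(v)) > 1e-6 || abs(sd(v) - 1) > 0.05) {
    abort("score must be Z-transformed first (see z_transform())")
  }
  m <- unclass(x)
  if (anyNA(m)) abort("jackstraw requires a complete matrix")
  nsamp <- ncol(m)
  if (nsamp < 3) abort("need >= 3 samples")
  rsd <- apply(m, 1, sd)
  const <- rsd == 0
  Z <- (m - rowMeans(m)) / ifelse(rsd == 0, 1, rsd)
  s <- as.numeric(scale(v))
  r <- as.numeric(Z %*% s) / (nsamp - 1)
  r[const] <- 0
  obs <- abs(r)
  Znull <- Z[!const, , drop = FALSE]
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  null_sorted <- jackstraw_null_stats(Znull, s, as.integer(B))
  n_null <- length(null_sorted)
  n_genes <- nrow(m)
  # count of null stats >= obs via binary search on the sorted pool
  ge <- n_null - findInterval(obs - 1e-15, null_sorted)
  p_perm <- (1 + ge) / (1 + n_null)
  p_perm[const] <- 1
  p_bonf <- pmin(1, p_perm * n_genes)
  out <- tibble(gene_id = rownames(m), stat = obs,
                direction = sign(r), p_perm = p_perm, p_bonf = p_bonf,
                selected = sign(r) > 0 & p_bonf < 0.05)
  structure(out, class = c("jackstraw_result", class(out)),
            B = B, n_genes = n_genes)
}

#' Positively score-associated genes
#'
#' Genes with a positive correlation direction and Bonferroni-adjusted
#' p below `alpha`, ordered by p then descending statistic.
#'
#' @param results a `jackstraw_result` tibble.
#' @param alpha Bonferroni threshold (default 0.05).
#' @return character vector of gene symbols (possibly empty).
#' @export
select_positive <- function(results, alpha = 0.05) {
  results |>
    dplyr::filter(.data$direction > 0, .data$p_bonf < alpha) |>
    dplyr::arrange(.data$p_perm, dplyr::desc(.data$stat)) |>
    dplyr::pull("gene_id")
}
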