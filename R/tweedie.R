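#' Tweedie EDM configuration
#'
#' @param power Tweedie variance-power index `p` in `[1, 2)`;
#'   `V(mu) = mu^p`. `1 < p < 2` gives the compound-Poisson-gamma family
#'   suited to nonnegative responses with exact zeros.
#' @param min_cells minimum observations per fit.
#' @param use_weights whether dropout reliability weights enter the fit as
#'   observation weights.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @export
edm_config <- function(power = 1.1, min_cells = 30, use_weights = TRUE,
                       max_iter = 60, tol = 1e-9) {
  if (power < 1 || power >= 2) abort("`power` must be in [1, 2)")
  list(power = power, min_cells = min_cells, use_weights = use_weights,
       max_iter = max_iter, tol = tol)
}

# Tweedie GLM with log link, response ~ intercept + x, fitted by IRLS.
# Working weights w0 * mu^(2-p); dispersion phi by the Pearson statistic;
# Wald SE from phi * (X'WX)^-1. Returns NULL on degenerate input.
tweedie_irls <- function(y, x, w0 = NULL, power = 1.1, max_iter = 60,
                         tol = 1e-9) {
  n <- length(y)
  if (is.null(w0)) w0 <- rep(1, n)
  my <- mean(y)
  if (my <= 0) return(NULL) # all-zero response: no log-link fit
  mu <- (y + my) / 2
  eta <- log(mu)
  b1 <- b2 <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- w0 * mu^(2 - power)
    z <- eta + (y - mu) / mu
    Sw <- sum(W); Swx <- sum(W * x); Swxx <- sum(W * x * x)
    Swz <- sum(W * z); Swxz <- sum(W * x * z)
    det <- Sw * Swxx - Swx * Swx
    if (!is.finite(det) || det <= 0) return(NULL)
    b1n <- (Swz * Swxx - Swx * Swxz) / det
    b2n <- (Sw * Swxz - Swx * Swz) / det
    if (!is.finite(b1n) || !is.finite(b2n)) return(NULL)
    delta <- max(abs(b1n - b1), abs(b2n - b2))
    b1 <- b1n; b2 <- b2n
    eta <- pmin(pmax(b1 + b2 * x, -30), 30)
    mu <- exp(eta)
    if (it > 1 && delta < tol * (1 + abs(b2))) { converged <- TRUE; break }
  }
  W <- w0 * mu^(2 - power)
  Sw <- sum(W); Swx <- sum(W * x); Swxx <- sum(W * x * x)
  det <- Sw * Swxx - Swx * Swx
  phi <- sum(w0 * (y - mu)^2 / mu^power) / (n - 2)
  se <- sqrt(phi * Sw / det)
  list(beta = b2, intercept = b1, se = se, dispersion = phi,
       converged = converged, iter = it, n = n)
}

#' Fit one anchor-vs-gene Tweedie EDM
#'
#' Fits `anchor ~ intercept + gene` under Tweedie variance `V(mu) = mu^p`
#' with log link by iteratively reweighted least squares; the GLM
#' dispersion is estimated by the Pearson statistic and inference is a
#' two-sided Wald test on the gene coefficient.
#'
#' @param anchor_expr nonnegative response vector (anchor expression).
#' @param gene_expr predictor vector (candidate co-expressed gene).
#' @param weights optional observation weights (e.g. dropout reliability).
#' @param cfg an [edm_config()].
#' @return one-row tibble: `beta`, `se`, `z`, `p`, `converged`, `n`, `note`.
#'   Non-convergence is flagged with `p = 1`; a constant predictor is
#'   returned as a skipped record (`note = "constant_predictor"`).
#' @export
fit_edm <- function(anchor_expr, gene_expr, weights = NULL,
                    cfg = edm_config()) {
  n <- length(anchor_expr)
  if (length(gene_expr) != n) abort("response/predictor length mismatch")
  if (n < cfg$min_cells) {
    abort(sprintf("%d observations < min_cells = %d", n, cfg$min_cells))
  }
  if (any(anchor_expr < 0)) abort("anchor expression must be nonnegative")
  skipped <- function(note) {
    tibble(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
           converged = FALSE, n = n, note = note)
  }
  if (var(gene_expr) == 0) return(skipped("constant_predictor"))
  fit <- tweedie_irls(anchor_expr, gene_expr, w0 = weights,
                      power = cfg$power, max_iter = cfg$max_iter,
                      tol = cfg$tol)
  if (is.null(fit)) return(skipped("degenerate_fit"))
  if (!fit$converged) {
    return(tibble(beta = fit$beta, se = fit$se, z = NA_real_, p = 1,
                  converged = FALSE, n = n, note = "non_convergence"))
  }
  z <- fit$beta / fit$se
  tibble(beta = fit$beta, se = fit$se, z = z, p = 2 * pnorm(-abs(z)),
         converged = TRUE, n = n, note = NA_character_)
}

#' Transcriptome-wide anchor association scan
#'
#' Runs [fit_edm()] of the anchor against every other retained gene over a
#' subset of cells. The anchor is excluded from its own candidate list.
#'
#' @param x an [expr_matrix()].
#' @param anchor anchor gene symbol (must be present).
#' @param cells optional character vector of observation IDs to use.
#' @param weights optional weight matrix from [compute_weights()].
#' @param cfg an [edm_config()].
#' @return tibble with one row per candidate gene: `gene_id`, `beta`, `se`,
#'   `z`, `p`, `converged`, `n`, `note`.
#' @export
fit_all_genes <- function(x, anchor, cells = NULL, weights = NULL,
                          cfg = edm_config()) {
  anchor <- toupper(anchor)
  if (!anchor %in% rownames(x)) {
    abort(sprintf("anchor gene '%s' absent from matrix", anchor))
  }
  m <- unclass(x)
  if (!is.null(cells)) {
    missing <- setdiff(cells, colnames(m))
    if (length(missing)) abort("unknown observation ids in `cells`")
    m <- m[, cells, drop = FALSE]
  }
  y <- m[anchor, ]
  genes <- setdiff(rownames(m), anchor)
  wmat <- NULL
  if (!is.null(weights) && cfg$use_weights) {
    wmat <- weights[, colnames(m), drop = FALSE]
  }
  res <- purrr::map(genes, function(g) {
    w <- if (is.null(wmat)) NULL else wmat[g, ]
    fit_edm(y, m[g, ], weights = w, cfg = cfg)
  })
  dplyr::bind_cols(tibble(gene_id = genes), dplyr::bind_rows(res))
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools per-patient EDM coefficients with weights `1/se^2`:
#' `pooled_beta = sum(w * beta) / sum(w)`, `pooled_se = sum(w)^(-1/2)`,
#' with a Wald Z test on the pooled coefficient.
#'
#' @param beta,se numeric vectors of per-study estimates and standard
#'   errors (`se > 0`).
#' @return one-row tibble: `pooled_beta`, `pooled_se`, `pooled_z`,
#'   `pooled_p`, `k_studies`.
#' @export
meta_fixed_effect <- function(beta, se) {
  keep <- is.finite(beta) & is.finite(se)
  beta <- beta[keep]; se <- se[keep]
  if (!length(beta)) abort("no studies to pool")
  if (any(se <= 0)) abort("standard errors must be positive")
  w <- 1 / se^2
  pb <- sum(w * beta) / sum(w)
  ps <- 1 / sqrt(sum(w))
  z <- pb / ps
  tibble(pooled_beta = pb, pooled_se = ps, pooled_z = z,
         pooled_p = 2 * pnorm(-abs(z)), k_studies = length(beta))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (monotone-enforced, capped
#' at 1) via [stats::p.adjust()]. Inputs must lie in (0, 1].
#'
#' @param pvalues numeric vector of p-values.
#' @return vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues > 0 & pvalues <= 1)
  if (!all(ok)) abort("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}
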