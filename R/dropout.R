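#' Per-cell detection curves from housekeeping genes
#'
#' Housekeeping genes are constitutively expressed, so an undetected
#' housekeeping gene in a cell reflects technical loss rather than biology.
#' For each cell, the detection indicator (expression strictly above zero)
#' of every housekeeping gene is regressed on the gene's pooled expression
#' with a logistic curve, giving a cell-specific detection probability
#' `p(e) = plogis(slope * (e - midpoint))`. Cells detecting every
#' housekeeping gene are flagged `"all_detected"` (all weights become 1);
#' cells detecting none are flagged `"none_detected"`; fits with a
#' non-positive slope are flagged `"unstable"` and treated as uninformative.
#'
#' @param x single-cell [expr_matrix()].
#' @param housekeeping character vector of housekeeping gene symbols
#'   (at least 10 must be present in the matrix).
#' @param pooled pooled expression tibble; defaults to
#'   [compute_pooled_expression()] of `x`.
#' @return tibble with columns `obs_id`, `midpoint`, `slope`, `fit_ok`
#'   (`"ok"`, `"all_detected"`, `"none_detected"`, `"unstable"`).
#' @export
fit_detection_curves <- function(x, housekeeping,
                                 pooled = compute_pooled_expression(x)) {
  housekeeping <- intersect(toupper(housekeeping), rownames(x))
  if (length(housekeeping) < 10) {
    abort(paste0("only ", length(housekeeping), " housekeeping genes found ",
                 "in the matrix; supply a list with >= 10 present genes"))
  }
  ep <- pooled$e_pooled[match(housekeeping, pooled$gene_id)]
  hk <- unclass(x)[housekeeping, , drop = FALSE] > 0
  fits <- purrr::map(seq_len(ncol(x)), function(j) {
    d <- hk[, j]
    if (all(d)) return(list(mid = -Inf, slope = 1, ok = "all_detected"))
    if (!any(d)) return(list(mid = Inf, slope = 1, ok = "none_detected"))
    fit <- suppressWarnings(glm(d ~ ep, family = binomial()))
    b <- coef(fit)
    if (!all(is.finite(b)) || b[2] <= 0) {
      return(list(mid = NA_real_, slope = NA_real_, ok = "unstable"))
    }
    list(mid = unname(-b[1] / b[2]), slope = unname(b[2]), ok = "ok")
  })
  tibble(obs_id = colnames(x),
         midpoint = purrr::map_dbl(fits, "mid"),
         slope = purrr::map_dbl(fits, "slope"),
         fit_ok = purrr::map_chr(fits, "ok"))
}

#' Gene-by-cell reliability weights
#'
#' Detected entries (expression > 0) get weight 1. A zero entry of gene `g`
#' in cell `c` gets weight `1 - p_c(e_pooled(g))` — the probability the
#' zero is a true absence rather than a dropout — floored at `weight_floor`.
#' Cells flagged `"all_detected"` or `"unstable"` contribute weight 1
#' everywhere; `"none_detected"` cells get the floor on all zeros.
#'
#' @param x single-cell [expr_matrix()].
#' @param curves tibble from [fit_detection_curves()] (one row per cell).
#' @param pooled pooled expression tibble covering all genes of `x`.
#' @param weight_floor minimum weight, keeps weighted fits non-degenerate.
#' @return numeric matrix of weights in `[weight_floor, 1]`, same dimnames
#'   as `x`.
#' @export
compute_weights <- function(x, curves,
                            pooled = compute_pooled_expression(x),
                            weight_floor = 0.05) {
  if (!all(colnames(x) %in% curves$obs_id)) {
    abort("`curves` must contain one row per cell of the matrix")
  }
  curves <- curves[match(colnames(x), curves$obs_id), ]
  ep <- pooled$e_pooled[match(rownames(x), pooled$gene_id)]
  if (anyNA(ep)) abort("`pooled` does not cover all genes")
  w <- matrix(1, nrow(x), ncol(x), dimnames = dimnames(x))
  zero <- unclass(x) == 0
  for (j in seq_len(ncol(x))) {
    ok <- curves$fit_ok[j]
    if (ok %in% c("all_detected", "unstable")) next
    wj <- if (ok == "none_detected") {
      rep(weight_floor, nrow(x))
    } else {
      pmax(1 - plogis(curves$slope[j] * (ep - curves$midpoint[j])),
           weight_floor)
    }
    w[zero[, j], j] <- wj[zero[, j]]
  }
  w
}
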