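#' Median dichotomization of a signature score
#'
#' Splits samples at the median; samples exactly at the median go to the
#' low group (documented tie rule).
#'
#' @param score an `anchor_scores` tibble or numeric vector (>= 4 values,
#'   non-constant).
#' @return factor with levels `low`, `high` (named by observation for
#'   `anchor_scores` input).
#' @export
dichotomize_by_median <- function(score) {
  v <- if (is.data.frame(score)) setNames(score$score, score$obs_id) else score
  if (length(v) < 4) abort("need >= 4 samples")
  if (sd(v) == 0) abort("constant scores cannot be dichotomized")
  factor(ifelse(v > median(v), "high", "low"), levels = c("low", "high"))
}

#' Retain samples above a tumor-purity cutoff
#'
#' @param clinical tibble with a purity column in `[0, 1]`.
#' @param min_purity exclusive lower bound (default 0.8).
#' @param column purity column name.
#' @return filtered tibble.
#' @export
filter_by_purity <- function(clinical, min_purity = 0.8, column = "purity") {
  if (!column %in% names(clinical)) {
    abort(sprintf("no '%s' column in the clinical table", column))
  }
  dplyr::filter(clinical, !is.na(.data[[column]]),
                .data[[column]] > min_purity)
}

#' Cox proportional-hazards fit for a signature score
#'
#' Fits `Surv(time, event) ~ score + covariates` by partial likelihood
#' (Efron tie handling by default) via [survival::coxph()]. The score is
#' entered per-SD (Z-scored) unless `scale_score = FALSE`, so hazard
#' ratios read per score standard deviation. Requires at least 10 events;
#' near-collinear covariates (condition number above `kappa_max`) are
#' rejected. Covariates missing from the table are dropped with a warning.
#'
#' @param clinical tibble with columns `time` (days), `event` (0/1), the
#'   score column and any covariates.
#' @param score_col name of the score column (default `"score"`).
#' @param covariates character vector of adjustment terms
#'   (e.g. `c("gender", "age")`).
#' @param ties `"efron"` or `"breslow"`.
#' @param scale_score Z-score the score before fitting.
#' @param kappa_max condition-number bound for the numeric design.
#' @return An `anchor_cox` object; use [tidy()] for per-term hazard ratios
#'   and [glance()] for fit-level summaries.
#' @export
cox_fit <- function(clinical, score_col = "score", covariates = character(),
                    ties = c("efron", "breslow"), scale_score = TRUE,
                    kappa_max = 1e8) {
  ties <- match.arg(ties)
  need <- c("time", "event", score_col)
  if (!all(need %in% names(clinical))) {
    abort(paste0("clinical table needs columns: ",
                 paste(setdiff(need, names(clinical)), collapse = ", ")))
  }
  drop <- setdiff(covariates, names(clinical))
  if (length(drop)) {
    warn(paste0("covariates missing from table, dropped: ",
                paste(drop, collapse = ", ")))
    covariates <- setdiff(covariates, drop)
  }
  d <- clinical[complete.cases(clinical[, c(need, covariates)]), ]
  if (any(d$time < 0)) abort("negative survival times")
  if (!all(d$event %in% c(0, 1))) abort("event must be 0/1")
  if (sum(d$event) < 10) {
    abort(sprintf("only %d events (< 10)", sum(d$event)))
  }
  if (scale_score) d[[score_col]] <- as.numeric(scale(d[[score_col]]))
  num <- d[, c(score_col, covariates), drop = FALSE]
  num <- num[, vapply(num, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) > 1) {
    kap <- kappa(cbind(1, as.matrix(num)), exact = TRUE)
    if (!is.finite(kap) || kap > kappa_max) {
      abort(sprintf("collinear covariates (condition number %.3g)", kap))
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(c(score_col, covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties)
  converged <- is.null(fit$info) && all(is.finite(coef(fit)))
  structure(list(fit = fit, n = nrow(d), n_events = sum(d$event),
                 converged = converged, ties = ties,
                 score_col = score_col),
            class = "anchor_cox")
}

#' @export
print.anchor_cox <- function(x, ...) {
  cat(sprintf("<anchor_cox> n = %d, events = %d, ties = %s\n",
              x$n, x$n_events, x$ties))
  print(tidy(x))
  invisible(x)
}

#' @rdname cox_fit
#' @param x an `anchor_cox` object.
#' @param ... unused.
#' @method tidy anchor_cox
#' @export
tidy.anchor_cox <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(term = rownames(co),
         log_hr = co[, "coef"], se = co[, "se(coef)"],
         hr = exp(co[, "coef"]),
         conf.low = exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
         conf.high = exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"]),
         p = co[, "Pr(>|z|)"])
}

#' @rdname cox_fit
#' @method glance anchor_cox
#' @export
glance.anchor_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, converged = x$converged,
         concordance = unname(summary(x$fit)$concordance[1]))
}

#' Logistic association between a score and a binary response
#'
#' Maximum-likelihood logistic regression of the response on the score
#' with optional covariates; reports the Wald odds ratio, 95% CI and
#' p-value for the score term. Perfect separation is detected (diverging
#' coefficient / degenerate fitted probabilities) and flagged with the
#' p-value omitted.
#'
#' @param data tibble with the response, score and covariate columns.
#' @param response_col binary response column name.
#' @param score_col score column name.
#' @param covariates adjustment terms.
#' @return one-row tibble: `or`, `conf.low`, `conf.high`, `p`, `n`,
#'   `separation`.
#' @export
logistic_response_test <- function(data, response_col = "response",
                                   score_col = "score",
                                   covariates = character()) {
  d <- data[complete.cases(data[, c(response_col, score_col, covariates)]), ]
  if (nrow(d) < 10) abort("need >= 10 complete observations")
  y <- d[[response_col]]
  if (length(unique(y)) < 2) abort("both response classes must be present")
  fml <- stats::as.formula(paste(
    response_col, "~", paste(c(score_col, covariates), collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = d, family = binomial()))
  co <- summary(fit)$coefficients
  b <- co[score_col, "Estimate"]
  se <- co[score_col, "Std. Error"]
  probs <- stats::fitted(fit)
  separation <- !fit$converged || abs(b) > 15 ||
    all(probs > 0.9999 | probs < 1e-4)
  tibble(or = exp(b),
         conf.low = if (separation) NA_real_ else exp(b - qnorm(0.975) * se),
         conf.high = if (separation) NA_real_ else exp(b + qnorm(0.975) * se),
         p = if (separation) NA_real_ else co[score_col, "Pr(>|z|)"],
         n = nrow(d), separation = separation)
}

#' Nonparametric and permutation group comparisons
#'
#' Kruskal-Wallis (any number of groups), Mann-Whitney (two groups), or an
#' approximative Fisher-Pitman permutation test (two groups; seeded label
#' permutations of the group-mean difference with the add-one estimator,
#' so p is never 0).
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param test one of `"kruskal_wallis"`, `"mann_whitney"`,
#'   `"fisher_pitman_permutation"`.
#' @param B permutations for the Fisher-Pitman test.
#' @param seed permutation seed.
#' @return one-row tibble: `test`, `statistic`, `p`.
#' @export
group_tests <- function(values, groups,
                        test = c("kruskal_wallis", "mann_whitney",
                                 "fisher_pitman_permutation"),
                        B = 10000, seed = 1L) {
  test <- match.arg(test)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) abort("need >= 2 groups")
  if (any(table(groups) == 0)) abort("empty group")
  if (test == "kruskal_wallis") {
    kt <- kruskal.test(values, groups)
    return(tibble(test = test, statistic = unname(kt$statistic),
                  p = kt$p.value))
  }
  if (nlevels(groups) != 2) {
    abort(sprintf("'%s' requires exactly 2 groups", test))
  }
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  if (test == "mann_whitney") {
    wt <- suppressWarnings(wilcox.test(g1, g2))
    return(tibble(test = test, statistic = unname(wt$statistic),
                  p = wt$p.value))
  }
  obs <- abs(mean(g1) - mean(g2))
  n1 <- length(g1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  null <- vapply(seq_len(B), function(i) {
    idx <- sample.int(length(values), n1)
    abs(mean(values[idx]) - mean(values[-idx]))
  }, numeric(1))
  tibble(test = test, statistic = obs,
         p = (1 + sum(null >= obs - 1e-15)) / (1 + B))
}
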