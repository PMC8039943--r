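test_that("median split sends boundary values to the low group", {
  g <- dichotomize_by_median(c(1, 2, 3, 4))
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  odd <- dichotomize_by_median(c(1, 2, 3, 4, 5))
  expect_identical(as.character(odd)[3], "low") # middle value at median
  withr::with_seed(2, {
    v <- sample(1:6, 40, replace = TRUE)
  })
  g2 <- dichotomize_by_median(v)
  ties <- sum(v == median(v))
  expect_lte(abs(sum(g2 == "high") - sum(g2 == "low")), ties)
  expect_error(dichotomize_by_median(rep(1, 10)), "constant")
  expect_error(dichotomize_by_median(1:3), ">= 4")
})

test_that("purity filtering is an exact row filter", {
  cl <- tibble::tibble(sample_id = sprintf("s%02d", 1:30),
                       purity = withr::with_seed(3, runif(30)))
  out <- filter_by_purity(cl, 0.8)
  expect_identical(out$sample_id, cl$sample_id[cl$purity > 0.8])
  expect_error(filter_by_purity(dplyr::select(cl, -purity)), "purity")
})

simulate_survival <- function(n, log_hr, censor_frac, seed) {
  withr::with_seed(seed, {
    score <- rnorm(n)
    t_event <- rexp(n, 0.001 * exp(log_hr * score))
    t_cens <- if (censor_frac > 0) {
      rexp(n, 0.001 * censor_frac / (1 - censor_frac))
    } else rep(Inf, n)
    tibble::tibble(sample_id = seq_len(n), time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens), score = score,
                   age = rnorm(n, 60, 10),
                   gender = sample(c("F", "M"), n, TRUE))
  })
}

test_that("Cox fit recovers a two-group hazard ratio of 2", {
  withr::with_seed(11, {
    grp <- rep(0:1, each = 3000)
    tt <- rexp(6000, 0.001 * 2^grp)
  })
  cl <- tibble::tibble(time = tt, event = 1L, score = grp)
  fit <- cox_fit(cl, scale_score = FALSE)
  td <- tidy(fit)
  expect_equal(td$hr, 2, tolerance = 0.1)
  expect_true(glance(fit)$converged)
})

test_that("null covariates rarely exceed two standard errors", {
  inside <- vapply(1:100, function(i) {
    d <- simulate_survival(300, log_hr = 0, censor_frac = 0.3, seed = 100 + i)
    td <- tidy(cox_fit(d, covariates = "age"))
    abs(td$log_hr[td$term == "score"]) <
      2 * td$se[td$term == "score"]
  }, logical(1))
  expect_gt(mean(inside), 0.9) # nominal ~0.954, binomial 99% lower bound
})

test_that("Cox guards reject degenerate designs", {
  d <- simulate_survival(100, -0.3, 0.3, seed = 7)
  expect_error(cox_fit(dplyr::mutate(d, event = 0L)), "events")
  d$copy <- d$score * 2
  expect_error(cox_fit(d, covariates = "copy", scale_score = FALSE),
               "collinear")
  expect_warning(cox_fit(d, covariates = c("age", "weight")), "dropped")
})

test_that("hazard-ratio p-values are invariant to covariate rescaling", {
  d <- simulate_survival(250, -0.4, 0.2, seed = 21)
  f1 <- tidy(cox_fit(d, scale_score = FALSE))
  d2 <- dplyr::mutate(d, score = score * 10)
  f2 <- tidy(cox_fit(d2, scale_score = FALSE))
  expect_equal(f2$p, f1$p, tolerance = 1e-6)
  expect_equal(f2$log_hr, f1$log_hr / 10, tolerance = 1e-6)
})

test_that("logistic response test estimates odds ratios and flags separation", {
  withr::with_seed(41, {
    score <- rnorm(400)
    resp <- rbinom(400, 1, plogis(1.0 * score))
  })
  d <- tibble::tibble(response = resp, score = score)
  res <- logistic_response_test(d)
  expect_false(res$separation)
  expect_lt(abs(log(res$or) - 1.0), 0.4)
  expect_lt(res$p, 0.001)

  sep <- tibble::tibble(response = rep(0:1, each = 20),
                        score = rep(0:1, each = 20))
  flagged <- logistic_response_test(sep)
  expect_true(flagged$separation)
  expect_true(is.na(flagged$p))
  expect_error(logistic_response_test(
    tibble::tibble(response = rep(1, 20), score = rnorm(20))), "classes")
})

test_that("group tests match their reference implementations", {
  withr::with_seed(51, {
    v <- c(rnorm(30), rnorm(30, 2))
    g <- rep(c("a", "b"), each = 30)
  })
  kw <- group_tests(v, g, "kruskal_wallis")
  expect_equal(kw$p, kruskal.test(v, factor(g))$p.value)
  mw <- group_tests(v, g, "mann_whitney")
  expect_equal(mw$p, wilcox.test(v[g == "a"], v[g == "b"])$p.value)
  # disjoint supports: exact minimum attainable rank p
  d1 <- 1:8; d2 <- 101:108
  mm <- group_tests(c(d1, d2), rep(c("a", "b"), each = 8), "mann_whitney")
  expect_equal(mm$p, wilcox.test(d1, d2, exact = TRUE)$p.value)
  expect_equal(mm$p, 2 / choose(16, 8), tolerance = 1e-12)
})

test_that("Fisher-Pitman permutation p is seeded, positive, and sane", {
  withr::with_seed(61, {
    v <- c(rnorm(25), rnorm(25, 1.5))
    g <- rep(c("a", "b"), each = 25)
  })
  p1 <- group_tests(v, g, "fisher_pitman_permutation", B = 2000, seed = 3)
  p2 <- group_tests(v, g, "fisher_pitman_permutation", B = 2000, seed = 3)
  expect_identical(p1$p, p2$p)
  expect_gt(p1$p, 0)
  expect_lt(p1$p, 0.01)
  same <- withr::with_seed(62, rnorm(40))
  pnull <- group_tests(same, rep(c("a", "b"), 20),
                       "fisher_pitman_permutation", B = 1000, seed = 4)
  expect_gt(pnull$p, 0.05)
  expect_error(group_tests(v, rep("a", 50), "kruskal_wallis"), "2 groups")
  expect_error(group_tests(v, c(rep("a", 48), "b", "c"),
                           "fisher_pitman_permutation"), "exactly 2")
})
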