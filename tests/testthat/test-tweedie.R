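# correlated nonnegative pair with exact zeros, the regime the EDM targets
tweedie_pair <- function(n, beta = 0.4, seed = 1) {
  withr::with_seed(seed, {
    x <- pmax(rnorm(n, 3, 1), 0)
    mu <- exp(0.2 + beta * (x - 3) / 3)
    y <- pmax(mu + rnorm(n, 0, 0.6), 0)
    y[runif(n) < 0.15] <- 0
    list(x = x, y = y)
  })
}

test_that("IRLS matches glm with the Tweedie family on coefficients and SEs", {
  skip_if_not_installed("mgcv")
  for (case in list(list(p = 1.1, seed = 1), list(p = 1.5, seed = 2),
                    list(p = 1.9, seed = 3))) {
    d <- tweedie_pair(300, seed = case$seed)
    mine <- fit_edm(d$y, d$x, cfg = edm_config(power = case$p))
    ref <- glm(d$y ~ d$x,
               family = mgcv::Tweedie(p = case$p, link = "log"))
    rs <- summary(ref)
    expect_equal(mine$beta, unname(coef(ref)[2]), tolerance = 1e-4)
    expect_equal(mine$se, unname(rs$coefficients[2, 2]), tolerance = 1e-4)
  }
})

test_that("observation weights enter the fit like glm prior weights", {
  skip_if_not_installed("mgcv")
  d <- tweedie_pair(250, seed = 5)
  w <- withr::with_seed(6, runif(250, 0.2, 1))
  mine <- fit_edm(d$y, d$x, weights = w, cfg = edm_config(power = 1.1))
  ref <- glm(d$y ~ d$x, weights = w,
             family = mgcv::Tweedie(p = 1.1, link = "log"))
  expect_equal(mine$beta, unname(coef(ref)[2]), tolerance = 1e-5)
  expect_equal(mine$se, unname(summary(ref)$coefficients[2, 2]),
               tolerance = 1e-4)
})

test_that("rescaling the predictor halves beta and leaves Z unchanged", {
  d <- tweedie_pair(300, seed = 7)
  f1 <- fit_edm(d$y, d$x)
  f2 <- fit_edm(d$y, 2 * d$x)
  expect_equal(f2$beta, f1$beta / 2, tolerance = 1e-6)
  expect_equal(f2$z, f1$z, tolerance = 1e-6)
})

test_that("Wald test holds its nominal size under the null", {
  n_rep <- 1000
  rej <- withr::with_seed(13, {
    vapply(seq_len(n_rep), function(i) {
      y <- pmax(rnorm(500, 1.5, 0.8), 0)
      x <- rnorm(500, 3, 1)
      fit_edm(y, x)$p < 0.05
    }, logical(1))
  })
  bounds <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(mean(rej), bounds[1])
  expect_lt(mean(rej), bounds[2])
})

test_that("degenerate predictors and responses are flagged, not fitted", {
  y <- c(rep(1, 40), rep(0, 10))
  expect_identical(fit_edm(y, rep(2, 50))$note, "constant_predictor")
  expect_error(fit_edm(y[1:10], rnorm(10)), "min_cells")
  all_zero <- fit_edm(rep(0, 50), rnorm(50))
  expect_identical(all_zero$note, "degenerate_fit")
})

test_that("fixed-effect pooling matches its closed form and metafor", {
  one <- meta_fixed_effect(0.2, 0.1)
  expect_equal(one$pooled_beta, 0.2)
  expect_equal(one$pooled_se, 0.1)

  two <- meta_fixed_effect(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(two$pooled_beta, 0.2)
  expect_equal(two$pooled_se, 0.1 / sqrt(2), tolerance = 1e-12)

  for (seed in 1:10) {
    withr::with_seed(seed, {
      k <- sample(2:7, 1)
      beta <- rnorm(k); se <- runif(k, 0.05, 0.5)
    })
    got <- meta_fixed_effect(beta, se)
    want <- meta_oracle(beta, se)
    expect_equal(got$pooled_beta, unname(want["beta"]), tolerance = 1e-12)
    expect_equal(got$pooled_se, unname(want["se"]), tolerance = 1e-12)
    expect_equal(got$pooled_p, unname(want["p"]), tolerance = 1e-12)
  }

  skip_if_not_installed("metafor")
  withr::with_seed(99, { beta <- rnorm(5); se <- runif(5, 0.1, 0.4) })
  ref <- metafor::rma(yi = beta, sei = se, method = "FE")
  got <- meta_fixed_effect(beta, se)
  expect_equal(got$pooled_beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(got$pooled_se, as.numeric(ref$se), tolerance = 1e-10)

  k_id <- meta_fixed_effect(rep(0.3, 4), rep(0.2, 4))
  expect_equal(k_id$pooled_se, 0.2 / sqrt(4), tolerance = 1e-15)
  expect_error(meta_fixed_effect(numeric(), numeric()), "no studies")
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  for (seed in 1:100) {
    p <- withr::with_seed(seed, runif(sample(3:40, 1))^2)
    expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})
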