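# Shared fixtures and independent oracles. Heavy shared computations are
# cached per test run in `.fixture_cache` so several test files can reuse
# the same simulated cohort without re-fitting.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# small cohort: quick discovery for unit tests (3 patients, 400 genes);
# the module link is stronger than the default study conditions so the
# reduced cohort keeps comparable power
small_sim_config <- function(seed = 42, ...) {
  defaults <- list(n_patients = 3,
                   cells_per_type = c(malignant = 60, CAF = 8,
                                      endothelial = 6, B = 8,
                                      macrophage = 8, NK = 6, T = 16),
                   n_genes = 400, n_module_genes = 30, module_beta = 0.8,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_sim <- function() cached("small_sim", simulate_single_cell(small_sim_config()))

random_expr <- function(n_genes, n_obs, seed, scale_tag = "bulk_log2",
                        max_val = 8) {
  withr::with_seed(seed, {
    m <- matrix(round(runif(n_genes * n_obs, 0, max_val), 3), n_genes)
    dimnames(m) <- list(sprintf("G%04d", seq_len(n_genes)),
                        sprintf("O%04d", seq_len(n_obs)))
    expr_matrix(m, scale_tag = scale_tag)
  })
}

# --- independent oracles -------------------------------------------------

# BH step-up from the definition, independent of stats::p.adjust
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

# inverse-variance pooling written out longhand
meta_oracle <- function(beta, se) {
  w <- 1 / se^2
  pb <- sum(w * beta) / sum(w)
  ps <- sqrt(1 / sum(w))
  c(beta = pb, se = ps, z = pb / ps,
    p = 2 * stats::pnorm(-abs(pb / ps)))
}

# brute-force mHG statistic: explicit loop over prefixes
mhg_stat_oracle <- function(membership, n_max) {
  N <- length(membership); K <- sum(membership)
  best <- Inf; best_n <- NA
  b <- 0
  for (n in seq_len(n_max)) {
    b <- b + membership[n]
    tail <- stats::phyper(b - 1, K, N - K, n, lower.tail = FALSE)
    if (tail < best - 1e-15) { best <- tail; best_n <- n }
  }
  list(stat = best, cutoff = best_n)
}

# exact mHG p by full enumeration of all C(N, K) placements
mhg_p_oracle <- function(stat, N, K, n_max) {
  hits <- 0
  combs <- utils::combn(N, K)
  for (j in seq_len(ncol(combs))) {
    mem <- integer(N); mem[combs[, j]] <- 1L
    if (mhg_stat_oracle(mem, n_max)$stat <= stat * (1 + 1e-10)) {
      hits <- hits + 1
    }
  }
  hits / ncol(combs)
}

# Monte-Carlo mHG p via sequential hypergeometric sampling of the first
# n_max ranks, vectorized across permutations
mhg_p_mc <- function(stat, N, K, n_max, n_perm, seed) {
  lat <- sapply(0:K, function(b) {
    stats::phyper(b - 1, K, N - K, seq_len(n_max), lower.tail = FALSE)
  }) # n_max x (K+1)
  withr::with_seed(seed, {
    b <- integer(n_perm)
    mins <- rep(Inf, n_perm)
    for (n in seq_len(n_max)) {
      take <- stats::runif(n_perm) < (K - b) / (N - n + 1)
      b <- b + take
      mins <- pmin(mins, lat[n, b + 1])
    }
    mean(mins <= stat * (1 + 1e-10))
  })
}
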