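#' Minimum-hypergeometric enrichment statistic
#'
#' Over a ranked binary membership vector (1 = target gene), the mHG
#' statistic is the minimum, over prefixes `n = 1..n_max`, of the
#' hypergeometric upper-tail probability `P(X >= b(n))` where `b(n)` is
#' the number of targets in the top `n`. `n_max` is a fraction of the
#' list length (the "first N_max partition").
#'
#' @param membership binary vector in rank order (best rank first).
#' @param n_max_fraction fraction of the list searched (e.g. 0.2, 0.3, 0.4);
#'   ignored when `n_max` is given directly.
#' @param n_max absolute prefix bound, overrides `n_max_fraction`.
#' @return list with `mhg_stat`, `cutoff_rank` (smallest minimizing prefix),
#'   `n_max`, `N`, `K`.
#' @export
mhg_statistic <- function(membership, n_max_fraction = 0.2, n_max = NULL) {
  membership <- as.integer(membership)
  if (any(!membership %in% c(0L, 1L))) abort("membership must be binary")
  N <- length(membership)
  K <- sum(membership)
  if (K == 0 || K == N) abort("need 0 < K < N target genes")
  if (is.null(n_max)) n_max <- floor(n_max_fraction * N)
  n_max <- as.integer(n_max)
  if (n_max < 1 || n_max > N) abort("n_max out of range")
  b <- cumsum(membership[seq_len(n_max)])
  tails <- phyper(b - 1, K, N - K, seq_len(n_max), lower.tail = FALSE)
  i <- which.min(tails)
  list(mhg_stat = tails[i], cutoff_rank = i, n_max = n_max, N = N, K = K)
}

#' Exact p-value for the mHG statistic
#'
#' Probability, under uniformly random placement of `K` targets among `N`
#' ranks, that the prefix-minimum hypergeometric tail over `n <= n_max`
#' reaches `mhg_stat` or less. Computed by dynamic programming on the
#' rank/target-count lattice: lattice paths are counted while blocking
#' every cell whose tail probability is at or below the statistic, and the
#' surviving fraction of the `choose(N, K)` paths is subtracted from 1.
#' Counts are rescaled on the fly and combined in log space, so the DP is
#' stable for large `N`.
#'
#' @param mhg_stat statistic from [mhg_statistic()] with the same
#'   `(N, K, n_max)`.
#' @param N,K,n_max ranked-list size, target count, prefix bound.
#' @return exact p-value in `(0, 1]`, always `>= mhg_stat`.
#' @export
mhg_pvalue <- function(mhg_stat, N, K, n_max) {
  if (K <= 0 || K >= N) abort("need 0 < K < N")
  if (n_max < 1 || n_max > N) abort("n_max out of range")
  thresh <- mhg_stat * (1 + 1e-10) # float-safe "tail <= stat" comparison
  # smallest blocked b per prefix: upper tail decreases in b
  W <- numeric(K + 1)
  W[1] <- 1
  log_scale <- 0
  for (n in seq_len(N)) {
    bmax <- min(n, K)
    idx <- seq_len(bmax) + 1L # positions of b = 1..bmax
    W[idx] <- W[idx] + W[idx - 1L] # RHS evaluated before assignment
    if (n <= n_max) {
      b_range <- 0:bmax
      tails <- phyper(b_range - 1, K, N - K, n, lower.tail = FALSE)
      W[b_range[tails <= thresh] + 1L] <- 0
    }
    mx <- max(W)
    if (mx > 1e280) {
      W <- W / 1e280
      log_scale <- log_scale + log(1e280)
    }
  }
  if (W[K + 1] <= 0) return(1)
  log_surv <- log(W[K + 1]) + log_scale - lchoose(N, K)
  p <- -expm1(log_surv)
  max(min(p, 1), mhg_stat)
}

#' Ranked-list mHG enrichment test
#'
#' Convenience wrapper running [mhg_statistic()] and [mhg_pvalue()] for one
#' or more prefix fractions.
#'
#' @param ranked_genes character vector of gene symbols, best rank first
#'   (break ranking ties by gene symbol before calling for determinism).
#' @param targets character vector of target gene symbols.
#' @param n_max_fraction numeric vector of prefix fractions.
#' @return An `mhg_result` tibble: `n_max_fraction`, `n_max`, `mhg_stat`,
#'   `cutoff_rank`, `p_exact`, `N`, `K`.
#' @export
mhg_test <- function(ranked_genes, targets, n_max_fraction = c(0.2, 0.3, 0.4)) {
  membership <- as.integer(ranked_genes %in% targets)
  rows <- purrr::map(n_max_fraction, function(f) {
    s <- mhg_statistic(membership, n_max_fraction = f)
    tibble(n_max_fraction = f, n_max = s$n_max, mhg_stat = s$mhg_stat,
           cutoff_rank = s$cutoff_rank,
           p_exact = mhg_pvalue(s$mhg_stat, s$N, s$K, s$n_max),
           N = s$N, K = s$K)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("mhg_result", class(out)))
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric upper-tail test of the overlap between a query gene list
#' and each set of a collection, against a stated universe (by default the
#' genes detected in the analyzed dataset, not the genome). BH q-values
#' are computed across the tested sets.
#'
#' @param query character vector of query genes (subset of `universe`;
#'   violations are dropped with a warning).
#' @param collection a `gene_set_collection` (or named list of symbol
#'   vectors).
#' @param universe character vector of background genes.
#' @param min_overlap sets overlapping the query in fewer genes are skipped.
#' @return tibble: `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`.
#' @export
ora_test <- function(query, collection, universe, min_overlap = 2) {
  universe <- unique(toupper(universe))
  if (!length(universe)) abort("empty universe")
  query <- unique(toupper(query))
  out_of <- setdiff(query, universe)
  if (length(out_of)) {
    warn(sprintf("%d query genes outside the universe dropped", length(out_of)))
    query <- intersect(query, universe)
  }
  U <- length(universe)
  q_size <- length(query)
  rows <- purrr::imap(as.list(collection), function(genes, nm) {
    set_u <- intersect(unique(toupper(genes)), universe)
    ov <- length(intersect(set_u, query))
    tibble(set_name = nm, overlap = ov, set_size = length(set_u),
           query_size = q_size, universe_size = U,
           p = phyper(ov - 1, length(set_u), U - length(set_u), q_size,
                      lower.tail = FALSE))
  })
  res <- dplyr::bind_rows(rows) |> dplyr::filter(.data$overlap >= min_overlap)
  res |> dplyr::mutate(q = bh_fdr(.data$p)) |> dplyr::arrange(.data$p)
}
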