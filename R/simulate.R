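#' Simulation configuration
#'
#' Defaults describe the study conditions the package is validated under:
#' 8 patients contributing 150 malignant cells each plus smaller
#' populations of the non-malignant types, 2,000 genes of which 100 form
#' an anchor-linked co-expression module (link strength `module_beta`
#' 0.3 per latent-anchor unit), 96 constitutively expressed housekeeping
#' genes, 20 exclusive marker genes per cell type, and
#' magnitude-dependent dropout with per-cell quality variation (logistic
#' detection with midpoint 4.5 and slope 1 on the pooled log2(TPM + 1)
#' scale, cell midpoints jittered with SD 0.5). Bulk samples mix
#' cell-type mean profiles with Beta(4, 2) tumor purity; survival is
#' exponential with log-hazard `log_hr_per_sd` per SD of the true module
#' score and independent exponential censoring tuned to `censor_frac`.
#'
#' @param n_patients patients in the single-cell cohort.
#' @param cells_per_type named vector of per-patient cell counts.
#' @param n_genes total genes (anchor + housekeeping + markers + module +
#'   decoys).
#' @param n_module_genes planted anchor-coexpressed genes.
#' @param module_beta link strength of module genes to the anchor latent.
#' @param module_cell_types cell types carrying the module link.
#' @param module_elev extra module-gene expression in module cell types.
#' @param module_noise_sd residual SD of module genes.
#' @param anchor anchor gene symbol used in the matrix.
#' @param n_housekeeping housekeeping genes (default 96).
#' @param anchor_mu_module,anchor_mu_other mean anchor latent by type.
#' @param dropout_midpoint,dropout_slope,quality_sd detection-curve
#'   parameters (pooled log2(TPM+1) units).
#' @param bulk_n_samples,bulk_purity_shape1,bulk_purity_shape2,bulk_noise_sd
#'   bulk mixture settings.
#' @param log_hr_per_sd,censor_frac,logor_response survival/response
#'   settings.
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 8,
                       cells_per_type = c(malignant = 150, CAF = 8,
                                          endothelial = 6, B = 8,
                                          macrophage = 8, NK = 6, T = 16),
                       n_genes = 2000,
                       n_module_genes = 100,
                       module_beta = 0.3,
                       module_cell_types = "malignant",
                       module_elev = 0.75,
                       module_noise_sd = 0.5,
                       anchor = "ANCHOR",
                       n_housekeeping = 96,
                       anchor_mu_module = 2.5,
                       anchor_mu_other = 1.0,
                       dropout_midpoint = 4.5,
                       dropout_slope = 1.0,
                       quality_sd = 0.5,
                       bulk_n_samples = 150,
                       bulk_purity_shape1 = 4,
                       bulk_purity_shape2 = 2,
                       bulk_noise_sd = 0.3,
                       log_hr_per_sd = -0.3,
                       censor_frac = 0.3,
                       logor_response = 1.0,
                       seed = NULL) {
  if (is.null(seed)) abort("`seed` is mandatory")
  if (n_module_genes > n_genes / 2) abort("module larger than half the genes")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

softplus <- function(x) log1p(exp(pmin(x, 30)))

#' Simulate an annotated multi-patient single-cell dataset
#'
#' Generates, per cell: a latent anchor activity `a ~ N(mu_type, 1)`
#' (higher mean in module-carrying types), anchor expression
#' `softplus(a)`, module genes `base + module_beta * a + noise` (plus a
#' constant elevation) in module cell types, exclusive cell-type markers
#' including the T-subtype surface markers (CD8A/CD8B, FOXP3/IL2RA, CD4),
#' high-mean low-variance housekeeping genes, and uniform-base decoys.
#' Each value is then zeroed with probability
#' `1 - plogis(slope_c * (e_pooled - midpoint_c))` where the cell-specific
#' midpoint emulates library quality, and clipped at zero.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` ([expr_matrix()], scale `sc_log2_tpm10`),
#'   `annotation` tibble, and `truth` (planted module genes per cell type,
#'   per-cell anchor latent, marker panels, pre-dropout matrix, dropout
#'   curve parameters per cell).
#' @export
simulate_single_cell <- function(cfg) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  types <- names(cfg$cells_per_type)
  cells <- dplyr::bind_rows(purrr::map(seq_len(cfg$n_patients), function(p) {
    dplyr::bind_rows(purrr::map(types, function(t) {
      n <- cfg$cells_per_type[[t]]
      tibble(patient_id = sprintf("P%02d", p), cell_type = t,
             idx = seq_len(n))
    }))
  }))
  n_cells <- nrow(cells)
  cells$obs_id <- sprintf("C%05d", seq_len(n_cells))
  # T subtypes via planted surface-marker expression
  t_sub <- rep("not_applicable", n_cells)
  is_t <- cells$cell_type == "T"
  t_sub[is_t] <- sample(c("CD8T", "CD4Treg", "CD4Th", "otherT"), sum(is_t),
                        replace = TRUE, prob = c(0.35, 0.25, 0.25, 0.15))

  n_markers_per_type <- 20
  surface <- c("CD8A", "CD8B", "FOXP3", "IL2RA", "CD4")
  marker_names <- unlist(purrr::map(types, function(t) {
    sprintf("MK%s%02d", toupper(substr(t, 1, 3)), seq_len(n_markers_per_type))
  }))
  module_names <- sprintf("MOD%03d", seq_len(cfg$n_module_genes))
  hk_names <- sprintf("HK%03d", seq_len(cfg$n_housekeeping))
  n_decoy <- cfg$n_genes - 1 - cfg$n_housekeeping - length(marker_names) -
    length(surface) - cfg$n_module_genes
  if (n_decoy < 1) abort("n_genes too small for the configured components")
  decoy_names <- sprintf("DEC%04d", seq_len(n_decoy))
  genes <- c(toupper(cfg$anchor), hk_names, marker_names, surface,
             module_names, decoy_names)

  in_module_type <- cells$cell_type %in% cfg$module_cell_types
  a <- rnorm(n_cells,
             ifelse(in_module_type, cfg$anchor_mu_module,
                    cfg$anchor_mu_other), 1)

  X <- matrix(0, length(genes), n_cells, dimnames = list(genes, cells$obs_id))
  X[1, ] <- softplus(a)
  hk_mu <- rnorm(cfg$n_housekeeping, 6, 0.5)
  X[hk_names, ] <- hk_mu + matrix(rnorm(cfg$n_housekeeping * n_cells, 0, 0.3),
                                  ncol = n_cells)
  for (i in seq_along(types)) {
    mk <- marker_names[(i - 1) * n_markers_per_type + seq_len(n_markers_per_type)]
    own <- cells$cell_type == types[i]
    X[mk, ] <- 0.3 + abs(matrix(rnorm(length(mk) * n_cells, 0, 0.2),
                                ncol = n_cells))
    X[mk, own] <- 6.5 + matrix(rnorm(length(mk) * sum(own), 0, 0.5),
                               ncol = sum(own))
  }
  # T-subtype surface markers
  X[surface, ] <- abs(matrix(rnorm(length(surface) * n_cells, 0.3, 0.2),
                             ncol = n_cells))
  hi <- function(n) 8 + rnorm(n, 0, 0.6)
  cd8 <- t_sub == "CD8T"; trg <- t_sub == "CD4Treg"; th <- t_sub == "CD4Th"
  X["CD8A", cd8] <- hi(sum(cd8)); X["CD8B", cd8] <- hi(sum(cd8))
  X["FOXP3", trg] <- hi(sum(trg)); X["IL2RA", trg] <- hi(sum(trg))
  X["CD4", trg] <- hi(sum(trg)); X["CD4", th] <- hi(sum(th))

  base_mod <- runif(cfg$n_module_genes, 3, 6)
  X[module_names, ] <- base_mod +
    matrix(rnorm(cfg$n_module_genes * n_cells, 0, cfg$module_noise_sd),
           ncol = n_cells)
  X[module_names, in_module_type] <-
    sweep(X[module_names, in_module_type, drop = FALSE], 2,
          cfg$module_beta * a[in_module_type], `+`) + cfg$module_elev

  base_dec <- runif(n_decoy, 1, 7)
  X[decoy_names, ] <- base_dec +
    matrix(rnorm(n_decoy * n_cells, 0, 0.7), ncol = n_cells)
  X <- pmax(X, 0)

  # magnitude-dependent dropout with per-cell quality
  lin <- 10 * (2^X - 1)
  ep <- log2(rowMeans(lin) + 1)
  mid_c <- rnorm(n_cells, cfg$dropout_midpoint, cfg$quality_sd)
  slope_c <- rep(cfg$dropout_slope, n_cells)
  p_det <- plogis(outer(ep, mid_c, `-`) * rep(slope_c, each = length(ep)))
  Y <- X * (matrix(runif(length(X)), nrow(X)) < p_det)

  truth <- list(
    scg = setNames(lapply(types, function(t) {
      if (t %in% cfg$module_cell_types) module_names else character()
    }), types),
    module_genes = module_names,
    anchor_latent = setNames(a, cells$obs_id),
    markers = tibble(
      cell_type = rep(types, each = n_markers_per_type),
      gene_id = marker_names),
    housekeeping = hk_names,
    t_subtype = setNames(t_sub, cells$obs_id),
    pre_dropout = X,
    dropout = tibble(obs_id = cells$obs_id, midpoint = mid_c,
                     slope = slope_c))
  list(expr = expr_matrix(Y, scale_tag = "sc_log2_tpm10"),
       annotation = tibble(obs_id = cells$obs_id,
                           patient_id = cells$patient_id,
                           cell_type = cells$cell_type,
                           t_subtype = "not_applicable"),
       truth = truth)
}

#' Simulate bulk mixtures with clinical outcomes
#'
#' Each bulk sample is a purity-weighted mixture of the single-cell
#' type-mean profiles (malignant fraction = purity; the remainder split
#' over the other types by a uniform Dirichlet draw) plus Gaussian noise.
#' The true score is the Z-scored mean of the planted module genes in the
#' noisy bulk matrix; survival times are exponential with log-hazard
#' `log_hr_per_sd` per true-score SD under independent exponential
#' censoring, and the binary response follows a logistic model in the
#' true score.
#'
#' @param cfg a [sim_config()].
#' @param sc output of [simulate_single_cell()] (profiles and truth).
#' @return list with `expr` (bulk [expr_matrix()]), `clinical` tibble
#'   (`sample_id`, `time`, `event`, `gender`, `age`, `purity`,
#'   `response`), and `truth` (`purity`, per-type fractions, `true_score`,
#'   `log_hr_per_sd`).
#' @export
simulate_bulk <- function(cfg, sc) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(cfg$seed + 1L)
  ann <- sc$annotation
  m <- unclass(sc$expr)
  types <- unique(ann$cell_type)
  profiles <- sapply(types, function(t) {
    rowMeans(m[, ann$obs_id[ann$cell_type == t], drop = FALSE])
  })
  n <- cfg$bulk_n_samples
  purity <- rbeta(n, cfg$bulk_purity_shape1, cfg$bulk_purity_shape2)
  if (any(purity < 0 | purity > 1)) abort("purity outside [0, 1]")
  others <- setdiff(types, "malignant")
  w_other <- matrix(rexp(n * length(others)), n)
  w_other <- w_other / rowSums(w_other) * (1 - purity)
  frac <- cbind(malignant = purity, w_other)
  colnames(frac) <- c("malignant", others)
  B <- profiles[, colnames(frac)] %*% t(frac) +
    matrix(rnorm(nrow(profiles) * n, 0, cfg$bulk_noise_sd), ncol = n)
  B <- pmax(B, 0)
  colnames(B) <- sprintf("S%04d", seq_len(n))
  rownames(frac) <- colnames(B)
  true_score <- as.numeric(scale(colMeans(B[sc$truth$module_genes, ,
                                            drop = FALSE])))
  rate0 <- 1 / 1000 # baseline hazard, per day
  t_event <- rexp(n, rate0 * exp(cfg$log_hr_per_sd * true_score))
  cens_rate <- rate0 * cfg$censor_frac / max(1 - cfg$censor_frac, 1e-6)
  t_cens <- if (cfg$censor_frac > 0) rexp(n, cens_rate) else rep(Inf, n)
  response <- rbinom(n, 1, plogis(cfg$logor_response * true_score))
  clinical <- tibble(
    sample_id = colnames(B),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    gender = sample(c("F", "M"), n, replace = TRUE),
    age = rnorm(n, 60, 10),
    purity = purity,
    response = response)
  list(expr = expr_matrix(B, scale_tag = "bulk_log2"),
       clinical = clinical,
       truth = list(purity = setNames(purity, colnames(B)),
                    fractions = frac,
                    true_score = setNames(true_score, colnames(B)),
                    log_hr_per_sd = cfg$log_hr_per_sd))
}
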