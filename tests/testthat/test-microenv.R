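test_that("planted exclusive markers are recovered, ubiquitous genes are not", {
  sim <- small_sim()
  panel <- suppressWarnings(find_markers(sim$expr, sim$annotation))
  truth <- sim$truth$markers
  for (t in unique(truth$cell_type)) {
    planted <- truth$gene_id[truth$cell_type == t]
    got <- panel$gene_id[panel$cell_type == t]
    expect_gt(length(intersect(got, planted)) / length(planted), 0.9)
  }
  # housekeeping genes are expressed everywhere: never markers
  expect_length(intersect(panel$gene_id, sim$truth$housekeeping), 0)
  # panels are disjoint by construction
  expect_false(anyDuplicated(panel$gene_id) > 0)
})

test_that("metagenes average available markers and respect the 50% rule", {
  m <- expr_matrix(matrix(c(2, 4, 1, 6, 5, 5), 3, 2, byrow = TRUE),
                   c("MA", "MB", "MC"), c("s1", "s2"), "bulk_log2")
  panel <- tibble::tibble(cell_type = c("B", "B", "NK", "NK"),
                          gene_id = c("MA", "MB", "MC", "GONE"))
  out <- compute_metagenes(m, panel)
  b <- out[out$cell_type == "B", ]
  expect_equal(b$value, c(mean(c(2, 1)), mean(c(4, 6))))
  nk <- out[out$cell_type == "NK", ]
  expect_equal(unique(nk$frac_markers_present), 0.5)
  # below half present: metagene omitted
  panel2 <- tibble::tibble(cell_type = "T",
                           gene_id = c("MC", "GONE1", "GONE2"))
  expect_warning(out2 <- compute_metagenes(m, panel2), "omitted")
  expect_equal(nrow(out2), 0)
  # duplicated marker entries and order do not change the value
  dup <- tibble::tibble(cell_type = "B", gene_id = c("MB", "MA", "MA"))
  out3 <- compute_metagenes(m, dup)
  expect_equal(out3$value, b$value)
})

test_that("metagene-score correlation matches the closed form with CIs", {
  withr::with_seed(31, {
    score_v <- rnorm(60)
    mg_v <- 0.7 * score_v + rnorm(60, 0, 0.5)
  })
  score <- tibble::tibble(obs_id = sprintf("s%02d", 1:60), score = score_v)
  mg <- tibble::tibble(obs_id = sprintf("s%02d", 1:60), cell_type = "NK",
                       value = mg_v)
  res <- correlate_score_metagenes(score, mg)
  manual <- sum((score_v - mean(score_v)) * (mg_v - mean(mg_v))) /
    sqrt(sum((score_v - mean(score_v))^2) * sum((mg_v - mean(mg_v))^2))
  expect_equal(res$r, manual, tolerance = 1e-12)
  expect_true(res$conf.low < res$r && res$r < res$conf.high)

  self <- correlate_score_metagenes(
    score, dplyr::mutate(mg, value = score_v))
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_lt(self$p, 1e-12)
  expect_error(correlate_score_metagenes(score[1:5, ], mg[1:5, ]), ">= 10")
})

test_that("crosstalk edges require ligand in SCGs and expressed receptor", {
  genes <- c("CXCL12", "CXCR4", "CCL5", "CCR5", "FILL1", "FILL2")
  n_per <- 20
  types <- c("malignant", "T", "NK", "B")
  ann <- tibble::tibble(
    obs_id = sprintf("c%03d", seq_len(n_per * length(types))),
    patient_id = "P1",
    cell_type = rep(types, each = n_per),
    t_subtype = "not_applicable")
  m <- matrix(0, length(genes), nrow(ann),
              dimnames = list(genes, ann$obs_id))
  m["CXCR4", ann$cell_type %in% c("T", "NK")] <- 4 # receptor on T/NK only
  m["FILL1", ] <- 2; m["FILL2", ] <- 2
  em <- expr_matrix(m, scale_tag = "sc_log2_tpm10")
  pairs <- tibble::tibble(ligand = c("CXCL12", "CCL5"),
                          receptor = c("CXCR4", "CCR5"))
  edges <- crosstalk_map(c("CXCL12", "CCL5"), pairs, em, ann,
                         source_cell_type = "malignant")
  expect_setequal(edges$target_cell_type[edges$ligand == "CXCL12"],
                  c("T", "NK"))
  # CCR5 expressed nowhere: no edge despite CCL5 being an SCG
  expect_false("CCL5" %in% edges$ligand)
  expect_true(all(edges$receptor_evidence >= 0.1 &
                    edges$receptor_evidence <= 1))
  # ligand not in the SCG list contributes nothing
  none <- crosstalk_map("FILL1", pairs, em, ann, source_cell_type = "malignant")
  expect_equal(nrow(none), 0)
  expect_error(crosstalk_map("CXCL12", pairs[0, ], em, ann), "empty")
})

test_that("crosstalk output shrinks as thresholds tighten", {
  sim <- small_sim()
  scg <- sim$truth$module_genes
  pairs <- tibble::tibble(ligand = scg[1:5],
                          receptor = sim$truth$markers$gene_id[1:5])
  loose <- crosstalk_map(scg, pairs, sim$expr, sim$annotation,
                         expr_threshold = 0.5, min_frac = 0.05,
                         source_cell_type = "malignant")
  tight <- crosstalk_map(scg, pairs, sim$expr, sim$annotation,
                         expr_threshold = 2, min_frac = 0.3,
                         source_cell_type = "malignant")
  expect_lte(nrow(tight), nrow(loose))
})
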