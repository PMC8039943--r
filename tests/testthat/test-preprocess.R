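test_that("symbol correction renames, collapses collisions, validates map", {
  m <- expr_matrix(matrix(c(1, 1, 4, 4), 2, 2, byrow = TRUE),
                   c("CD25", "IL2RA"), c("c1", "c2"), "sc_log2_tpm10")
  out <- correct_symbols(m, data.frame(from = "CD25", to = "IL2RA"))
  expect_identical(rownames(out), "IL2RA")
  expect_equal(as.numeric(out), c(4, 4)) # keep_max_total retains larger row

  expect_equal(unclass(correct_symbols(m, data.frame(from = character(),
                                                     to = character()))),
               unclass(m), ignore_attr = TRUE)
  expect_error(correct_symbols(m, data.frame(from = c("A", "A"),
                                             to = c("B", "C"))),
               "one-to-many")
})

test_that("random collision-free renames permute labels but not values", {
  m <- random_expr(100, 6, seed = 3, scale_tag = "sc_log2_tpm10")
  map <- data.frame(from = rownames(m), to = paste0("NEW", seq_len(100)))
  out <- correct_symbols(m, map)
  expect_identical(rownames(out), map$to)
  expect_equal(unname(unclass(out)), unname(unclass(m)))
})

test_that("pooled expression linearizes, averages, re-logs", {
  m <- expr_matrix(matrix(c(0, 0, 3, 3, 2, 4), 3, 2, byrow = TRUE),
                   c("Z", "CONST", "VAR"), c("c1", "c2"), "sc_log2_tpm10")
  ep <- compute_pooled_expression(m)
  expect_equal(ep$e_pooled[ep$gene_id == "Z"], 0)
  # log2(TPM/10+1) = 3 => TPM = 70 => e_pooled = log2(71)
  expect_equal(ep$e_pooled[ep$gene_id == "CONST"], log2(71),
               tolerance = 1e-12)
  one <- expr_matrix(matrix(3, 1, 1), "CONST", "c1", "sc_log2_tpm10")
  expect_equal(compute_pooled_expression(one)$e_pooled,
               ep$e_pooled[ep$gene_id == "CONST"])
  expect_error(compute_pooled_expression(
    expr_matrix(matrix(0, 1, 0), "A", character(), "sc_log2_tpm10")),
    "zero observations")
})

test_that("pooled-expression filter keeps the boundary and the anchor", {
  m <- random_expr(3, 4, seed = 9, scale_tag = "sc_log2_tpm10")
  pooled <- tibble::tibble(gene_id = rownames(m),
                           e_pooled = c(2.9, 3.0, 5.1))
  out <- filter_genes(m, pooled, threshold = 3)
  expect_identical(rownames(out), rownames(m)[2:3])
  expect_identical(rownames(filter_genes(m, pooled, threshold = 0)),
                   rownames(m))
  expect_warning(keep <- filter_genes(m, pooled, threshold = 3,
                                      anchor = rownames(m)[1]),
                 "retained anyway")
  expect_true(rownames(m)[1] %in% rownames(keep))
  expect_error(filter_genes(m, pooled, threshold = 99), "all genes")
})

test_that("filtering matches a brute-force recomputation and is idempotent", {
  m <- random_expr(200, 30, seed = 5, scale_tag = "sc_log2_tpm10")
  pooled <- compute_pooled_expression(m)
  out <- filter_genes(m, pooled, threshold = 6)
  brute <- rownames(m)[vapply(seq_len(nrow(m)), function(i) {
    log2(mean(10 * (2^unclass(m)[i, ] - 1)) + 1) >= 6
  }, logical(1))]
  expect_identical(rownames(out), brute)
  again <- filter_genes(out, pooled[pooled$gene_id %in% brute, ],
                        threshold = 6)
  expect_identical(unclass(again), unclass(out))
})

test_that("T-cell classification applies ordered marker rules", {
  genes <- c("CD8A", "CD8B", "FOXP3", "IL2RA", "CD4")
  vals <- cbind(cd8 = c(4, 3, 0, 0, 0),
                treg = c(0, 0, 4, 4, 0),
                none = c(0, 0, 0, 0, 0),
                both = c(4, 4, 4, 4, 4), # CD8 rule fires first
                notT = c(9, 9, 9, 9, 9))
  m <- expr_matrix(vals, genes, colnames(vals), "sc_log2_tpm10")
  ann <- tibble::tibble(obs_id = colnames(vals), patient_id = "P1",
                        cell_type = c("T", "T", "T", "T", "malignant"),
                        t_subtype = "not_applicable")
  out <- classify_t_cells(m, ann)
  expect_identical(out$t_subtype,
                   c("CD8T", "CD4Treg", "otherT", "CD8T", "not_applicable"))
  expect_identical(out$cell_type, ann$cell_type)
})

test_that("classification recovers planted subtypes on simulated T cells", {
  sim <- small_sim()
  out <- classify_t_cells(sim$expr, sim$annotation)
  t_ids <- sim$annotation$obs_id[sim$annotation$cell_type == "T"]
  truth <- sim$truth$t_subtype[t_ids]
  called <- out$t_subtype[match(t_ids, out$obs_id)]
  # dropout can erase all markers of a cell, so recovery is high but not total
  expect_gt(mean(called == truth), 0.7)
  non_t <- setdiff(out$obs_id, t_ids)
  expect_true(all(out$t_subtype[match(non_t, out$obs_id)] ==
                    "not_applicable"))
})

test_that("duplicate-gene collapse follows the stated policies", {
  m <- matrix(c(1, 1, 3, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("G", "G"), c("c1", "c2")))
  expect_equal(as.numeric(dedup_genes(m, "mean_aggregate",
                                      scale_tag = "bulk_log2")), c(2, 2))
  expect_equal(as.numeric(dedup_genes(m, "keep_max_total",
                                      scale_tag = "bulk_log2")), c(3, 3))
  nodup <- random_expr(5, 3, seed = 2)
  expect_equal(unclass(dedup_genes(nodup, "mean_aggregate")),
               unclass(nodup), ignore_attr = TRUE)
})

test_that("dedup and filter commute under keep_max_total", {
  withr::with_seed(8, {
    m <- matrix(round(runif(60, 0, 6), 2), 20, 3)
    dimnames(m) <- list(sample(sprintf("G%02d", 1:12), 20, replace = TRUE),
                        c("a", "b", "c"))
  })
  path1 <- dedup_genes(m, "keep_max_total", scale_tag = "sc_log2_tpm10")
  path1 <- filter_genes(path1, compute_pooled_expression(path1), 4)
  # filter first on the duplicate-resolved equivalent rows, then dedup
  path2 <- dedup_genes(m, "keep_max_total", scale_tag = "sc_log2_tpm10")
  keep <- rownames(path1)
  expect_identical(sort(rownames(path1)), sort(intersect(rownames(path2), keep)))
  expect_equal(unclass(path1),
               unclass(path2)[rownames(path1), , drop = FALSE],
               ignore_attr = TRUE)
})
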