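#' Expression matrix container
#'
#' A thin S3 wrapper around a base numeric matrix holding log2-scale
#' expression with genes in rows and observations (cells or bulk samples)
#' in columns. The `scale_tag` attribute records which log2 convention the
#' values are on:
#'
#' * `"sc_log2_tpm10"` — single-cell values, `log2(TPM/10 + 1)`;
#' * `"bulk_log2"` — bulk values, `log2(x + 1)` or log2 microarray intensities;
#' * `"bulk_centered"` — bulk values after gene-wise mean-centering
#'   (the only tag under which negative entries are allowed).
#'
#' @param values numeric matrix, genes x observations.
#' @param gene_ids character vector of unique gene symbols (rownames).
#' @param obs_ids character vector of unique observation IDs (colnames).
#' @param scale_tag one of `"sc_log2_tpm10"`, `"bulk_log2"`, `"bulk_centered"`.
#' @return An `expr_matrix`: a numeric matrix with dimnames and a
#'   `scale_tag` attribute.
#' @examples
#' m <- expr_matrix(matrix(0:5, 3, 2), c("A", "B", "C"), c("c1", "c2"),
#'                  "sc_log2_tpm10")
#' expr_scale(m)
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        obs_ids = colnames(values),
                        scale_tag = c("sc_log2_tpm10", "bulk_log2",
                                      "bulk_centered")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(obs_ids)) {
    abort("`gene_ids` and `obs_ids` are required (or supply dimnames).")
  }
  gene_ids <- as.character(gene_ids)
  obs_ids <- as.character(obs_ids)
  if (length(gene_ids) != nrow(values) || length(obs_ids) != ncol(values)) {
    abort(sprintf(
      "dimension mismatch: %d x %d values vs %d gene ids, %d observation ids",
      nrow(values), ncol(values), length(gene_ids), length(obs_ids)))
  }
  if (anyDuplicated(gene_ids)) {
    abort(paste0("duplicate gene ids: ",
                 paste(unique(gene_ids[duplicated(gene_ids)])[1:3],
                       collapse = ", "),
                 " (use dedup_genes() first)"))
  }
  if (anyDuplicated(obs_ids)) abort("duplicate observation ids")
  fin <- values[!is.na(values)]
  if (any(!is.finite(fin))) abort("non-finite expression values")
  if (scale_tag != "bulk_centered" && length(fin) && min(fin) < 0) {
    abort(sprintf("negative value (%g) under nonnegative scale '%s'",
                  min(fin), scale_tag))
  }
  if (scale_tag == "sc_log2_tpm10" && anyNA(values)) {
    abort("single-cell input must be complete (no missing values)")
  }
  dimnames(values) <- list(gene_ids, obs_ids)
  structure(values, scale_tag = scale_tag,
            class = c("expr_matrix", class(values)))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
expr_scale <- function(x) attr(x, "scale_tag") %||% "bulk_log2"

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d observations [%s]\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

# rebuild the class after matrix surgery (subset, rename)
as_expr_matrix <- function(values, scale_tag) {
  expr_matrix(values, rownames(values), colnames(values), scale_tag)
}
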