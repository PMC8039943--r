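#' Read an expression matrix from disk
#'
#' Supports a dense TSV layout (gene symbols in the first column, header row
#' of observation IDs) and Matrix Market triplet files with sidecar ID files
#' (one ID per line; `<path>.genes.txt` / `<path>.obs.txt` by default).
#' Orientation is normalized to genes x observations; gene symbols are
#' uppercased; file order is preserved.
#'
#' @param path input file.
#' @param format `"tsv_dense"` or `"mtx_triplet"`.
#' @param scale_tag scale of the stored values, see [expr_matrix()].
#' @param gene_file,obs_file sidecar ID files for MTX input.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path,
                            format = c("tsv_dense", "mtx_triplet"),
                            scale_tag = "bulk_log2",
                            gene_file = paste0(path, ".genes.txt"),
                            obs_file = paste0(path, ".obs.txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "tsv_dense") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (ncol(df) < 2) abort(sprintf("%s line 1: malformed header (< 2 columns)", path))
    genes <- toupper(as.character(df[[1]]))
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
      abort(sprintf("%s: non-numeric expression column '%s'",
                    path, names(df)[-1][bad]))
    }
    neg <- which(vals < 0, arr.ind = TRUE)
    if (nrow(neg) && scale_tag != "bulk_centered") {
      abort(sprintf("%s line %d: negative value under scale '%s'",
                    path, neg[1, 1] + 1L, scale_tag))
    }
    rownames(vals) <- genes
    m <- vals
  } else {
    if (!file.exists(gene_file) || !file.exists(obs_file)) {
      abort("MTX input needs sidecar gene and observation ID files")
    }
    sp <- Matrix::readMM(path)
    genes <- toupper(readr::read_lines(gene_file, progress = FALSE))
    obs <- readr::read_lines(obs_file, progress = FALSE)
    if (nrow(sp) == length(genes) && ncol(sp) == length(obs)) {
      m <- as.matrix(sp)
    } else if (nrow(sp) == length(obs) && ncol(sp) == length(genes)) {
      m <- t(as.matrix(sp)) # stored observations x genes; normalize
    } else {
      abort(sprintf(
        "%s: %d x %d matrix does not match %d genes / %d observations",
        path, nrow(sp), ncol(sp), length(genes), length(obs)))
    }
    dimnames(m) <- list(genes, obs)
  }
  if (anyDuplicated(rownames(m))) {
    abort("duplicate gene symbols in input; use dedup_genes() on a raw matrix")
  }
  expr_matrix(m, scale_tag = scale_tag)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; `write_expression()` then
#' `read_expression()` reproduces gene IDs, observation IDs and values.
#'
#' @inheritParams read_expression
#' @param x an [expr_matrix()].
#' @export
write_expression <- function(x, path,
                             format = c("tsv_dense", "mtx_triplet"),
                             gene_file = paste0(path, ".genes.txt"),
                             obs_file = paste0(path, ".obs.txt")) {
  format <- match.arg(format)
  if (format == "tsv_dense") {
    df <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
    df <- dplyr::bind_cols(tibble(gene = rownames(x)), df)
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE), path)
    readr::write_lines(rownames(x), gene_file)
    readr::write_lines(colnames(x), obs_file)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each non-empty line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Gene symbols are uppercased and deduplicated within a set.
#'
#' @param path GMT file.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `description` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn(sprintf("%s: empty GMT file", path))
    return(gene_set_collection(list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(sprintf("%s line %d: GMT line has %d < 3 tab-separated fields",
                  path, which(nf < 3)[1], nf[nf < 3][1]))
  }
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  gene_set_collection(sets, vapply(parts, `[[`, character(1), 2))
}

#' @rdname read_gene_sets
#' @param sets named list of gene symbol vectors.
#' @param description character vector of per-set descriptions.
#' @export
gene_set_collection <- function(sets, description = rep("", length(sets))) {
  if (length(sets) && any(lengths(sets) == 0)) abort("empty gene set")
  sets <- lapply(sets, function(g) unique(toupper(g)))
  structure(sets, description = setNames(description, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d genes total\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' @rdname read_gene_sets
#' @param x a `gene_set_collection`.
#' @export
write_gene_sets <- function(x, path) {
  desc <- attr(x, "description") %||% setNames(rep("", length(x)), names(x))
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], desc[[i]], x[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a curated ligand-receptor pair table
#'
#' CSV with columns `ligand` and `receptor`; symbols uppercased, duplicate
#' pairs dropped.
#'
#' @param path CSV file.
#' @return tibble with columns `ligand`, `receptor`.
#' @export
read_lr_pairs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df))) {
    abort(sprintf("%s: need columns 'ligand' and 'receptor'", path))
  }
  out <- df |>
    dplyr::transmute(ligand = toupper(trimws(.data$ligand)),
                     receptor = toupper(trimws(.data$receptor))) |>
    dplyr::filter(nzchar(.data$ligand), nzchar(.data$receptor)) |>
    dplyr::distinct()
  out
}

#' Read / validate a cell annotation table
#'
#' TSV with columns `obs_id`, `patient_id`, `cell_type` and optionally
#' `t_subtype`. Cell types outside the recognized vocabulary raise an error;
#' a missing `t_subtype` column is filled with `"not_applicable"`.
#'
#' @param path TSV file.
#' @return tibble with the four annotation columns.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotations(df)
}

cell_type_levels <- function() {
  c("malignant", "CAF", "endothelial", "B", "macrophage", "NK", "T",
    "unresolved")
}

t_subtype_levels <- function() {
  c("CD4Th", "CD4Treg", "CD8T", "otherT", "not_applicable")
}

validate_annotations <- function(df) {
  need <- c("obs_id", "patient_id", "cell_type")
  if (!all(need %in% names(df))) {
    abort(paste0("annotation table needs columns: ",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (!"t_subtype" %in% names(df)) df$t_subtype <- "not_applicable"
  bad <- setdiff(unique(df$cell_type), cell_type_levels())
  if (length(bad)) abort(paste0("unknown cell_type: ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(df$t_subtype), t_subtype_levels())
  if (length(bad)) abort(paste0("unknown t_subtype: ", paste(bad, collapse = ", ")))
  if (anyDuplicated(df$obs_id)) abort("duplicate obs_id in annotation")
  if (any(df$t_subtype != "not_applicable" & df$cell_type != "T")) {
    abort("t_subtype set on a non-T cell")
  }
  as_tibble(df[, c("obs_id", "patient_id", "cell_type", "t_subtype")])
}
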