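#' Construct an OmicsDataset
#'
#' The basic container for one modality's cell-by-feature matrix together
#' with per-cell covariates, optional cell-type labels, and an optional
#' pairing map that links local cells to global joint-cell identifiers for
#' jointly-profiled data.
#'
#' @param matrix cells x features numeric matrix (dense or a `Matrix` sparse
#'   matrix; sparse input is kept sparse)
#' @param feature_ids character vector, one id per column
#' @param cell_ids character vector, one barcode per row
#' @param modality modality tag, e.g. `"rna"`, `"atac"`, `"histone:H3K4me3"`,
#'   `"methyl:CG"`, or `"other"`
#' @param covariates data.frame of per-cell categorical covariates
#'   (batch / species / modality); one row per cell
#' @param cell_type_labels optional character vector or data.frame of
#'   per-cell annotations
#' @param pairing optional named character vector mapping `cell_ids` to
#'   global joint-cell identifiers; names must be a subset of `cell_ids` and
#'   identifiers must be unique within the dataset
#' @return an object of class `OmicsDataset`
#' @export
omics_dataset <- function(matrix, feature_ids, cell_ids, modality = "other",
                          covariates = NULL, cell_type_labels = NULL,
                          pairing = NULL) {
  stop_if(nrow(matrix) != length(cell_ids),
          "matrix has ", nrow(matrix), " rows but ", length(cell_ids),
          " cell ids")
  stop_if(ncol(matrix) != length(feature_ids),
          "matrix has ", ncol(matrix), " columns but ", length(feature_ids),
          " feature ids")
  stop_if(anyDuplicated(cell_ids) > 0, "duplicated cell ids")
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = cell_ids)
  } else {
    covariates <- as.data.frame(covariates)
    stop_if(nrow(covariates) != length(cell_ids),
            "covariates must have one row per cell")
    rownames(covariates) <- cell_ids
  }
  if (!is.null(cell_type_labels) && !is.data.frame(cell_type_labels)) {
    stop_if(length(cell_type_labels) != length(cell_ids),
            "cell_type_labels must have one value per cell")
    cell_type_labels <- as.character(cell_type_labels)
  }
  if (!is.null(pairing)) {
    stop_if(is.null(names(pairing)), "pairing must be named by cell id")
    stop_if(!all(names(pairing) %in% cell_ids),
            "pairing names must be cell ids of this dataset")
    stop_if(anyDuplicated(pairing) > 0,
            "joint-cell identifiers must be unique within a dataset")
    pairing <- setNames(as.character(pairing), names(pairing))
  }
  rownames(matrix) <- cell_ids
  colnames(matrix) <- feature_ids
  structure(list(matrix = matrix,
                 feature_ids = as.character(feature_ids),
                 cell_ids = as.character(cell_ids),
                 modality = modality,
                 covariates = covariates,
                 cell_type_labels = cell_type_labels,
                 pairing = pairing),
            class = "OmicsDataset")
}

#' @export
print.OmicsDataset <- function(x, ...) {
  cat(sprintf("OmicsDataset [%s]: %d cells x %d features (%s)\n",
              x$modality, length(x$cell_ids), length(x$feature_ids),
              if (is(x$matrix, "Matrix")) "sparse" else "dense"))
  if (ncol(x$covariates) > 0) {
    cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  }
  if (!is.null(x$pairing)) {
    cat("  paired cells:", length(x$pairing), "\n")
  }
  invisible(x)
}

#' @export
dim.OmicsDataset <- function(x) dim(x$matrix)

#' Read a cell-by-feature dataset from disk
#'
#' Supported formats: MatrixMarket (`mtx`, with companion `features.tsv` and
#' `barcodes.tsv` files in the same directory or given via the companion
#' arguments; the on-disk matrix is features x cells in the 10x convention
#' and is transposed on read) and plain `tsv` (cells in rows, header row of
#' feature ids, first column of barcodes). AnnData `h5ad` is not supported
#' by this implementation; export to MTX or TSV upstream.
#'
#' @param path path to the matrix file
#' @param format one of `"mtx"`, `"tsv"`
#' @param features_path,barcodes_path companion files for `mtx` (defaults to
#'   `features.tsv` / `barcodes.tsv` next to the matrix)
#' @param modality,covariates,cell_type_labels,pairing passed to
#'   [omics_dataset()]
#' @return an [omics_dataset()]
#' @export
read_dataset <- function(path, format = c("mtx", "tsv", "h5ad"),
                         features_path = NULL, barcodes_path = NULL,
                         modality = "other", covariates = NULL,
                         cell_type_labels = NULL, pairing = NULL) {
  format <- match.arg(format)
  stop_if(!file.exists(path), "input file not found: ", path)
  if (format == "h5ad") {
    stop("h5ad input is not supported; convert to MTX + TSV upstream",
         call. = FALSE)
  }
  if (format == "mtx") {
    dir <- dirname(path)
    features_path <- features_path %||% file.path(dir, "features.tsv")
    barcodes_path <- barcodes_path %||% file.path(dir, "barcodes.tsv")
    stop_if(!file.exists(features_path),
            "missing companion feature file: ", features_path)
    stop_if(!file.exists(barcodes_path),
            "missing companion barcode file: ", barcodes_path)
    m <- Matrix::t(Matrix::readMM(path))
    feats <- read.delim(features_path, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(barcodes_path, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    stop_if(nrow(m) != length(cells),
            "matrix has ", nrow(m), " cells but barcode file lists ",
            length(cells))
    stop_if(ncol(m) != length(feats),
            "matrix has ", ncol(m), " features but feature file lists ",
            length(feats))
    mat <- as(m, "CsparseMatrix")
    omics_dataset(mat, feats, cells, modality = modality,
                  covariates = covariates,
                  cell_type_labels = cell_type_labels, pairing = pairing)
  } else {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    cells <- as.character(tab[[1]])
    mat <- as.matrix(tab[, -1, drop = FALSE])
    omics_dataset(mat, colnames(mat), cells, modality = modality,
                  covariates = covariates,
                  cell_type_labels = cell_type_labels, pairing = pairing)
  }
}

#' Write a dataset to MTX + TSV companions
#'
#' Writes the matrix as MatrixMarket (features x cells, 10x convention) next
#' to `features.tsv` and `barcodes.tsv`.
#'
#' @param dataset an [omics_dataset()]
#' @param dir output directory (created if missing)
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "OmicsDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as(Matrix::t(Matrix::Matrix(dataset$matrix, sparse = TRUE)),
          "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(dataset$feature_ids, file.path(dir, "features.tsv"))
  writeLines(dataset$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(file.path(dir, "matrix.mtx"))
}

#' Construct an EmbeddingTable
#'
#' The unit of all downstream evaluation: integrated latent coordinates with
#' their provenance.
#'
#' @param z cells x k numeric matrix of latent coordinates; must be finite
#' @param cell_ids character vector of barcodes
#' @param covariates optional per-cell data.frame (batch / species /
#'   modality)
#' @param cell_type_labels optional per-cell annotation
#' @param source_dataset per-cell tag naming the dataset each row came from
#' @return object of class `EmbeddingTable`
#' @export
embedding_table <- function(z, cell_ids, covariates = NULL,
                            cell_type_labels = NULL, source_dataset = NULL) {
  z <- as_dense(z)
  stop_if(nrow(z) != length(cell_ids), "z rows must match cell ids")
  stop_if(any(!is.finite(z)), "embedding contains non-finite values")
  if (is.null(covariates)) covariates <- data.frame(row.names = cell_ids)
  covariates <- as.data.frame(covariates)
  stop_if(nrow(covariates) != length(cell_ids),
          "covariates must have one row per cell")
  rownames(covariates) <- cell_ids
  if (!is.null(cell_type_labels)) {
    stop_if(length(cell_type_labels) != length(cell_ids),
            "cell_type_labels must have one value per cell")
    cell_type_labels <- as.character(cell_type_labels)
  }
  if (is.null(source_dataset)) source_dataset <- rep(NA_character_,
                                                     length(cell_ids))
  rownames(z) <- cell_ids
  structure(list(z = z, cell_ids = as.character(cell_ids),
                 covariates = covariates,
                 cell_type_labels = cell_type_labels,
                 source_dataset = as.character(source_dataset)),
            class = "EmbeddingTable")
}

#' @export
print.EmbeddingTable <- function(x, ...) {
  cat(sprintf("EmbeddingTable: %d cells x %d latent dims\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Subset an EmbeddingTable by cell index
#' @param table an [embedding_table()]
#' @param idx integer or logical index over cells
#' @return an [embedding_table()]
#' @export
subset_embedding <- function(table, idx) {
  embedding_table(table$z[idx, , drop = FALSE], table$cell_ids[idx],
                  table$covariates[idx, , drop = FALSE],
                  if (!is.null(table$cell_type_labels))
                    table$cell_type_labels[idx] else NULL,
                  table$source_dataset[idx])
}

#' Combine embedding tables row-wise
#' @param ... [embedding_table()] objects with identical latent dimension
#' @return an [embedding_table()]
#' @export
rbind_embeddings <- function(...) {
  tabs <- list(...)
  ks <- vapply(tabs, function(t) ncol(t$z), 1L)
  stop_if(length(unique(ks)) != 1, "latent dimensions differ")
  cov_cols <- unique(unlist(lapply(tabs, function(t) colnames(t$covariates))))
  covs <- do.call(rbind, lapply(tabs, function(t) {
    cv <- t$covariates
    for (cc in setdiff(cov_cols, colnames(cv))) cv[[cc]] <- NA_character_
    cv[, cov_cols, drop = FALSE]
  }))
  labs <- unlist(lapply(tabs, function(t)
    t$cell_type_labels %||% rep(NA_character_, length(t$cell_ids))))
  embedding_table(do.call(rbind, lapply(tabs, function(t) t$z)),
                  unlist(lapply(tabs, function(t) t$cell_ids)),
                  covs, labs,
                  unlist(lapply(tabs, function(t) t$source_dataset)))
}

#' Write an EmbeddingTable to disk
#'
#' `tsv` writes a header of `cell_id`, covariate columns, optional
#' `cell_type`, `source_dataset`, then the latent coordinates `z1..zk` at
#' full precision (readable back bit-identically). `h5ad` is not supported
#' by this implementation.
#'
#' @param table an [embedding_table()]
#' @param path output file path
#' @param format `"tsv"`
#' @export
write_embedding <- function(table, path, format = c("tsv", "h5ad")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "EmbeddingTable"))
  stop_if(nrow(table$z) == 0, "refusing to write an empty embedding table")
  if (format == "h5ad") {
    stop("h5ad output is not supported; use tsv", call. = FALSE)
  }
  df <- data.frame(cell_id = table$cell_ids, stringsAsFactors = FALSE)
  for (cc in colnames(table$covariates)) df[[cc]] <- table$covariates[[cc]]
  if (!is.null(table$cell_type_labels)) df$cell_type <- table$cell_type_labels
  df$source_dataset <- table$source_dataset
  zdf <- as.data.frame(table$z)
  colnames(zdf) <- paste0("z", seq_len(ncol(zdf)))
  for (j in seq_len(ncol(zdf))) {
    zdf[[j]] <- sprintf("%.17g", zdf[[j]])
  }
  out <- cbind(df, zdf)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write embedding to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read an EmbeddingTable written by [write_embedding()]
#' @param path tsv path
#' @return an [embedding_table()]
#' @export
read_embedding <- function(path) {
  stop_if(!file.exists(path), "input file not found: ", path)
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  zcols <- grep("^z[0-9]+$", colnames(tab), value = TRUE)
  zcols <- zcols[order(as.integer(sub("^z", "", zcols)))]
  z <- as.matrix(tab[, zcols, drop = FALSE])
  meta <- setdiff(colnames(tab), c("cell_id", "cell_type", "source_dataset",
                                   zcols))
  embedding_table(z, tab$cell_id,
                  tab[, meta, drop = FALSE],
                  if ("cell_type" %in% colnames(tab)) tab$cell_type else NULL,
                  if ("source_dataset" %in% colnames(tab))
                    tab$source_dataset else NULL)
}
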