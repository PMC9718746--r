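#' UMI count matrix container
#'
#' A light container for droplet scRNA-seq UMI counts. The matrix is held
#' cells x genes internally (rows are cell barcodes, columns gene ids),
#' regardless of the genes x cells orientation used on disk by the 10x
#' MatrixMarket convention. Counts are sparse, non-negative and integral.
#'
#' @param counts a matrix or sparse Matrix of UMI counts, cells x genes.
#' @param barcodes character vector of unique cell barcodes (row ids).
#' @param genes data.frame with columns `id` and `symbol`, one row per
#'   matrix column.
#' @return an object of class `count_matrix` with elements `counts`
#'   (a `dgCMatrix`), and `genes`.
#' @export
count_matrix <- function(counts, barcodes, genes) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (anyDuplicated(barcodes))
    stop_mosaic("cell barcodes must be unique", class = "format_error")
  if (anyDuplicated(genes$id))
    stop_mosaic("gene ids must be unique", class = "format_error")
  if (nrow(counts) != length(barcodes) || ncol(counts) != nrow(genes))
    stop_mosaic("count matrix dimensions (", nrow(counts), " x ", ncol(counts),
                ") do not match ", length(barcodes), " barcodes / ",
                nrow(genes), " genes", class = "format_error")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop_mosaic("UMI counts must be non-negative integers", class = "format_error")
  dimnames(counts) <- list(as.character(barcodes), as.character(genes$id))
  structure(list(counts = counts,
                 genes = data.frame(id = as.character(genes$id),
                                    symbol = as.character(genes$symbol))),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Cell barcodes of a count matrix
#' @param x a `count_matrix`.
#' @return character vector of barcodes.
#' @export
barcodes <- function(x) rownames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%d nonzero UMI entries)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' Subset a count matrix by cells and/or genes
#' @param x a `count_matrix`.
#' @param cells logical/integer/character index of cells to keep.
#' @param genes logical/integer/character index of genes to keep.
#' @return a `count_matrix`.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  m <- x$counts
  if (is.null(genes)) genes <- seq_len(ncol(m))
  if (is.null(cells)) cells <- seq_len(nrow(m))
  m2 <- m[cells, genes, drop = FALSE]
  count_matrix(m2, rownames(m2), x$genes[match(colnames(m2), x$genes$id), ])
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else file(path)
}

#' Read a 10x-style MatrixMarket triplet into a count matrix
#'
#' Reads `matrix.mtx`(.gz) together with its barcode and feature TSVs.
#' On disk the matrix is genes x cells (10x convention); the result is
#' transposed to cells x genes.
#'
#' @param matrix_path path to the MatrixMarket file.
#' @param barcodes_path path to the one-column barcode TSV.
#' @param features_path path to the feature TSV (columns: id, symbol, and
#'   optionally feature type).
#' @return a [count_matrix()].
#' @export
read_mtx_triplet <- function(matrix_path, barcodes_path, features_path) {
  for (p in c(matrix_path, barcodes_path, features_path))
    if (!file.exists(p)) stop_mosaic("file not found: ", p, class = "format_error")
  m <- tryCatch(Matrix::readMM(open_maybe_gz(matrix_path)),
                error = function(e) stop_mosaic("invalid MatrixMarket file ",
                                                matrix_path, ": ", conditionMessage(e),
                                                class = "format_error"))
  bc <- readLines(open_maybe_gz(barcodes_path))
  bc <- bc[nzchar(bc)]
  ft <- read.delim(open_maybe_gz(features_path), header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(ft) < 2)
    stop_mosaic("feature file needs at least 2 columns (id, symbol): ",
                features_path, class = "format_error")
  if (nrow(m) != nrow(ft) || ncol(m) != length(bc))
    stop_mosaic("MatrixMarket header is ", nrow(m), " genes x ", ncol(m),
                " cells but found ", nrow(ft), " features and ", length(bc),
                " barcodes", class = "format_error")
  count_matrix(Matrix::t(m), bc, data.frame(id = ft[[1]], symbol = ft[[2]]))
}

#' Write a count matrix as a 10x-style MatrixMarket triplet
#'
#' Inverse of [read_mtx_triplet()]: writes genes x cells on disk.
#'
#' @param x a `count_matrix`.
#' @param dir output directory (created if missing).
#' @param prefix optional file-name prefix.
#' @return invisibly, the three paths written.
#' @export
write_mtx_triplet <- function(x, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "barcodes.tsv", "features.tsv")))
  Matrix::writeMM(Matrix::t(x$counts), paths[1])
  writeLines(barcodes(x), paths[2])
  write.table(data.frame(x$genes$id, x$genes$symbol, "Gene Expression"),
              paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Read a per-cell type label table
#'
#' @param path TSV with a header and columns `barcode` and `cell_type`.
#' @return data.frame with columns barcode, cell_type.
#' @export
read_cell_labels <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "cell_type") %in% names(d)))
    stop_mosaic("cell label table must have columns 'barcode' and 'cell_type': ",
                path, class = "format_error")
  d[c("barcode", "cell_type")]
}
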