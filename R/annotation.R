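#' GRCh38 pseudoautosomal region coordinates
#'
#' PAR1 and PAR2 intervals on X and Y (1-based inclusive, GRCh38). Genes
#' overlapping these regions by at least one base are shared between X and
#' Y, so their reads cannot identify the chromosome of origin and they are
#' excluded from both sex-chromosome panels.
#'
#' @return data.frame with columns chrom, start, end, name.
#' @export
par_regions_grch38 <- function() {
  data.frame(
    chrom = c("X", "Y", "X", "Y"),
    start = c(10001L, 10001L, 155701383L, 56887903L),
    end   = c(2781479L, 2781479L, 156030895L, 57217415L),
    name  = c("PAR1", "PAR1", "PAR2", "PAR2"))
}

strip_chr <- function(x) sub("^chr", "", as.character(x))

#' Read a gene annotation and flag pseudoautosomal genes
#'
#' Accepts either a GTF (gene-level records) or a plain TSV with columns
#' gene id, symbol, chromosome, and optionally start and end (1-based
#' inclusive). Every gene gets a chromosome label and a PAR flag; a gene
#' overlapping a PAR interval by >= 1 bp is flagged.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"gtf"` (GTF needs the rtracklayer package).
#' @param par_regions data.frame of PAR intervals as in
#'   [par_regions_grch38()] (the default).
#' @return data.frame with columns id, symbol, chrom, start, end, par.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "gtf"),
                                 par_regions = par_regions_grch38()) {
  format <- match.arg(format)
  if (format == "gtf") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop_mosaic("reading GTF requires the rtracklayer package",
                  class = "annotation_error")
    g <- rtracklayer::import(path, format = "gtf")
    g <- g[g$type == "gene"]
    if (!length(g))
      stop_mosaic("no gene-level records in GTF: ", path, class = "annotation_error")
    ann <- data.frame(
      id = as.character(g$gene_id),
      symbol = as.character(g$gene_name %||% g$gene_id),
      chrom = strip_chr(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g),
      end = GenomicRanges::end(g))
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "symbol", "chrom")
    if (!all(need %in% names(d))) {
      # also accept a headerless 3/5-column layout
      d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(d) < 3)
        stop_mosaic("annotation TSV needs columns id, symbol, chrom[, start, end]: ",
                    path, class = "annotation_error")
      names(d) <- c("id", "symbol", "chrom", "start", "end")[seq_len(ncol(d))]
    }
    if (is.null(d$start)) d$start <- NA_integer_
    if (is.null(d$end)) d$end <- NA_integer_
    ann <- data.frame(id = as.character(d$id), symbol = as.character(d$symbol),
                      chrom = strip_chr(d$chrom),
                      start = as.integer(d$start), end = as.integer(d$end))
  }
  if (anyDuplicated(ann$id))
    stop_mosaic("duplicated gene ids in annotation", class = "annotation_error")
  sex <- ann$chrom %in% c("X", "Y")
  if (!is.null(par_regions)) {
    if (any(sex & (is.na(ann$start) | is.na(ann$end))))
      stop_mosaic("genes on X or Y need start/end coordinates for PAR flagging",
                  class = "annotation_error")
    par_regions$chrom <- strip_chr(par_regions$chrom)
    ann$par <- FALSE
    for (i in seq_len(nrow(par_regions))) {
      hit <- sex & ann$chrom == par_regions$chrom[i] &
        ann$start <= par_regions$end[i] & ann$end >= par_regions$start[i]
      ann$par <- ann$par | (hit %in% TRUE)
    }
  } else {
    ann$par <- FALSE
  }
  ann
}

#' Build the X/Y gene panels used for genotyping and dosage ratios
#'
#' The Y panel is every annotated Y gene outside the pseudoautosomal
#' regions; the X panel likewise for X. PAR genes are excluded from both
#' because their reads cannot distinguish an X from a Y origin.
#'
#' @param annotations data.frame from [read_gene_annotation()].
#' @return object of class `gene_panel`: list with character vectors
#'   `y_panel` and `x_panel` of gene ids.
#' @export
build_gene_panel <- function(annotations) {
  if (is.null(annotations) || !nrow(annotations))
    stop_mosaic("empty annotation", class = "config_error")
  y <- sort(annotations$id[annotations$chrom == "Y" & !annotations$par])
  x <- sort(annotations$id[annotations$chrom == "X" & !annotations$par])
  if (!length(y))
    stop_mosaic("no non-PAR Y-linked genes in annotation; genotyping impossible",
                class = "config_error")
  structure(list(y_panel = y, x_panel = x), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: %d Y-linked, %d X-linked genes (PAR excluded)\n",
              length(x$y_panel), length(x$x_panel)))
  invisible(x)
}

#' Per-cell QC metrics
#'
#' Genes detected, total UMIs and mitochondrial fraction per cell,
#' computed from the matrix itself. Mitochondrial genes are those with
#' chromosome label `"MT"` in the annotation, or, absent an annotation,
#' those whose symbol starts with `"MT-"`.
#'
#' @param x a `count_matrix`.
#' @param annotations optional annotation data.frame.
#' @return data.frame: barcode, n_genes, n_umi, mito_fraction.
#' @export
cell_qc_metrics <- function(x, annotations = NULL) {
  m <- x$counts
  n_umi <- Matrix::rowSums(m)
  n_genes <- Matrix::rowSums(m > 0)
  if (!is.null(annotations)) {
    mt <- x$genes$id %in% annotations$id[annotations$chrom == "MT"]
  } else {
    mt <- grepl("^MT-", x$genes$symbol)
  }
  mito <- if (any(mt)) Matrix::rowSums(m[, mt, drop = FALSE]) else 0
  data.frame(barcode = barcodes(x), n_genes = n_genes, n_umi = n_umi,
             mito_fraction = ifelse(n_umi > 0, mito / n_umi, 0),
             row.names = NULL)
}

#' Quality-control filter on cells
#'
#' Removes cells failing any of the thresholds from both the count matrix
#' and the cell table, preserving order. QC metrics are recomputed from
#' the matrix so the returned table is always consistent with it.
#'
#' @param x a `count_matrix`.
#' @param cells data.frame with columns barcode and cell_type (one row per
#'   cell of `x`).
#' @param min_genes minimum genes detected per cell.
#' @param min_umi minimum total UMIs per cell.
#' @param max_mito_fraction maximum mitochondrial UMI fraction.
#' @param annotations optional annotation for mitochondrial gene lookup.
#' @param verbose log a summary line.
#' @return list with elements `counts` (filtered `count_matrix`), `cells`
#'   (filtered table with refreshed QC metric columns) and `summary`.
#' @export
qc_filter <- function(x, cells, min_genes = 200, min_umi = 500,
                      max_mito_fraction = 0.10, annotations = NULL,
                      verbose = TRUE) {
  stopifnot(min_genes >= 0, min_umi >= 0, max_mito_fraction >= 0)
  if (!setequal(cells$barcode, barcodes(x)) ||
      nrow(cells) != nrow(x$counts))
    stop_mosaic("cell table barcodes do not match count matrix",
                class = "join_error")
  cells <- cells[match(barcodes(x), cells$barcode), , drop = FALSE]
  qc <- cell_qc_metrics(x, annotations)
  keep <- qc$n_genes >= min_genes & qc$n_umi >= min_umi &
    qc$mito_fraction <= max_mito_fraction
  if (!any(keep))
    stop_mosaic("no cells pass QC (min_genes=", min_genes, ", min_umi=",
                min_umi, ", max_mito_fraction=", max_mito_fraction, ")",
                class = "empty_result_error")
  xf <- subset_cells(x, which(keep))
  cf <- cbind(cells[keep, c("barcode", "cell_type"), drop = FALSE],
              qc[keep, c("n_genes", "n_umi", "mito_fraction"), drop = FALSE])
  rownames(cf) <- NULL
  s <- list(n_in = nrow(qc), n_kept = sum(keep),
            median_genes = median(cf$n_genes), median_umi = median(cf$n_umi))
  if (verbose)
    message(sprintf("qc_filter: kept %d/%d cells (median %d genes, %d UMIs per cell)",
                    s$n_kept, s$n_in, round(s$median_genes), round(s$median_umi)))
  list(counts = xf, cells = cf, summary = s)
}
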