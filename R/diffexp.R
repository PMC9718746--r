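#' Log-normalize UMI counts
#'
#' Per cell: value = ln(1 + count / cell_total * scale_factor) — the
#' library-size log-normalization conventional for droplet data.
#'
#' @param x a QC-filtered [count_matrix()].
#' @param scale_factor target library size (default 10,000).
#' @return sparse `dgCMatrix`, cells x genes, of normalized values.
#' @export
normalize_counts <- function(x, scale_factor = 10000) {
  tot <- Matrix::rowSums(x$counts)
  if (any(tot == 0))
    stop_mosaic("cells with zero total counts present; run qc_filter first",
                class = "empty_result_error")
  m <- Matrix::Diagonal(x = scale_factor / tot) %*% x$counts
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(x$counts)
  methods::as(m, "CsparseMatrix")
}

rank_sum_genes <- function(norm_a, norm_b, gene_ids) {
  # two-sided Wilcoxon rank-sum per gene; exact for small untied samples,
  # normal approximation with tie correction otherwise (stats::wilcox.test)
  vapply(gene_ids, function(g) {
    suppressWarnings(
      wilcox.test(norm_a[, g], norm_b[, g], alternative = "two.sided")$p.value)
  }, numeric(1))
}

#' Differential expression between genotype lineages within a cell type
#'
#' For the cells of `target_type` (or all cells when `target_type` is
#' NULL — the pooled comparison), genes expressed in at least
#' `min_frac_expressing` of either genotype group are tested with a
#' two-sided Wilcoxon rank-sum test on log-normalized values; p-values are
#' Bonferroni-corrected over the genes tested in this comparison.
#'
#' @param norm normalized matrix from [normalize_counts()] (cells x genes).
#' @param calls a `genotype_calls` object.
#' @param cells data.frame with barcode and cell_type.
#' @param target_type cell type to test, or NULL for all cells pooled.
#' @param min_frac_expressing expression filter (fraction of nonzero cells
#'   required in at least one group).
#' @param alpha significance threshold on the Bonferroni-adjusted p.
#' @param min_cells minimum cells per genotype group.
#' @param genes optional gene metadata data.frame (id, symbol, chrom) for
#'   annotation of the results.
#' @param return_all return every tested gene, not only significant ones.
#' @return data.frame of class `de_results`: cell_type, gene, symbol,
#'   chrom, mean_45x, mean_48xyyy, log2fc (48,XYYY vs 45,X), p, p_bonf,
#'   direction, significant; sorted by p_bonf. Attribute `n_tested` holds
#'   the Bonferroni multiplier. NULL (with a warning) when a genotype
#'   group has too few cells.
#' @export
de_test <- function(norm, calls, cells, target_type = NULL,
                    min_frac_expressing = 0.1, alpha = 0.05, min_cells = 20,
                    genes = NULL, return_all = FALSE) {
  d <- join_cells_calls(cells, calls)
  keep <- if (is.null(target_type)) rep(TRUE, nrow(d)) else d$cell_type == target_type
  d <- d[keep, , drop = FALSE]
  a_bc <- d$barcode[d$call == "48,XYYY"]
  b_bc <- d$barcode[d$call == "45,X"]
  label <- target_type %||% "all"
  if (length(a_bc) < min_cells || length(b_bc) < min_cells) {
    warning(sprintf("de_test[%s]: skipped (%d 48,XYYY vs %d 45,X cells; need >= %d each)",
                    label, length(a_bc), length(b_bc), min_cells))
    return(NULL)
  }
  na <- norm[a_bc, , drop = FALSE]
  nb <- norm[b_bc, , drop = FALSE]
  frac_a <- Matrix::colSums(na > 0) / nrow(na)
  frac_b <- Matrix::colSums(nb > 0) / nrow(nb)
  test_genes <- colnames(norm)[pmax(frac_a, frac_b) >= min_frac_expressing]
  if (!length(test_genes)) {
    warning(sprintf("de_test[%s]: no genes pass the expression filter", label))
    return(NULL)
  }
  da <- as.matrix(na[, test_genes, drop = FALSE])
  db <- as.matrix(nb[, test_genes, drop = FALSE])
  p <- rank_sum_genes(da, db, test_genes)
  m <- length(test_genes)
  p_bonf <- pmin(1, p * m)
  mean_a <- colMeans(da)
  mean_b <- colMeans(db)
  # fold change on de-logged average expression with pseudocount 1
  log2fc <- log2((expm1(mean_a) + 1) / (expm1(mean_b) + 1))
  res <- data.frame(
    cell_type = label, gene = test_genes,
    symbol = if (!is.null(genes)) genes$symbol[match(test_genes, genes$id)] else test_genes,
    chrom = if (!is.null(genes) && !is.null(genes$chrom))
      genes$chrom[match(test_genes, genes$id)] else NA_character_,
    mean_45x = as.numeric(mean_b), mean_48xyyy = as.numeric(mean_a),
    log2fc = as.numeric(log2fc), p = as.numeric(p),
    p_bonf = as.numeric(p_bonf),
    direction = ifelse(log2fc >= 0, "up_in_48XYYY", "up_in_45X"),
    significant = p_bonf < alpha, row.names = NULL)
  res <- res[order(res$p_bonf, res$p), , drop = FALSE]
  if (!return_all) res <- res[res$significant, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- m
  class(res) <- c("de_results", class(res))
  res
}

#' Run [de_test()] for every cell type
#'
#' @inheritParams de_test
#' @param types cell types to test (default: all present).
#' @return a single `de_results` data.frame (rows from all testable
#'   types), with attribute `n_tested_by_type`.
#' @export
de_test_all_types <- function(norm, calls, cells, types = NULL,
                              min_frac_expressing = 0.1, alpha = 0.05,
                              min_cells = 20, genes = NULL,
                              return_all = FALSE) {
  types <- types %||% sort(unique(cells$cell_type))
  out <- list()
  n_tested <- integer(0)
  for (tt in types) {
    r <- withCallingHandlers(
      de_test(norm, calls, cells, tt, min_frac_expressing, alpha,
              min_cells, genes, return_all),
      warning = function(w) { message(conditionMessage(w)); invokeRestart("muffleWarning") })
    if (!is.null(r)) {
      n_tested[tt] <- attr(r, "n_tested")
      out[[tt]] <- r
    }
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
         else data.frame()
  attr(res, "n_tested_by_type") <- n_tested
  class(res) <- c("de_results", class(res))
  res
}

#' Flag differentially expressed genes linked to hematological malignancy
#'
#' Annotates DE results against a curated list of genes associated with
#' hematological malignancies (the packaged default list includes TCL1A,
#' a known leukemia/lymphoma risk factor, and other recurrent
#' leukemia/lymphoma drivers).
#'
#' @param results a `de_results` data.frame.
#' @param gene_list_path 2+ column TSV (symbol, association); default is
#'   the packaged curated list.
#' @return list with `results` (annotated with `malignancy_flag`),
#'   `flagged` (the flagged subset) and `by_cell_type` (breakdown table).
#' @export
flag_malignancy_genes <- function(results,
                                  gene_list_path = system.file(
                                    "extdata", "hematologic_malignancy_genes.tsv",
                                    package = "mosaicY")) {
  if (!nzchar(gene_list_path) || !file.exists(gene_list_path))
    stop_mosaic("malignancy gene list not found", class = "config_error")
  lst <- read.delim(gene_list_path, stringsAsFactors = FALSE)
  if (!nrow(lst) || !"symbol" %in% names(lst))
    stop_mosaic("malignancy gene list is empty or lacks a 'symbol' column",
                class = "config_error")
  if (!nrow(results))
    return(list(results = results, flagged = results,
                by_cell_type = data.frame()))
  results$malignancy_flag <- results$symbol %in% lst$symbol
  flagged <- results[results$malignancy_flag, , drop = FALSE]
  by_ct <- if (nrow(flagged))
    as.data.frame(table(cell_type = flagged$cell_type), responseName = "n_flagged")
  else data.frame()
  list(results = results, flagged = flagged, by_cell_type = by_ct)
}
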