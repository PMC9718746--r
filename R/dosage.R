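#' Pseudobulk Y/X expression-dosage ratio
#'
#' Sums UMIs over the Y panel and over the X panel across the selected
#' cells and reports their ratio r = y_sum / x_sum. Pseudobulk summing is
#' robust to per-cell zeros; per-cell ratios (with a pseudocount) are
#' optionally attached for plotting.
#'
#' @param x a [count_matrix()].
#' @param cell_mask logical/integer/character index selecting >= 1 cell.
#' @param panel a [build_gene_panel()] result.
#' @param group group label carried into the output.
#' @param per_cell also compute per-cell (y+pseudocount)/(x+pseudocount)
#'   ratios.
#' @param pseudocount pseudocount for per-cell ratios.
#' @return object of class `dosage_ratio`: list with `group`, `y_sum`,
#'   `x_sum`, `ratio`, `n_cells`, and optionally `per_cell_ratio`.
#' @export
yx_ratio <- function(x, cell_mask = NULL, panel, group = "case",
                     per_cell = FALSE, pseudocount = 1) {
  stopifnot(inherits(panel, "gene_panel"))
  m <- x$counts
  if (!is.null(cell_mask)) m <- m[cell_mask, , drop = FALSE]
  if (!nrow(m))
    stop_mosaic("cell mask selects no cells", class = "empty_result_error")
  yg <- intersect(panel$y_panel, colnames(m))
  xg <- intersect(panel$x_panel, colnames(m))
  y_cell <- Matrix::rowSums(m[, yg, drop = FALSE])
  x_cell <- Matrix::rowSums(m[, xg, drop = FALSE])
  y_sum <- sum(y_cell)
  x_sum <- sum(x_cell)
  if (x_sum == 0)
    stop_mosaic("X-panel UMI total is zero; Y/X ratio undefined",
                class = "undefined_ratio_error")
  out <- list(group = group, y_sum = y_sum, x_sum = x_sum,
              ratio = y_sum / x_sum, n_cells = nrow(m))
  if (per_cell)
    out$per_cell_ratio <- (y_cell + pseudocount) / (x_cell + pseudocount)
  structure(out, class = "dosage_ratio")
}

#' @export
print.dosage_ratio <- function(x, ...) {
  cat(sprintf("dosage_ratio [%s]: Y/X = %.4f (%g Y UMIs / %g X UMIs over %d cells)\n",
              x$group, x$ratio, x$y_sum, x$x_sum, x$n_cells))
  invisible(x)
}

#' Compare a case Y/X ratio against reference male profiles
#'
#' Ranks the case ratio among per-donor reference ratios and flags it
#' "elevated" when it exceeds every reference value (the empirical
#' comparison used when references are few).
#'
#' @param r_case a `dosage_ratio` (or single numeric ratio).
#' @param reference list of `dosage_ratio` objects or numeric vector of
#'   per-donor reference ratios (>= 2 donors).
#' @return list: case_ratio, reference_ratios, reference_median,
#'   reference_range, rank (1 = highest), n_profiles, elevated.
#' @export
compare_to_reference <- function(r_case, reference) {
  rc <- if (inherits(r_case, "dosage_ratio")) r_case$ratio else as.numeric(r_case)
  rr <- vapply(reference,
               function(r) if (inherits(r, "dosage_ratio")) r$ratio else as.numeric(r),
               numeric(1))
  if (length(rr) < 2)
    stop_mosaic("need >= 2 reference donors", class = "config_error")
  list(case_ratio = rc,
       reference_ratios = rr,
       reference_median = median(rr),
       reference_range = range(rr),
       rank = 1L + sum(rr >= rc),
       n_profiles = length(rr) + 1L,
       elevated = rc > max(rr))
}
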