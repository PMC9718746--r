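#' Call per-cell karyotype from Y-panel expression
#'
#' The presence/absence rule: a cell is called "48,XYYY" when its total
#' UMI count over the (PAR-excluded) Y-linked panel reaches `min_y_umi`
#' (default 1, i.e. expression of any single Y-linked gene), otherwise
#' "45,X". Every QC-passing cell receives a call; ambiguity is handled
#' statistically through the false-negative rate, not per cell.
#'
#' @param x a QC-filtered [count_matrix()].
#' @param panel a [build_gene_panel()] result.
#' @param min_y_umi minimum Y-panel UMIs to call a cell Y-bearing.
#' @return object of class `genotype_calls`: list with `calls` (data.frame
#'   barcode, y_umi, call), counts `n_x`/`n_xyyy`, and the observed mosaic
#'   fraction `f_obs = n_xyyy / (n_x + n_xyyy)`.
#' @export
call_genotype <- function(x, panel, min_y_umi = 1L) {
  stopifnot(inherits(panel, "gene_panel"), min_y_umi >= 1)
  if (!nrow(x$counts))
    stop_mosaic("empty count matrix", class = "empty_result_error")
  yg <- intersect(panel$y_panel, x$genes$id)
  if (!length(yg))
    stop_mosaic("no Y-panel genes present in the count matrix",
                class = "config_error")
  y_umi <- Matrix::rowSums(x$counts[, yg, drop = FALSE])
  call <- ifelse(y_umi >= min_y_umi, "48,XYYY", "45,X")
  n_xyyy <- sum(call == "48,XYYY")
  structure(list(
    calls = data.frame(barcode = barcodes(x), y_umi = as.numeric(y_umi),
                       call = call, row.names = NULL),
    n_x = length(call) - n_xyyy, n_xyyy = n_xyyy,
    f_obs = n_xyyy / length(call),
    min_y_umi = as.integer(min_y_umi),
    n_y_genes = length(yg)),
    class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf(paste0("genotype_calls: %d cells | 45,X: %d (%.2f%%) | ",
                     "48,XYYY: %d (%.2f%%)\n"),
              x$n_x + x$n_xyyy, x$n_x, 100 * (1 - x$f_obs),
              x$n_xyyy, 100 * x$f_obs))
  if (!is.null(x$f_hat))
    cat(sprintf("  dropout-corrected f_hat = %.4f (q = %.4f, 95%% CI %.4f-%.4f)\n",
                x$f_hat, x$q, x$f_hat_ci[1], x$f_hat_ci[2]))
  invisible(x)
}

#' Estimate the Y-expression false-negative rate from reference cells
#'
#' On reference cells that all truly carry Y (e.g. PBMCs of karyotypically
#' normal male donors), a zero Y-panel UMI total is a dropout event. The
#' false-negative rate q is the fraction of such zero-Y cells, with a
#' Clopper-Pearson 95% CI.
#'
#' @param reference a [count_matrix()] of Y-bearing reference cells.
#' @param panel a [build_gene_panel()] result.
#' @param min_y_umi detection threshold, matching [call_genotype()].
#' @return list with `q`, `ci` (length-2), `n_zero`, `n_ref`.
#' @export
estimate_false_negative_rate <- function(reference, panel, min_y_umi = 1L) {
  g <- call_genotype(reference, panel, min_y_umi = min_y_umi)
  n <- g$n_x + g$n_xyyy
  if (n < 100)
    warning("false-negative rate estimated from only ", n,
            " reference cells; the confidence interval will be wide")
  k <- g$n_x  # zero-Y (below-threshold) reference cells
  ci <- as.numeric(binom.test(k, n)$conf.int)
  list(q = k / n, ci = ci, n_zero = k, n_ref = n)
}

#' Dropout-correct an observed mosaic fraction
#'
#' With false-negative rate q (probability a truly Y-bearing cell shows no
#' Y-panel expression) and negligible false positives, the expected
#' observed Y-bearing fraction is f(1-q), so `f_hat = min(1, f_obs/(1-q))`.
#'
#' @param f_obs observed Y-bearing cell fraction.
#' @param q false-negative rate, in `[0, 1)`.
#' @return corrected fraction f_hat.
#' @export
correct_mosaic_fraction <- function(f_obs, q) {
  check_fraction(f_obs, "f_obs")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q >= 1)
    stop_mosaic("q must be in [0, 1)", class = "domain_error")
  min(1, f_obs / (1 - q))
}

#' Attach a dropout-corrected mosaic fraction with a bootstrap CI
#'
#' Resamples both the case calls (binomial in n cells) and the reference
#' zero-Y count (binomial in n reference cells) to propagate the
#' uncertainty of q into f_hat.
#'
#' @param calls a `genotype_calls` object.
#' @param fnr result of [estimate_false_negative_rate()] (or a list with
#'   `q`, `n_zero`, `n_ref`).
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return the `genotype_calls` object with `f_hat`, `q`, `f_hat_ci` added.
#' @export
apply_fnr_correction <- function(calls, fnr, n_boot = 2000, conf = 0.95,
                                 seed = 1L) {
  stopifnot(inherits(calls, "genotype_calls"))
  n <- calls$n_x + calls$n_xyyy
  set.seed(seed)
  fo <- rbinom(n_boot, n, calls$f_obs) / n
  qb <- rbinom(n_boot, fnr$n_ref, fnr$q) / fnr$n_ref
  qb <- pmin(qb, 1 - 1e-9)
  fh <- pmin(1, fo / (1 - qb))
  calls$q <- fnr$q
  calls$f_hat <- correct_mosaic_fraction(calls$f_obs, fnr$q)
  a <- (1 - conf) / 2
  calls$f_hat_ci <- as.numeric(quantile(fh, c(a, 1 - a)))
  calls
}

#' Write per-cell calls and a JSON genotype summary
#'
#' @param calls a `genotype_calls` object.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_genotype_results <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "genotype_calls.tsv")
  write.table(calls$calls[c("barcode", "call", "y_umi")], p1, sep = "\t",
              quote = FALSE, row.names = FALSE)
  s <- list(n_x = calls$n_x, n_xyyy = calls$n_xyyy, f_obs = calls$f_obs,
            f_hat = calls$f_hat, q = calls$q, f_hat_ci = calls$f_hat_ci,
            min_y_umi = calls$min_y_umi)
  p2 <- file.path(dir, "genotype_summary.json")
  jsonlite::write_json(s[!vapply(s, is.null, TRUE)], p2, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(p1, p2))
}
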