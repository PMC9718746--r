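#' Read a ddPCR droplet count table
#'
#' @param path TSV with header columns well, channel, n_droplets,
#'   n_positive; channels are AMELX and AMELY.
#' @return validated data.frame.
#' @export
read_ddpcr_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("well", "channel", "n_droplets", "n_positive")
  if (!all(need %in% names(d)))
    stop_mosaic("ddPCR table must have columns ", paste(need, collapse = ", "),
                class = "format_error")
  if (any(d$n_droplets <= 0) || any(d$n_positive < 0) ||
      any(d$n_positive > d$n_droplets))
    stop_mosaic("ddPCR table needs 0 <= n_positive <= n_droplets, n_droplets > 0",
                class = "format_error")
  d[need]
}

#' Poisson concentration estimate from droplet positivity
#'
#' Droplet digital PCR partitions the sample so that the mean copies per
#' droplet lambda satisfies P(positive) = 1 - exp(-lambda); inverting the
#' observed positive fraction gives lambda = -ln(1 - k/n). The CI is the
#' Clopper-Pearson binomial CI on the positive fraction pushed through the
#' same transform.
#'
#' @param n_positive positive droplet count (must leave >= 1 negative
#'   droplet, otherwise lambda is unbounded).
#' @param n_droplets total droplets.
#' @param conf confidence level.
#' @return list: lambda, ci (length 2), n_positive, n_droplets.
#' @export
estimate_lambda <- function(n_positive, n_droplets, conf = 0.95) {
  stopifnot(n_droplets > 0, n_positive >= 0)
  if (n_positive >= n_droplets)
    stop_mosaic("all droplets positive: lambda saturated/unbounded; dilute the sample",
                class = "saturation_error")
  ci_p <- as.numeric(binom.test(n_positive, n_droplets,
                                conf.level = conf)$conf.int)
  list(lambda = -log1p(-n_positive / n_droplets),
       ci = -log1p(-ci_p),
       n_positive = n_positive, n_droplets = n_droplets)
}

#' Estimate the Y-bearing cell fraction from AMELX/AMELY wells
#'
#' Wells are pooled per channel (summed positives and droplets) before
#' Poisson inversion — the merged-well estimator. The AMELX channel
#' measures genome equivalents (one X per genome in both lineages); the
#' AMELY channel measures Y copies, `y_copies_per_positive_cell` per
#' Y-bearing genome. The Y-bearing cell fraction is
#' f = (lambda_AMELY / y_copies) / lambda_AMELX, clamped to [0, 1]. The
#' CI combines the channel CIs conservatively (low Y / high X bound and
#' vice versa).
#'
#' @param wells data.frame as from [read_ddpcr_table()] or
#'   [simulate_ddpcr()].
#' @param y_copies_per_positive_cell Y copies per Y-bearing genome
#'   (3 for 48,XYYY; set 1 for a naive per-allele fraction).
#' @param conf confidence level.
#' @return object of class `ddpcr_estimate`: per-channel lambda with CI,
#'   `f_ddpcr`, `f_ci`, `clamped`.
#' @export
estimate_fraction <- function(wells, y_copies_per_positive_cell = 3,
                              conf = 0.95) {
  stopifnot(y_copies_per_positive_cell > 0)
  for (ch in c("AMELX", "AMELY"))
    if (!any(wells$channel == ch))
      stop_mosaic("missing ddPCR channel: ", ch, class = "input_error")
  pool <- function(ch) {
    w <- wells[wells$channel == ch, , drop = FALSE]
    estimate_lambda(sum(w$n_positive), sum(w$n_droplets), conf = conf)
  }
  lx <- pool("AMELX")
  ly <- pool("AMELY")
  if (lx$lambda <= 0)
    stop_mosaic("AMELX concentration is zero; cannot normalize",
                class = "input_error")
  f_raw <- (ly$lambda / y_copies_per_positive_cell) / lx$lambda
  f <- min(1, max(0, f_raw))
  clamped <- f != f_raw
  if (clamped)
    message(sprintf("estimate_fraction: raw fraction %.4f clamped to [0,1]", f_raw))
  lo <- (ly$ci[1] / y_copies_per_positive_cell) / max(lx$ci[2], 1e-12)
  hi <- (ly$ci[2] / y_copies_per_positive_cell) / max(lx$ci[1], 1e-12)
  structure(list(lambda_amelx = lx, lambda_amely = ly,
                 y_copies = y_copies_per_positive_cell,
                 f_ddpcr = f, f_ci = c(min(1, max(0, lo)), min(1, max(0, hi))),
                 clamped = clamped),
            class = "ddpcr_estimate")
}

#' @export
print.ddpcr_estimate <- function(x, ...) {
  cat(sprintf("ddpcr_estimate: lambda AMELX %.4f, AMELY %.4f (Y copies/cell: %g)\n",
              x$lambda_amelx$lambda, x$lambda_amely$lambda, x$y_copies))
  cat(sprintf("  Y-bearing cell fraction f_ddpcr = %.4f (95%% CI %.4f-%.4f)%s\n",
              x$f_ddpcr, x$f_ci[1], x$f_ci[2],
              if (x$clamped) " [clamped]" else ""))
  invisible(x)
}
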