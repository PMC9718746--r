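#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix readMM writeMM rowSums colSums Diagonal t sparseMatrix
#' @importFrom stats rbinom rpois rnbinom rlnorm rhyper runif p.adjust
#'   binom.test wilcox.test quantile median setNames
#' @importFrom utils read.delim write.table packageVersion combn
NULL

stop_mosaic <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mosaicY_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a master seed
#'
#' Each pipeline stage draws its randomness from a seed derived
#' deterministically from the single master seed, so the whole report is
#' reproducible from one number while stages stay independent.
#'
#' @param master_seed single integer master seed.
#' @param stage stage name (character scalar).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  # fold the stage name into the seed with a small polynomial hash
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(master_seed) %% 2147480009 * 48271 + h) %% 2147480009)
}

# shared check that a numeric scalar is a fraction in [0, 1]
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_mosaic(name, " must be a single number in [0, 1]", class = "config_error")
  invisible(x)
}
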