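join_cells_calls <- function(cells, calls) {
  cl <- calls$calls
  miss1 <- setdiff(cells$barcode, cl$barcode)
  miss2 <- setdiff(cl$barcode, cells$barcode)
  if (length(miss1) || length(miss2))
    stop_mosaic("barcode mismatch between cell labels and genotype calls; ",
                "offenders: ",
                paste(utils::head(c(miss1, miss2), 10), collapse = ", "),
                class = "join_error")
  data.frame(barcode = cells$barcode, cell_type = cells$cell_type,
             call = cl$call[match(cells$barcode, cl$barcode)])
}

#' Per-cell-type genotype fractions
#'
#' @param cells data.frame with barcode and cell_type.
#' @param calls a `genotype_calls` object covering the same barcodes.
#' @param min_cells types with fewer cells are flagged `low_n`.
#' @return data.frame: cell_type, n_cells, n_xyyy, fraction, low_n.
#' @export
composition_fractions <- function(cells, calls, min_cells = 20) {
  d <- join_cells_calls(cells, calls)
  n <- tapply(d$call, d$cell_type, length)
  k <- tapply(d$call == "48,XYYY", d$cell_type, sum)
  out <- data.frame(cell_type = names(n), n_cells = as.integer(n),
                    n_xyyy = as.integer(k),
                    fraction = as.numeric(k / n),
                    low_n = as.integer(n) < min_cells,
                    row.names = NULL)
  out[order(out$cell_type), , drop = FALSE]
}

comp_stat <- function(k, n, p_bar) abs(k / n - p_bar)

#' Monte Carlo permutation test of genotype composition across cell types
#'
#' Tests, per cell type c, whether its 48,XYYY fraction p_c deviates from
#' the pooled fraction p-bar more than expected from random sampling. The
#' statistic is T_c = |p_c - p_bar|. The null shuffles genotype calls
#' across all cells while preserving each type's size, which is realized
#' by sequential multivariate-hypergeometric draws of per-type Y-bearing
#' counts (the last type receives the remainder, so every permuted dataset
#' carries exactly the observed genotype multiset). P-values use the
#' add-one estimator (b+1)/(n_perm+1); a permuted T equal to the observed
#' T counts as extreme. Benjamini-Hochberg FDR across cell types.
#'
#' @param cells data.frame with barcode and cell_type (>= 2 types).
#' @param calls a `genotype_calls` object.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param alpha FDR threshold for the significance flag.
#' @param min_cells low-cell-count flag threshold.
#' @return object of class `composition_test`: the fraction table plus
#'   `statistic`, `p_value`, `q_value`, `significant`, and metadata
#'   (`p_bar`, `n_perm`, `seed`, `alpha`).
#' @export
permutation_test_composition <- function(cells, calls, n_perm = 10000,
                                         seed = 1L, alpha = 0.05,
                                         min_cells = 20) {
  if (n_perm < 100)
    stop_mosaic("n_perm must be >= 100 (p-value resolution too coarse)",
                class = "config_error")
  tab <- composition_fractions(cells, calls, min_cells = min_cells)
  if (nrow(tab) < 2)
    stop_mosaic("composition test needs >= 2 cell types", class = "config_error")
  N <- sum(tab$n_cells)
  K <- sum(tab$n_xyyy)
  p_bar <- K / N
  t_obs <- comp_stat(tab$n_xyyy, tab$n_cells, p_bar)

  set.seed(seed)
  n_types <- nrow(tab)
  b <- integer(n_types)
  remaining_k <- rep(K, n_perm)       # Y-bearing calls left to place
  remaining_n <- rep(N, n_perm)       # cells left
  for (ci in seq_len(n_types)) {
    sz <- tab$n_cells[ci]
    k_perm <- if (ci == n_types) remaining_k else
      rhyper(n_perm, remaining_k, remaining_n - remaining_k, sz)
    b[ci] <- sum(comp_stat(k_perm, sz, p_bar) >= t_obs[ci] - 1e-12)
    remaining_k <- remaining_k - k_perm
    remaining_n <- remaining_n - sz
  }
  p <- (b + 1) / (n_perm + 1)
  q <- p.adjust(p, method = "BH")
  tab$statistic <- t_obs
  tab$p_value <- p
  tab$q_value <- q
  tab$significant <- q < alpha
  structure(list(table = tab, p_bar = p_bar, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), alpha = alpha),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("composition_test: %d cell types, pooled 48,XYYY fraction %.4f, %d permutations\n",
              nrow(x$table), x$p_bar, x$n_perm))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Exact enumeration version of the composition test (small instances)
#'
#' Enumerates every distinct assignment of the observed genotype multiset
#' to the cells (equivalently, every subset of cells receiving the
#' Y-bearing calls) and computes, per cell type, the fraction of
#' assignments with T_c >= observed T_c. Feasible up to 12 cells; used as
#' an oracle for the Monte Carlo test.
#'
#' @param cells data.frame with barcode and cell_type.
#' @param calls a `genotype_calls` object.
#' @return data.frame: cell_type, n_cells, n_xyyy, statistic, p_exact.
#' @export
exact_enumeration_test <- function(cells, calls) {
  d <- join_cells_calls(cells, calls)
  N <- nrow(d)
  if (N > 12)
    stop_mosaic("exact enumeration limited to <= 12 cells (got ", N, ")",
                class = "config_error")
  K <- sum(d$call == "48,XYYY")
  types <- sort(unique(d$cell_type))
  n_c <- table(factor(d$cell_type, levels = types))
  p_bar <- K / N
  k_obs <- tapply(d$call == "48,XYYY", factor(d$cell_type, levels = types), sum)
  t_obs <- comp_stat(as.numeric(k_obs), as.numeric(n_c), p_bar)

  if (K == 0) {
    sets <- matrix(integer(0), nrow = 0, ncol = 1)
  } else {
    sets <- combn(N, K)
  }
  n_assign <- ncol(sets)
  ge <- numeric(length(types))
  type_idx <- match(d$cell_type, types)
  for (a in seq_len(n_assign)) {
    member <- tabulate(type_idx[sets[, a]], nbins = length(types))
    t_a <- comp_stat(member, as.numeric(n_c), p_bar)
    ge <- ge + (t_a >= t_obs - 1e-12)
  }
  data.frame(cell_type = types, n_cells = as.integer(n_c),
             n_xyyy = as.integer(k_obs), statistic = t_obs,
             p_exact = ge / n_assign, row.names = NULL)
}

#' Write a composition test table as TSV
#' @param x a `composition_test`.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_composition_results <- function(x, path) {
  write.table(x$table[c("cell_type", "n_cells", "n_xyyy", "fraction",
                        "p_value", "q_value", "significant")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
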