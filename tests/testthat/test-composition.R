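two_type_instance <- function() {
  # 6 cells: type A all 45,X, type B all 48,XYYY
  cells <- data.frame(barcode = sprintf("c%d", 1:6),
                      cell_type = rep(c("A", "B"), each = 3))
  calls <- make_calls(cells$barcode, rep(c("45,X", "48,XYYY"), each = 3))
  list(cells = cells, calls = calls)
}

test_that("exact enumeration reproduces the analytic two-type p-value", {
  # C(6,3) = 20 assignments of the genotype multiset; only the observed
  # split and its mirror reach the maximal per-type deviation -> p = 2/20
  inst <- two_type_instance()
  ex <- exact_enumeration_test(inst$cells, inst$calls)
  expect_equal(ex$p_exact, c(0.1, 0.1))
  expect_equal(ex$statistic, c(0.5, 0.5))
})

test_that("Monte Carlo p-values agree with exact enumeration within MC error", {
  inst <- two_type_instance()
  mc <- permutation_test_composition(inst$cells, inst$calls,
                                     n_perm = 10000, seed = 7)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(mc$table$p_value - 0.1) <= 3 * se + 1 / 10001))
})

test_that("Monte Carlo converges to the exact p on a random small instance", {
  set.seed(13)
  cells <- data.frame(barcode = sprintf("c%d", 1:11),
                      cell_type = sample(c("A", "B", "C"), 11, replace = TRUE,
                                         prob = c(0.4, 0.4, 0.2)))
  calls <- make_calls(cells$barcode,
                      sample(c("45,X", "48,XYYY"), 11, replace = TRUE))
  ex <- exact_enumeration_test(cells, calls)
  mc <- permutation_test_composition(cells, calls, n_perm = 100000, seed = 3,
                                     min_cells = 1)
  for (i in seq_len(nrow(ex))) {
    p <- ex$p_exact[i]
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(mc$table$p_value[match(ex$cell_type[i], mc$table$cell_type)] - p),
              4 * se + 2 / 1e5 + 1e-9)
  }
})

test_that("a single-genotype dataset is the exact null: T = 0, p = 1", {
  cells <- data.frame(barcode = sprintf("c%d", 1:10),
                      cell_type = rep(c("A", "B"), 5))
  calls <- make_calls(cells$barcode, rep("45,X", 10))
  mc <- permutation_test_composition(cells, calls, n_perm = 500, seed = 1)
  expect_true(all(mc$table$statistic == 0))
  expect_true(all(mc$table$p_value == 1))
  ex <- exact_enumeration_test(cells, calls)
  expect_true(all(ex$p_exact == 1))
})

test_that("exact p-values are invariant to relabeling the genotype classes", {
  set.seed(29)
  cells <- data.frame(barcode = sprintf("c%d", 1:10),
                      cell_type = sample(c("A", "B"), 10, replace = TRUE))
  call_vec <- sample(c("45,X", "48,XYYY"), 10, replace = TRUE)
  flipped <- ifelse(call_vec == "45,X", "48,XYYY", "45,X")
  ex1 <- exact_enumeration_test(cells, make_calls(cells$barcode, call_vec))
  ex2 <- exact_enumeration_test(cells, make_calls(cells$barcode, flipped))
  expect_equal(ex1$p_exact, ex2$p_exact)
  expect_equal(ex1$statistic, ex2$statistic)
})

test_that("composition fractions are exact counts with low-n flags", {
  cells <- data.frame(barcode = sprintf("c%d", 1:5),
                      cell_type = c("A", "A", "A", "B", "B"))
  calls <- make_calls(cells$barcode, c("45,X", "45,X", "45,X", "48,XYYY", "45,X"))
  fr <- composition_fractions(cells, calls, min_cells = 3)
  expect_equal(fr$fraction, c(0, 0.5))
  expect_equal(fr$low_n, c(FALSE, TRUE))

  # degenerate: one type containing all cells has p_c = pooled fraction
  cells1 <- data.frame(barcode = sprintf("c%d", 1:4), cell_type = "A")
  calls1 <- make_calls(cells1$barcode, c("45,X", "48,XYYY", "45,X", "48,XYYY"))
  fr1 <- composition_fractions(cells1, calls1)
  expect_equal(fr1$fraction, 0.5)
})

test_that("simulator per-type fractions are recovered within binomial CIs", {
  cfg <- tiny_sim_config(
    n_cells = 2000, seed = 37,
    cell_types = data.frame(cell_type = c("A", "B"), proportion = c(0.5, 0.5)),
    type_fractions = c(A = 0.2, B = 0.8))
  sim <- simulate_pbmc(cfg)
  panel <- build_gene_panel(sim$annotation)
  calls <- call_genotype(sim$counts, panel)
  fr <- composition_fractions(sim$cells, calls)
  for (i in 1:2) {
    f_target <- c(A = 0.2, B = 0.8)[fr$cell_type[i]]
    ci <- qbinom(c(0.005, 0.995), fr$n_cells[i], f_target) / fr$n_cells[i]
    expect_gte(fr$fraction[i], ci[1])
    expect_lte(fr$fraction[i], ci[2])
  }
})

test_that("guard rails: coarse n_perm, one type, mismatched barcodes, big instances", {
  inst <- two_type_instance()
  expect_error(permutation_test_composition(inst$cells, inst$calls, n_perm = 50),
               class = "config_error")
  cells1 <- data.frame(barcode = sprintf("c%d", 1:6), cell_type = "A")
  expect_error(permutation_test_composition(cells1, inst$calls, n_perm = 1000),
               class = "config_error")
  bad <- inst$cells
  bad$barcode[1] <- "nope"
  expect_error(composition_fractions(bad, inst$calls), class = "join_error")
  cells13 <- data.frame(barcode = sprintf("c%d", 1:13),
                        cell_type = rep(c("A", "B"), length.out = 13))
  calls13 <- make_calls(cells13$barcode,
                        rep(c("45,X", "48,XYYY"), length.out = 13))
  expect_error(exact_enumeration_test(cells13, calls13), class = "config_error")
})

test_that("permutation p-values are uniform under the simulator's global null", {
  # pooled across the 8 default cell types; per-type uniformity at 500
  # replicates cannot distinguish KS 0.05 from sampling noise, so the
  # Kolmogorov-Smirnov check runs on the pooled p-values and each type
  # additionally gets a binomial check on P(p < 0.05)
  n_rep <- 500
  pmat <- matrix(NA_real_, n_rep, 8)
  for (r in seq_len(n_rep)) {
    sim <- simulate_pbmc(tiny_sim_config(n_cells = 2000, f = 0.5,
                                         seed = 20000 + r))
    panel <- build_gene_panel(sim$annotation)
    calls <- call_genotype(sim$counts, panel)
    mc <- permutation_test_composition(sim$cells, calls, n_perm = 500,
                                       seed = 30000 + r)
    pmat[r, ] <- mc$table$p_value[order(mc$table$cell_type)]
  }
  pooled <- as.vector(pmat)
  ks <- max(abs(ecdf(pooled)(pooled) - pooled))
  expect_lt(ks, 0.05)
  for (j in 1:8) {
    lo_hi <- qbinom(c(0.0005, 0.9995), n_rep, 0.05)
    expect_gte(sum(pmat[, j] < 0.05), lo_hi[1] - 1)
    expect_lte(sum(pmat[, j] < 0.05), lo_hi[2] + 1)
  }
})
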