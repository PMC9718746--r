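# Shared fixtures and independent oracles used across test files.

# genotype_calls object from externally known calls (bypasses the matrix)
make_calls <- function(barcode, call) {
  structure(list(
    calls = data.frame(barcode = barcode, y_umi = NA_real_, call = call),
    n_x = sum(call == "45,X"), n_xyyy = sum(call == "48,XYYY"),
    f_obs = mean(call == "48,XYYY"),
    min_y_umi = 1L, n_y_genes = NA_integer_),
    class = "genotype_calls")
}

# reduced gene catalogue: composition/genotype behaviour depends only on
# calls, so replicate-heavy checks run on ~100 genes instead of ~3000
tiny_sim_config <- function(...) {
  sim_config(n_autosomal = 60, n_x = 20, n_y = 10, n_par = 5, n_mt = 5, ...)
}

# a small hand-built count matrix: rows cells, cols genes
toy_count_matrix <- function(m, barcodes = NULL, ids = NULL, symbols = NULL) {
  m <- as.matrix(m)
  barcodes <- barcodes %||% sprintf("BC%02d", seq_len(nrow(m)))
  ids <- ids %||% sprintf("G%02d", seq_len(ncol(m)))
  count_matrix(m, barcodes, data.frame(id = ids, symbol = symbols %||% ids))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# independent exact two-sided rank-sum oracle: enumerates every assignment
# of the pooled observations to the two groups and doubles the smaller
# tail (ties in ranks not supported)
exact_ranksum_p <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  sets <- utils::combn(length(r), n)
  w <- apply(sets, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(w <= w_obs), mean(w >= w_obs)))
}

# write a tiny MatrixMarket triplet by hand (genes x cells on disk)
write_toy_triplet <- function(dir, entries, n_genes, n_cells) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c("%%MatrixMarket matrix coordinate integer general",
           sprintf("%d %d %d", n_genes, n_cells, nrow(entries)))
  body <- sprintf("%d %d %d", entries$gene, entries$cell, entries$count)
  writeLines(c(hdr, body), file.path(dir, "matrix.mtx"))
  writeLines(sprintf("CELL%02d", seq_len(n_cells)), file.path(dir, "barcodes.tsv"))
  writeLines(sprintf("G%02d\tSym%02d\tGene Expression", seq_len(n_genes), seq_len(n_genes)),
             file.path(dir, "features.tsv"))
  dir
}
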