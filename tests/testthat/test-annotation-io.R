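test_that("MTX triplets are read cells x genes with counts transcribed exactly", {
  d <- write_toy_triplet(withr::local_tempdir(),
                         data.frame(gene = c(1, 3), cell = c(1, 2), count = c(5, 1)),
                         n_genes = 3, n_cells = 2)
  cm <- read_mtx_triplet(file.path(d, "matrix.mtx"), file.path(d, "barcodes.tsv"),
                         file.path(d, "features.tsv"))
  expect_equal(dim(cm), c(2L, 3L))
  expect_equal(unname(Matrix::rowSums(cm$counts)), c(5, 1))
  expect_equal(as.numeric(cm$counts["CELL01", "G01"]), 5)
  expect_equal(as.numeric(cm$counts["CELL02", "G03"]), 1)
})

test_that("an entry-less MTX yields an all-zero matrix of the header shape", {
  d <- write_toy_triplet(withr::local_tempdir(),
                         data.frame(gene = integer(0), cell = integer(0),
                                    count = integer(0)),
                         n_genes = 3, n_cells = 2)
  cm <- read_mtx_triplet(file.path(d, "matrix.mtx"), file.path(d, "barcodes.tsv"),
                         file.path(d, "features.tsv"))
  expect_equal(dim(cm), c(2L, 3L))
  expect_equal(sum(cm$counts), 0)
})

test_that("read -> write -> read round-trips random sparse fixtures bit-exactly", {
  set.seed(42)
  for (rep in 1:5) {
    n_c <- sample(3:40, 1)
    n_g <- sample(3:60, 1)
    m <- matrix(rpois(n_c * n_g, 0.3), n_c, n_g)
    cm <- toy_count_matrix(m)
    d <- withr::local_tempdir()
    write_mtx_triplet(cm, d)
    cm2 <- read_mtx_triplet(file.path(d, "matrix.mtx"), file.path(d, "barcodes.tsv"),
                            file.path(d, "features.tsv"))
    expect_identical(as.matrix(cm2$counts), as.matrix(cm$counts))
    expect_identical(barcodes(cm2), barcodes(cm))
    expect_identical(cm2$genes$id, cm$genes$id)
    # second round trip is also identical
    d2 <- withr::local_tempdir()
    write_mtx_triplet(cm2, d2)
    cm3 <- read_mtx_triplet(file.path(d2, "matrix.mtx"), file.path(d2, "barcodes.tsv"),
                            file.path(d2, "features.tsv"))
    expect_identical(as.matrix(cm3$counts), as.matrix(cm$counts))
  }
})

test_that("malformed triplets are rejected as format errors", {
  d <- write_toy_triplet(withr::local_tempdir(),
                         data.frame(gene = 1, cell = 1, count = 2),
                         n_genes = 3, n_cells = 2)
  # header says 3 genes but feature file has 2 lines
  writeLines(c("G01\tS1", "G02\tS2"), file.path(d, "features.tsv"))
  expect_error(read_mtx_triplet(file.path(d, "matrix.mtx"),
                                file.path(d, "barcodes.tsv"),
                                file.path(d, "features.tsv")),
               class = "format_error")
  # non-integer counts
  expect_error(toy_count_matrix(matrix(c(1.5, 0, 0, 1), 2, 2)),
               class = "format_error")
  # negative counts
  expect_error(count_matrix(matrix(c(-1, 0, 0, 1), 2, 2), c("a", "b"),
                            data.frame(id = c("g1", "g2"), symbol = c("g1", "g2"))),
               class = "format_error")
  expect_error(read_mtx_triplet("no/such.mtx", "no/such.tsv", "no/such.tsv"),
               class = "format_error")
})

test_that("TSV annotation assigns chromosomes and PAR flags by interval overlap", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsymbol\tchrom\tstart\tend",
               "ENSG0001\tRPS4Y1\tY\t2841602\t2932000",
               "ENSG0002\tSLC25A6\tY\t1386152\t1392113",
               "ENSG0003\tXIST\tX\t73820651\t73852753",
               "ENSG0004\tAKT1\t14\t104769349\t104795748"), tf)
  ann <- read_gene_annotation(tf, format = "tsv")
  expect_equal(ann$chrom, c("Y", "Y", "X", "14"))
  expect_equal(ann$par, c(FALSE, TRUE, FALSE, FALSE))
  # PAR gene excluded from both panels; RPS4Y1 / XIST retained
  panel <- build_gene_panel(ann)
  expect_equal(panel$y_panel, "ENSG0001")
  expect_equal(panel$x_panel, "ENSG0003")
})

test_that("sex-chromosome genes without coordinates fail PAR flagging", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsymbol\tchrom", "g1\tDDX3Y\tY"), tf)
  expect_error(read_gene_annotation(tf, format = "tsv"),
               class = "annotation_error")
})

test_that("GTF annotation matches the TSV path on the same genes", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0('chrY\thavana\tgene\t2841602\t2932000\t.\t+\t.\t',
           'gene_id "ENSG0001"; gene_name "RPS4Y1";'),
    paste0('chrY\thavana\tgene\t1386152\t1392113\t.\t+\t.\t',
           'gene_id "ENSG0002"; gene_name "SLC25A6";'),
    paste0('chr7\thavana\tgene\t100\t200\t.\t-\t.\t',
           'gene_id "ENSG0005"; gene_name "FOO";')), gtf)
  ann <- read_gene_annotation(gtf, format = "gtf")
  expect_equal(ann$chrom, c("Y", "Y", "7"))
  expect_equal(ann$par, c(FALSE, TRUE, FALSE))
})

test_that("gene panels are order-invariant and fail without Y genes", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsymbol\tchrom\tstart\tend",
               "g1\tRPS4Y1\tY\t2841602\t2932000",
               "g2\tDDX3Y\tY\t12903998\t12920478",
               "g3\tXIST\tX\t73820651\t73852753",
               "g4\tA1\t1\t1\t2"), tf)
  ann <- read_gene_annotation(tf)
  p1 <- build_gene_panel(ann)
  p2 <- build_gene_panel(ann[sample(nrow(ann)), ])
  expect_identical(p1, p2)
  # independent count of non-PAR Y genes straight from the file text
  lines <- readLines(tf)[-1]
  n_y <- sum(vapply(strsplit(lines, "\t"), function(f) f[3] == "Y", TRUE))
  expect_length(p1$y_panel, n_y)
  expect_error(build_gene_panel(ann[ann$chrom == "1", ]), class = "config_error")
})

test_that("qc_filter drops exactly the cells failing thresholds and is idempotent", {
  # genes detected per cell: 150, 500, 2000 -> min_genes=200 keeps 2
  set.seed(7)
  m <- rbind(
    c(rep(1, 150), rep(0, 1850)),
    c(rep(1, 500), rep(0, 1500)),
    rep(1, 2000))
  cm <- toy_count_matrix(m)
  cells <- data.frame(barcode = barcodes(cm), cell_type = "t")
  out <- qc_filter(cm, cells, min_genes = 200, min_umi = 0,
                   max_mito_fraction = 1, verbose = FALSE)
  expect_equal(out$summary$n_kept, 2)
  expect_equal(out$cells$barcode, c("BC02", "BC03"))

  # zero thresholds are the identity
  out0 <- qc_filter(cm, cells, 0, 0, 1, verbose = FALSE)
  expect_equal(out0$summary$n_kept, 3)

  # idempotence
  out2 <- qc_filter(out$counts, out$cells, 200, 0, 1, verbose = FALSE)
  expect_identical(as.matrix(out2$counts$counts), as.matrix(out$counts$counts))
  expect_identical(out2$cells, out$cells)
})

test_that("planted low-quality simulator cells are exactly the ones removed", {
  sim <- simulate_pbmc(tiny_sim_config(n_cells = 300, n_lowq_cells = 12, seed = 5))
  # the reduced test catalogue has ~100 genes, so scale min_genes down
  out <- qc_filter(sim$counts, sim$cells, min_genes = 30, verbose = FALSE)
  removed <- setdiff(sim$cells$barcode, out$cells$barcode)
  expect_setequal(removed, sim$truth$cells$barcode[sim$truth$cells$low_quality])
})

test_that("qc metrics in the filtered table are consistent with the matrix", {
  sim <- simulate_pbmc(tiny_sim_config(n_cells = 100, seed = 9))
  out <- qc_filter(sim$counts, sim$cells, min_genes = 30, verbose = FALSE)
  expect_equal(out$cells$n_genes,
               unname(Matrix::rowSums(out$counts$counts > 0)))
  expect_equal(out$cells$n_umi, unname(Matrix::rowSums(out$counts$counts)))
})
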