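# builds a complete on-disk pipeline fixture from the simulator
make_pipeline_fixture <- function(dir, n_cells = 600, f = 0.4843, seed = 77,
                                  with_optional = TRUE) {
  sim <- simulate_pbmc(tiny_sim_config(n_cells = n_cells, f = f,
                                       n_lowq_cells = 10, seed = seed))
  write_sim_dataset(sim, dir)
  cfg <- list(matrix = file.path(dir, "matrix.mtx"),
              barcodes = file.path(dir, "barcodes.tsv"),
              features = file.path(dir, "features.tsv"),
              cell_types = file.path(dir, "cell_types.tsv"),
              annotation = file.path(dir, "annotation.tsv"),
              seed = 11,
              n_perm = 2000,
              min_genes = 30,  # reduced test catalogue has ~100 genes
              outdir = file.path(dir, "out"))
  if (with_optional) {
    ref <- simulate_pbmc(tiny_sim_config(n_cells = 500, f = 1, seed = seed + 1))
    refdir <- file.path(dir, "ref")
    write_sim_dataset(ref, refdir)
    cfg$reference_matrix <- file.path(refdir, "matrix.mtx")
    cfg$reference_barcodes <- file.path(refdir, "barcodes.tsv")
    cfg$reference_features <- file.path(refdir, "features.tsv")
    dd <- simulate_ddpcr(ddpcr_sim_config(f = f, seed = seed + 2))
    write.table(dd, file.path(dir, "ddpcr.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cfg$ddpcr <- file.path(dir, "ddpcr.tsv")
    rr <- data.frame(donor = c("M1", "M2", "M3"),
                     y_sum = c(100, 110, 95), x_sum = c(9000, 9400, 8800))
    write.table(rr, file.path(dir, "reference_ratios.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cfg$reference_ratios <- file.path(dir, "reference_ratios.tsv")
  }
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  list(sim = sim, cfg = cfg, cfg_path = cfg_path)
}
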