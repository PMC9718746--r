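default_cell_types <- function() {
  data.frame(
    cell_type = c("CD4+ T cells", "CD8+ T cells", "NK cells", "B cells",
                  "CD14+ Monocytes", "FCGR3A+ Monocytes", "Dendritic cells",
                  "Megakaryocytes"),
    proportion = c(0.30, 0.15, 0.10, 0.12, 0.22, 0.05, 0.03, 0.03))
}

y_gene_symbols <- c("RPS4Y1", "DDX3Y", "EIF1AY", "KDM5D", "UTY", "USP9Y",
                    "ZFY", "NLGN4Y", "TMSB4Y", "TXLNGY", "PRKY", "RPS4Y2")

#' Simulation configuration for mosaic PBMC UMI data
#'
#' Defines a two-lineage (45,X vs 48,XYYY) peripheral-blood mononuclear
#' cell population: eight immune cell types with given global proportions,
#' a per-type or global 48,XYYY lineage fraction, log-normal library
#' sizes, log-normal per-gene base expression partitioned into chromosome
#' classes, and gamma-Poisson (negative binomial) UMI sampling. Dropout
#' arises from low means; there is no separate zero-inflation knob.
#' Y-linked gene means scale with Y copy number (both lineages carry a
#' single X, so X-linked expression is lineage-invariant).
#'
#' Defaults mirror a PBMC study at desk scale: ~3000 cells, ~7400 UMIs
#' per cell, eight immune cell types, a near-balanced lineage split.
#'
#' @param n_cells number of cells.
#' @param f global 48,XYYY lineage fraction, used for any type without an
#'   entry in `type_fractions`.
#' @param type_fractions optional named numeric vector of per-cell-type
#'   48,XYYY fractions.
#' @param cell_types data.frame with columns cell_type, proportion.
#' @param n_autosomal,n_x,n_y,n_par,n_mt gene catalogue sizes by class.
#' @param x_frac,y_frac,par_frac,mt_frac expected fraction of a cell's
#'   transcriptome from each class; `y_frac` is per single Y copy.
#'   Autosomes take the remainder.
#' @param base_mean_sdlog log-normal sd of relative per-gene expression
#'   weights within a class (meanlog fixed at 0; weights are normalized).
#' @param library_meanlog,library_sdlog log-normal library-size
#'   parameters (total expected UMIs per cell).
#' @param y_dosage_multiplier Y-gene mean scaling in 48,XYYY cells
#'   (3 Y copies by default).
#' @param ambient_y_rate expected spurious ambient Y-panel UMIs added per
#'   cell (Poisson, spread uniformly over the Y panel); default 0.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param n_de_genes,de_fold optionally plant `n_de_genes` autosomal genes
#'   whose mean is multiplied by `de_fold` in the 48,XYYY lineage.
#' @param n_lowq_cells number of planted low-quality cells (tiny library,
#'   high mitochondrial load) that a QC filter should remove.
#' @param seed mandatory RNG seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 3000, f = 0.4843, type_fractions = NULL,
                       cell_types = default_cell_types(),
                       n_autosomal = 2900, n_x = 60, n_y = 12, n_par = 16,
                       n_mt = 13,
                       x_frac = 0.03, y_frac = 4e-4, par_frac = 2e-3,
                       mt_frac = 0.05,
                       base_mean_sdlog = 1.0,
                       library_meanlog = log(7400), library_sdlog = 0.35,
                       y_dosage_multiplier = 3, ambient_y_rate = 0,
                       dispersion = 0.1,
                       n_de_genes = 0, de_fold = 1,
                       n_lowq_cells = 0, seed) {
  if (missing(seed) || is.null(seed))
    stop_mosaic("sim_config: seed is mandatory for reproducibility",
                class = "config_error")
  check_fraction(f, "f")
  if (!is.null(type_fractions)) {
    if (is.null(names(type_fractions)) ||
        !all(names(type_fractions) %in% cell_types$cell_type))
      stop_mosaic("type_fractions names must be cell types of the catalogue",
                  class = "config_error")
    for (v in type_fractions) check_fraction(v, "type_fractions")
  }
  if (y_dosage_multiplier <= 0)
    stop_mosaic("y_dosage_multiplier must be > 0", class = "config_error")
  if (ambient_y_rate < 0)
    stop_mosaic("ambient_y_rate must be >= 0", class = "config_error")
  stopifnot(n_cells >= 1, n_y >= 1, dispersion > 0,
            n_lowq_cells >= 0, n_lowq_cells <= n_cells,
            n_de_genes >= 0, n_de_genes <= n_autosomal, de_fold > 0)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_catalogue <- function(cfg) {
  classes <- rep(c("autosome", "X", "Y", "PAR", "MT"),
                 c(cfg$n_autosomal, cfg$n_x, cfg$n_y, cfg$n_par, cfg$n_mt))
  n <- length(classes)
  id <- sprintf("SIMG%05d", seq_len(n))
  symbol <- sprintf("Gene%05d", seq_len(n))
  symbol[classes == "Y"] <- c(y_gene_symbols,
                              sprintf("YG%03d", seq_len(max(0, cfg$n_y - length(y_gene_symbols)))))[seq_len(cfg$n_y)]
  symbol[classes == "X"][seq_len(min(1, cfg$n_x))] <- "XIST"
  symbol[classes == "MT"] <- sprintf("MT-G%02d", seq_len(cfg$n_mt))
  chrom <- c(autosome = "7", X = "X", Y = "Y", PAR = "Y", MT = "MT")[classes]
  # autosomal genes spread over chromosomes 1..22 for flavor
  chrom[classes == "autosome"] <-
    as.character(rep_len(1:22, cfg$n_autosomal))
  # synthetic coordinates so the annotation round-trips through the
  # PAR-interval overlap logic: PAR-class genes inside GRCh38 PAR1 on Y,
  # X/Y-class genes safely outside both PARs
  start <- 1000000L + 5000L * seq_len(n)
  start[classes %in% c("X", "Y")] <- 3000000L + 5000L * seq_len(sum(classes %in% c("X", "Y")))
  start[classes == "PAR"] <- 20000L + 5000L * seq_len(sum(classes == "PAR"))
  data.frame(id = id, symbol = symbol, chrom = chrom, class = classes,
             start = start, end = start + 2000L)
}

#' Simulate a mosaic PBMC UMI count matrix with known ground truth
#'
#' Draws cell types and 48,XYYY lineage membership, then samples UMI
#' counts per cell from a negative binomial with mean
#' library_size x relative gene expression; Y-panel means are scaled by
#' `y_dosage_multiplier` in 48,XYYY cells and are zero in 45,X cells
#' (up to optional ambient contamination). Identical seed and config give
#' bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (a [count_matrix()]), `cells` (barcode,
#'   cell_type), `annotation` (gene annotation data.frame usable with
#'   [build_gene_panel()]; PAR-class genes carry a TRUE par flag), and
#'   `truth` (per-cell lineage, planted DE genes, expected per-gene means,
#'   realized per-type fractions, config echo).
#' @export
simulate_pbmc <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sim_gene_catalogue(cfg)
  n <- cfg$n_cells

  ct <- cfg$cell_types
  cell_type <- sample(ct$cell_type, n, replace = TRUE, prob = ct$proportion)
  fr <- setNames(rep(cfg$f, nrow(ct)), ct$cell_type)
  if (!is.null(cfg$type_fractions))
    fr[names(cfg$type_fractions)] <- cfg$type_fractions
  lineage <- ifelse(runif(n) < fr[cell_type], "48,XYYY", "45,X")

  # relative expression: within-class log-normal weights scaled to the
  # class transcriptome budget (single-copy genome)
  w <- rlnorm(nrow(genes), 0, cfg$base_mean_sdlog)
  budget <- c(autosome = 1 - cfg$x_frac - cfg$y_frac - cfg$par_frac - cfg$mt_frac,
              X = cfg$x_frac, Y = cfg$y_frac, PAR = cfg$par_frac, MT = cfg$mt_frac)
  p <- numeric(nrow(genes))
  for (cl in names(budget)) {
    i <- genes$class == cl
    if (any(i)) p[i] <- w[i] / sum(w[i]) * budget[[cl]]
  }

  de_idx <- integer(0)
  if (cfg$n_de_genes > 0)
    de_idx <- sample(which(genes$class == "autosome"), cfg$n_de_genes)

  # per-lineage relative expression
  p_x <- p
  p_x[genes$class == "Y"] <- 0
  p_xyyy <- p
  p_xyyy[genes$class == "Y"] <- p[genes$class == "Y"] * cfg$y_dosage_multiplier
  p_xyyy[de_idx] <- p_xyyy[de_idx] * cfg$de_fold

  lib <- rlnorm(n, cfg$library_meanlog, cfg$library_sdlog)
  lowq <- rep(FALSE, n)
  if (cfg$n_lowq_cells > 0) {
    li <- sample.int(n, cfg$n_lowq_cells)
    lowq[li] <- TRUE
    lib[li] <- lib[li] * 0.015  # ~100 UMIs: fails any sane QC threshold
  }

  size <- 1 / cfg$dispersion
  counts <- matrix(0L, n, nrow(genes))
  for (lin in c("45,X", "48,XYYY")) {
    i <- which(lineage == lin)
    if (!length(i)) next
    pv <- if (lin == "45,X") p_x else p_xyyy
    mu <- outer(lib[i], pv)
    counts[i, ] <- rnbinom(length(mu), mu = mu, size = size)
  }
  if (cfg$ambient_y_rate > 0) {
    yi <- which(genes$class == "Y")
    counts[, yi] <- counts[, yi] +
      rpois(n * length(yi), cfg$ambient_y_rate / length(yi))
  }

  bc <- sprintf("CELL%05d-1", seq_len(n))
  cm <- count_matrix(counts, bc, genes[c("id", "symbol")])
  cells <- data.frame(barcode = bc, cell_type = cell_type)

  ann <- data.frame(id = genes$id, symbol = genes$symbol, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    par = genes$class == "PAR")

  realized <- tapply(lineage == "48,XYYY", cell_type, mean)
  truth <- list(
    cells = data.frame(barcode = bc, cell_type = cell_type, lineage = lineage,
                       library_size = lib, low_quality = lowq),
    genes = data.frame(id = genes$id, class = genes$class,
                       expected_mean_45x = exp(cfg$library_meanlog + cfg$library_sdlog^2 / 2) * p_x,
                       expected_mean_48xyyy = exp(cfg$library_meanlog + cfg$library_sdlog^2 / 2) * p_xyyy),
    de_genes = genes$id[de_idx],
    realized_type_fractions = realized,
    config = cfg)
  list(counts = cm, cells = cells, annotation = ann, truth = truth)
}

#' ddPCR simulation configuration (AMELX/AMELY assay)
#'
#' Droplets partition genomic DNA; a droplet is positive for a channel
#' when it contains at least one target copy, so positivity is
#' Binomial(n_droplets, 1 - exp(-lambda)) with lambda the mean copies per
#' droplet. With `lambda_gdna` genome-equivalents per droplet, a mixture
#' with 48,XYYY cell fraction `f` has lambda_AMELX = lambda_gdna (one X in
#' both lineages) and lambda_AMELY = lambda_gdna * 3f (three Y copies per
#' 48,XYYY genome, none in 45,X).
#'
#' @param n_droplets droplets per well.
#' @param lambda_gdna genome-equivalents per droplet (> 0).
#' @param f true 48,XYYY cell fraction in the DNA input.
#' @param n_wells replicate wells per assay.
#' @param y_copies Y copies per Y-bearing genome (3 for 48,XYYY).
#' @param seed mandatory RNG seed.
#' @return an object of class `ddpcr_sim_config`.
#' @export
ddpcr_sim_config <- function(n_droplets = 20000, lambda_gdna = 0.5, f = 0.5,
                             n_wells = 8, y_copies = 3, seed) {
  if (missing(seed) || is.null(seed))
    stop_mosaic("ddpcr_sim_config: seed is mandatory", class = "config_error")
  if (lambda_gdna <= 0)
    stop_mosaic("lambda_gdna must be > 0", class = "config_error")
  check_fraction(f, "f")
  stopifnot(n_droplets >= 1, n_wells >= 1, y_copies > 0)
  structure(list(n_droplets = as.integer(n_droplets),
                 lambda_gdna = lambda_gdna, f = f,
                 n_wells = as.integer(n_wells), y_copies = y_copies,
                 seed = as.integer(seed)),
            class = "ddpcr_sim_config")
}

#' Simulate ddPCR droplet counts for the AMELX/AMELY assay
#'
#' @param cfg a [ddpcr_sim_config()].
#' @return data.frame with columns well, channel, n_droplets, n_positive.
#' @export
simulate_ddpcr <- function(cfg) {
  stopifnot(inherits(cfg, "ddpcr_sim_config"))
  set.seed(cfg$seed)
  lam <- c(AMELX = cfg$lambda_gdna,
           AMELY = cfg$lambda_gdna * cfg$y_copies * cfg$f)
  out <- expand.grid(well = sprintf("W%02d", seq_len(cfg$n_wells)),
                     channel = names(lam), stringsAsFactors = FALSE)
  out <- out[order(out$well, out$channel), ]
  out$n_droplets <- cfg$n_droplets
  out$n_positive <- rbinom(nrow(out), cfg$n_droplets, 1 - exp(-lam[out$channel]))
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits the MTX triplet, a cell-type TSV, an annotation TSV and a truth
#' TSV, so the simulator output can feed the file-based pipeline.
#'
#' @param sim result of [simulate_pbmc()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_triplet(sim$counts, dir)
  write.table(sim$cells, file.path(dir, "cell_types.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$cells, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
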