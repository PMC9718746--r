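pipeline_defaults <- function() {
  list(
    annotation_format = "tsv",
    ddpcr = NULL, reference_ratios = NULL,
    reference_matrix = NULL, reference_barcodes = NULL,
    reference_features = NULL,
    malignancy_genes = NULL,
    min_genes = 200, min_umi = 500, max_mito_fraction = 0.10,
    min_y_umi = 1, n_perm = 10000, alpha = 0.05, min_cells = 20,
    de_mode = "per_type", min_frac_expressing = 0.1,
    scale_factor = 10000, y_copies = 3,
    seed = 1, outdir = "mosaicY_out")
}

mandatory_keys <- c("matrix", "barcodes", "features", "cell_types", "annotation")

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, checks ranges, and verifies that
#' every referenced input path exists. Accepts a YAML path or a named
#' list.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated object of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_mosaic("config file not found: ", config, class = "validation_error")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop_mosaic("config must be a YAML file or a named list",
                class = "validation_error")
  defs <- pipeline_defaults()
  known <- c(mandatory_keys, names(defs))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop_mosaic("unknown config keys: ", paste(unknown, collapse = ", "),
                class = "validation_error")
  for (k in mandatory_keys)
    if (is.null(config[[k]]))
      stop_mosaic("missing mandatory config key: ", k, class = "validation_error")
  cfg <- utils::modifyList(defs, config)
  # modifyList drops NULL-valued keys; keep optional keys present
  for (k in names(defs))
    if (!k %in% names(cfg)) cfg[k] <- list(NULL)
  path_keys <- c(mandatory_keys, "ddpcr", "reference_ratios", "malignancy_genes",
                 "reference_matrix", "reference_barcodes", "reference_features")
  for (k in path_keys)
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop_mosaic("config key '", k, "' points to a missing file: ", cfg[[k]],
                  class = "validation_error")
  ref_keys <- c("reference_matrix", "reference_barcodes", "reference_features")
  if (any(!vapply(cfg[ref_keys], is.null, TRUE)) &&
      any(vapply(cfg[ref_keys], is.null, TRUE)))
    stop_mosaic("reference_matrix/_barcodes/_features must be given together",
                class = "validation_error")
  if (!cfg$annotation_format %in% c("tsv", "gtf"))
    stop_mosaic("annotation_format must be 'tsv' or 'gtf'",
                class = "validation_error")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop_mosaic("alpha must be in (0, 1)", class = "validation_error")
  if (!cfg$de_mode %in% c("per_type", "pooled"))
    stop_mosaic("de_mode must be 'per_type' or 'pooled'",
                class = "validation_error")
  stopifnot(cfg$n_perm >= 100, cfg$min_y_umi >= 1, cfg$min_genes >= 0,
            cfg$min_umi >= 0, cfg$max_mito_fraction >= 0, cfg$y_copies > 0,
            cfg$scale_factor > 0, cfg$min_frac_expressing >= 0,
            cfg$min_frac_expressing <= 1)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg[order(match(names(cfg), known))], class = "pipeline_config")
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL  # where the report lands does not change the analysis
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

provenance_line <- function(cfg, hash) {
  sprintf("# mosaicY %s | config_hash=%s | seed=%d",
          as.character(packageVersion("mosaicY")), hash, cfg$seed)
}

write_tsv_prov <- function(d, path, prov) {
  writeLines(prov, path)
  suppressWarnings(write.table(d, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full mosaicism analysis pipeline
#'
#' Orchestrates annotate -> QC -> genotype (with optional dropout
#' correction from a reference matrix) -> composition permutation test ->
#' Y/X dosage (with optional reference comparison) -> per-cell-type
#' differential expression with malignancy-gene flagging -> optional
#' ddPCR cross-check. Writes per-stage TSV/JSON outputs and a
#' consolidated `summary.json`; every output carries a provenance header
#' (tool version, config hash, seed). Optional stages with absent inputs
#' are marked "skipped" in the summary.
#'
#' @param config a `pipeline_config`, YAML path, or named list.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  prov <- provenance_line(cfg, hash)
  yaml::write_yaml(unclass(cfg), file.path(cfg$outdir, "effective_config.yaml"))
  logf <- file.path(cfg$outdir, "pipeline.log")
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    message(line)
    cat(line, "\n", file = logf, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    log_msg("stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      stop_mosaic("stage '", name, "' failed: ", conditionMessage(e),
                  " (check the corresponding config inputs)",
                  class = "pipeline_error")
    })
  }
  summary_out <- list(provenance = list(
    version = as.character(packageVersion("mosaicY")),
    config_hash = hash, seed = cfg$seed))

  ann <- stage("annotation", read_gene_annotation(cfg$annotation, cfg$annotation_format))
  panel <- stage("annotation", build_gene_panel(ann))
  cm <- stage("read_counts", read_mtx_triplet(cfg$matrix, cfg$barcodes, cfg$features))
  labels <- stage("read_counts", read_cell_labels(cfg$cell_types))

  qc <- stage("qc", qc_filter(cm, labels, cfg$min_genes, cfg$min_umi,
                              cfg$max_mito_fraction, annotations = ann,
                              verbose = FALSE))
  write_tsv_prov(qc$cells, file.path(cfg$outdir, "qc_report.tsv"), prov)
  summary_out$qc <- qc$summary
  log_msg(sprintf("qc: kept %d/%d cells", qc$summary$n_kept, qc$summary$n_in))

  calls <- stage("genotype", call_genotype(qc$counts, panel, cfg$min_y_umi))
  if (!is.null(cfg$reference_matrix)) {
    ref <- stage("genotype", read_mtx_triplet(cfg$reference_matrix,
                                              cfg$reference_barcodes,
                                              cfg$reference_features))
    fnr <- stage("genotype", estimate_false_negative_rate(ref, panel, cfg$min_y_umi))
    calls <- apply_fnr_correction(calls, fnr,
                                  seed = derive_seed(cfg$seed, "fnr_boot"))
  }
  write_genotype_results(calls, cfg$outdir)
  summary_out$genotype <- list(
    n_x = calls$n_x, n_xyyy = calls$n_xyyy, f_obs = calls$f_obs,
    f_hat = calls$f_hat %||% calls$f_obs, q = calls$q %||% 0)
  log_msg(sprintf("genotype: f_obs=%.4f", calls$f_obs))

  comp <- stage("composition",
                permutation_test_composition(qc$cells, calls,
                                             n_perm = cfg$n_perm,
                                             seed = derive_seed(cfg$seed, "composition"),
                                             alpha = cfg$alpha,
                                             min_cells = cfg$min_cells))
  write_composition_results(comp, file.path(cfg$outdir, "composition.tsv"))
  summary_out$composition <- list(
    p_bar = comp$p_bar, n_perm = comp$n_perm,
    q_values = as.list(setNames(comp$table$q_value, comp$table$cell_type)),
    significant_types = comp$table$cell_type[comp$table$significant])

  dr <- stage("dosage", yx_ratio(qc$counts,
                                 calls$calls$call == "48,XYYY",
                                 panel, group = "48,XYYY"))
  dos_tab <- data.frame(group = dr$group, y_sum = dr$y_sum, x_sum = dr$x_sum,
                        ratio = dr$ratio, n_cells = dr$n_cells)
  summary_out$dosage <- list(yx_ratio_48xyyy = dr$ratio)
  if (!is.null(cfg$reference_ratios)) {
    rr <- read.delim(cfg$reference_ratios, stringsAsFactors = FALSE)
    if (!all(c("donor", "y_sum", "x_sum") %in% names(rr)))
      stop_mosaic("reference_ratios TSV needs columns donor, y_sum, x_sum",
                  class = "format_error")
    cmp <- compare_to_reference(dr, rr$y_sum / rr$x_sum)
    dos_tab <- rbind(dos_tab,
                     data.frame(group = paste0("ref:", rr$donor),
                                y_sum = rr$y_sum, x_sum = rr$x_sum,
                                ratio = rr$y_sum / rr$x_sum, n_cells = NA))
    summary_out$dosage$reference_median <- cmp$reference_median
    summary_out$dosage$rank <- cmp$rank
    summary_out$dosage$elevated <- cmp$elevated
  } else {
    summary_out$dosage$reference_comparison <- "skipped"
  }
  write_tsv_prov(dos_tab, file.path(cfg$outdir, "dosage.tsv"), prov)

  norm <- stage("diffexp", normalize_counts(qc$counts, cfg$scale_factor))
  de <- stage("diffexp", {
    if (cfg$de_mode == "pooled")
      de_test(norm, calls, qc$cells, NULL, cfg$min_frac_expressing,
              cfg$alpha, cfg$min_cells, genes = ann)
    else
      de_test_all_types(norm, calls, qc$cells,
                        min_frac_expressing = cfg$min_frac_expressing,
                        alpha = cfg$alpha, min_cells = cfg$min_cells,
                        genes = ann)
  })
  de <- de %||% data.frame()
  fl <- stage("diffexp", flag_malignancy_genes(
    de, cfg$malignancy_genes %||% system.file(
      "extdata", "hematologic_malignancy_genes.tsv", package = "mosaicY")))
  if (nrow(fl$results))
    write_tsv_prov(fl$results, file.path(cfg$outdir, "de_results.tsv"), prov)
  summary_out$diffexp <- list(
    mode = cfg$de_mode, n_deg = nrow(de),
    n_flagged = if (nrow(fl$results)) nrow(fl$flagged) else 0L,
    flagged_genes = if (nrow(fl$results)) unique(fl$flagged$symbol) else character(0))
  log_msg(sprintf("diffexp: %d DEGs, %d malignancy-flagged",
                  summary_out$diffexp$n_deg, summary_out$diffexp$n_flagged))

  if (!is.null(cfg$ddpcr)) {
    wells <- stage("ddpcr", read_ddpcr_table(cfg$ddpcr))
    est <- stage("ddpcr", estimate_fraction(wells, cfg$y_copies))
    jsonlite::write_json(list(provenance = summary_out$provenance,
                              lambda_amelx = est$lambda_amelx$lambda,
                              lambda_amely = est$lambda_amely$lambda,
                              f_ddpcr = est$f_ddpcr, f_ci = est$f_ci),
                         file.path(cfg$outdir, "ddpcr_estimate.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary_out$ddpcr <- list(
      f_ddpcr = est$f_ddpcr, f_ci = est$f_ci,
      concordance_abs_diff = abs((summary_out$genotype$f_hat) - est$f_ddpcr))
  } else {
    summary_out$ddpcr <- "skipped"
  }

  jsonlite::write_json(summary_out, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("pipeline complete: ", file.path(cfg$outdir, "summary.json"))
  invisible(summary_out)
}
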