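# End-to-end orchestration: simulate -> QC -> classify -> normalize ->
# cluster -> report, from one config, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the study's
#' defaults: measurement QC (quality >= 0.65, Ct < 35), the UBB integrity
#' ceiling (25 cycles), the minimum expressed-gene count (10), the gene
#' detectability fraction (0.15), balanced subsampling caps (5 per patient,
#' 7 per cell line), the k = 2 cut for the CTC tree, the +/-3 SD
#' imputation/truncation multiplier, the reference panel and the clustering
#' metric/linkage.
#'
#' @param quality_min,ct_max measurement QC thresholds.
#' @param ubb_max_ct exclusive UBB Ct ceiling for RNA integrity.
#' @param min_genes minimum expressed genes per retained cell.
#' @param min_frac minimum expressed fraction for a detectable gene.
#' @param max_per_patient,per_cell_line balanced-subsampling caps.
#' @param k number of CTC clusters cut from the tree.
#' @param k_sd SD multiplier for imputation and display truncation.
#' @param reference_panel reference assays for -dCt normalization.
#' @param metric,linkage clustering distance and linkage.
#' @param seed master seed; simulation and subsampling use streams derived
#'   from it.
#' @param heatmap render heatmap figures (pdf) in the output directory.
#' @param combined also cluster the combined cell-line + CTC analysis set.
#' @return a validated `pipeline_config` list.
#' @export
pipelineConfig <- function(quality_min = 0.65, ct_max = 35, ubb_max_ct = 25,
                           min_genes = 10, min_frac = 0.15,
                           max_per_patient = 5, per_cell_line = 7, k = 2,
                           k_sd = 3,
                           reference_panel = c("UBB", "ACTB", "GAPDH"),
                           metric = "euclidean", linkage = "complete",
                           seed = 1, heatmap = TRUE, combined = TRUE) {
  if (quality_min < 0 || quality_min > 1) stop("config error: quality_min outside [0, 1]")
  if (ct_max <= 0 || ubb_max_ct <= 0) stop("config error: Ct thresholds must be positive")
  if (min_genes < 0) stop("config error: negative min_genes")
  if (min_frac < 0 || min_frac > 1) stop("config error: min_frac outside [0, 1]")
  if (max_per_patient < 1 || per_cell_line < 1) stop("config error: subsampling caps must be >= 1")
  if (k < 1) stop("config error: k must be >= 1")
  if (k_sd <= 0) stop("config error: k_sd must be positive")
  structure(list(quality_min = quality_min, ct_max = ct_max,
                 ubb_max_ct = ubb_max_ct, min_genes = min_genes,
                 min_frac = min_frac, max_per_patient = max_per_patient,
                 per_cell_line = per_cell_line, k = k, k_sd = k_sd,
                 reference_panel = reference_panel, metric = metric,
                 linkage = linkage, seed = as.integer(seed),
                 heatmap = heatmap, combined = combined),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full profiling pipeline
#'
#' Executes simulate (unless data are supplied), measurement QC, gene
#' exclusion, the minimum-gene screen, reference-integrity gating,
#' classification, balanced subsampling, -dCt normalization, detectability
#' gene selection, imputation, hierarchical clustering with a k-cut,
#' cluster composition, and reporting. All stage outputs, the filter
#' funnel, a human-readable summary and a manifest (config echo + seed +
#' content hashes of the text outputs) are written to `out_dir`. A rerun
#' with the same config and inputs is bit-identical on every hashed
#' output.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir output directory (created if needed).
#' @param data optional list with `experiment` (a [CtExperiment-class]),
#'   `panel` (a [GenePanel-class]) and optionally `truth`; default
#'   simulates [defaultStudyConfig()] under the config seed.
#' @return invisibly, a list with every intermediate object and the paths
#'   written.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir, data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths <<- c(paths, p)
    p
  }

  ## 1. simulate (or accept provided data)
  sim <- .stage("simulate", {
    if (is.null(data)) {
      cfg <- defaultStudyConfig()
      out <- generateChipData(cfg$specs, cfg$noise, cfg$panel,
                              seed = config$seed,
                              unmeasured = cfg$unmeasured)
      out$panel <- cfg$panel
      out
    } else {
      if (is.null(data$experiment) || is.null(data$panel))
        stop("data must provide 'experiment' and 'panel'")
      data
    }
  })
  x <- sim$experiment
  meta <- cellMeta(x)
  panel <- sim$panel
  put("cell_meta.tsv", function(p) writeCellMeta(meta, p))
  if (!is.null(sim$truth))
    put("truth.tsv", function(p)
      utils::write.table(sim$truth, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))

  ## 2. measurement + gene + cell QC
  calls <- .stage("measurement_qc",
                  applyMeasurementQC(x, config$quality_min, config$ct_max))
  ntc_cells <- meta$cell_id[meta$source == "ntc"]
  panel <- .stage("gene_exclusion",
                  excludeGenes(panel, x, calls, ntc_cells))
  calls <- maskExcluded(calls, panel)
  put("panel.json", function(p) writeGenePanel(panel, p))
  put("calls.tsv", function(p) {
    m <- callsMatrix(calls)
    storage.mode(m) <- "double"
    writeMatrix(t(m), p)
  })

  patient_cells <- meta$cell_id[meta$source == "patient"]
  min_ok <- .stage("min_gene_filter", {
    keep <- filterCellsMinGenes(calls, config$min_genes,
                                cells = patient_cells)
    if (!length(keep)) stop("no cells retained")
    keep
  })
  intact <- .stage("reference_integrity",
                   referenceIntegrityGate(x, calls, config$ubb_max_ct,
                                          cells = min_ok))

  ## 3. classification
  classification <- .stage("classification",
                           classifyCells(calls, panel, meta,
                                         integrity_pass = intact,
                                         cells = min_ok))
  put("classification.tsv", function(p)
    utils::write.table(classification, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  ## funnel over patient cells
  ctc_cells <- classification$cell_id[classification$label == "CTC"]
  funnel_pre <- list(
    list(name = "min_gene_filter",
         removed = list(too_few_genes = setdiff(patient_cells, min_ok))),
    list(name = "reference_integrity",
         removed = list(degraded_rna = setdiff(min_ok, intact))),
    list(name = "classification",
         removed = lapply(
           split(classification$cell_id, classification$label)[
             c("WBC", "AMBIGUOUS_KRT_CD45", "NON_EPITHELIAL")],
           identity))
  )

  ## 4. balanced subsampling
  line_cells <- meta$cell_id[meta$source == "cell_line"]
  line_ok <- referenceComplete(calls, config$reference_panel,
                               cells = line_cells)
  aset <- .stage("subsample",
                 subsampleCells(classification, meta,
                                line_cells = if (length(line_ok)) line_ok else NULL,
                                max_per_patient = config$max_per_patient,
                                per_cell_line = config$per_cell_line,
                                seed = (config$seed + 1L) %% 2147483647L))
  ctc_aset <- intersect(aset$cells, ctc_cells)
  line_aset <- intersect(aset$cells, line_cells)
  funnel <- funnelReport(patient_cells, c(funnel_pre, list(
    list(name = "balanced_subsampling",
         removed = list(over_patient_cap = setdiff(ctc_cells, ctc_aset))))))
  put("funnel.tsv", function(p)
    utils::write.table(as.data.frame(funnel), p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  put("funnel.json", function(p)
    jsonlite::write_json(as.data.frame(funnel), p, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE))
  put("analysis_set.tsv", function(p)
    writeLines(aset$cells, p))

  ## 5. normalization + gene selection + clustering (CTC mode)
  if (length(ctc_aset) < 2L)
    stopStage("normalize", "fewer than 2 CTCs in the analysis set")
  norm <- .stage("normalize",
                 normalizeExpression(x, calls, ctc_aset,
                                     reference_panel = config$reference_panel))
  detectable <- .stage("gene_selection",
                       selectDetectableGenes(calls, ctc_aset,
                                             config$min_frac))
  put("detectable_genes.txt", function(p) writeLines(detectable, p))
  norm_sub <- subsetGenes(norm, detectable)
  put("normalized_ctc.tsv", function(p)
    writeMatrix(t(normalizedValues(norm_sub)), p))
  imp <- .stage("imputation", imputeAndTruncate(norm_sub, config$k_sd))
  result <- .stage("clustering",
                   hclusterCells(t(imp$clustering), config$metric,
                                 config$linkage))
  labels <- cutClusters(result, config$k)
  put("ctc_cluster_labels.tsv", function(p)
    utils::write.table(data.frame(cell_id = names(labels),
                                  cluster = as.character(utils::as.roman(labels))),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))
  put("ctc_dendrogram.nwk", function(p) exportNewick(result, p))
  composition <- .stage("composition", compositionTable(labels, meta))
  put("composition.tsv", function(p)
    utils::write.table(composition$clusters, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  put("composition.json", function(p)
    jsonlite::write_json(list(clusters = composition$clusters,
                              overlap = composition$overlap[
                                c("n_cases_total", "n_shared", "pct_shared")]),
                         p, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE))
  if (config$heatmap) {
    ann <- data.frame(cluster = as.character(utils::as.roman(labels)),
                      row.names = names(labels))
    .stage("heatmap",
           renderHeatmap(imp$display, result,
                         file = file.path(out_dir, "ctc_heatmap.pdf"),
                         annotations = ann, k_sd = config$k_sd,
                         pooled_sd = imp$pooled_sd))
    paths <- c(paths, file.path(out_dir, "ctc_heatmap.pdf.order.txt"))
  }

  ## 6. combined cell-line + CTC mode on the same detectable-gene subset
  combined <- NULL
  if (config$combined && length(line_aset) >= 2L) {
    comb_cells <- c(line_aset, ctc_aset)
    comb_norm <- .stage("normalize_combined",
                        normalizeExpression(x, calls, comb_cells,
                                            reference_panel = config$reference_panel))
    comb_sub <- subsetGenes(comb_norm, detectable)
    comb_imp <- imputeAndTruncate(comb_sub, config$k_sd)
    comb_res <- hclusterCells(t(comb_imp$clustering), config$metric,
                              config$linkage)
    comb_labels <- cutClusters(comb_res, 2L)
    src <- stats::setNames(meta$source[match(comb_cells, meta$cell_id)],
                           comb_cells)
    combined <- list(result = comb_res, labels = comb_labels, source = src)
    put("combined_dendrogram.nwk", function(p) exportNewick(comb_res, p))
    put("combined_cluster_labels.tsv", function(p)
      utils::write.table(data.frame(cell_id = names(comb_labels),
                                    cluster = comb_labels,
                                    source = src[names(comb_labels)]),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## 7. report + manifest
  res <- list(experiment = x, panel = panel, truth = sim$truth,
              calls = calls, min_gene_pass = min_ok, integrity_pass = intact,
              classification = classification, funnel = funnel,
              analysis_set = aset, ctc_cells = ctc_aset,
              line_cells = line_aset, normalized = norm_sub,
              detectable_genes = detectable, cluster_result = result,
              labels = labels, composition = composition,
              combined = combined, config = config, out_dir = out_dir)
  put("summary.txt", function(p) writeLines(summarizeRun(res), p))
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    files = as.list(tools::md5sum(sort(paths)))
  )
  names(manifest$files) <- basename(sort(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Human-readable run report
#'
#' Formats the filter funnel, class summary, selected genes, cluster sizes
#' and cluster composition of a finished run as plain text.
#'
#' @param res result list from [runPipeline()].
#' @return character vector of report lines.
#' @export
summarizeRun <- function(res) {
  f <- as.data.frame(res$funnel)
  cs <- classificationSummary(res$classification)
  lab <- res$labels
  lines <- c(
    "== Single-cell qPCR CTC profiling run ==",
    sprintf("seed: %d", res$config$seed),
    "",
    "-- filter funnel (patient cells) --",
    utils::capture.output(print.data.frame(f, row.names = FALSE)),
    "",
    "-- classification --",
    sprintf("  %s: %d (%.1f%% of classified; %.1f%% of intact)",
            names(cs$counts), as.integer(cs$counts),
            100 * as.numeric(cs$frac_all),
            100 * as.numeric(cs$frac_intact[names(cs$counts)])),
    "",
    "-- gene selection --",
    sprintf("  excluded assays: %d (%s)",
            sum(res$panel$excluded),
            paste(res$panel$assay[res$panel$excluded], collapse = ", ")),
    sprintf("  detectable genes (>= %.0f%% of %d CTCs): %d",
            100 * res$config$min_frac, length(res$ctc_cells),
            length(res$detectable_genes)),
    "",
    "-- CTC clustering --",
    sprintf("  cluster %s: %d cells",
            as.character(utils::as.roman(sort(unique(lab)))),
            as.integer(table(lab))),
    "",
    "-- cluster composition --",
    utils::capture.output(print(res$composition))
  )
  if (!is.null(res$combined)) {
    tab <- table(res$combined$source, res$combined$labels)
    lines <- c(lines, "",
               "-- combined cell-line + CTC clustering (k = 2) --",
               utils::capture.output(print(tab)))
  }
  lines
}
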