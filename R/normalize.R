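# Balanced subsampling, reference-panel negative delta-Ct normalization
# with per-gene median centering, and detectability-based gene selection.

#' Cells with expressed calls for every reference assay
#'
#' @param calls an [ExpressionCalls-class].
#' @param reference_panel reference assay names.
#' @param cells candidate cells (default all).
#' @return cell ids whose every reference assay carries an expressed call.
#' @export
referenceComplete <- function(calls, reference_panel = referenceGenes(),
                              cells = NULL) {
  m <- callsMatrix(calls)
  miss <- setdiff(reference_panel, rownames(m))
  if (length(miss))
    stop("reference assay(s) not in calls: ", paste(miss, collapse = ", "))
  if (is.null(cells)) cells <- colnames(m)
  cells[colSums(!m[reference_panel, cells, drop = FALSE]) == 0]
}

#' Balanced subsampling of the analysis set
#'
#' To keep heavily sampled patients from dominating, at most
#' `max_per_patient` CTCs are drawn uniformly without replacement per
#' patient (patients at or under the cap contribute all their CTCs), and
#' exactly `per_cell_line` cells per cell line (an error names any line
#' with fewer eligible cells). Deterministic under `seed`; subjects are
#' visited in sorted order so the draw does not depend on input order.
#'
#' @param classification output of [classifyCells()]; only `CTC`-labeled
#'   cells are eligible on the patient side.
#' @param meta per-cell metadata (`cell_id`, `source`, `subject_id`).
#' @param line_cells eligible cell-line cells (typically reference-complete
#'   cells from [referenceComplete()]); `NULL` for a patient-only set.
#' @param max_per_patient cap per patient (default 5).
#' @param per_cell_line exact count per line (default 7).
#' @param seed integer seed for the random draws.
#' @return an `analysis_set` list with `cells`, the selection-rule echo and
#'   the seed.
#' @export
subsampleCells <- function(classification, meta, line_cells = NULL,
                           max_per_patient = 5, per_cell_line = 7,
                           seed = 1) {
  ctc <- classification$cell_id[classification$label == "CTC"]
  subj <- stats::setNames(meta$subject_id, meta$cell_id)
  picked <- withSeed(seed, {
    out <- character(0)
    by_pat <- split(ctc, subj[ctc])
    for (p in sort(names(by_pat))) {
      v <- by_pat[[p]]
      out <- c(out, if (length(v) <= max_per_patient) v
               else sort(sample(v, max_per_patient)))
    }
    if (!is.null(line_cells)) {
      by_line <- split(line_cells, subj[line_cells])
      for (ln in sort(names(by_line))) {
        v <- by_line[[ln]]
        if (length(v) < per_cell_line)
          stop("cell line '", ln, "' has only ", length(v),
               " eligible cells; ", per_cell_line, " required")
        out <- c(out, if (length(v) == per_cell_line) v
                 else sort(sample(v, per_cell_line)))
      }
    }
    out
  })
  structure(list(cells = picked,
                 rule = list(max_per_patient = max_per_patient,
                             per_cell_line = per_cell_line),
                 seed = seed),
            class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("Analysis set: %d cells (<= %d per patient, %d per cell line; seed %d)\n",
              length(x$cells), x$rule$max_per_patient, x$rule$per_cell_line,
              x$seed))
  invisible(x)
}

#' Reference-panel negative delta-Ct normalization with median centering
#'
#' Per cell, the mean Ct of the reference panel is computed; the normalized
#' expression of a gene is the negative of the difference between its raw
#' Ct and that reference mean (`-dCt`, higher = more expressed). Values
#' whose measurements were not called expressed are missing. Each gene is
#' then median-centered over its observed values (a gene observed nowhere
#' gets median 0 and stays all-missing). Reference assays are normalized
#' like any other and remain in the matrix.
#'
#' @param x the [CtExperiment-class] with raw Ct values.
#' @param calls an [ExpressionCalls-class] (exclusions masked).
#' @param cells the analysis set: an `analysis_set` from
#'   [subsampleCells()] or a character vector of cell ids. Every cell must
#'   carry expressed calls for the whole reference panel.
#' @param reference_panel assays averaged as the per-cell reference level;
#'   default the UBB/ACTB/GAPDH panel, `"UBB"` alone for cell-line-style
#'   analyses.
#' @param genes assays to normalize (default: all non-excluded assays).
#' @return a [NormalizedMatrix-class].
#' @export
#' @examples
#' # refs at Ct 18/20/22 -> reference mean 20; gene at Ct 24 -> -dCt = -4
normalizeExpression <- function(x, calls, cells,
                                reference_panel = referenceGenes(),
                                genes = NULL) {
  stopifnot(is(x, "CtExperiment"), is(calls, "ExpressionCalls"))
  if (inherits(cells, "analysis_set")) cells <- cells$cells
  m <- callsMatrix(calls)
  ct <- ctValues(x)
  miss <- setdiff(reference_panel, rownames(ct))
  if (length(miss))
    stop("reference assay(s) not in data: ", paste(miss, collapse = ", "))
  bad <- cells[colSums(!m[reference_panel, cells, drop = FALSE]) > 0]
  if (length(bad))
    stop("reference call missing for cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(genes)) genes <- setdiff(rownames(m), excludedAssays(calls))
  ref_mean <- colMeans(ct[reference_panel, cells, drop = FALSE])
  v <- -(ct[genes, cells, drop = FALSE] -
           rep(ref_mean, each = length(genes)))
  v[!m[genes, cells, drop = FALSE]] <- NA_real_
  med <- apply(v, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) stats::median(r) else 0
  })
  v <- v - med
  obs <- v[!is.na(v)]
  new("NormalizedMatrix", values = v, gene_medians = med,
      pooled_sd = if (length(obs) > 1L) stats::sd(obs) else 0,
      reference_panel = reference_panel)
}

#' Detectability-based gene selection
#'
#' Keeps genes consistently detectable in at least `min_frac` of the
#' analysis cells (expressed-call fraction, boundary inclusive).
#'
#' @param calls an [ExpressionCalls-class] (exclusions masked).
#' @param cells the CTC analysis cells (an `analysis_set` or ids).
#' @param min_frac minimum expressed fraction (default 0.15).
#' @return character vector of retained assay names.
#' @export
selectDetectableGenes <- function(calls, cells, min_frac = 0.15) {
  if (inherits(cells, "analysis_set")) cells <- cells$cells
  if (!length(cells)) stop("empty analysis set")
  m <- callsMatrix(calls, drop_excluded = TRUE)
  frac <- rowMeans(m[, cells, drop = FALSE])
  names(frac)[frac >= min_frac]
}
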