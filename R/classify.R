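# Rule-based classification of patient-derived cells.
#
# Stringent CTC definition: intact reference-gene RNA, at least one
# epithelial keratin expressed, and no CD45 expression. Keratin+/CD45+
# double positives are set aside as a class of their own rather than being
# counted as leukocytes.

.CLASS_LABELS <- c("CTC", "WBC", "AMBIGUOUS_KRT_CD45", "DEGRADED",
                   "NON_EPITHELIAL")

#' Classify patient-derived cells from expression calls
#'
#' Deterministic gate sequence per cell:
#' \enumerate{
#'   \item reference-integrity failure -> `DEGRADED`;
#'   \item CD45 expressed and >= 1 keratin expressed ->
#'     `AMBIGUOUS_KRT_CD45`;
#'   \item CD45 expressed -> `WBC`;
#'   \item >= 1 of KRT7/KRT8/KRT18/KRT19 expressed -> `CTC`;
#'   \item otherwise `NON_EPITHELIAL`.
#' }
#' Cell lines and no-template controls bypass classification. The
#' classifier is a pure function of the calls row and integrity flag; the
#' fired-rule trail is recorded per cell.
#'
#' @param calls an [ExpressionCalls-class] (post gene exclusion).
#' @param panel a [GenePanel-class]; must retain the keratin and CD45
#'   assays.
#' @param meta per-cell metadata with `cell_id` and `source`.
#' @param integrity_pass cell ids that passed [referenceIntegrityGate()].
#' @param cells patient cells to classify (default: all patient-source
#'   cells present in the calls).
#' @return data.frame with `cell_id`, `label`, `keratins` (which keratins
#'   were expressed), `cd45` (logical), and the gate `trail`.
#' @export
classifyCells <- function(calls, panel, meta, integrity_pass, cells = NULL) {
  stopifnot(is(calls, "ExpressionCalls"), is(panel, "GenePanel"))
  m <- callsMatrix(calls)
  keratins <- intersect(panel$assay[panel$epithelial & !panel$excluded],
                        rownames(m))
  cd45 <- intersect(panel$assay[panel$leukocyte & !panel$excluded],
                    rownames(m))
  if (!length(keratins))
    stop("configuration error: no epithelial keratin assay in panel")
  if (!length(cd45))
    stop("configuration error: no CD45/PTPRC assay in panel")
  patient_cells <- meta$cell_id[meta$source == "patient"]
  if (is.null(cells)) cells <- intersect(colnames(m), patient_cells)
  else if (!all(cells %in% patient_cells))
    stop("classification is defined for patient-derived cells only")
  res <- lapply(cells, function(cell) {
    krt <- keratins[m[keratins, cell]]
    cd <- any(m[cd45, cell])
    intact <- cell %in% integrity_pass
    trail <- sprintf("integrity=%s; CD45=%s; keratin=%s",
                     if (intact) "pass" else "fail",
                     if (cd) "expressed" else "absent",
                     if (length(krt)) paste(krt, collapse = ",") else "none")
    label <- if (!intact) "DEGRADED"
      else if (cd && length(krt)) "AMBIGUOUS_KRT_CD45"
      else if (cd) "WBC"
      else if (length(krt)) "CTC"
      else "NON_EPITHELIAL"
    data.frame(cell_id = cell, label = label,
               keratins = paste(krt, collapse = ","), cd45 = cd,
               trail = paste0(trail, " -> ", label),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(cell_id = character(0), label = character(0),
                      keratins = character(0), cd45 = logical(0),
                      trail = character(0))
  out$label <- factor(out$label, levels = .CLASS_LABELS)
  out
}

#' Class summary of a classification
#'
#' Fractions per label among integrity-passing cells and among all
#' classified cells.
#'
#' @param classification output of [classifyCells()].
#' @return list with `counts`, `frac_all` and `frac_intact` (label -> value).
#' @export
classificationSummary <- function(classification) {
  counts <- table(classification$label)
  intact <- classification$label != "DEGRADED"
  n_int <- sum(intact)
  frac_intact <- table(classification$label[intact]) / max(1, n_int)
  list(counts = counts,
       frac_all = counts / max(1, nrow(classification)),
       frac_intact = frac_intact,
       n_intact = n_int)
}
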