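# Measurement-, gene- and cell-level quality control.
#
# Measurement rule: a reading with quality score < 0.65 or Ct >= 35 is
# missing/immeasurable; otherwise the gene is called expressed. Gene rule:
# assays not run on every chip, or amplifying in any no-template control,
# are excluded panel-wide. Cell rules: at least 10 expressed genes, and
# intact reference-gene RNA (UBB Ct below 25 plus expressed ACTB and GAPDH).

#' Apply measurement-level QC to raw Ct readings
#'
#' A measurement is called expressed iff its Ct is present, below `ct_max`
#' (readings at or above 35 cycles are immeasurable) and its quality score
#' is at least `quality_min`. Absent quality scores count as passing (1.0).
#' Raw Ct values are left untouched on the experiment; non-expressed
#' entries are simply masked for all downstream use.
#'
#' @param x a [CtExperiment-class].
#' @param quality_min minimum quality score (default 0.65).
#' @param ct_max exclusive Ct ceiling in cycles (default 35).
#' @return an [ExpressionCalls-class].
#' @export
#' @examples
#' ct <- matrix(c(34.2, 35, 20, NA), 2, 2,
#'              dimnames = list(c("KRT19", "UBB"), c("a", "b")))
#' q <- matrix(c(0.8, 0.99, 0.64, NA), 2, 2, dimnames = dimnames(ct))
#' callsMatrix(applyMeasurementQC(CtExperiment(ct, q)))
applyMeasurementQC <- function(x, quality_min = 0.65, ct_max = 35) {
  stopifnot(is(x, "CtExperiment"), is.finite(quality_min), is.finite(ct_max),
            quality_min >= 0, quality_min <= 1)
  ct <- ctValues(x)
  q <- qualityScores(x)
  q[is.na(q)] <- 1
  calls <- !is.na(ct) & ct < ct_max & q >= quality_min & measuredMask(x)
  new("ExpressionCalls", calls = calls, excluded = character(0),
      quality_min = quality_min, ct_max = ct_max)
}

#' Chip-level gene exclusion
#'
#' Flags assays as excluded when (rule 1) any chip lacks every measurement
#' row for the assay (`not_on_all_chips`), or (rule 2) any no-template
#' control well carries an expressed call for it (`ntc_positive`,
#' amplification without input RNA on at least one chip). Rule 1 is checked
#' first and the first matching reason is stored; already-excluded assays
#' keep their annotation.
#'
#' @param panel a [GenePanel-class].
#' @param x the [CtExperiment-class] (for chip assignments and the
#'   measured mask).
#' @param calls [ExpressionCalls-class] from [applyMeasurementQC()]
#'   (rule 2 operates on post-QC calls).
#' @param ntc_cells cell ids of the no-template controls; if empty, rule 2
#'   is skipped with a warning.
#' @return the updated [GenePanel-class].
#' @export
excludeGenes <- function(panel, x, calls, ntc_cells = character(0)) {
  stopifnot(is(panel, "GenePanel"), is(x, "CtExperiment"),
            is(calls, "ExpressionCalls"))
  meas <- measuredMask(x)
  chip <- chipOf(x)
  excl <- panel$excluded
  reason <- panel$exclusion_reason
  for (a in intersect(panel$assay, rownames(meas))) {
    on_chip <- tapply(meas[a, ], chip, any)
    if (!all(on_chip) && !excl[panel$assay == a]) {
      excl[panel$assay == a] <- TRUE
      reason[panel$assay == a] <- "not_on_all_chips"
    }
  }
  if (!length(ntc_cells)) {
    warning("no NTC cells present; ntc_positive exclusion rule skipped")
  } else {
    cm <- callsMatrix(calls)
    miss <- setdiff(ntc_cells, colnames(cm))
    if (length(miss)) stop("unknown NTC cell(s): ", paste(miss, collapse = ", "))
    pos <- rowSums(cm[, ntc_cells, drop = FALSE]) > 0
    for (a in names(pos)[pos]) {
      i <- which(panel$assay == a)
      if (length(i) && !excl[i]) {
        excl[i] <- TRUE
        reason[i] <- "ntc_positive"
      }
    }
  }
  df <- as(panel, "DFrame")
  df$excluded <- excl
  df$exclusion_reason <- reason
  out <- new("GenePanel", df)
  validObject(out)
  out
}

#' Mask excluded assays in an ExpressionCalls
#'
#' Forces the calls of panel-excluded assays to `FALSE` and records them,
#' so downstream gene counts and detectability run over the retained panel
#' only while keeping the full matrix shape.
#'
#' @param calls an [ExpressionCalls-class].
#' @param panel a [GenePanel-class] with exclusion flags set.
#' @return an [ExpressionCalls-class].
#' @export
maskExcluded <- function(calls, panel) {
  stopifnot(is(calls, "ExpressionCalls"), is(panel, "GenePanel"))
  m <- callsMatrix(calls)
  excl <- intersect(panel$assay[panel$excluded], rownames(m))
  m[excl, ] <- FALSE
  new("ExpressionCalls", calls = m,
      excluded = union(calls@excluded, excl),
      quality_min = calls@quality_min, ct_max = calls@ct_max)
}

#' Minimum expressed-gene screen
#'
#' Cells must express at least `min_genes` genes (counted over the
#' retained, post-exclusion panel) to remain in the analysis.
#'
#' @param calls an [ExpressionCalls-class], exclusions already masked.
#' @param min_genes minimum expressed-call count (default 10).
#' @param cells cells to screen (default all).
#' @return character vector of retained cell ids, in input order.
#' @export
filterCellsMinGenes <- function(calls, min_genes = 10, cells = NULL) {
  m <- callsMatrix(calls)
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  colnames(m)[colSums(m) >= min_genes]
}

#' Reference-gene RNA-integrity gate
#'
#' A cell is retained iff UBB is expressed with Ct strictly below
#' `ubb_max_ct` (strong UBB expression marks non-degraded RNA; a cell at
#' exactly the threshold is excluded) and both ACTB and GAPDH carry
#' expressed calls. Cells failing the gate are treated as RNA-degraded.
#'
#' @param x the [CtExperiment-class] with raw Ct values.
#' @param calls an [ExpressionCalls-class].
#' @param ubb_max_ct exclusive UBB Ct ceiling (default 25 cycles).
#' @param cells cells to gate (default all).
#' @return character vector of retained cell ids.
#' @export
referenceIntegrityGate <- function(x, calls, ubb_max_ct = 25, cells = NULL) {
  stopifnot(is(x, "CtExperiment"), is(calls, "ExpressionCalls"))
  need <- c("UBB", "ACTB", "GAPDH")
  miss <- setdiff(need, rownames(callsMatrix(calls)))
  if (length(miss))
    stop("configuration error: reference assay(s) missing from data: ",
         paste(miss, collapse = ", "))
  if (any(need %in% excludedAssays(calls)))
    stop("configuration error: reference assay excluded by gene-level QC; ",
         "the pipeline cannot proceed")
  m <- callsMatrix(calls)
  ct <- ctValues(x)
  if (is.null(cells)) cells <- colnames(m)
  ok <- m["UBB", cells] & !is.na(ct["UBB", cells]) &
    ct["UBB", cells] < ubb_max_ct & m["ACTB", cells] & m["GAPDH", cells]
  cells[ok]
}

#' Filter-funnel report
#'
#' Chains the cell-removal stages of the pipeline into an auditable funnel:
#' per stage the input count, removals by reason, output count, and
#' percentages relative to both the stage input and the initial capture.
#'
#' @param initial_cells cell ids entering the funnel.
#' @param stages ordered list; each element is
#'   `list(name =, removed = list(<reason> = <cell ids>))`.
#' @return a `funnel_report`: data.frame of chained counts with the
#'   removed-cell ids by stage and reason attached as attribute `removals`.
#' @export
funnelReport <- function(initial_cells, stages) {
  n0 <- length(initial_cells)
  current <- initial_cells
  rows <- list(); removals <- list()
  for (st in stages) {
    rem <- st$removed
    rem <- lapply(rem, intersect, x = current)
    gone <- unique(unlist(rem, use.names = FALSE))
    if (!all(gone %in% current))
      stop("funnel stage '", st$name, "' removes cells not in its input")
    out <- setdiff(current, gone)
    rows[[st$name]] <- data.frame(
      stage = st$name,
      n_in = length(current),
      n_removed = length(gone),
      n_out = length(out),
      pct_of_input = roundHalfUp(100 * length(out) / max(1, length(current)), 1),
      pct_of_initial = roundHalfUp(100 * length(out) / max(1, n0), 1),
      reasons = paste(sprintf("%s=%d", names(rem), lengths(rem)),
                      collapse = "; "),
      stringsAsFactors = FALSE
    )
    removals[[st$name]] <- rem
    current <- out
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(df, class = c("funnel_report", "data.frame"),
            removals = removals, initial = initial_cells, final = current)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Filter funnel:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Cells surviving a funnel
#'
#' @param funnel a `funnel_report`.
#' @return character vector of cells left after the last stage.
#' @export
funnelSurvivors <- function(funnel) attr(funnel, "final")
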