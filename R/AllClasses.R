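#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

## marker definitions used throughout the pipeline ---------------------------

#' Marker gene sets
#'
#' The fixed marker roles of the profiling panel: reference (housekeeping)
#' genes used for RNA-integrity gating and negative delta-Ct normalization,
#' epithelial keratins used as positive CTC markers, and the leukocyte-common
#' antigen CD45 (gene symbol PTPRC) whose expression marks a captured cell as
#' a white blood cell.
#'
#' @name markerGenes
#' @aliases referenceGenes epithelialKeratins leukocyteMarkers
NULL

#' @rdname markerGenes
#' @export
referenceGenes <- function() c("UBB", "ACTB", "GAPDH")

#' @rdname markerGenes
#' @export
epithelialKeratins <- function() c("KRT7", "KRT8", "KRT18", "KRT19")

#' @rdname markerGenes
#' @export
leukocyteMarkers <- function() c("PTPRC", "CD45")

.EXCLUSION_REASONS <- c("none", "not_on_all_chips", "ntc_positive")
.PANEL_CATEGORIES <- c("reference", "epithelial", "leukocyte", "cancer_associated")

## GenePanel ------------------------------------------------------------------

#' GenePanel: assay catalogue with marker roles and exclusion annotations
#'
#' A `DataFrame` subclass with one row per assay and columns `assay`,
#' `category` (reference / epithelial / leukocyte / cancer_associated),
#' logical marker flags `reference`, `epithelial`, `leukocyte`, and the
#' exclusion audit trail `excluded` / `exclusion_reason`. Excluded assays are
#' kept in the panel so the reason for their removal is preserved.
#'
#' @export
setClass("GenePanel", contains = "DFrame")

setValidity("GenePanel", function(object) {
  need <- c("assay", "category", "reference", "epithelial", "leukocyte",
            "excluded", "exclusion_reason")
  miss <- setdiff(need, colnames(object))
  if (length(miss)) return(paste("missing panel column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(object$assay)) return("duplicated assay names")
  if (!all(object$category %in% .PANEL_CATEGORIES))
    return("invalid category value")
  if (!all(object$exclusion_reason %in% .EXCLUSION_REASONS))
    return("invalid exclusion_reason value")
  if (!identical(object$reference, object$assay %in% referenceGenes()))
    return("reference flag must be TRUE exactly for UBB, ACTB, GAPDH")
  if (!identical(object$epithelial, object$assay %in% epithelialKeratins()))
    return("epithelial flag must be TRUE exactly for KRT7, KRT8, KRT18, KRT19")
  if (!identical(object$leukocyte, object$assay %in% leukocyteMarkers()))
    return("leukocyte flag must be TRUE exactly for CD45/PTPRC")
  if (!any(object$reference)) return("panel must contain at least one reference assay")
  if (any(object$excluded & object$exclusion_reason == "none"))
    return("excluded assays must carry an exclusion reason")
  TRUE
})

#' Construct a GenePanel
#'
#' Marker roles are derived from the assay names themselves (UBB/ACTB/GAPDH
#' are reference genes, KRT7/8/18/19 the epithelial keratins, PTPRC/CD45 the
#' leukocyte marker); every other assay is `cancer_associated`.
#'
#' @param assays character vector of unique assay (gene) names.
#' @return a [GenePanel-class] with no assays excluded.
#' @export
#' @examples
#' genePanel(c("UBB", "ACTB", "GAPDH", "KRT19", "PTPRC", "VIM"))
genePanel <- function(assays) {
  assays <- as.character(assays)
  if (anyDuplicated(assays)) stop("duplicated assay names in panel")
  category <- rep("cancer_associated", length(assays))
  category[assays %in% referenceGenes()] <- "reference"
  category[assays %in% epithelialKeratins()] <- "epithelial"
  category[assays %in% leukocyteMarkers()] <- "leukocyte"
  new("GenePanel", DataFrame(
    assay = assays,
    category = category,
    reference = assays %in% referenceGenes(),
    epithelial = assays %in% epithelialKeratins(),
    leukocyte = assays %in% leukocyteMarkers(),
    excluded = logical(length(assays)),
    exclusion_reason = rep("none", length(assays)),
    row.names = assays
  ))
}

#' Assays retained by a panel
#'
#' @param panel a [GenePanel-class].
#' @return character vector of assay names not flagged as excluded.
#' @export
retainedAssays <- function(panel) {
  stopifnot(is(panel, "GenePanel"))
  panel$assay[!panel$excluded]
}

## CtExperiment ---------------------------------------------------------------

#' CtExperiment: raw chip Ct values with quality scores
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the raw
#' dynamic-array readout: assays (genes) in rows, cells in columns, with
#' matrices
#' \describe{
#'   \item{`ct`}{PCR cycle-threshold values in cycles; `NA` = no amplification
#'     detected (absent).}
#'   \item{`quality`}{per-measurement quality scores in `[0, 1]`; `NA` for a
#'     present Ct is treated as 1 (pass) downstream.}
#'   \item{`measured`}{logical; `FALSE` where an assay was never run for that
#'     cell's chip (no export row), as opposed to a failed reaction.}
#' }
#' `colData` carries at least the `chip` assignment and, when supplied, the
#' per-cell metadata (`source`, `subject_id`, `sample_id`, `stage`,
#' `er_status`, `pr_status`, `her2_status`, `age`).
#'
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment")

setValidity("CtExperiment", function(object) {
  an <- names(assays(object))
  if (!all(c("ct", "quality", "measured") %in% an))
    return("assays must include 'ct', 'quality' and 'measured'")
  ct <- assay(object, "ct"); q <- assay(object, "quality")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("assay and cell names are required")
  if (anyDuplicated(rownames(object))) return("duplicated assay ids")
  if (anyDuplicated(colnames(object))) return("duplicated cell ids")
  if (any(ct < 0, na.rm = TRUE)) return("Ct values must be non-negative")
  if (any(q < 0 | q > 1, na.rm = TRUE)) return("quality scores must lie in [0, 1]")
  if (!"chip" %in% colnames(colData(object))) return("colData must contain 'chip'")
  TRUE
})

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of Ct values (assays x cells) with dimnames;
#'   `NA` marks absent (no-amplification) measurements.
#' @param quality matrix of quality scores in `[0, 1]`, same shape as `ct`.
#'   Default: 1 wherever a Ct is present (quality-free exports stay usable;
#'   QC then reduces to the Ct cutoff alone).
#' @param measured logical matrix marking which (assay, cell) reactions were
#'   physically present on the chip. Default: all `TRUE`.
#' @param chip chip identifier per cell (scalar recycled, or named/ordered
#'   vector over cells).
#' @param meta optional per-cell metadata `data.frame` with a `cell_id`
#'   column (see [readCellMeta()]); merged into `colData`.
#' @return a [CtExperiment-class].
#' @export
CtExperiment <- function(ct, quality = NULL, measured = NULL, chip = "chip1",
                         meta = NULL) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("ct matrix must have assay rownames and cell colnames")
  if (is.null(quality)) {
    quality <- matrix(ifelse(is.na(ct), NA_real_, 1), nrow(ct), ncol(ct),
                      dimnames = dimnames(ct))
  }
  quality <- as.matrix(quality)
  if (is.null(measured)) {
    measured <- matrix(TRUE, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  }
  measured <- as.matrix(measured)
  if (!identical(dim(ct), dim(quality)) || !identical(dim(ct), dim(measured)))
    stop("ct, quality and measured must have identical dimensions")
  if (length(chip) == 1L) chip <- rep(chip, ncol(ct))
  if (!is.null(names(chip))) chip <- chip[colnames(ct)]
  cd <- DataFrame(chip = as.character(chip), row.names = colnames(ct))
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!"cell_id" %in% colnames(meta)) stop("meta must contain a 'cell_id' column")
    idx <- match(colnames(ct), meta$cell_id)
    if (anyNA(idx))
      stop("meta is missing cells: ", paste(colnames(ct)[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
    add <- meta[idx, setdiff(colnames(meta), "cell_id"), drop = FALSE]
    rownames(add) <- colnames(ct)
    cd <- cbind(cd, DataFrame(add))
  }
  new("CtExperiment", SummarizedExperiment(
    assays = list(ct = ct, quality = quality, measured = measured),
    colData = cd
  ))
}

#' Accessors for CtExperiment
#'
#' `ctValues()`, `qualityScores()` and `measuredMask()` return the raw
#' matrices (assays x cells); `chipOf()` the named chip assignment per cell;
#' `cellIds()`/`assayIds()` the dimension names; `cellMeta()` the `colData`
#' as a plain `data.frame` with a `cell_id` column.
#'
#' @param x a [CtExperiment-class].
#' @name ct-accessors
NULL

#' @rdname ct-accessors
#' @export
ctValues <- function(x) assay(x, "ct")

#' @rdname ct-accessors
#' @export
qualityScores <- function(x) assay(x, "quality")

#' @rdname ct-accessors
#' @export
measuredMask <- function(x) assay(x, "measured")

#' @rdname ct-accessors
#' @export
chipOf <- function(x) stats::setNames(colData(x)$chip, colnames(x))

#' @rdname ct-accessors
#' @export
cellIds <- function(x) colnames(x)

#' @rdname ct-accessors
#' @export
assayIds <- function(x) rownames(x)

#' @rdname ct-accessors
#' @export
cellMeta <- function(x) {
  df <- as.data.frame(colData(x))
  cbind(cell_id = rownames(df), df, row.names = NULL)
}

setMethod("show", "CtExperiment", function(object) {
  cat(sprintf("CtExperiment: %d assays x %d cells on %d chip(s)\n",
              nrow(object), ncol(object), length(unique(colData(object)$chip))))
  ct <- assay(object, "ct")
  cat(sprintf("  absent Ct entries: %d/%d (%.1f%%)\n",
              sum(is.na(ct)), length(ct), 100 * mean(is.na(ct))))
  callNextMethod()
})

## ExpressionCalls ------------------------------------------------------------

#' ExpressionCalls: expressed / not-expressed matrix after measurement QC
#'
#' Boolean matrix (assays x cells) where `TRUE` means the gene is called
#' expressed: Ct present, Ct below the cutoff, and quality at or above the
#' minimum. Rows of assays excluded by chip-level gene exclusion are forced
#' `FALSE` and tracked in `excluded` so "not expressed" and "assay excluded"
#' stay distinguishable. The thresholds used are stored alongside.
#'
#' @slot calls logical matrix of expression calls.
#' @slot excluded character vector of excluded assay names.
#' @slot quality_min,ct_max thresholds used to make the calls.
#' @export
setClass("ExpressionCalls", representation(
  calls = "matrix", excluded = "character",
  quality_min = "numeric", ct_max = "numeric"
))

setValidity("ExpressionCalls", function(object) {
  m <- object@calls
  if (!is.logical(m)) return("calls must be a logical matrix")
  if (anyNA(m)) return("calls must not contain NA")
  if (is.null(rownames(m)) || is.null(colnames(m))) return("calls must have dimnames")
  if (!all(object@excluded %in% rownames(m))) return("excluded assays not in calls")
  if (length(object@excluded) && any(m[object@excluded, , drop = FALSE]))
    return("excluded assays must carry no expressed calls")
  if (object@quality_min < 0 || object@quality_min > 1)
    return("quality_min must lie in [0, 1]")
  TRUE
})

#' Expression call matrix
#'
#' @param x an [ExpressionCalls-class].
#' @param drop_excluded drop rows of excluded assays (default keeps them,
#'   forced to `FALSE`).
#' @return logical matrix (assays x cells).
#' @export
callsMatrix <- function(x, drop_excluded = FALSE) {
  m <- x@calls
  if (drop_excluded && length(x@excluded))
    m <- m[setdiff(rownames(m), x@excluded), , drop = FALSE]
  m
}

#' @rdname callsMatrix
#' @export
excludedAssays <- function(x) x@excluded

setMethod("show", "ExpressionCalls", function(object) {
  m <- object@calls
  cat(sprintf("ExpressionCalls: %d assays x %d cells (quality >= %.2f, Ct < %g)\n",
              nrow(m), ncol(m), object@quality_min, object@ct_max))
  cat(sprintf("  expressed calls: %d (%.1f%%); excluded assays: %d\n",
              sum(m), 100 * mean(m), length(object@excluded)))
})

## NormalizedMatrix -----------------------------------------------------------

#' NormalizedMatrix: median-centered negative delta-Ct values
#'
#' Assays x cells matrix of normalized expression, where
#' `value = -(Ct_gene - mean Ct of the reference panel)` per cell, then
#' median-centered per gene over observed values. Higher = more expressed,
#' on a log2-like scale; `NA` marks measurements not called expressed.
#'
#' @slot values numeric matrix (assays x cells) with `NA` for missing.
#' @slot gene_medians per-gene medians subtracted during centering.
#' @slot pooled_sd SD of all observed centered values pooled across genes.
#' @slot reference_panel the reference assays averaged per cell.
#' @export
setClass("NormalizedMatrix", representation(
  values = "matrix", gene_medians = "numeric",
  pooled_sd = "numeric", reference_panel = "character"
))

setValidity("NormalizedMatrix", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    return("values must have dimnames")
  if (length(object@gene_medians) != nrow(object@values))
    return("one median per gene required")
  if (length(object@reference_panel) < 1L) return("reference panel is empty")
  TRUE
})

#' @rdname normalizeExpression
#' @param x a [NormalizedMatrix-class].
#' @export
normalizedValues <- function(x) x@values

#' @rdname normalizeExpression
#' @export
pooledSD <- function(x) x@pooled_sd

#' @rdname normalizeExpression
#' @export
geneMedians <- function(x) x@gene_medians

#' Subset a NormalizedMatrix to a gene set
#'
#' Keeps the stored per-gene medians and recomputes the pooled SD over the
#' observed values of the retained genes (so downstream imputation uses the
#' spread of the matrix actually clustered).
#'
#' @param x a [NormalizedMatrix-class].
#' @param genes assay names to keep.
#' @export
subsetGenes <- function(x, genes) {
  stopifnot(is(x, "NormalizedMatrix"))
  miss <- setdiff(genes, rownames(x@values))
  if (length(miss)) stop("genes not in matrix: ", paste(miss, collapse = ", "))
  v <- x@values[genes, , drop = FALSE]
  new("NormalizedMatrix", values = v,
      gene_medians = x@gene_medians[genes],
      pooled_sd = stats::sd(v[!is.na(v)]),
      reference_panel = x@reference_panel)
}

setMethod("show", "NormalizedMatrix", function(object) {
  v <- object@values
  cat(sprintf("NormalizedMatrix: %d genes x %d cells (-dCt vs %s, median-centered)\n",
              nrow(v), ncol(v), paste(object@reference_panel, collapse = "/")))
  cat(sprintf("  missing: %.1f%%; pooled SD of observed values: %.3f\n",
              100 * mean(is.na(v)), object@pooled_sd))
})

## ClusterResult --------------------------------------------------------------

#' ClusterResult: agglomerative clustering of cells
#'
#' Wraps the merge tree from hierarchical clustering together with the
#' matrix that was clustered and the distance/linkage used.
#'
#' @slot tree an object of S3 class `hclust` (n-1 merges with heights).
#' @slot data the cells x genes matrix clustered (imputed, no missing values).
#' @slot metric,linkage distance metric and linkage method names.
#' @export
setClass("ClusterResult", representation(
  tree = "ANY", data = "matrix", metric = "character", linkage = "character"
))

setValidity("ClusterResult", function(object) {
  if (!inherits(object@tree, "hclust")) return("tree must be an hclust object")
  if (anyNA(object@data)) return("clustered matrix must not contain missing values")
  if (length(object@tree$order) != nrow(object@data))
    return("tree size does not match matrix rows")
  TRUE
})

#' @rdname hclusterCells
#' @param x a [ClusterResult-class].
#' @export
clusterTree <- function(x) x@tree

#' @rdname hclusterCells
#' @export
leafOrder <- function(x) x@tree$labels[x@tree$order]

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d cells, %s distance, %s linkage\n",
              nrow(object@data), object@metric, object@linkage))
  cat(sprintf("  merge heights: %.3g .. %.3g\n",
              min(object@tree$height), max(object@tree$height)))
})
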