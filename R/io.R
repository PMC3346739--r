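# Reading and writing chip exports, panels, metadata and matrices.
# The BioMark-style export schema is not standardized across sites, so the
# column names and no-amplification sentinels are configurable via a dialect.

#' Chip-export dialect
#'
#' Describes the long-format chip export: which columns hold the chip, cell,
#' assay, Ct and quality fields, which Ct strings mean "no amplification"
#' (mapped to absent), and the field separator. The default mimics a
#' long-format dynamic-array export with columns Chip, Sample, Assay, Ct,
#' Quality and sentinels `"999"`, `"No Call"` and the empty string.
#'
#' @param chip,cell,assay,ct,quality column names in the export.
#' @param replicate optional column with a technical-replicate index
#'   (triplicate-assay mode); when present, cell ids become
#'   `<cell>_r<replicate>`.
#' @param absent_values Ct strings mapped to absent measurements.
#' @param sep field separator.
#' @param quality_optional if `TRUE`, a missing quality column yields
#'   quality 1.0 for every present Ct (the table remains usable and QC
#'   reduces to the Ct cutoff).
#' @return a `ct_dialect` list.
#' @export
ctDialect <- function(chip = "Chip", cell = "Sample", assay = "Assay",
                      ct = "Ct", quality = "Quality", replicate = NULL,
                      absent_values = c("999", "No Call", ""), sep = "\t",
                      quality_optional = TRUE) {
  structure(list(chip = chip, cell = cell, assay = assay, ct = ct,
                 quality = quality, replicate = replicate,
                 absent_values = absent_values, sep = sep,
                 quality_optional = quality_optional),
            class = "ct_dialect")
}

#' Read a long-format chip export into a CtExperiment
#'
#' One input row per (cell, assay) reaction. Ct fields matching the
#' dialect's sentinels become absent (`NA`) but the reaction is still
#' recorded as measured; reactions with no row at all are marked
#' not-measured (feeding the not-on-all-chips gene-exclusion rule).
#' Cell and assay order follow first appearance in the file.
#'
#' @param path path to the delimited export.
#' @param dialect a [ctDialect()].
#' @return a [CtExperiment-class].
#' @export
readCtTable <- function(path, dialect = ctDialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", na.strings = NULL)
  need <- c(dialect$chip, dialect$cell, dialect$assay, dialect$ct)
  if (!dialect$quality_optional) need <- c(need, dialect$quality)
  for (col in need) {
    if (!col %in% colnames(df))
      stop(sprintf("format error: missing required column '%s'", col))
  }
  cells <- df[[dialect$cell]]
  if (!is.null(dialect$replicate) && dialect$replicate %in% colnames(df))
    cells <- paste0(cells, "_r", df[[dialect$replicate]])
  assays <- df[[dialect$assay]]
  key <- paste(cells, assays, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("integrity error: duplicate (cell, assay) row for '%s'",
                 sub("\r", ", ", dup, fixed = TRUE)))
  }
  ct_raw <- trimws(df[[dialect$ct]])
  ct <- ifelse(ct_raw %in% dialect$absent_values, NA_real_,
               suppressWarnings(as.numeric(ct_raw)))
  bad <- !(ct_raw %in% dialect$absent_values) & is.na(ct)
  if (any(bad))
    stop(sprintf("format error: unparseable Ct value '%s'", ct_raw[bad][1L]))
  if (dialect$quality %in% colnames(df)) {
    q_raw <- trimws(df[[dialect$quality]])
    q <- ifelse(q_raw %in% c("", "NA"), NA_real_,
                suppressWarnings(as.numeric(q_raw)))
    if (any(q < 0 | q > 1, na.rm = TRUE))
      stop("range error: quality score outside [0, 1]")
  } else {
    q <- ifelse(is.na(ct), NA_real_, 1)
  }
  cell_ids <- unique(cells)
  assay_ids <- unique(assays)
  mk <- function(fill) matrix(fill, length(assay_ids), length(cell_ids),
                              dimnames = list(assay_ids, cell_ids))
  ct_m <- mk(NA_real_); q_m <- mk(NA_real_); meas <- mk(FALSE)
  i <- cbind(match(assays, assay_ids), match(cells, cell_ids))
  ct_m[i] <- ct; q_m[i] <- q; meas[i] <- TRUE
  chip_by_cell <- tapply(df[[dialect$chip]], cells, function(v) unique(v))
  if (any(lengths(chip_by_cell) != 1L))
    stop("integrity error: a cell is assigned to more than one chip")
  CtExperiment(ct_m, q_m, meas, chip = unlist(chip_by_cell)[cell_ids])
}

#' Write a CtExperiment as a long-format chip export
#'
#' Inverse of [readCtTable()]: one row per measured reaction; absent Ct
#' values are written with the dialect's first sentinel. Reading the file
#' back reproduces the object's matrices exactly.
#'
#' @param x a [CtExperiment-class].
#' @param path output path.
#' @param dialect a [ctDialect()].
#' @export
writeCtTable <- function(x, path, dialect = ctDialect()) {
  ct <- ctValues(x); q <- qualityScores(x); meas <- measuredMask(x)
  chip <- chipOf(x)
  idx <- which(meas, arr.ind = TRUE)
  # preserve file order = column-major by cell, assay within cell
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  cells <- colnames(ct)[idx[, 2L]]
  rows <- data.frame(
    chip = chip[cells],
    cell = cells,
    assay = rownames(ct)[idx[, 1L]],
    ct = ifelse(is.na(ct[idx]), dialect$absent_values[1L], fmtNum(ct[idx])),
    quality = fmtNum(q[idx]),
    stringsAsFactors = FALSE
  )
  colnames(rows) <- c(dialect$chip, dialect$cell, dialect$assay,
                      dialect$ct, dialect$quality)
  utils::write.table(rows, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a named matrix as delimited text
#'
#' `writeMatrix()` writes any matrix with row and column names as
#' tab-separated text, one row per line, `NA` for missing values, and full
#' `%.17g` precision so that `readMatrix(writeMatrix(m)) == m` bit for bit.
#' Non-finite values other than `NA` are refused.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @return `readMatrix()` returns the numeric matrix.
#' @export
writeMatrix <- function(m, path) {
  m <- as.matrix(m)
  if ((nrow(m) > 0L && is.null(rownames(m))) || is.null(colnames(m)))
    stop("matrix must have row and column names")
  if (any(!is.na(m) & !is.finite(m)))
    stop("matrix contains non-finite values")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  if (nrow(m)) {
    body <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], fmtNum(m[i, ])), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname writeMatrix
#' @export
readMatrix <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  if (length(lines) == 1L)
    return(matrix(numeric(0), 0L, length(header),
                  dimnames = list(character(0), header)))
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, na.strings = "NA")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}

#' Read / write a gene panel (JSON or YAML)
#'
#' The file holds a list of records with fields `assay` and optionally
#' `excluded` / `exclusion_reason`; marker roles are re-derived from the
#' assay names (see [genePanel()]).
#'
#' @param path file path; format chosen by extension (`.json` / `.yaml` /
#'   `.yml`).
#' @param panel a [GenePanel-class].
#' @export
readGenePanel <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  }
  p <- genePanel(recs$assay)
  if (!is.null(recs$excluded)) {
    df <- as(p, "DFrame")
    df$excluded <- as.logical(recs$excluded)
    df$exclusion_reason <- as.character(recs$exclusion_reason)
    p <- new("GenePanel", df)
  }
  validObject(p)
  p
}

#' @rdname readGenePanel
#' @export
writeGenePanel <- function(panel, path) {
  stopifnot(is(panel, "GenePanel"))
  df <- as.data.frame(panel)[, c("assay", "category", "excluded", "exclusion_reason")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(lapply(seq_len(nrow(df)), function(i) as.list(df[i, ])), path)
  }
  invisible(path)
}

#' Read / write per-cell metadata
#'
#' Tab-separated table with columns `cell_id`, `source` (patient /
#' cell_line / ntc), `subject_id`, `sample_id`, `stage`, `er_status`,
#' `pr_status`, `her2_status`, `age`.
#'
#' @param path file path.
#' @param meta metadata `data.frame`.
#' @export
readCellMeta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"cell_id" %in% colnames(df)) stop("format error: missing required column 'cell_id'")
  df
}

#' @rdname readCellMeta
#' @export
writeCellMeta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-file consistency report
#'
#' Checks a Ct experiment against a gene panel and cell metadata: assays in
#' the data but absent from the panel and cells without metadata are fatal;
#' assays missing from some chip (candidates for the not-on-all-chips
#' exclusion rule) are reported informationally.
#'
#' @param x a [CtExperiment-class].
#' @param panel a [GenePanel-class].
#' @param meta per-cell metadata `data.frame` with `cell_id`; default uses
#'   the metadata already in `colData(x)`.
#' @return a `validation_report` list with `ok` (no fatal issue) and a
#'   data.frame of `issues`.
#' @export
validateDataset <- function(x, panel, meta = NULL) {
  if (is.null(meta)) meta <- cellMeta(x)
  issues <- data.frame(type = character(0), item = character(0),
                       fatal = logical(0), stringsAsFactors = FALSE)
  add <- function(type, items, fatal) {
    if (length(items))
      rbind(issues, data.frame(type = type, item = items, fatal = fatal))
    else issues
  }
  issues <- add("assay_not_in_panel", setdiff(assayIds(x), panel$assay), TRUE)
  issues <- add("cell_without_meta", setdiff(cellIds(x), meta$cell_id), TRUE)
  meas <- measuredMask(x)
  chip <- chipOf(x)
  incomplete <- character(0)
  for (a in assayIds(x)) {
    on_chip <- tapply(meas[a, ], chip, any)
    if (!all(on_chip))
      incomplete <- c(incomplete,
                      sprintf("%s (missing on %s)", a,
                              paste(names(on_chip)[!on_chip], collapse = ",")))
  }
  issues <- add("assay_incomplete_across_chips", incomplete, FALSE)
  structure(list(ok = !any(issues$fatal), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Dataset validation: %s\n", if (x$ok) "OK" else "FATAL ISSUES"))
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s: %s\n",
                  if (x$issues$fatal[i]) "fatal" else "info",
                  x$issues$type[i], x$issues$item[i]))
  } else cat("  no issues\n")
  invisible(x)
}
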