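# balanced subsampling, -dCt normalization, detectability selection

# two-cell experiment over refs + two genes with all calls expressed
normFixture <- function() {
  assays <- c("UBB", "ACTB", "GAPDH", "VIM", "CD44")
  ct <- matrix(c(18, 20, 22, 24, 20,      # cellA: ref mean 20
                 17, 19, 21, 25, 19),     # cellB: ref mean 19
               ncol = 2, dimnames = list(assays, c("cellA", "cellB")))
  tinyExperiment(ct)
}

test_that("negative delta-Ct and median centering follow the definition", {
  x <- normFixture()
  calls <- applyMeasurementQC(x)
  norm <- normalizeExpression(x, calls, c("cellA", "cellB"))
  v <- normalizedValues(norm)
  med <- geneMedians(norm)
  # pre-centering -dCt: refs (18,20,22) mean 20, VIM Ct 24 -> -4
  expect_equal((v + med)["VIM", "cellA"], -4)
  expect_equal((v + med)["VIM", "cellB"], -6)
  # gene Ct equal to the reference mean -> -dCt of 0 pre-centering
  expect_equal((v + med)["CD44", "cellA"], 0)
  # per-gene observed median is zero after centering
  expect_true(all(abs(apply(v, 1, stats::median, na.rm = TRUE)) < 1e-9))
  # reference assays stay in the matrix, normalized like any other gene
  expect_true(all(c("UBB", "ACTB", "GAPDH") %in% rownames(v)))
})

test_that("per-cell additive Ct shifts cancel out exactly", {
  x <- normFixture()
  calls <- applyMeasurementQC(x)
  base <- normalizedValues(normalizeExpression(x, calls, cellIds(x)))
  ct2 <- ctValues(x)
  ct2[, "cellA"] <- ct2[, "cellA"] + 3.7
  x2 <- tinyExperiment(ct2)
  shifted <- normalizedValues(normalizeExpression(x2, applyMeasurementQC(x2),
                                                  cellIds(x2)))
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("a single-gene reference panel reproduces the cell-line mode", {
  x <- normFixture()
  calls <- applyMeasurementQC(x)
  norm <- normalizeExpression(x, calls, cellIds(x), reference_panel = "UBB")
  v <- normalizedValues(norm) + geneMedians(norm)
  expect_equal(v["VIM", "cellA"], -(24 - 18))
  expect_identical(norm@reference_panel, "UBB")
})

test_that("a missing reference call is an error naming the cell", {
  x <- normFixture()
  m <- callsMatrix(applyMeasurementQC(x))
  m["GAPDH", "cellB"] <- FALSE
  expect_error(normalizeExpression(x, callsFrom(m), cellIds(x)),
               "reference call missing for cell\\(s\\): cellB")
})

test_that("non-expressed entries are missing and all-missing genes get median 0", {
  x <- normFixture()
  m <- callsMatrix(applyMeasurementQC(x))
  m["VIM", ] <- FALSE
  norm <- normalizeExpression(x, callsFrom(m), cellIds(x))
  expect_true(all(is.na(normalizedValues(norm)["VIM", ])))
  expect_identical(unname(geneMedians(norm)["VIM"]), 0)
})

test_that("subsampling caps patients, draws exact line counts, and is reproducible", {
  cells <- c(sprintf("p1_%02d", 1:12), sprintf("p2_%02d", 1:3))
  lv <- c("CTC", "WBC", "AMBIGUOUS_KRT_CD45", "DEGRADED", "NON_EPITHELIAL")
  cls <- data.frame(cell_id = cells, label = factor("CTC", levels = lv))
  line_cells <- sprintf("L%d_%02d", rep(1:7, each = 9), 1:9)
  meta <- data.frame(
    cell_id = c(cells, line_cells),
    source = c(rep("patient", 15), rep("cell_line", 63)),
    subject_id = c(rep("P1", 12), rep("P2", 3),
                   sprintf("L%d", rep(1:7, each = 9))))
  a <- subsampleCells(cls, meta, line_cells, seed = 7)
  b <- subsampleCells(cls, meta, line_cells, seed = 7)
  expect_identical(a$cells, b$cells)
  expect_identical(sum(grepl("^p1", a$cells)), 5L)  # 12 CTCs capped at 5
  expect_identical(sum(grepl("^p2", a$cells)), 3L)  # under the cap: all kept
  expect_identical(sum(grepl("^L", a$cells)), 49L)  # 7 lines x 7 cells
  # a different seed draws a different subset of the capped patient
  c2 <- subsampleCells(cls, meta, line_cells, seed = 8)
  expect_false(identical(sort(a$cells), sort(c2$cells)))
  # a line below the required count is an error naming the line
  short <- meta[!(meta$subject_id == "L3" & grepl("_0[5-9]$", meta$cell_id)), ]
  expect_error(subsampleCells(cls, short,
                              line_cells[line_cells %in% short$cell_id],
                              seed = 7),
               "cell line 'L3'")
})

test_that("subsampling a set already at the caps returns it unchanged", {
  cells <- sprintf("p1_%02d", 1:5)
  lv <- c("CTC", "WBC", "AMBIGUOUS_KRT_CD45", "DEGRADED", "NON_EPITHELIAL")
  cls <- data.frame(cell_id = cells, label = factor("CTC", levels = lv))
  meta <- data.frame(cell_id = cells, source = "patient", subject_id = "P1")
  a <- subsampleCells(cls, meta, NULL, seed = 1)
  cls2 <- cls[cls$cell_id %in% a$cells, ]
  b <- subsampleCells(cls2, meta, NULL, seed = 99)
  expect_identical(a$cells, b$cells)
})

test_that("detectability selection is boundary-inclusive and monotone", {
  m <- matrix(FALSE, 3, 105,
              dimnames = list(c("A16", "B15", "C0"), sprintf("c%03d", 1:105)))
  m["A16", 1:16] <- TRUE   # 16/105 = 0.1524 >= 0.15
  m["B15", 1:15] <- TRUE   # 15/105 = 0.1429 <  0.15
  calls <- callsFrom(m)
  cells <- colnames(m)
  expect_identical(selectDetectableGenes(calls, cells, 0.15), "A16")
  expect_setequal(selectDetectableGenes(calls, cells, 0), rownames(m))
  expect_error(selectDetectableGenes(calls, character(0)), "empty")
  # raising the threshold can only shrink the selection
  fracs <- c(0, 0.1, 0.15, 0.2, 1)
  sel <- lapply(fracs, function(f) selectDetectableGenes(calls, cells, f))
  for (i in seq_len(length(sel) - 1))
    expect_true(all(sel[[i + 1]] %in% sel[[i]]))
})
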