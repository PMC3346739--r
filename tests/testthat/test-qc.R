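# measurement QC, gene exclusion, cell screens, funnel accounting

test_that("measurement QC applies the exact quality and Ct boundaries", {
  ct <- matrix(c(34.2, 35.0, 20.0, NA, 34.999, 10),
               nrow = 1, dimnames = list("G1", paste0("c", 1:6)))
  q <- matrix(c(0.80, 0.99, 0.64, 0.9, 0.65, NA),
              nrow = 1, dimnames = dimnames(ct))
  x <- tinyExperiment(ct, q)
  m <- callsMatrix(applyMeasurementQC(x))
  expect_identical(unname(m[1, ]),
                   c(TRUE,   # 34.2 / 0.80: both pass
                     FALSE,  # Ct exactly 35 is immeasurable
                     FALSE,  # quality 0.64 just below 0.65
                     FALSE,  # absent Ct
                     TRUE,   # just under both boundaries
                     TRUE))  # absent quality counts as 1.0
})

test_that("gene exclusion fires on missing chips and NTC amplification", {
  assays <- c("UBB", "ACTB", "GAPDH", "GOOD", "PARTIAL", "FALSEPOS")
  cells <- c("a", "b", "c", "ntc1")
  ct <- matrix(20, length(assays), length(cells),
               dimnames = list(assays, cells))
  ct[, "ntc1"] <- NA               # NTC silent ...
  ct["FALSEPOS", "ntc1"] <- 28     # ... except one false positive
  meas <- matrix(TRUE, length(assays), length(cells),
                 dimnames = dimnames(ct))
  meas["PARTIAL", "c"] <- FALSE    # assay never loaded on chip C
  ct["PARTIAL", "c"] <- NA
  x <- CtExperiment(ct, measured = meas,
                    chip = c("A", "B", "C", "D"),
                    meta = data.frame(cell_id = cells,
                                      source = c(rep("patient", 3), "ntc")))
  calls <- applyMeasurementQC(x)
  panel <- excludeGenes(genePanel(assays), x, calls, ntc_cells = "ntc1")
  expect_identical(panel$exclusion_reason[panel$assay == "PARTIAL"],
                   "not_on_all_chips")
  expect_identical(panel$exclusion_reason[panel$assay == "FALSEPOS"],
                   "ntc_positive")
  expect_identical(sum(panel$excluded), 2L)

  # rule 1 is checked first: an assay matching both keeps that reason
  meas["FALSEPOS", "a"] <- FALSE   # chip A holds only cell a
  ct2 <- ct; ct2["FALSEPOS", "a"] <- NA
  x2 <- CtExperiment(ct2, measured = meas, chip = chipOf(x),
                     meta = cellMeta(x))
  p2 <- excludeGenes(genePanel(assays), x2, applyMeasurementQC(x2), "ntc1")
  expect_identical(p2$exclusion_reason[p2$assay == "FALSEPOS"],
                   "not_on_all_chips")

  expect_warning(excludeGenes(genePanel(assays), x, calls, character(0)),
                 "ntc_positive exclusion rule skipped")
})

test_that("the default study yields the ten configured gene exclusions", {
  res <- cachedRun()
  expect_identical(sum(res$panel$excluded), 10L)
  expect_setequal(res$panel$assay[res$panel$excluded],
                  c("HGF", "RPS11", "RPS18", "RPS27A",
                    "BMI1", "EIF4E", "EIF4EBP1", "MED1", "POU5F1", "RPLPO"))
  expect_setequal(res$panel$exclusion_reason[res$panel$excluded],
                  c("not_on_all_chips", "ntc_positive"))
  expect_identical(length(retainedAssays(res$panel)), 77L)
})

test_that("the minimum-gene screen counts over the retained panel only", {
  m <- matrix(FALSE, 12, 3,
              dimnames = list(sprintf("G%02d", 1:12), c("ten", "nine", "none")))
  m[1:10, "ten"] <- TRUE
  m[1:9, "nine"] <- TRUE
  calls <- callsFrom(m)
  expect_identical(filterCellsMinGenes(calls, 10), "ten")
  # excluding an expressed gene drops the boundary cell below the screen
  m2 <- m; m2["G01", ] <- FALSE
  calls2 <- new("ExpressionCalls", calls = m2, excluded = "G01",
                quality_min = 0.65, ct_max = 35)
  expect_identical(filterCellsMinGenes(calls2, 10), character(0))
})

test_that("the reference-integrity gate is strict at the UBB threshold", {
  assays <- c("UBB", "ACTB", "GAPDH")
  ct <- matrix(c(24.9, 18, 19,   25.0, 18, 19,   18, 18, 34.2),
               nrow = 3, dimnames = list(assays, c("pass", "atUBB", "ok2")))
  x <- tinyExperiment(ct)
  calls <- applyMeasurementQC(x)
  expect_identical(referenceIntegrityGate(x, calls), c("pass", "ok2"))
  # GAPDH not expressed -> removed even with strong UBB
  ct2 <- ct; ct2["GAPDH", "ok2"] <- 36
  x2 <- tinyExperiment(ct2)
  expect_identical(referenceIntegrityGate(x2, applyMeasurementQC(x2)), "pass")
  # excluded reference gene is a fatal configuration error
  bad <- new("ExpressionCalls", calls = callsMatrix(calls) & (assays != "UBB"),
             excluded = "UBB", quality_min = 0.65, ct_max = 35)
  expect_error(referenceIntegrityGate(x, bad), "reference assay excluded")
})

test_that("degraded cells far above the gate are recovered without error", {
  panel <- genePanel(c("UBB", "ACTB", "GAPDH", "KRT19"))
  intact <- populationSpec("intact", 60,
                           mean_ct = c(UBB = 17, ACTB = 18, GAPDH = 19,
                                       KRT19 = 20), sd = 1)
  degraded <- populationSpec(
    "degraded", 60,
    mean_ct = c(UBB = 33, ACTB = 34, GAPDH = 34.5, KRT19 = 20), sd = 1)
  sim <- generateChipData(list(intact, degraded), quietNoise(), panel,
                          seed = 31)
  calls <- applyMeasurementQC(sim$experiment)
  got <- referenceIntegrityGate(sim$experiment, calls)
  truth_intact <- sim$truth$cell_id[sim$truth$population == "intact"]
  expect_setequal(got, truth_intact)
})

test_that("measurement QC and gene exclusion commute on the final calls", {
  res <- cachedRun()
  x <- res$experiment
  meta <- cellMeta(x)
  ntc <- meta$cell_id[meta$source == "ntc"]
  # route 1: the pipeline's own calls (QC, then exclusion, then masking)
  a <- res$calls
  # route 2: exclusions recomputed from scratch on a fresh panel, then the
  # mask applied to freshly recomputed measurement calls
  fresh <- applyMeasurementQC(x)
  panel2 <- excludeGenes(studyGenePanel(), x, fresh, ntc)
  b <- maskExcluded(fresh, panel2)
  expect_identical(as.data.frame(panel2), as.data.frame(res$panel))
  expect_identical(callsMatrix(a), callsMatrix(b))
})

test_that("the default mixture lands in the binomial band of the planted funnel", {
  res <- cachedRun()
  df <- as.data.frame(res$funnel)
  # 321/510 cells are planted reference-intact; the realized gate output
  # must sit inside the 99% binomial interval around that expectation
  n_intact <- df$n_out[df$stage == "reference_integrity"]
  half <- qnorm(0.995) * sqrt(510 * (321 / 510) * (1 - 321 / 510))
  expect_gte(n_intact, 321 - half)
  expect_lte(n_intact, 321 + half)
  # CTC fraction among intact cells near the planted 0.60
  cls <- res$classification
  intact_cls <- cls[cls$cell_id %in% res$integrity_pass, ]
  frac <- mean(intact_cls$label == "CTC")
  half_f <- qnorm(0.995) * sqrt(0.6 * 0.4 / nrow(intact_cls))
  expect_gte(frac, 0.6 - half_f)
  expect_lte(frac, 0.6 + half_f)
})

test_that("funnel counts chain and conserve cells", {
  cells <- sprintf("c%02d", 1:20)
  fr <- funnelReport(cells, list(
    list(name = "screen", removed = list(low = cells[1:4], bad = cells[5:6])),
    list(name = "gate", removed = list(degraded = cells[7:11]))
  ))
  df <- as.data.frame(fr)
  expect_equal(df$n_out, df$n_in - df$n_removed)
  expect_equal(df$n_in[2], df$n_out[1])
  expect_equal(df$n_out[2] + sum(df$n_removed), length(cells))
  expect_identical(funnelSurvivors(fr), cells[12:20])
  # percentages recomputed from counts equal the stored percentages
  expect_equal(df$pct_of_input, roundHalfUp(100 * df$n_out / df$n_in, 1))
  expect_equal(df$pct_of_initial, roundHalfUp(100 * df$n_out / 20, 1))
  # single stage removing nothing
  fr0 <- funnelReport(cells, list(list(name = "noop", removed = list())))
  expect_equal(as.data.frame(fr0)$n_removed, 0L)
  expect_equal(as.data.frame(fr0)$n_in, as.data.frame(fr0)$n_out)
})
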