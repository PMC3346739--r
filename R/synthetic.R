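# Synthetic chip-data generator: planted cell populations with a dropout /
# censoring / quality noise model, producing CtExperiment + ground truth.
#
# The generator emulates the structure of a 96.96 dynamic-array study of
# EpCAM-captured cells: clonal cancer cell lines, two CTC expression
# programs, CD45+ leukocytes, keratin+/CD45+ double positives, RNA-degraded
# cells and no-template controls. Ct magnitudes are free parameters of the
# config; the observational missingness rule (Ct >= 35 unmeasurable) is the
# only part the assay itself fixes.

#' Population specification for the generator
#'
#' Describes one planted cell population: its expression program (per-assay
#' mean Ct and SD), structural zeros, subject assignment and metadata.
#' Assays not named in `mean_ct` and not in `never_expressed` are drawn
#' around `baseline_ct` (effectively undetectable under the default noise).
#'
#' @param label population label (also the default truth label).
#' @param n_cells number of cells to generate (>= 0).
#' @param mean_ct named numeric vector of mean Ct values (cycles) for the
#'   expressed program; all means must lie in `[5, 45]`.
#' @param sd per-assay Ct standard deviation: a scalar, or a named vector
#'   overriding the scalar for specific assays.
#' @param never_expressed assays that are structural zeros (never amplify).
#' @param source cell source: `"patient"`, `"cell_line"` or `"ntc"`.
#' @param subjects optional `data.frame(subject_id, n_cells, ...)` splitting
#'   cells over patients/lines; extra columns (`stage`, `er_status`,
#'   `pr_status`, `her2_status`, `age`) become per-cell metadata.
#'   Default: a single subject named after the label.
#' @param dropout_multiplier multiplies the noise model's dropout
#'   probability (degraded cells use 2).
#' @param baseline_ct mean for unnamed assays (default 40 cycles, at the
#'   detection limit).
#' @param truth_label label recorded in the ground-truth table.
#' @return a `population_spec` list.
#' @export
populationSpec <- function(label, n_cells, mean_ct = numeric(0), sd = 1,
                           never_expressed = character(0),
                           source = c("patient", "cell_line", "ntc"),
                           subjects = NULL, dropout_multiplier = 1,
                           baseline_ct = 40, truth_label = label) {
  source <- match.arg(source)
  if (n_cells < 0) stop("config error: negative n_cells for population ", label)
  if (length(mean_ct) && is.null(names(mean_ct)))
    stop("config error: mean_ct must be named by assay")
  if (any(mean_ct < 5 | mean_ct > 45))
    stop("config error: mean Ct outside [5, 45] in population ", label)
  if (any(sd < 0)) stop("config error: negative SD in population ", label)
  if (dropout_multiplier < 0) stop("config error: negative dropout_multiplier")
  if (is.null(subjects)) {
    subjects <- data.frame(subject_id = if (source == "ntc") "NTC" else label,
                           n_cells = n_cells, stringsAsFactors = FALSE)
  }
  if (sum(subjects$n_cells) != n_cells)
    stop("config error: subjects n_cells do not sum to n_cells in ", label)
  structure(list(label = label, n_cells = n_cells, mean_ct = mean_ct, sd = sd,
                 never_expressed = never_expressed, source = source,
                 subjects = subjects, dropout_multiplier = dropout_multiplier,
                 baseline_ct = baseline_ct, truth_label = truth_label),
            class = "population_spec")
}

#' Measurement noise model for the generator
#'
#' Missingness is a logistic function of the true Ct (weak transcripts fail
#' more often) on top of hard censoring at the detection limit, reproducing
#' the "low to undetectable" pattern of weakly expressing cells with one
#' mechanism. Quality scores for successful reactions follow a
#' `Beta(quality_alpha, quality_beta)`; independently, a fraction
#' `low_quality_rate` of measurements receives a uniform quality below 0.65
#' regardless of Ct (the instrument's occasional bad curve fits).
#'
#' @param censor_ct detection-limit cycle; observed Ct is capped here.
#' @param dropout_midpoint true Ct at which dropout probability is 50%.
#' @param dropout_slope logistic slope (>= 0 so dropout is non-decreasing
#'   in true Ct).
#' @param quality_alpha,quality_beta Beta parameters of the quality score.
#' @param low_quality_rate probability of a label-independent low-quality
#'   measurement.
#' @return a `noise_model` list.
#' @export
noiseModel <- function(censor_ct = 40, dropout_midpoint = 36,
                       dropout_slope = 1, quality_alpha = 20,
                       quality_beta = 1, low_quality_rate = 0.01) {
  if (censor_ct <= 0) stop("config error: censor_ct must be positive")
  if (dropout_slope < 0)
    stop("config error: dropout_slope must be >= 0 (dropout non-decreasing in Ct)")
  if (low_quality_rate < 0 || low_quality_rate > 1)
    stop("config error: low_quality_rate must lie in [0, 1]")
  if (quality_alpha <= 0 || quality_beta <= 0)
    stop("config error: Beta parameters must be positive")
  structure(list(censor_ct = censor_ct, dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope, quality_alpha = quality_alpha,
                 quality_beta = quality_beta,
                 low_quality_rate = low_quality_rate),
            class = "noise_model")
}

# fixed-length draw layout per cell (5 blocks) so RNG streams are stable:
# changing dropout_midpoint re-uses the same uniforms, making missingness
# monotone in the midpoint draw-by-draw, not just in expectation
.drawCell <- function(mu, sdv, structural, noise, mult) {
  n <- length(mu)
  true_ct <- stats::rnorm(n, mu, sdv)
  u_drop <- stats::runif(n)
  q_beta <- stats::rbeta(n, noise$quality_alpha, noise$quality_beta)
  u_lowq <- stats::runif(n)
  q_low <- stats::runif(n) * 0.65
  z <- noise$dropout_slope * (true_ct - noise$dropout_midpoint)
  z[is.nan(z)] <- -Inf  # slope 0 with midpoint at infinity: failure onset never reached
  p_drop <- pmin(1, mult * stats::plogis(z))
  absent <- structural | (u_drop < p_drop)
  ct <- pmin(pmax(true_ct, 0), noise$censor_ct)
  q <- q_beta
  low <- u_lowq < noise$low_quality_rate
  q[low] <- q_low[low]
  ct[absent] <- NA_real_
  q[absent] <- NA_real_
  list(ct = ct, quality = q)
}

#' Generate a synthetic chip dataset with known ground truth
#'
#' For each cell of each population, true Ct values are drawn
#' `Normal(mean, SD)` per assay; structural zeros and logistic dropout
#' events become absent; surviving values are censored at the detection
#' limit; quality scores are drawn from the noise model. Each population
#' owns a random stream derived from its label (adding a population never
#' perturbs the others), split per cell.
#'
#' @param specs list of [populationSpec()] objects.
#' @param noise a [noiseModel()].
#' @param panel a [GenePanel-class] naming every assay measured.
#' @param seed integer seed; the same seed and config reproduce the output
#'   bit for bit.
#' @param cells_per_chip chip capacity; cells fill chips in generation
#'   order (96-sample dynamic arrays by default).
#' @param unmeasured optional list of `list(assays=, chips=)` marking
#'   reactions never loaded on given chips (feeds the not-on-all-chips
#'   exclusion rule).
#' @return list with `experiment` (a [CtExperiment-class] whose `colData`
#'   carries the cell metadata) and `truth` (data.frame of per-cell
#'   population labels, with the seed and config as attributes).
#' @export
generateChipData <- function(specs, noise, panel, seed,
                             cells_per_chip = 96, unmeasured = NULL) {
  stopifnot(is(panel, "GenePanel"))
  if (!length(specs)) stop("config error: no population specs")
  if (inherits(specs, "population_spec")) specs <- list(specs)
  assays <- panel$assay
  ct_cols <- list(); q_cols <- list()
  meta_rows <- list(); truth_rows <- list()
  for (spec in specs) {
    bad <- setdiff(c(names(spec$mean_ct), spec$never_expressed), assays)
    if (length(bad))
      stop("config error: unknown assay in population '", spec$label, "': ",
           paste(bad, collapse = ", "))
    if (spec$n_cells == 0) next
    mu <- stats::setNames(rep(spec$baseline_ct, length(assays)), assays)
    mu[names(spec$mean_ct)] <- spec$mean_ct
    sdv <- rep(if (is.null(names(spec$sd))) spec$sd[1L] else 1, length(assays))
    names(sdv) <- assays
    if (!is.null(names(spec$sd))) sdv[names(spec$sd)] <- spec$sd
    structural <- assays %in% spec$never_expressed
    pop_seed <- stringSeed(spec$label, seed)
    subj <- spec$subjects
    subj_of_cell <- rep(subj$subject_id, subj$n_cells)
    ids <- sprintf("%s_c%03d", spec$label, seq_len(spec$n_cells))
    for (i in seq_len(spec$n_cells)) {
      cell_seed <- (pop_seed + 7919 * i) %% 2147483647L
      d <- withSeed(cell_seed,
                    .drawCell(mu, sdv, structural, noise, spec$dropout_multiplier))
      ct_cols[[ids[i]]] <- d$ct
      q_cols[[ids[i]]] <- d$quality
    }
    si <- match(subj_of_cell, subj$subject_id)
    getcol <- function(col, default) {
      if (col %in% colnames(subj)) subj[[col]][si] else rep(default, spec$n_cells)
    }
    meta_rows[[spec$label]] <- data.frame(
      cell_id = ids,
      source = spec$source,
      subject_id = subj_of_cell,
      sample_id = if (spec$source == "ntc") subj_of_cell
                  else paste0(subj_of_cell, "_d1"),
      stage = getcol("stage", "not_applicable"),
      er_status = getcol("er_status", "unknown"),
      pr_status = getcol("pr_status", "unknown"),
      her2_status = getcol("her2_status", "unknown"),
      age = getcol("age", NA_real_),
      stringsAsFactors = FALSE
    )
    truth_rows[[spec$label]] <- data.frame(
      cell_id = ids, population = spec$truth_label,
      subject_id = subj_of_cell, profile = spec$label,
      stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, c(meta_rows, list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  if (anyDuplicated(meta$cell_id)) stop("config error: duplicate population labels")
  ct <- do.call(cbind, ct_cols)
  q <- do.call(cbind, q_cols)
  rownames(ct) <- rownames(q) <- assays
  chip <- paste0("chip", (seq_len(ncol(ct)) - 1L) %/% cells_per_chip + 1L)
  measured <- matrix(TRUE, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  if (!is.null(unmeasured)) {
    for (u in unmeasured) {
      on <- chip %in% u$chips
      measured[u$assays, on] <- FALSE
      ct[u$assays, on] <- NA_real_
      q[u$assays, on] <- NA_real_
    }
  }
  x <- CtExperiment(ct, q, measured, chip = chip, meta = meta)
  attr(truth, "seed") <- seed
  attr(truth, "config") <- list(specs = specs, noise = noise)
  list(experiment = x, truth = truth)
}

## ready-made study configuration --------------------------------------------

.GENES_RULE1 <- c("HGF", "RPS11", "RPS18", "RPS27A")
.GENES_RULE2 <- c("BMI1", "EIF4E", "EIF4EBP1", "MED1", "POU5F1", "RPLPO")

# the ten genes that separate the strongly-expressing CTC subgroup
.CLUSTER_I_PROGRAM <- c("S100A9", "CD24", "VIM", "CXCR4", "MAPK14",
                        "AKT2", "PIK3R1", "CTNNB1", "CD44", "ZEB2")

# the 25 commonly detectable cancer-associated genes shared by both CTC
# programs (with the three reference genes and KRT8/18/19 these make 31)
.CTC_COMMON <- c("CTNNB1", "TGFB1", "FOXC1", "CXCR4", "NFKB1", "VIM", "ZEB2",
                 "S100A9", "NPTN", "S100A4", "AKT1", "AKT2", "PIK3R1", "PTEN",
                 "BAX", "CASP3", "CD53", "CD59", "RRM1", "MAPK14", "PARP1",
                 "SLC2A1", "TFRC", "CD24", "CD44")

#' The 87-assay study gene panel
#'
#' Reference genes (UBB, ACTB, GAPDH), the four epithelial keratins, CD45
#' (PTPRC), the commonly CTC-expressed cancer-associated genes, receptor and
#' proliferation markers, EMT and stemness genes, and the ten assays that
#' chip-level QC removes in the emulated study (four not run on every chip,
#' six amplifying in no-template controls).
#'
#' @return a [GenePanel-class] of 87 assays, none excluded yet.
#' @export
studyGenePanel <- function() {
  extra <- c("EPCAM", "CDH1", "ESR1", "PGR", "ERBB2", "EGFR", "VEGFA", "MET",
             "MYC", "ATF3", "TERT", "RAC1", "FOXA1", "CCNB1", "BIRC5", "S100P",
             "BRCA1", "BRCA2", "TP53", "PIK3CA", "CCND1", "CDK4", "CDK6",
             "CDKN1A", "CDKN2A", "MKI67", "AURKA", "PLK1", "TOP2A", "MMP2",
             "MMP9", "TIMP1", "SNAI1", "SNAI2", "TWIST1", "FN1", "ALDH1A1",
             "PROM1", "NOTCH1", "JAG1", "GATA3", "XBP1", "SCUBE2", "ERBB3")
  genePanel(c(referenceGenes(), epithelialKeratins(), "PTPRC",
              .GENES_RULE1, .GENES_RULE2, .CTC_COMMON, extra))
}

.refMeans <- function(shift = 0) {
  c(UBB = 17, ACTB = 18, GAPDH = 19) + shift
}

# Shared CTC expression program. Both subgroups express references,
# keratins and a moderate metastasis/survival core; the remaining common
# genes sit near the detection limit ("low to undetectable"), so weakly
# expressing cells show heavy, informative missingness. Cluster I adds
# exactly 4 cycles of expression (lower Ct) on the ten-gene program.
.CTC_MODERATE <- c("TGFB1", "NPTN", "S100A4", "PTEN", "BAX", "CD59",
                   "SLC2A1", "TFRC")
.ctcMeans <- function(cluster = c("I", "II")) {
  cluster <- match.arg(cluster)
  low <- setdiff(.CTC_COMMON, c(.CTC_MODERATE, .CLUSTER_I_PROGRAM))
  m <- c(.refMeans(),
         KRT8 = 20, KRT18 = 20, KRT19 = 21,
         stats::setNames(rep(26, length(.CTC_MODERATE)), .CTC_MODERATE),
         stats::setNames(rep(34.5, length(low)), low),
         stats::setNames(rep(34.5, length(.CLUSTER_I_PROGRAM)),
                         .CLUSTER_I_PROGRAM),
         RPLPO = 23, EIF4E = 23)
  if (cluster == "I") m[.CLUSTER_I_PROGRAM] <- 30.5
  m
}

#' Planted CTC population
#'
#' A patient-derived CTC population carrying the study's expression
#' structure: reference genes strongly expressed, keratins KRT8/18/19
#' present, CD45 structurally absent, a moderate metastasis/survival core
#' expressed by both subgroups, and the remaining common genes low to
#' undetectable — except that cluster I expresses the ten-gene program
#' 4 cycles more strongly than cluster II.
#'
#' @param cluster `"I"` (strongly expressing subgroup) or `"II"`.
#' @param n_cells number of cells.
#' @param subjects optional subject table (see [populationSpec()]).
#' @param sd Ct standard deviation (default 1 cycle).
#' @return a [populationSpec()].
#' @export
ctcPopulation <- function(cluster = c("I", "II"), n_cells, subjects = NULL,
                          sd = 1) {
  cluster <- match.arg(cluster)
  populationSpec(label = paste0("ctc_cluster_", cluster), n_cells = n_cells,
                 mean_ct = .ctcMeans(cluster), sd = sd,
                 never_expressed = "PTPRC", source = "patient",
                 subjects = subjects)
}

.LINE_NAMES <- c("MCF7", "T47D", "SKBR3", "MDA231",
                 "CCdl054", "CCdl672", "CCdl675")
.LINE_ER_POS <- c("MCF7", "T47D", "CCdl054", "CCdl672", "CCdl675")
.LINE_SIGNATURES <- list(
  MCF7 = c("BRCA1", "BRCA2", "TP53", "PIK3CA"),
  T47D = c("CDK4", "CDK6", "CDKN1A", "CDKN2A"),
  SKBR3 = c("MMP2", "MMP9", "TIMP1", "AURKA"),
  MDA231 = c("SNAI1", "TWIST1", "PROM1", "ALDH1A1"),
  CCdl054 = c("NOTCH1", "JAG1", "PLK1", "S100P"),
  CCdl672 = c("MET", "VEGFA", "ATF3", "TERT"),
  CCdl675 = c("SCUBE2", "ERBB3", "NPTN", "S100A4")
)

# deterministic line-specific expression level for a shared-program gene:
# each clonal line sits at its own level (+/- 2 cycles around the program
# mean), giving lines the distinctive quantitative profiles real clones
# show, independent of the RNG seed
.lineOffset <- function(line, genes) {
  vapply(genes, function(g) {
    h <- 0
    for (k in utf8ToInt(paste0(line, ":", g))) h <- (h * 31 + k) %% 1000003
    (h %% 5) - 2
  }, numeric(1))
}

#' Clonal breast-cancer cell-line population
#'
#' Epithelial program (keratins, EPCAM, CDH1), proliferation genes, an
#' ER-status block for the luminal-like lines, a line-specific signature
#' of strongly expressed genes, and line-specific expression levels across
#' the shared program, at tight clonal SD.
#'
#' @param line one of MCF7, T47D, SKBR3, MDA231, CCdl054, CCdl672, CCdl675.
#' @param n_cells cells to generate (default 10, from which balanced
#'   subsampling later draws exactly 7 reference-complete cells).
#' @param sd clonal Ct standard deviation (default 0.5 cycles).
#' @return a [populationSpec()].
#' @export
linePopulation <- function(line, n_cells = 10, sd = 0.5) {
  line <- match.arg(line, .LINE_NAMES)
  shared <- c(KRT7 = 22, KRT8 = 20, KRT18 = 20, KRT19 = 21,
              EPCAM = 20, CDH1 = 21,
              RRM1 = 21, AKT1 = 21, AKT2 = 22, MYC = 21, CCNB1 = 22,
              BIRC5 = 22, MKI67 = 22, TOP2A = 23, CCND1 = 22, CTNNB1 = 22,
              SLC2A1 = 23, TFRC = 22, BAX = 23, CASP3 = 23, PARP1 = 23,
              RPLPO = 23, EIF4E = 23)
  m <- c(.refMeans(), shared + .lineOffset(line, names(shared)))
  if (line %in% .LINE_ER_POS)
    m <- c(m, ESR1 = 21, PGR = 23, FOXA1 = 21, GATA3 = 21, XBP1 = 22)
  if (line == "SKBR3") m <- c(m, ERBB2 = 18, EGFR = 22)
  if (line == "MDA231") m <- c(m, VIM = 19, EGFR = 21, FN1 = 22, CD44 = 21)
  sig <- stats::setNames(rep(18, 4L), .LINE_SIGNATURES[[line]])
  m[names(sig)] <- sig
  subjects <- data.frame(subject_id = line, n_cells = n_cells,
                         stage = if (line %in% c("CCdl054", "CCdl672", "CCdl675"))
                                   "primary" else "metastatic",
                         er_status = if (line %in% .LINE_ER_POS) "pos" else "neg",
                         pr_status = "unknown", her2_status = "unknown",
                         age = NA_real_, stringsAsFactors = FALSE)
  populationSpec(label = paste0("line_", line), n_cells = n_cells,
                 mean_ct = m, sd = sd, never_expressed = "PTPRC",
                 source = "cell_line", subjects = subjects)
}

.wbcMeans <- function() {
  c(.refMeans(), PTPRC = 20, CD53 = 21, CD59 = 21, BAX = 23, CASP3 = 23,
    NFKB1 = 22, S100A4 = 22, S100A9 = 21, SLC2A1 = 24, TFRC = 23,
    RAC1 = 23, MYC = 24, CXCR4 = 23)
}

# 50-patient cohort: CTC-bearing patients P01..P35 (14 primary, 21
# metastatic); the two CTC programs share 8 patients (P06..P13) so cluster
# composition shows cross-cluster case overlap
.patientTable <- function() {
  ids <- sprintf("P%02d", 1:50)
  primary <- ids %in% c(sprintf("P%02d", 4:7), sprintf("P%02d", 14:23))
  receptor <- rep(c("erpr", "tn", "erpr", "her2", "tn"), length.out = 50)
  data.frame(
    subject_id = ids,
    stage = ifelse(primary, "primary", "metastatic"),
    er_status = ifelse(receptor == "erpr", "pos", "neg"),
    pr_status = ifelse(receptor == "erpr", "pos", "neg"),
    her2_status = ifelse(receptor == "her2", "pos", "neg"),
    age = 28 + ((1:50) * 7) %% 40,
    stringsAsFactors = FALSE
  )
}

.subjectsFor <- function(patients, n_per) {
  tab <- .patientTable()
  df <- tab[match(patients, tab$subject_id), , drop = FALSE]
  df$n_cells <- n_per
  rownames(df) <- NULL
  df
}

#' Default synthetic study configuration
#'
#' A ready-made configuration mirroring the emulated study's structure:
#' the 87-assay panel; seven clonal cell lines; a captured patient-cell
#' mixture of 510 cells in which 63% carry intact reference-gene RNA and,
#' of those, 60% are CTCs (split 39 strongly-expressing / 154 weakly-
#' expressing over 13 and 30 patients with 8 patients shared), 21% are
#' CD45+ leukocytes and the rest keratin+/CD45+ double positives; RNA-
#' degraded cells with reference genes shifted far above the UBB integrity
#' gate; and six no-template control wells whose only amplification is the
#' six false-positive assays. Four assays are never loaded on the first
#' chip. Population sizes are fixed; all randomness comes from the noise
#' model at generation time.
#'
#' @param noise a [noiseModel()]; override to study noise regimes.
#' @param line_sd,ctc_sd clonal and CTC Ct standard deviations.
#' @return list with `specs`, `noise`, `panel`, `unmeasured` and
#'   `expected` (the planted mixture proportions implied by the spec
#'   sizes, for reference in tests and reports).
#' @export
defaultStudyConfig <- function(noise = noiseModel(), line_sd = 0.5,
                               ctc_sd = 1) {
  panel <- studyGenePanel()
  lines <- lapply(.LINE_NAMES, linePopulation, n_cells = 10, sd = line_sd)
  names(lines) <- paste0("line_", .LINE_NAMES)

  ctcI <- ctcPopulation("I", n_cells = 39,
                        subjects = .subjectsFor(sprintf("P%02d", 1:13), 3),
                        sd = ctc_sd)
  ctcII <- ctcPopulation("II", n_cells = 154,
                         subjects = .subjectsFor(sprintf("P%02d", 6:35),
                                                 c(rep(6, 4), rep(5, 26))),
                         sd = ctc_sd)
  wbc <- populationSpec(
    "wbc", 67, mean_ct = .wbcMeans(), sd = ctc_sd,
    never_expressed = epithelialKeratins(), source = "patient",
    subjects = .subjectsFor(sprintf("P%02d", 1:50), c(rep(2, 17), rep(1, 33))))
  ambiguous <- populationSpec(
    "ambiguous", 61,
    mean_ct = c(.wbcMeans(), KRT8 = 22, KRT18 = 22, KRT19 = 23), sd = ctc_sd,
    source = "patient",
    subjects = .subjectsFor(sprintf("P%02d", 1:50), c(rep(2, 11), rep(1, 39))))
  deg_means <- .ctcMeans("II")
  deg_means[names(.refMeans())] <- .refMeans(13)  # UBB mean 30, 5 SD over gate
  degraded <- populationSpec(
    "degraded", 189, mean_ct = deg_means, sd = ctc_sd,
    never_expressed = "PTPRC", source = "patient", dropout_multiplier = 2,
    subjects = .subjectsFor(sprintf("P%02d", 1:50), c(rep(4, 39), rep(3, 11))))
  ntc <- populationSpec(
    "ntc", 6,
    mean_ct = stats::setNames(rep(28, length(.GENES_RULE2)), .GENES_RULE2),
    sd = 1, never_expressed = setdiff(panel$assay, .GENES_RULE2),
    source = "ntc")

  specs <- c(lines, list(ctc_cluster_I = ctcI, ctc_cluster_II = ctcII,
                         wbc = wbc, ambiguous = ambiguous,
                         degraded = degraded, ntc = ntc))
  n_intact <- 39 + 154 + 67 + 61
  list(
    specs = specs, noise = noise, panel = panel,
    unmeasured = list(list(assays = .GENES_RULE1, chips = "chip1")),
    expected = list(
      n_patient_cells = 510,
      frac_reference_intact = n_intact / 510,
      frac_ctc_among_intact = (39 + 154) / n_intact,
      frac_wbc_among_intact = 67 / n_intact,
      cluster_I_program = .CLUSTER_I_PROGRAM
    )
  )
}
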