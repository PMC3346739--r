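# fixtures built in code + an independent clustering oracle

# small CtExperiment: assays x cells matrix with optional quality
tinyExperiment <- function(ct, quality = NULL, chip = "chip1",
                           source = "patient", subject = NULL) {
  cells <- colnames(ct)
  if (is.null(subject)) subject <- cells
  meta <- data.frame(cell_id = cells, source = source, subject_id = subject,
                     sample_id = paste0(subject, "_d1"),
                     stage = "metastatic", er_status = "unknown",
                     pr_status = "unknown", her2_status = "unknown",
                     age = NA_real_, stringsAsFactors = FALSE)
  CtExperiment(ct, quality, chip = chip, meta = meta)
}

# all-expressed calls object for a logical matrix
callsFrom <- function(m, quality_min = 0.65, ct_max = 35) {
  new("ExpressionCalls", calls = m, excluded = character(0),
      quality_min = quality_min, ct_max = ct_max)
}

# Brute-force O(n^3) agglomeration: recompute the full inter-cluster
# dissimilarity from the pairwise point distances at every step and merge
# the globally closest pair (lowest-index pair first on exact ties).
# Independent of stats::hclust by construction.
oracleAgglomerate <- function(mat, linkage = "complete") {
  n <- nrow(mat)
  d <- as.matrix(stats::dist(mat))
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  cd <- function(a, b) {
    dd <- d[clusters[[a]], clusters[[b]], drop = FALSE]
    switch(linkage, complete = max(dd), single = min(dd), average = mean(dd))
  }
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL; bh <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1L)) {
        h <- cd(active[j], active[i])
        if (h < bh) { bh <- h; best <- c(active[j], active[i]) }
      }
    }
    k <- length(clusters) + 1L
    clusters[[k]] <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    merges[[step]] <- list(members = clusters[[k]], height = bh)
    active <- c(setdiff(active, best), k)
  }
  merges
}

# merge sequence of an hclust tree in the oracle's format
hclustMerges <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    grab <- function(v) if (v < 0) -v else members[[v]]
    members[[i]] <- sort(c(grab(hc$merge[i, 1L]), grab(hc$merge[i, 2L])))
  }
  Map(function(m, h) list(members = m, height = h), members, hc$height)
}

expect_same_merges <- function(result, oracle, tol = 1e-9) {
  got <- hclustMerges(clusterTree(result))
  expect_equal(length(got), length(oracle))
  for (i in seq_along(oracle)) {
    expect_identical(got[[i]]$members, oracle[[i]]$members)
    expect_equal(got[[i]]$height, oracle[[i]]$height, tolerance = tol)
  }
}

# noise with every stochastic failure mode off (for exact-recovery fixtures)
quietNoise <- function(...) {
  noiseModel(dropout_slope = 0, dropout_midpoint = Inf,
             low_quality_rate = 0, quality_alpha = 50, quality_beta = 1, ...)
}

# one cached default-config pipeline run shared by tests in a session
.pipeline_cache <- new.env(parent = emptyenv())
cachedRun <- function(seed = 7) {
  key <- paste0("run", seed)
  if (is.null(.pipeline_cache[[key]])) {
    out <- file.path(tempdir(), paste0("ctcprof_cached_", seed))
    .pipeline_cache[[key]] <- runPipeline(pipelineConfig(seed = seed),
                                          out_dir = out)
  }
  .pipeline_cache[[key]]
}
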