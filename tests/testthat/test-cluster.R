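# imputation, hierarchical clustering vs oracle, k-cuts, composition

normObj <- function(values, pooled_sd, medians = NULL) {
  if (is.null(medians)) medians <- setNames(rep(0, nrow(values)),
                                            rownames(values))
  new("NormalizedMatrix", values = values, gene_medians = medians,
      pooled_sd = pooled_sd, reference_panel = "UBB")
}

test_that("imputation plugs -3 SD and truncation clips display only", {
  v <- matrix(c(0.5, NA, 7.2, -1), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  out <- imputeAndTruncate(normObj(v, pooled_sd = 1.5), k_sd = 3)
  expect_equal(out$clustering["g2", "a"], -4.5)   # -3 x 1.5
  expect_equal(out$clustering["g1", "b"], 7.2)    # observed: not clipped
  expect_equal(out$display["g1", "b"], 4.5)       # display: clipped at +3 SD
  expect_true(is.na(out$display["g2", "a"]))      # missing stays flagged
  # without missing values the clustering matrix equals the centered matrix
  v2 <- v; v2[is.na(v2)] <- 0
  out2 <- imputeAndTruncate(normObj(v2, 1.5))
  expect_equal(out2$clustering, v2)
  expect_error(imputeAndTruncate(normObj(v, 0)), "pooled SD is zero")
})

test_that("the imputed value floors the observed range within +/-3 SD", {
  set.seed(4)
  v <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  v[sample(60, 8)] <- NA
  s <- sd(v[!is.na(v)])
  out <- imputeAndTruncate(normObj(v, s))
  if (all(abs(v) <= 3 * s, na.rm = TRUE))
    expect_lte(-3 * s, min(v, na.rm = TRUE))
  expect_equal(min(out$clustering), -3 * s)
})

test_that("two tight pairs merge first and the k=2 cut recovers them", {
  m <- rbind(a1 = c(0, 0), a2 = c(0.1, 0), b1 = c(10, 10), b2 = c(10, 10.15))
  res <- hclusterCells(m)
  merges <- hclustMerges(clusterTree(res))
  expect_identical(merges[[1]]$members, c(1L, 2L))
  expect_identical(merges[[2]]$members, c(3L, 4L))
  lab <- cutClusters(res, 2)
  expect_identical(unname(lab[c("a1", "a2")]), rep(lab[["a1"]], 2))
  expect_identical(unname(lab[c("b1", "b2")]), rep(lab[["b1"]], 2))
  expect_false(lab[["a1"]] == lab[["b1"]])
})

test_that("duplicate cells merge at height zero first", {
  m <- rbind(x = c(1, 1), y = c(1, 1), z = c(5, 5))
  res <- hclusterCells(m)
  expect_equal(clusterTree(res)$height[1], 0)
  expect_identical(hclustMerges(clusterTree(res))[[1]]$members, c(1L, 2L))
})

test_that("merge sequences equal the brute-force oracle for small n", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    m <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(paste0("c", seq_len(n)), NULL))
    for (linkage in c("complete", "single", "average")) {
      res <- hclusterCells(m, linkage = linkage)
      expect_same_merges(res, oracleAgglomerate(m, linkage))
    }
  }
})

test_that("k-cut labels partition the cells with size-ordered indices", {
  set.seed(5)
  m <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("c%02d", 1:20), NULL))
  m[1:6, ] <- m[1:6, ] + 20   # a small, well-separated subgroup
  res <- hclusterCells(m)
  expect_identical(unname(cutClusters(res, 1)), rep(1L, 20))
  expect_identical(sort(unname(cutClusters(res, 20))), 1:20)
  lab <- cutClusters(res, 2)
  expect_identical(unname(table(lab)[1]), 6L)   # cluster 1 = smaller group
  expect_setequal(names(lab)[lab == 1], sprintf("c%02d", 1:6))
  expect_error(cutClusters(res, 0), "k must lie")
})

test_that("permuting the input order permutes labels consistently", {
  set.seed(6)
  m <- matrix(rnorm(36), 12, 3,
              dimnames = list(sprintf("c%02d", 1:12), NULL))
  m[1:4, ] <- m[1:4, ] + 15
  lab1 <- cutClusters(hclusterCells(m), 2)
  perm <- sample(nrow(m))
  lab2 <- cutClusters(hclusterCells(m[perm, ]), 2)
  expect_identical(lab1[names(lab2)], lab2)
})

test_that("composition percentages use round-half-up over case counts", {
  # cluster I: 13 cases (4 primary), cluster II: 30 cases (13 triple
  # negative), 8 cases in both -> 35 distinct, 23% shared
  cases_I <- sprintf("P%02d", 1:13)
  cases_II <- sprintf("P%02d", 6:35)
  meta <- data.frame(
    cell_id = c(paste0("i", 1:13), paste0("j", 1:30)),
    subject_id = c(cases_I, cases_II),
    source = "patient",
    stage = "metastatic", er_status = "pos", pr_status = "neg",
    her2_status = "neg", age = 45)
  allc <- sprintf("P%02d", 1:35)
  meta$stage[meta$subject_id %in% sprintf("P%02d", 1:4)] <- "primary"
  tn <- sprintf("P%02d", 14:26)   # 13 triple-negative cases in cluster II
  meta$er_status[meta$subject_id %in% tn] <- "neg"
  labels <- setNames(c(rep(1L, 13), rep(2L, 30)), meta$cell_id)
  tab <- compositionTable(labels, meta)
  cl <- tab$clusters
  expect_identical(cl$n_cases, c(13L, 30L))
  expect_identical(cl$pct_primary[1], 31)        # 4/13 -> 31
  expect_identical(cl$pct_metastatic[1], 69)     # 9/13 -> 69
  expect_identical(cl$pct_triple_neg[2], 43)     # 13/30 -> 43
  expect_identical(tab$overlap$n_cases_total, 35L)
  expect_identical(tab$overlap$n_shared, 8L)
  expect_identical(tab$overlap$pct_shared, 23)   # 8/35 -> 23
  expect_identical(unname(tab$overlap$n_exclusive), c(5L, 22L))
})

test_that("newick export reproduces the tree's leaves", {
  set.seed(8)
  m <- matrix(rnorm(24), 8, 3,
              dimnames = list(paste0("cell", 1:8), NULL))
  res <- hclusterCells(m)
  path <- withr::local_tempfile(fileext = ".nwk")
  exportNewick(res, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(m))
})

test_that("heatmap rendering writes the figure and ordering manifest", {
  set.seed(10)
  v <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  v[1, 2] <- NA
  norm <- normObj(v, sd(v[!is.na(v)]))
  out <- imputeAndTruncate(norm)
  res <- hclusterCells(t(out$clustering))
  file <- withr::local_tempfile(fileext = ".pdf")
  hm <- renderHeatmap(out$display, res, file = file, pooled_sd = out$pooled_sd)
  expect_true(file.exists(file))
  expect_true(file.exists(hm$manifest))
  expect_identical(hm$cell_order, leafOrder(res))
  lines <- readLines(hm$manifest)
  expect_identical(strsplit(sub("^cells\t", "", lines[2]), ",")[[1]],
                   leafOrder(res))
})
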