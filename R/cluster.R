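# Missing-value imputation, hierarchical clustering, k-cut labels,
# cluster composition, heatmap rendering and dendrogram export.
#
# Missing values represent low/undetectable expression, so for clustering
# they are replaced by the matrix minimum of -3 pooled SDs; for display,
# observed values are clipped to +/-3 SD and missing entries are flagged
# for black rendering.

#' Impute missing values and build the display matrix
#'
#' The pooled SD is the standard deviation of all observed centered values,
#' genes pooled, computed before imputation. The clustering matrix replaces
#' every missing value with `-k_sd * pooled SD` (observed values are not
#' clipped for clustering); the display matrix clips observed values to
#' `[-k_sd, +k_sd]` pooled SDs and leaves missing entries `NA` (rendered
#' black).
#'
#' @param norm a [NormalizedMatrix-class] (subset to the clustered gene set
#'   first, e.g. via [subsetGenes()]).
#' @param k_sd SD multiplier (default 3).
#' @param clip_clustering also clip the clustering matrix (default `FALSE`).
#' @return list with `clustering` and `display` matrices (genes x cells)
#'   and the `pooled_sd` used.
#' @export
imputeAndTruncate <- function(norm, k_sd = 3, clip_clustering = FALSE) {
  stopifnot(is(norm, "NormalizedMatrix"))
  v <- normalizedValues(norm)
  s <- pooledSD(norm)
  if (!is.finite(s) || s <= 0)
    stop("pooled SD is zero; matrix is constant and cannot be scaled")
  lim <- k_sd * s
  display <- pmin(pmax(v, -lim), lim)
  clustering <- if (clip_clustering) display else v
  clustering[is.na(clustering)] <- -lim
  list(clustering = clustering, display = display, pooled_sd = s)
}

#' Agglomerative hierarchical clustering of cells
#'
#' Standard agglomerative clustering with the Euclidean distance metric
#' (default) and complete linkage: at every step the pair of clusters with
#' the smallest inter-cluster dissimilarity is merged. Deterministic given
#' the input order.
#'
#' @param mat cells x genes matrix without missing values (from
#'   [imputeAndTruncate()], transposed).
#' @param metric distance metric passed to [stats::dist()].
#' @param linkage one of `"complete"` (default), `"single"`, `"average"`,
#'   `"ward.D2"`.
#' @return a [ClusterResult-class].
#' @export
hclusterCells <- function(mat, metric = "euclidean", linkage = "complete") {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("at least 2 cells are required for clustering")
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  linkage <- match.arg(linkage, c("complete", "single", "average", "ward.D2"))
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  hc <- stats::hclust(stats::dist(mat, method = metric), method = linkage)
  new("ClusterResult", tree = hc, data = mat, metric = metric,
      linkage = linkage)
}

#' Cut a cluster tree into k groups
#'
#' Cuts the merge tree at the height yielding exactly `k` groups and
#' renumbers clusters by size ascending (cluster 1 = smallest subgroup),
#' ties broken by first leaf position.
#'
#' @param result a [ClusterResult-class].
#' @param k number of groups (default 2, the two major CTC subgroups).
#' @return named integer vector of cluster labels per cell.
#' @export
cutClusters <- function(result, k = 2) {
  stopifnot(is(result, "ClusterResult"))
  n <- length(result@tree$order)
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  cl <- stats::cutree(result@tree, k = k)
  sizes <- table(cl)
  leaf_pos <- order(result@tree$order)  # position of each cell in leaf order
  first_leaf <- tapply(leaf_pos, cl, min)
  ord <- order(as.integer(sizes), first_leaf)
  remap <- integer(k)
  remap[as.integer(names(sizes))[ord]] <- seq_len(k)
  stats::setNames(remap[cl], names(cl))
}

#' Cluster composition table
#'
#' Per-cluster phenotype summary over the distinct cases (patients)
#' represented: number of cases and CTCs, median age at diagnosis, and
#' counts with integer percentages (round half up) of primary vs
#' metastatic stage, ER-or-PR-positive, HER2-positive and triple-negative
#' primaries. A case counts in every cluster one of its cells carries, so
#' the report also gives the cross-cluster case overlap.
#'
#' @param labels named cluster labels from [cutClusters()].
#' @param meta per-cell metadata (`cell_id`, `subject_id`, `stage`,
#'   `er_status`, `pr_status`, `her2_status`, `age`).
#' @return a `composition_table`: list with `clusters` (data.frame), and
#'   `overlap` (distinct cases, per-cluster exclusive counts, shared
#'   cases with percentage).
#' @export
compositionTable <- function(labels, meta) {
  idx <- match(names(labels), meta$cell_id)
  if (anyNA(idx)) stop("labeled cell(s) missing from metadata")
  mi <- meta[idx, , drop = FALSE]
  ks <- sort(unique(labels))
  per_case <- function(cases, col) {
    m <- meta[match(cases, meta$subject_id), col]
    m
  }
  rows <- lapply(ks, function(k) {
    cases <- unique(mi$subject_id[labels == k])
    n <- length(cases)
    stage <- per_case(cases, "stage")
    er <- per_case(cases, "er_status"); pr <- per_case(cases, "pr_status")
    h2 <- per_case(cases, "her2_status")
    cnt <- function(x) sum(x, na.rm = TRUE)
    pct <- function(x) roundHalfUp(100 * cnt(x) / max(1, n))
    data.frame(
      cluster = as.character(utils::as.roman(k)),
      n_cases = n,
      n_ctcs = sum(labels == k),
      median_age = stats::median(per_case(cases, "age"), na.rm = TRUE),
      n_primary = cnt(stage == "primary"), pct_primary = pct(stage == "primary"),
      n_metastatic = cnt(stage == "metastatic"),
      pct_metastatic = pct(stage == "metastatic"),
      n_er_pr_pos = cnt(er == "pos" | pr == "pos"),
      pct_er_pr_pos = pct(er == "pos" | pr == "pos"),
      n_her2_pos = cnt(h2 == "pos"), pct_her2_pos = pct(h2 == "pos"),
      n_triple_neg = cnt(er == "neg" & pr == "neg" & h2 == "neg"),
      pct_triple_neg = pct(er == "neg" & pr == "neg" & h2 == "neg"),
      stringsAsFactors = FALSE
    )
  })
  case_sets <- lapply(ks, function(k) unique(mi$subject_id[labels == k]))
  all_cases <- unique(unlist(case_sets))
  in_n <- vapply(all_cases, function(cs)
    sum(vapply(case_sets, function(s) cs %in% s, logical(1))), integer(1))
  shared <- all_cases[in_n > 1L]
  exclusive <- vapply(seq_along(ks), function(i)
    length(setdiff(case_sets[[i]], unlist(case_sets[-i]))), integer(1))
  structure(list(
    clusters = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    overlap = list(
      n_cases_total = length(all_cases),
      n_shared = length(shared),
      shared_cases = shared,
      pct_shared = roundHalfUp(100 * length(shared) / max(1, length(all_cases))),
      n_exclusive = stats::setNames(exclusive,
                                    as.character(utils::as.roman(ks)))
    )
  ), class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Cluster composition (cases = distinct patients):\n")
  print.data.frame(x$clusters, row.names = FALSE)
  cat(sprintf("Cases total %d; shared across clusters %d (%d%%); exclusive: %s\n",
              x$overlap$n_cases_total, x$overlap$n_shared, x$overlap$pct_shared,
              paste(sprintf("%s=%d", names(x$overlap$n_exclusive),
                            x$overlap$n_exclusive), collapse = ", ")))
  invisible(x)
}

#' Render the clustered expression heatmap
#'
#' Yellow = high, gray = median, blue = low expression on a diverging scale
#' centered at 0 and clipped at `+/- k_sd` pooled SDs; black = undetectable
#' (missing). Cells are ordered by the cluster dendrogram; genes are
#' ordered by the same algorithm applied to the transpose. A plain-text
#' ordering manifest is written next to the figure.
#'
#' @param display display matrix (genes x cells) from [imputeAndTruncate()].
#' @param result the cells' [ClusterResult-class].
#' @param file output figure path (pdf).
#' @param annotations optional data.frame (rownames = cell ids) of
#'   per-cell annotations drawn as color bars.
#' @param k_sd,pooled_sd the clip range used for the color scale.
#' @return invisibly, list with the cell/gene orderings and the manifest
#'   path.
#' @export
renderHeatmap <- function(display, result, file, annotations = NULL,
                          k_sd = 3, pooled_sd = NULL) {
  stopifnot(is(result, "ClusterResult"))
  if (is.null(pooled_sd)) pooled_sd <- stats::sd(display[!is.na(display)])
  lim <- k_sd * pooled_sd
  gene_tree <- if (nrow(display) >= 2L) {
    imp <- display
    imp[is.na(imp)] <- -lim
    clusterTree(hclusterCells(imp, result@metric, result@linkage))
  } else FALSE
  pheatmap::pheatmap(
    display,
    cluster_rows = gene_tree, cluster_cols = clusterTree(result),
    color = grDevices::colorRampPalette(c("blue", "gray85", "yellow"))(100),
    breaks = seq(-lim, lim, length.out = 101),
    na_col = "black",
    annotation_col = annotations,
    show_colnames = ncol(display) <= 60,
    filename = file, silent = TRUE
  )
  cell_order <- leafOrder(result)
  gene_order <- if (isFALSE(gene_tree)) rownames(display)
                else gene_tree$labels[gene_tree$order]
  manifest <- paste0(file, ".order.txt")
  writeLines(c("# heatmap ordering manifest",
               paste0("cells\t", paste(cell_order, collapse = ",")),
               paste0("genes\t", paste(gene_order, collapse = ","))),
             manifest)
  invisible(list(cell_order = cell_order, gene_order = gene_order,
                 manifest = manifest, file = file))
}

#' Export a dendrogram in Newick format
#'
#' @param result a [ClusterResult-class].
#' @param path output path.
#' @export
exportNewick <- function(result, path) {
  stopifnot(is(result, "ClusterResult"))
  ape::write.tree(ape::as.phylo(clusterTree(result)), file = path)
  invisible(path)
}
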