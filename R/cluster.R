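#' Hierarchical clustering order of matrix rows
#'
#' Euclidean-distance agglomerative clustering (average linkage by default)
#' used to order heatmap rows and columns. Deterministic for a fixed input.
#'
#' @param mat Numeric matrix; rows are the objects clustered.
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method: `average` (default), `complete` or
#'   `ward.D2`.
#' @return List with `order` (integer leaf order), `labels` (rownames in leaf
#'   order) and `tree` (an `hclust`, `NULL` for a single row).
#' @export
hierarchical_order <- function(mat, metric = "euclidean",
                               linkage = c("average", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  mat <- as.matrix(mat)
  if (anyNA(mat) || any(!is.finite(mat))) {
    abort("matrix contains missing or non-finite values")
  }
  if (nrow(mat) < 2) {
    return(list(order = seq_len(nrow(mat)), labels = rownames(mat),
                tree = NULL))
  }
  tree <- hclust(dist(mat, method = metric), method = linkage)
  list(order = tree$order, labels = rownames(mat)[tree$order], tree = tree)
}

#' K-means clustering with silhouette summary
#'
#' Best-of-`n_init` k-means partition (by within-cluster sum of squares) with
#' per-point silhouette widths; the reported headline statistic is the median
#' silhouette width over points, as used to judge the separation of cancer
#' groups.
#'
#' @param points Numeric matrix or vector (rows = objects).
#' @param k Number of clusters (default 2).
#' @param n_init Random restarts (default 50).
#' @param seed Integer seed for the restarts.
#' @return A list of class `cluster_report`: `labels`, `median_silhouette`,
#'   `silhouette` (tibble point/cluster/width), `tot_withinss`.
#' @export
kmeans_silhouette <- function(points, k = 2, n_init = 50, seed = 1) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  points <- as.matrix(points)
  if (k > nrow(points)) abort("k exceeds the number of points")
  km <- with_seed(stream_seed(seed, 4L), {
    kmeans(points, centers = k, nstart = n_init)
  })
  sil <- cluster::silhouette(km$cluster, dist(points))
  widths <- if (k == 1) rep(0, nrow(points)) else sil[, "sil_width"]
  report <- list(
    labels = km$cluster,
    median_silhouette = stats::median(widths),
    silhouette = tibble::tibble(
      point = seq_len(nrow(points)),
      cluster = as.integer(km$cluster),
      width = as.numeric(widths)),
    tot_withinss = km$tot.withinss)
  class(report) <- "cluster_report"
  report
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> k =", length(unique(x$labels)),
      " median silhouette =", round(x$median_silhouette, 3), "\n")
  invisible(x)
}

#' Ordinary bootstrap support for a k-means partition
#'
#' Resamples feature columns with replacement, re-clusters, and reports for
#' each reference cluster the fraction of resamples in which some bootstrap
#' cluster reproduces its membership exactly. This is plain bootstrap
#' support, not a multiscale (AU) approximation.
#'
#' @param mat Numeric matrix (rows = objects, columns = features).
#' @param k Number of clusters.
#' @param n_boot Bootstrap resamples (minimum 100).
#' @param seed Integer seed.
#' @param labels Optional reference partition; defaults to
#'   [kmeans_silhouette()] on the full matrix.
#' @return Tibble `cluster`, `size`, `support`.
#' @export
bootstrap_support <- function(mat, k = 2, n_boot = 100, seed = 1,
                              labels = NULL) {
  mat <- as.matrix(mat)
  if (n_boot < 100) abort("n_boot must be at least 100")
  if (all(mat == mat[1])) abort("constant matrix: bootstrap support undefined")
  if (is.null(labels)) {
    labels <- kmeans_silhouette(mat, k = k, seed = seed)$labels
  }
  ref_sets <- split(seq_len(nrow(mat)), labels)
  hits <- numeric(length(ref_sets))
  with_seed(stream_seed(seed, 5L), {
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(mat), replace = TRUE)
      bm <- mat[, cols, drop = FALSE]
      bl <- tryCatch(kmeans(bm, centers = k, nstart = 10)$cluster,
                     error = function(e) rep(1L, nrow(mat)))
      boot_sets <- split(seq_len(nrow(mat)), bl)
      for (ci in seq_along(ref_sets)) {
        reproduced <- any(vapply(boot_sets, function(s) {
          identical(sort(s), sort(ref_sets[[ci]]))
        }, logical(1)))
        if (reproduced) hits[ci] <- hits[ci] + 1
      }
    }
  })
  tibble::tibble(cluster = seq_along(ref_sets),
                 size = lengths(ref_sets),
                 support = hits / n_boot)
}
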