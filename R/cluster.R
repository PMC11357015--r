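#' Pearson correlation distance
#'
#' `1 - r` between two equal-length vectors, ranging from 0 (perfectly
#' correlated) to 2 (perfectly anti-correlated). A constant vector has no
#' defined correlation; its distance is set to 1 (r treated as 0) with a
#' warning, so degenerate profiles sit at the neutral distance.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Distance in `[0, 2]`.
#' @export
correlation_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector in correlation_distance; distance set to 1")
    return(1)
  }
  1 - stats::cor(x, y)
}

# full pairwise correlation-distance object over matrix rows
cor_dist <- function(v) {
  sds <- apply(v, 1L, stats::sd)
  d <- matrix(1, nrow(v), nrow(v), dimnames = list(rownames(v), rownames(v)))
  ok <- sds > 0
  if (any(ok)) {
    d[ok, ok] <- 1 - stats::cor(t(v[ok, , drop = FALSE]))
  }
  if (!all(ok)) {
    warning("constant profiles found; their correlation distances set to 1")
  }
  diag(d) <- 0
  stats::as.dist(d)
}

#' Hierarchical clustering of one axis of a domain matrix
#'
#' Agglomerative (average-linkage by default) clustering of genomes or of
#' domain families, under either Pearson-correlation distance (`1 - r`) or
#' Euclidean distance. Running it on both axes gives the bi-clustering used
#' to order heatmaps of domain content.
#'
#' @param m A `domain_matrix` (any normalization).
#' @param axis `"genomes"` (rows) or `"features"` (columns).
#' @param metric `"pearson"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A `cluster_result`: list with the `hclust` object, `order`
#'   (dendrogram leaf permutation), `labels`, `metric`, `axis`.
#' @export
hierarchical_cluster <- function(m, axis = c("genomes", "features"),
                                 metric = c("pearson", "euclidean"),
                                 linkage = "average") {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  v <- unclass(m)
  if (axis == "features") v <- t(v)
  if (nrow(v) < 2L) stop("need at least two items to cluster", call. = FALSE)
  d <- if (metric == "pearson") cor_dist(v) else stats::dist(v)
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, order = hc$order, labels = rownames(v),
                 merge = hc$merge, height = hc$height,
                 metric = metric, axis = axis),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d %s, %s distance, %s linkage\n",
              length(x$labels), x$axis, x$metric, x$hclust$method))
  invisible(x)
}

#' Bi-cluster a domain matrix over both axes
#'
#' @inheritParams hierarchical_cluster
#' @return List with elements `genomes` and `features`, each a
#'   `cluster_result`, plus `ordered` — the input matrix re-ordered by both
#'   dendrograms (the data behind a clustered heatmap).
#' @export
bicluster <- function(m, metric = c("pearson", "euclidean"), linkage = "average") {
  metric <- match.arg(metric)
  rows <- hierarchical_cluster(m, "genomes", metric, linkage)
  cols <- hierarchical_cluster(m, "features", metric, linkage)
  list(genomes = rows, features = cols,
       ordered = unclass(m)[rows$order, cols$order, drop = FALSE])
}

#' Two-component PLS ordination against the HL/LL label
#'
#' Partial least squares of the (column-centered) domain matrix on the
#' binary ecotype label, computed by the NIPALS-style SVD of the
#' cross-covariance with deflation. The first component captures the
#' direction of domain content that best covaries with the HL/LL contrast;
#' well-separated ecotypes appear as opposite-signed score clusters.
#'
#' @param m A labeled `domain_matrix`.
#' @param ncomp Number of components (fixed at 2 for ordination plots).
#' @return A `pls_ordination`: list with `scores` (genomes x 2, centered),
#'   `loadings` (features x 2 weight vectors), `explained` (fraction of
#'   predictor variance per component), `labels`.
#' @export
pls_ordination <- function(m, ncomp = 2L) {
  stopifnot(inherits(m, "domain_matrix"))
  labels <- matrix_labels(m)
  if (is.null(labels)) stop("matrix has no HL/LL labels", call. = FALSE)
  if (min(table(labels)) < 2L) stop("each group needs n >= 2", call. = FALSE)
  v <- unclass(m)
  const <- apply(v, 2L, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant feature column(s) dropped for PLS")
    v <- v[, !const, drop = FALSE]
  }
  x <- scale(v, center = TRUE, scale = FALSE)
  y <- ifelse(labels == "HL", 1, -1)
  y <- y - mean(y)
  total_ss <- sum(x^2)
  scores <- matrix(0, nrow(x), ncomp, dimnames = list(rownames(x), paste0("comp", seq_len(ncomp))))
  loadings <- matrix(0, ncol(x), ncomp, dimnames = list(colnames(x), paste0("comp", seq_len(ncomp))))
  explained <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(x, y))
    w <- w / sqrt(sum(w^2))
    t_h <- drop(x %*% w)
    p_h <- drop(crossprod(x, t_h)) / sum(t_h^2)
    x <- x - tcrossprod(t_h, p_h)
    y <- y - t_h * (sum(t_h * y) / sum(t_h^2))
    scores[, h] <- t_h
    loadings[, h] <- w
    explained[h] <- sum(t_h^2) * sum(p_h^2) / total_ss
  }
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, labels = labels),
            class = "pls_ordination")
}

#' @export
print.pls_ordination <- function(x, ...) {
  cat(sprintf("pls_ordination: %d genomes, %d features, explained = %s\n",
              nrow(x$scores), nrow(x$loadings),
              paste(signif(x$explained, 3), collapse = ", ")))
  invisible(x)
}

#' @export
plot.pls_ordination <- function(x, ...) {
  col <- ifelse(x$labels == "HL", "dodgerblue3", "darkorange2")
  graphics::plot(x$scores[, 1L], x$scores[, 2L], col = col, pch = 19,
                 xlab = "PLS component 1", ylab = "PLS component 2", ...)
  graphics::legend("topright", legend = c("HL", "LL"), pch = 19,
                   col = c("dodgerblue3", "darkorange2"), bty = "n")
  invisible(x)
}
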