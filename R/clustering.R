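supported_metrics <- c("binary", "canberra", "correlation", "euclidean",
                       "manhattan", "maximum", "minkowski", "uncentered")
supported_linkages <- c("upgma", "average", "mcquitty", "median", "single",
                        "complete", "centroid", "ward", "ward.D", "ward.D2")

#' Pairwise distance matrix between invariant support vectors
#'
#' Supported metrics, applied to the rows of the (usually binary) support
#' matrix:
#' \describe{
#'   \item{binary}{Jaccard-style: fraction of discordant nonzero coordinates
#'     among coordinates where at least one row is nonzero}
#'   \item{canberra}{sum of |x-y| / (|x| + |y|), 0/0 coordinates skipped}
#'   \item{correlation}{1 - Pearson correlation}
#'   \item{uncentered}{1 - cosine similarity (uncentered Pearson)}
#'   \item{euclidean, manhattan, maximum, minkowski}{the standard norms;
#'     `minkowski_p` sets the Minkowski exponent (default 2)}
#' }
#' For the two correlation-type metrics a constant (or all-zero, for
#' uncentered) row has no defined correlation; its distance is defined as 0 to
#' an identical row and 1 to any other row, with a warning.
#'
#' @param support numeric matrix, rows = objects to cluster
#' @param metric one of the metric names above
#' @param minkowski_p Minkowski exponent (only used by `metric =
#'   "minkowski"`)
#' @return a [stats::dist] object with attribute `metric`
#' @export
distance_matrix <- function(support, metric = "binary", minkowski_p = 2) {
  x <- as.matrix(support)
  if (nrow(x) < 2) stop("need at least 2 rows to compute distances")
  metric <- match.arg(metric, supported_metrics)
  d <- switch(metric,
    canberra = canberra_dist(x),
    binary = ,
    euclidean = ,
    manhattan = ,
    maximum = stats::dist(x, method = metric),
    minkowski = stats::dist(x, method = "minkowski", p = minkowski_p),
    correlation = correlation_dist(x, centered = TRUE),
    uncentered = correlation_dist(x, centered = FALSE))
  attr(d, "metric") <- metric
  d
}

# plain Canberra sum (0/0 coordinates skipped, no rescaling by the number
# of used coordinates, unlike stats::dist)
canberra_dist <- function(x) {
  n <- nrow(x)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- abs(x[i, ] - x[j, ])
    den <- abs(x[i, ]) + abs(x[j, ])
    keep <- den != 0
    D[i, j] <- D[j, i] <- sum(num[keep] / den[keep])
  }
  stats::as.dist(D)
}

correlation_dist <- function(x, centered = TRUE) {
  n <- nrow(x)
  if (centered) {
    degen <- apply(x, 1, stats::sd) == 0
    sim <- suppressWarnings(stats::cor(t(x)))
  } else {
    nrm <- sqrt(rowSums(x^2))
    degen <- nrm == 0
    sim <- (x %*% t(x)) / outer(nrm, nrm)
  }
  D <- 1 - sim
  if (any(degen)) {
    warning("constant row(s) under a correlation metric; using distance 1 to ",
            "non-identical rows, 0 to identical rows")
    for (i in which(degen)) {
      same <- vapply(seq_len(n), function(k) all(x[k, ] == x[i, ]), logical(1))
      D[i, ] <- ifelse(same, 0, 1)
      D[, i] <- D[i, ]
    }
  }
  diag(D) <- 0
  stats::as.dist(D)
}

#' Hierarchical agglomeration of a distance matrix
#'
#' Standard Lance-Williams agglomerative clustering via [stats::hclust].
#' `"upgma"` is accepted as an alias for average linkage, `"ward"` for the
#' squared-distance Ward variant (`ward.D2`); `"ward.D"` selects the
#' unsquared update. Centroid and median linkage are computed on squared
#' distances (as their geometric definition requires) and the merge heights
#' are mapped back to the distance scale; these two linkages may show height
#' inversions, the other five are monotone.
#'
#' @param d a [stats::dist] object (e.g. from [distance_matrix()])
#' @param linkage one of upgma/average, mcquitty, median, single, complete,
#'   centroid, ward/ward.D/ward.D2
#' @return an [stats::hclust] tree (merge list, heights, labels)
#' @export
agglomerate <- function(d, linkage = "upgma") {
  linkage <- match.arg(linkage, supported_linkages)
  method <- switch(linkage, upgma = "average", ward = "ward.D2", linkage)
  if (method %in% c("centroid", "median")) {
    h <- stats::hclust(d^2, method = method)
    h$height <- sqrt(pmax(h$height, 0))
  } else {
    h <- stats::hclust(d, method = method)
  }
  h$call <- NULL
  h
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges of the agglomeration, yielding exactly k
#' non-empty clusters.
#'
#' @param dend an [stats::hclust] tree
#' @param k number of clusters, between 1 and the number of leaves
#' @return named integer vector mapping each leaf label to a cluster in 1..k
#' @export
cut_dendrogram <- function(dend, k) {
  n <- length(dend$order)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  stats::cutree(dend, k = k)
}

#' Per-element silhouette widths
#'
#' Classical silhouettes of the top-level partition: for element i with
#' within-cluster mean distance a(i) and smallest other-cluster mean distance
#' b(i), s(i) = (b(i) - a(i)) / max(a(i), b(i)). Elements of singleton
#' clusters get s(i) = 0 by convention, as do elements with a(i) = b(i) = 0.
#'
#' @param assign named cluster assignment (as from [cut_dendrogram()])
#' @param d the [stats::dist] the clustering was computed on
#' @return numeric vector of silhouette widths in [-1, 1], one per element
#' @export
silhouette_widths <- function(assign, d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (length(assign) != n) stop("assignment length does not match distance matrix")
  cl <- as.integer(factor(assign))
  if (max(cl) < 2) stop("silhouette undefined for a single-cluster assignment")
  sizes <- tabulate(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sizes[own] == 1L) { s[i] <- 0; next }
    a <- sum(D[i, cl == own]) / (sizes[own] - 1L)
    b <- min(vapply(setdiff(seq_len(max(cl)), own),
                    function(k) mean(D[i, cl == k]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Mean Split Silhouette style clustering score
#'
#' Scores a clustering by averaging per-element silhouette widths: the
#' per-cluster value is the mean over the cluster's members (0 for a
#' singleton) and the global value is the mean over all elements, which
#' equals the member-count-weighted mean of the per-cluster values. Values
#' lie in [-1, 1]; higher is better separated.
#'
#' @inheritParams silhouette_widths
#' @return list with `global` (scalar) and `per_cluster` (named numeric
#'   vector, one entry per cluster label)
#' @export
mean_split_silhouette <- function(assign, d) {
  s <- silhouette_widths(assign, d)
  per <- tapply(s, assign, mean)
  list(global = mean(s), per_cluster = per)
}

#' Evaluate a grid of clusterings
#'
#' Runs every combination of distance metric, linkage method and cluster
#' count, reporting the number of single-invariant clusters and the global
#' mean silhouette score for each; the standard first screen when choosing a
#' clustering of t-invariant supports.
#'
#' @param support matrix whose rows are clustered
#' @param metrics character vector of metric names (see [distance_matrix()])
#' @param linkages character vector of linkage names (see [agglomerate()])
#' @param k_range integer vector of cluster counts (each in 2..nrow-1 is
#'   meaningful; k = nrow yields all singletons and score 0)
#' @param minkowski_p Minkowski exponent forwarded to [distance_matrix()]
#' @return data frame with columns metric, linkage, k, singletons, mss
#' @export
evaluate_grid <- function(support, metrics = c("binary", "correlation"),
                          linkages = c("upgma", "complete"),
                          k_range = 2:13, minkowski_p = 2) {
  rows <- list()
  for (met in metrics) {
    d <- distance_matrix(support, met, minkowski_p)
    for (lnk in linkages) {
      dend <- agglomerate(d, lnk)
      for (k in k_range) {
        cl <- cut_dendrogram(dend, k)
        mss <- mean_split_silhouette(cl, d)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = met, linkage = lnk, k = as.integer(k),
          singletons = sum(table(cl) == 1L),
          mss = mss$global, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
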