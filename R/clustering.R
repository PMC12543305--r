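#' Feature matrix of incoming information-flow profiles
#'
#' Each region is represented by the column of the link-length matrix
#' `l = -log w` pointing into it (its incoming-flow profile). Absent links
#' have no length; they are filled with a large finite constant (default
#' 1.05 x the maximum finite length) so they read as "very weak" without
#' breaking Euclidean or correlation geometry.
#'
#' @param w Weight matrix in `[0, 1]` with region labels.
#' @param fill Fill value for absent links, or `NULL` for the default
#'   policy.
#' @return Object of class `flow_features`: list with `X` (regions x
#'   features matrix, row r = column r of the filled length matrix), `fill`,
#'   and `n_filled`.
#' @export
feature_matrix <- function(w, fill = NULL) {
  if (all(w == 0)) stop("cannot build features from an all-zero matrix")
  l <- link_lengths(w)
  finite_max <- max(l, na.rm = TRUE)
  if (is.null(fill)) fill <- 1.05 * finite_max
  n_filled <- sum(is.na(l))
  l[is.na(l)] <- fill
  X <- t(l)  # row per region: its incoming-length profile (column of l)
  rownames(X) <- colnames(w)
  structure(list(X = X, fill = fill, n_filled = n_filled),
            class = "flow_features")
}

#' Agglomerative hierarchical clustering of regions
#'
#' Ward's method (minimum within-cluster variance, Euclidean metric only),
#' or average/complete linkage with Euclidean, correlation or cosine
#' dissimilarity (similarities converted to distances as 1 - similarity).
#'
#' @param features A [feature_matrix()] result or a plain numeric matrix
#'   (rows = observations).
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @param metric `"euclidean"`, `"correlation"` or `"cosine"`.
#' @return An `hclust` object (leaf labels = region labels).
#' @export
hier_cluster <- function(features, linkage = c("ward", "average", "complete"),
                         metric = c("euclidean", "correlation", "cosine")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  if (linkage == "ward" && metric != "euclidean")
    stop("configuration error: Ward linkage requires the euclidean metric")
  X <- if (inherits(features, "flow_features")) features$X else
    as.matrix(features)
  d <- switch(metric,
    euclidean = stats::dist(X),
    correlation = stats::as.dist(1 - stats::cor(t(X))),
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      sim <- (X %*% t(X)) / outer(nrm, nrm)
      stats::as.dist(1 - sim)
    })
  stats::hclust(d, method = switch(linkage, ward = "ward.D2",
                                   average = "average",
                                   complete = "complete"))
}

#' Cut a dendrogram into k clusters
#'
#' @param dendrogram An `hclust` object.
#' @param k Number of clusters, `1 <= k <= N`.
#' @return Named integer vector: cluster id per leaf.
#' @export
cut_clusters <- function(dendrogram, k) {
  n <- length(dendrogram$order)
  if (k < 1 || k > n) stop("invalid k: must be in [1, ", n, "]")
  stats::cutree(dendrogram, k = k)
}

#' Co-clustering contingency matrix over a network ensemble
#'
#' Clusters each network independently into k clusters (each model network
#' has its own optimal structure; never cluster an averaged network) and
#' records for every node pair the fraction of networks in which the two
#' nodes share a cluster. The resulting probability matrix P (symmetric,
#' unit diagonal) is itself hierarchically clustered using 1 - P as the
#' distance.
#'
#' @param ws List of weight matrices sharing region labels (or an
#'   `edr_ensemble` with stored networks).
#' @param k Number of clusters per network (default 4).
#' @param linkage,metric Clustering options for the per-network step (see
#'   [hier_cluster()]).
#' @param p_linkage Linkage for clustering the contingency matrix itself;
#'   `1 - P` is not a Euclidean embedding, so the default is complete
#'   linkage.
#' @return List with `P` (co-clustering probability matrix), `dendrogram`
#'   (`hclust` of 1 - P), and `partitions` (k-cluster partition per
#'   network).
#' @export
cocluster_contingency <- function(ws, k = 4L, linkage = "ward",
                                  metric = "euclidean",
                                  p_linkage = c("complete", "average")) {
  p_linkage <- match.arg(p_linkage)
  if (inherits(ws, "edr_ensemble"))
    ws <- lapply(ws$networks, `[[`, "w")
  labels <- rownames(ws[[1L]])
  if (is.null(labels)) labels <- sprintf("V%d", seq_len(nrow(ws[[1L]])))
  N <- length(labels)
  P <- matrix(0, N, N, dimnames = list(labels, labels))
  partitions <- vector("list", length(ws))
  for (m in seq_along(ws)) {
    cl <- cut_clusters(hier_cluster(feature_matrix(ws[[m]]),
                                    linkage = linkage, metric = metric), k)
    partitions[[m]] <- cl
    same <- outer(cl, cl, `==`) * 1
    P <- P + same
  }
  P <- P / length(ws)
  dimnames(P) <- list(labels, labels)
  dend <- stats::hclust(stats::as.dist(1 - P), method = p_linkage)
  list(P = P, dendrogram = dend, partitions = partitions)
}
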