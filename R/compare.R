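# Proportion histogram on fixed shared breaks; values are clamped into the
# break range so model networks binned with data-derived edges lose no mass.
hist_proportions <- function(x, breaks) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(rep(0, length(breaks) - 1L))
  x <- pmin(pmax(x, breaks[1L]), breaks[length(breaks)])
  cnt <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  cnt / sum(cnt)
}

default_breaks <- function(x, n = 20L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(seq(0, 1, length.out = n + 1L))
  r <- range(x)
  if (diff(r) == 0) r <- r + c(-0.5, 0.5)
  seq(r[1L], r[2L], length.out = n + 1L)
}

#' Compute a named bundle of network properties
#'
#' The comparison suite's per-network record: binary properties are computed
#' on the adjacency, weighted ones on the weight matrix. Histogram-valued
#' properties use fixed shared breaks so that data and model networks are
#' binned identically; pass the `breaks` element of the data network's
#' report when computing model reports.
#'
#' @param w Column-normalized weight matrix (entries in `[0, 1]`).
#' @param A Optional binary adjacency (default `w > 0` off-diagonal).
#' @param properties Which properties to compute; any of `"degree"`,
#'   `"reciprocity"`, `"apl"`, `"cc"`, `"triads"`, `"cliques"`, `"log10w"`,
#'   `"outstrength"`, `"nodedist"`.
#' @param breaks Optional list with elements `log10w` and/or `nodedist`
#'   giving shared histogram edges.
#' @param clique_sizes Sizes for `"cliques"` (default 3:5; clique counting is
#'   exponential in dense graphs).
#' @return Object of class `property_report` (a named list); histogram
#'   properties store proportions, and the breaks used are stored under
#'   `$breaks`.
#' @export
property_report <- function(w, A = NULL,
                            properties = c("degree", "reciprocity", "apl",
                                           "cc", "triads", "log10w",
                                           "outstrength", "nodedist"),
                            breaks = NULL, clique_sizes = 3:5) {
  if (is.null(A)) {
    A <- (w > 0) * 1L
    diag(A) <- 0L
  }
  rep_ <- list()
  if ("degree" %in% properties) {
    ds <- degree_spectra(A)
    rep_$in_degree <- ds$in_degree
    rep_$out_degree <- ds$out_degree
  }
  if ("reciprocity" %in% properties) {
    rc <- reciprocity_counts(A)
    rep_$unidirectional <- unname(rc["unidirectional"])
    rep_$bidirectional <- unname(rc["bidirectional"])
  }
  if ("apl" %in% properties)
    rep_$apl <- as.numeric(average_binary_path_length(A))
  if ("cc" %in% properties)
    rep_$cc <- clustering_coefficient(A)
  if ("triads" %in% properties)
    rep_$triads <- triad_census(A)
  if ("cliques" %in% properties)
    rep_$cliques <- clique_counts(A, clique_sizes)$counts
  used_breaks <- list()
  if ("log10w" %in% properties) {
    lw <- log10(w[w > 0 & offdiag(w)])
    bk <- if (!is.null(breaks$log10w)) breaks$log10w else default_breaks(lw)
    rep_$log10w <- hist_proportions(lw, bk)
    used_breaks$log10w <- bk
  }
  if ("outstrength" %in% properties)
    rep_$out_strength <- sort(rowSums(w * offdiag(w)), decreasing = TRUE)
  if ("nodedist" %in% properties) {
    r <- node_distances(w)
    rv <- r[offdiag(r)]
    bk <- if (!is.null(breaks$nodedist)) breaks$nodedist else
      default_breaks(rv[is.finite(rv)])
    rep_$nodedist <- hist_proportions(rv, bk)
    used_breaks$nodedist <- bk
  }
  rep_$breaks <- used_breaks
  class(rep_) <- "property_report"
  rep_
}

# Comparable numeric vector for one property name.
prop_vector <- function(report, property) {
  switch(property,
    degree = c(report$in_degree, report$out_degree),
    reciprocity = c(report$unidirectional, report$bidirectional),
    apl = report$apl,
    cc = report$cc,
    triads = as.numeric(report$triads) / sum(report$triads),
    cliques = log10(1 + as.numeric(report$cliques)),
    log10w = report$log10w,
    outstrength = report$out_strength,
    nodedist = report$nodedist,
    stop("unknown property: ", property))
}

#' RMSD comparison of a data network against model ensembles across lambda
#'
#' For every lambda, computes the RMSD between the data network's property
#' vector and each model network's, then averages over the ensemble (the
#' per-network-then-average convention; model networks are analysed
#' separately). The pooled curve averages the per-property curves after
#' normalizing each by its mean over the grid, so properties with different
#' scales contribute comparably.
#'
#' @param data_report A [property_report()] of the data network.
#' @param ensembles Named list (names = lambda values) of lists of
#'   [property_report()]s, or of `edr_ensemble` objects carrying `$reports`.
#' @param properties Property names to compare (must be present in every
#'   report with matching lengths/binning).
#' @return Object of class `comparison_curve`: list with `curves` (long
#'   data.frame lambda x property x rmsd), `argmin` (named per-property
#'   lambda at minimum mean RMSD), `pooled` (data.frame lambda, rmsd) and
#'   `pooled_argmin`.
#' @export
compare_to_ensemble <- function(data_report, ensembles,
                                properties = c("degree", "reciprocity",
                                               "apl", "cc")) {
  lambdas <- as.numeric(names(ensembles))
  if (any(is.na(lambdas)))
    stop("ensembles must be a named list keyed by lambda values")
  rows <- list()
  for (k in seq_along(ensembles)) {
    ens <- ensembles[[k]]
    reports <- if (inherits(ens, "edr_ensemble")) ens$reports else ens
    for (p in properties) {
      target <- prop_vector(data_report, p)
      vals <- vapply(reports, function(r) {
        v <- prop_vector(r, p)
        if (length(v) != length(target))
          stop("binning mismatch for property '", p, "'")
        rmsd(target, v)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        lambda = lambdas[k], property = p, rmsd = mean(vals),
        rmsd_sd = stats::sd(vals))
    }
  }
  curves <- do.call(rbind, rows)
  argmin <- vapply(properties, function(p) {
    sub <- curves[curves$property == p, ]
    sub$lambda[which.min(sub$rmsd)]
  }, numeric(1))
  # Properties whose RMSD curve is identically zero carry no lambda
  # information (e.g. APL when every network has diameter 2, making APL a
  # deterministic function of M) and are dropped from the pooled curve.
  informative <- Filter(function(p) {
    mean(curves$rmsd[curves$property == p]) > 0
  }, properties)
  if (length(informative) == 0L) {
    # every curve identically zero: perfect agreement everywhere
    pooled <- data.frame(lambda = sort(lambdas), rmsd = 0)
    return(structure(list(curves = curves, argmin = argmin, pooled = pooled,
                          pooled_argmin = pooled$lambda[1L]),
                     class = "comparison_curve"))
  }
  pooled_mat <- sapply(informative, function(p) {
    sub <- curves[curves$property == p, ]
    sub <- sub[order(sub$lambda), ]
    sub$rmsd / mean(sub$rmsd)
  })
  pooled_mat <- matrix(pooled_mat, ncol = length(informative))
  pooled <- data.frame(lambda = sort(lambdas),
                       rmsd = rowMeans(pooled_mat))
  structure(list(curves = curves, argmin = argmin, pooled = pooled,
                 pooled_argmin = pooled$lambda[which.min(pooled$rmsd)]),
            class = "comparison_curve")
}

#' @export
print.comparison_curve <- function(x, ...) {
  cat("comparison_curve: per-property argmin lambda\n")
  print(x$argmin)
  cat(sprintf("pooled argmin lambda: %g\n", x$pooled_argmin))
  invisible(x)
}
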