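#' Generate a bilaterally symmetric synthetic region atlas
#'
#' Samples region (neuropil) centroids inside an axis-aligned ellipsoid with
#' mirror symmetry across the x = 0 midplane. Bilateral regions come in
#' `_L`/`_R` pairs that are exact mirror images; central regions sit on the
#' midplane (unsuffixed labels). Uniform sampling inside the ellipsoid yields
#' a unimodal, truncated-Gaussian-like pairwise-distance distribution, the
#' shape reported for real neuropil centroid distances.
#'
#' @param n_pairs Number of bilateral region pairs (>= 1).
#' @param n_central Number of midline regions (>= 0).
#' @param spatial_scale_mm Linear extent of the domain along x, in mm. The
#'   ellipsoid semi-axes are `spatial_scale_mm * c(0.5, 0.35, 0.25)`. The
#'   default 0.6 mm is a fly-brain-like extent.
#' @param seed Integer RNG seed; the same seed reproduces the atlas exactly.
#' @return An object of class `region_atlas`: a data.frame with columns
#'   `label`, `base`, `hemisphere` (`"L"`, `"R"` or `"C"`), and centroid
#'   coordinates `x`, `y`, `z` in mm.
#' @examples
#' atl <- make_atlas(n_pairs = 4, n_central = 1, seed = 1)
#' distance_matrix(atl)
#' @export
make_atlas <- function(n_pairs, n_central = 0, spatial_scale_mm = 0.6,
                       seed = 1L) {
  if (length(n_pairs) != 1L || is.na(n_pairs) || n_pairs < 1)
    stop("invalid atlas spec: n_pairs must be a positive count")
  if (length(n_central) != 1L || is.na(n_central) || n_central < 0)
    stop("invalid atlas spec: n_central must be a non-negative count")
  if (spatial_scale_mm <= 0)
    stop("invalid atlas spec: spatial_scale_mm must be positive")
  n_pairs <- as.integer(n_pairs)
  n_central <- as.integer(n_central)

  semi <- spatial_scale_mm * c(0.5, 0.35, 0.25)
  set.seed(as.integer(seed))

  # Rejection-sample points uniformly inside the unit ball, then scale by the
  # semi-axes. Bilateral seeds are constrained to x >= 4% of the semi-axis so
  # homotopic partners never coincide on the midplane.
  sample_ellipsoid <- function(n, x_min = 0) {
    out <- matrix(NA_real_, n, 3L)
    got <- 0L
    while (got < n) {
      m <- 4L * (n - got) + 16L
      p <- matrix(stats::runif(3L * m, -1, 1), m, 3L)
      keep <- rowSums(p^2) <= 1 & p[, 1L] >= x_min
      p <- p[keep, , drop = FALSE]
      take <- min(nrow(p), n - got)
      if (take > 0L) {
        out[(got + 1L):(got + take), ] <- p[seq_len(take), , drop = FALSE]
        got <- got + take
      }
    }
    sweep(out, 2L, semi, `*`)
  }

  right <- sample_ellipsoid(n_pairs, x_min = 0.04)
  left <- right
  left[, 1L] <- -left[, 1L]
  pieces <- list(
    data.frame(label = sprintf("R%d_L", seq_len(n_pairs) - 1L),
               base = sprintf("R%d", seq_len(n_pairs) - 1L),
               hemisphere = "L", x = left[, 1L], y = left[, 2L],
               z = left[, 3L], stringsAsFactors = FALSE),
    data.frame(label = sprintf("R%d_R", seq_len(n_pairs) - 1L),
               base = sprintf("R%d", seq_len(n_pairs) - 1L),
               hemisphere = "R", x = right[, 1L], y = right[, 2L],
               z = right[, 3L], stringsAsFactors = FALSE)
  )
  if (n_central > 0L) {
    ctr <- sample_ellipsoid(n_central)
    ctr[, 1L] <- 0
    pieces[[3L]] <- data.frame(
      label = sprintf("C%d", seq_len(n_central) - 1L),
      base = sprintf("C%d", seq_len(n_central) - 1L),
      hemisphere = "C", x = ctr[, 1L], y = ctr[, 2L], z = ctr[, 3L],
      stringsAsFactors = FALSE)
  }
  atlas <- do.call(rbind, pieces)
  rownames(atlas) <- NULL
  class(atlas) <- c("region_atlas", "data.frame")
  attr(atlas, "spatial_scale_mm") <- spatial_scale_mm
  attr(atlas, "seed") <- as.integer(seed)
  atlas
}

#' Euclidean distance matrix between region centroids
#'
#' @param atlas A `region_atlas` (or any data.frame with `label`, `x`, `y`,
#'   `z` columns in mm).
#' @return Symmetric N x N matrix of centroid distances in mm, zero diagonal,
#'   dimnames set to region labels. Coincident centroids for distinct labels
#'   are allowed but reported with a warning.
#' @export
distance_matrix <- function(atlas) {
  if (nrow(atlas) < 2L) stop("distance_matrix needs at least 2 regions")
  D <- as.matrix(stats::dist(as.matrix(atlas[, c("x", "y", "z")])))
  dimnames(D) <- list(atlas$label, atlas$label)
  if (any(D[upper.tri(D)] == 0))
    warning("coincident centroids: some off-diagonal distances are 0")
  D
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("region_atlas: %d regions (%d bilateral pairs, %d central)\n",
              nrow(x), sum(x$hemisphere == "L"), sum(x$hemisphere == "C")))
  NextMethod()
}
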