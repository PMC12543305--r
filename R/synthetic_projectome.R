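#' Generate a synthetic projectome with known hierarchy-driven asymmetry
#'
#' Wraps the EDR generator on the atlas's centroid distance matrix, then
#' imposes directional weight asymmetry along a ground-truth hierarchy:
#' for every reciprocally connected, non-homotopic region pair the weight of
#' the direction flowing toward the higher hierarchy score is multiplied by
#' `exp(+beta * dh)` and the opposite direction by `exp(-beta * dh)`
#' (`dh` = score difference), after which columns are renormalized.
#' Bilateral partners share a hierarchy score, so homotopic pairs receive a
#' bias factor of exactly 1 and stay symmetric apart from sampling noise.
#'
#' @param atlas A `region_atlas`.
#' @param truth A [synthetic_truth()]; the generator's decay rate defaults
#'   to `tortuosity_a * lambda_true_per_mm` (the Euclidean-length rate
#'   implied by the path-length rate and tortuosity).
#' @param M Target directed binary link count (<= N(N-1)).
#' @param beta Asymmetry bias strength (0 = no imposed bias).
#' @param lambda_per_mm Optional explicit generator rate overriding the
#'   default.
#' @param bin_width_mm Distance-bin width for the generator.
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return A `projectome` object with extra fields `hierarchy` (data.frame
#'   `label`, `base`, `score`), `beta`, `lambda_per_mm`, `seed`.
#' @export
make_projectome <- function(atlas, truth, M, beta = 0,
                            lambda_per_mm = NULL, bin_width_mm = NULL,
                            seed = truth$seed) {
  N <- nrow(atlas)
  if (M > N * (N - 1))
    stop("M exceeds the directed-pair capacity N(N-1)")
  if (is.null(lambda_per_mm))
    lambda_per_mm <- truth$tortuosity_a * truth$lambda_true_per_mm
  D <- distance_matrix(atlas)
  set.seed(as.integer(seed))
  bases <- unique(atlas$base)
  profile <- truth$asym_profile
  if (is.null(profile)) profile <- stats::runif(length(bases))
  if (length(profile) != length(bases))
    stop("asym_profile must have one score per region base name (",
         length(bases), ")")
  h <- profile[match(atlas$base, bases)]

  spec <- edr_spec(lambda_per_mm, M, bin_width_mm = bin_width_mm,
                   n_networks = 1L, seed = as.integer(seed))
  net <- edr_generate(D, spec)

  W <- net$counts * 1.0
  if (beta != 0) {
    dh <- outer(h, h, function(a, b) b - a)  # dh[i, j] = h_j - h_i
    recip <- net$counts > 0 & t(net$counts) > 0
    fac <- ifelse(recip, exp(beta * dh), 1)
    W <- W * fac
  }
  pj <- as_projectome(W)
  pj$hierarchy <- data.frame(label = atlas$label, base = atlas$base,
                             score = h, stringsAsFactors = FALSE)
  pj$beta <- beta
  pj$lambda_per_mm <- lambda_per_mm
  pj$seed <- as.integer(seed)
  pj
}
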