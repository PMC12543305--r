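#' Fit the exponential distance rule to a sample of cable lengths
#'
#' Builds a normalized length histogram at each requested bin size and fits
#' `log p` against the bin center by count-weighted least squares over the
#' bins from the modal bin upward that have nonzero counts; the decay rate
#' is minus the slope. The spread of the per-bin-size estimates is reported as
#' an interval, mirroring the bin-size sensitivity of reading a slope off a
#' log-scale histogram. (For an exponential law the bin mass is exactly
#' proportional to `exp(-lambda * center)`, so binning does not bias the
#' slope.)
#'
#' @param lengths_mm Positive sample of lengths in mm.
#' @param bin_sizes_mm Bin widths to try (default `c(0.01, 0.02, 0.05)` mm).
#' @param statistic Label recording which per-neuron length statistic the
#'   sample represents (`"min"` or `"mean"`); metadata only.
#' @return Object of class `edr_fit`: list with `lambda_per_mm` (mean of the
#'   per-bin-size estimates), `intercept_c`, `lambda_interval`
#'   (`[lambda_lo, lambda_hi]` spanning every per-bin-size fit), `per_bin_size`
#'   (data.frame), `statistic`, `n`.
#' @examples
#' set.seed(1)
#' fit_edr(rexp(5000, rate = 33))
#' @export
fit_edr <- function(lengths_mm, bin_sizes_mm = c(0.01, 0.02, 0.05),
                    statistic = c("min", "mean")) {
  statistic <- match.arg(statistic)
  x <- lengths_mm[is.finite(lengths_mm) & lengths_mm >= 0]
  if (length(x) < 2L) stop("need at least 2 finite lengths")
  if (diff(range(x)) == 0)
    stop("degenerate histogram: all lengths equal")
  fits <- lapply(bin_sizes_mm, function(h) {
    breaks <- seq(0, max(x) + h, by = h)
    cnt <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
    centers <- breaks[-1L] - h / 2
    modal <- which.max(cnt)
    keep <- seq_along(cnt) >= modal & cnt > 0L
    if (sum(keep) < 2L)
      stop("degenerate histogram: fewer than 2 nonempty bins at bin size ", h)
    p <- cnt[keep] / (length(x) * h)
    # weighted least squares with bin counts as weights: the sampling
    # variance of a log-count is ~1/count, so sparse far-tail bins (isolated
    # single counts that would otherwise flatten the slope) are downweighted
    fit <- stats::lm(log(p) ~ centers[keep], weights = cnt[keep])
    c(lambda = -unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]))
  })
  per <- data.frame(bin_size_mm = bin_sizes_mm,
                    lambda_per_mm = vapply(fits, `[[`, numeric(1), "lambda"),
                    intercept = vapply(fits, `[[`, numeric(1), "intercept"))
  structure(list(lambda_per_mm = mean(per$lambda_per_mm),
                 intercept_c = exp(mean(per$intercept)),
                 lambda_interval = range(per$lambda_per_mm),
                 per_bin_size = per,
                 statistic = statistic,
                 n = length(x)),
            class = "edr_fit")
}

#' @export
print.edr_fit <- function(x, ...) {
  cat(sprintf(
    "edr_fit (%s lengths, n = %d): lambda = %.2f mm^-1, interval [%.2f, %.2f]\n",
    x$statistic, x$n, x$lambda_per_mm,
    x$lambda_interval[1L], x$lambda_interval[2L]))
  invisible(x)
}

#' Maximum-likelihood exponential rate (cross-check)
#'
#' For an exponential law the MLE of the rate is simply `1 / mean(x)`;
#' offered as an independent cross-check of the histogram slope fit.
#'
#' @param lengths_mm Positive sample of lengths in mm.
#' @return Rate in mm^-1.
#' @export
fit_edr_mle <- function(lengths_mm) {
  x <- lengths_mm[is.finite(lengths_mm) & lengths_mm > 0]
  if (length(x) < 1L) stop("need at least 1 positive length")
  1 / mean(x)
}

#' Tortuosity scaling between path and Euclidean cable lengths
#'
#' Least-squares slope of cable length on Euclidean cable length through the
#' origin (zero straight-line separation must imply zero cable), plus the
#' Pearson correlation of the pairs.
#'
#' @param cable_mm,euclid_mm Equal-length paired samples, n >= 2.
#' @return List with `slope_a` and `pearson_r`.
#' @export
scaling_factor <- function(cable_mm, euclid_mm) {
  if (length(cable_mm) != length(euclid_mm))
    stop("paired samples must have equal length")
  if (length(cable_mm) < 2L) stop("need n >= 2 pairs")
  if (stats::sd(cable_mm) == 0 || stats::sd(euclid_mm) == 0)
    stop("undefined correlation: constant input")
  list(slope_a = sum(cable_mm * euclid_mm) / sum(euclid_mm^2),
       pearson_r = stats::cor(cable_mm, euclid_mm))
}
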