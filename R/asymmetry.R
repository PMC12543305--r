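#' Pairwise weight asymmetry
#'
#' Relative difference between the link weights in the two directions,
#' `|w_ij - w_ji| / (w_ij + w_ji)`. Ranges from 0 (perfectly symmetric) to 1
#' (unidirectional); symmetric in its arguments and invariant to scaling
#' both weights by the same positive constant.
#'
#' @param w_ij,w_ji Nonnegative weights (vectorized); each pair must have a
#'   positive sum.
#' @return Asymmetry value(s) in `[0, 1]`.
#' @export
asym <- function(w_ij, w_ji) {
  s <- w_ij + w_ji
  if (any(s <= 0)) stop("undefined pair: both weights zero")
  abs(w_ij - w_ji) / s
}

strip_side <- function(label) sub("_[LR]$", "", label)

side_tag <- function(label) {
  ifelse(endsWith(label, "_L"), "L",
         ifelse(endsWith(label, "_R"), "R", "C"))
}

#' Classify a region pair by hemispheric relation
#'
#' Labels follow the `_L`/`_R` suffix convention; unsuffixed labels are
#' central. Homotopic: same base name, opposite hemispheres. Ipsilateral:
#' same hemisphere tag (both L, both R, or both central). Contralateral:
#' opposite hemispheres with different base names. Pairs of a central and a
#' lateral region fit none of these and are classed `"unpaired"`.
#'
#' @param label_i,label_j Region labels (vectorized).
#' @return Character vector over `{"homotopic","ipsilateral","contralateral",
#'   "unpaired"}`.
#' @export
classify_pair <- function(label_i, label_j) {
  si <- side_tag(label_i)
  sj <- side_tag(label_j)
  bi <- strip_side(label_i)
  bj <- strip_side(label_j)
  opposite <- (si == "L" & sj == "R") | (si == "R" & sj == "L")
  ifelse(opposite & bi == bj, "homotopic",
         ifelse(si == sj, "ipsilateral",
                ifelse(opposite, "contralateral", "unpaired")))
}

# All unordered connected pairs of w with their ASYM values and pair class.
asym_pairs <- function(w, labels = rownames(w)) {
  if (is.null(labels)) labels <- sprintf("V%d", seq_len(nrow(w)))
  up <- which(upper.tri(w), arr.ind = TRUE)
  wij <- w[up]
  wji <- t(w)[upper.tri(w)]
  connected <- wij > 0 | wji > 0
  up <- up[connected, , drop = FALSE]
  wij <- wij[connected]
  wji <- wji[connected]
  data.frame(i = up[, 1L], j = up[, 2L],
             label_i = labels[up[, 1L]], label_j = labels[up[, 2L]],
             w_ij = wij, w_ji = wji,
             bidirectional = wij > 0 & wji > 0,
             asym = asym(wij, wji),
             pair_class = classify_pair(labels[up[, 1L]], labels[up[, 2L]]),
             stringsAsFactors = FALSE)
}

#' Distribution of pairwise weight asymmetries
#'
#' ASYM computed for every bidirectional pair (optionally restricted to one
#' hemispheric pair class), binned into a normalized histogram on `[0, 1]`.
#'
#' @param w Weight matrix with region labels as dimnames.
#' @param pair_class One of `"all"`, `"ipsilateral"`, `"contralateral"`,
#'   `"homotopic"`.
#' @param include_unidirectional Include one-way pairs (each contributing
#'   ASYM = 1)? Default `FALSE`, matching the bidirectional-only histogram
#'   convention.
#' @param n_bins Number of bins on `[0, 1]` (default 20).
#' @return List with `pairs` (data.frame of pair records), `breaks`,
#'   `proportions` (normalized histogram), `mean_asym`, `n_pairs`.
#' @export
asymmetry_distribution <- function(w, pair_class = c("all", "ipsilateral",
                                                     "contralateral",
                                                     "homotopic"),
                                   include_unidirectional = FALSE,
                                   n_bins = 20L) {
  pair_class <- match.arg(pair_class)
  pr <- asym_pairs(w)
  if (!include_unidirectional)
    pr <- pr[pr$bidirectional, , drop = FALSE]
  if (pair_class != "all")
    pr <- pr[pr$pair_class == pair_class, , drop = FALSE]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  if (nrow(pr) == 0L) {
    warning("no pairs in class '", pair_class, "'; empty histogram")
    props <- rep(0, n_bins)
  } else {
    props <- hist_proportions(pr$asym, breaks)
  }
  list(pairs = pr, breaks = breaks, proportions = props,
       mean_asym = if (nrow(pr)) mean(pr$asym) else NaN, n_pairs = nrow(pr))
}

#' Build the asymmetry network
#'
#' One directed link per connected unordered pair, oriented along the
#' predominant direction (`i -> j` iff `w_ij > w_ji`) and weighted by the
#' pair's ASYM value. Unidirectional pairs keep their direction with weight
#' 1; exact ties (`w_ij = w_ji > 0`) produce no link, as the weight would be
#' 0.
#'
#' @param w Weight matrix with region labels as dimnames.
#' @param include_unidirectional Include one-way pairs (default `TRUE`).
#' @return Object of class `asymmetry_network`: list with `edges`
#'   (data.frame `from`, `to`, `weight` using labels) and `labels`.
#' @export
build_asymmetry_network <- function(w, include_unidirectional = TRUE) {
  labels <- rownames(w)
  if (is.null(labels)) labels <- sprintf("V%d", seq_len(nrow(w)))
  pr <- asym_pairs(w, labels)
  if (!include_unidirectional)
    pr <- pr[pr$bidirectional, , drop = FALSE]
  pr <- pr[pr$asym > 0, , drop = FALSE]
  fwd <- pr$w_ij > pr$w_ji
  edges <- data.frame(
    from = ifelse(fwd, pr$label_i, pr$label_j),
    to = ifelse(fwd, pr$label_j, pr$label_i),
    weight = pr$asym, stringsAsFactors = FALSE)
  structure(list(edges = edges, labels = labels),
            class = "asymmetry_network")
}

#' Asymmetry in-/out-strengths and hierarchy ranking
#'
#' Sums of incident ASYM weights by direction in an asymmetry network.
#' Nodes with high asymmetry out-strength predominantly feed information
#' forward (bottom of the functional hierarchy, e.g. sensory input areas);
#' high in-strength marks higher-level integrative areas.
#'
#' @param net An [build_asymmetry_network()] result.
#' @return List with `strengths` (data.frame `label`, `in_strength`,
#'   `out_strength`) and `ranking` (labels sorted by descending
#'   out-strength, ties broken by label).
#' @export
asymmetry_strengths <- function(net) {
  labels <- net$labels
  out_s <- stats::setNames(numeric(length(labels)), labels)
  in_s <- out_s
  if (nrow(net$edges)) {
    agg_out <- tapply(net$edges$weight, net$edges$from, sum)
    agg_in <- tapply(net$edges$weight, net$edges$to, sum)
    out_s[names(agg_out)] <- agg_out
    in_s[names(agg_in)] <- agg_in
  }
  strengths <- data.frame(label = labels, in_strength = unname(in_s),
                          out_strength = unname(out_s),
                          stringsAsFactors = FALSE)
  ord <- order(-strengths$out_strength, strengths$label)
  list(strengths = strengths, ranking = strengths$label[ord])
}
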