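offdiag <- function(M) row(M) != col(M)

#' Link lengths l = -log w
#'
#' Converts transfer-probability weights into additive link lengths so that
#' products of probabilities along a path become sums: the shortest weighted
#' path then follows the most probable information route. Natural log is
#' used internally (shortest-path structure is base-invariant); display
#' histograms conventionally use log10 weights.
#'
#' @param w Weight matrix with entries in `[0, 1]`.
#' @return Matrix of lengths; absent links (w = 0) are `NA` (no length, not
#'   0 or Inf). Links with w = 1 get length 0 and their count is attached as
#'   attribute `"n_zero_length"`.
#' @export
link_lengths <- function(w) {
  if (any(w > 1)) stop("invalid weight: entries above 1")
  if (any(w < 0)) stop("invalid weight: negative entries")
  l <- matrix(NA_real_, nrow(w), ncol(w), dimnames = dimnames(w))
  pos <- w > 0
  l[pos] <- -log(w[pos])
  attr(l, "n_zero_length") <- sum(w == 1)
  l
}

graph_from_weights <- function(w) {
  N <- nrow(w)
  idx <- which(w > 0 & offdiag(w), arr.ind = TRUE)
  g <- igraph::make_empty_graph(N, directed = TRUE)
  if (nrow(idx))
    g <- igraph::add_edges(g, rbind(idx[, 1L], idx[, 2L]),
                           weight = -log(w[idx]))
  g
}

#' All-pairs weighted node distances (resistances)
#'
#' Shortest-path lengths on the `l = -log w` link lengths; the distance
#' r_ij measures how improbable the best information route from i to j is.
#'
#' @param w Weight matrix with entries in `[0, 1]`, zero meaning no link.
#' @return N x N matrix of distances (`Inf` for unreachable ordered pairs,
#'   0 on the diagonal).
#' @export
node_distances <- function(w) {
  g <- graph_from_weights(w)
  r <- igraph::distances(g, mode = "out",
                         weights = igraph::E(g)$weight)
  dimnames(r) <- dimnames(w)
  r
}

#' Global communication efficiency
#'
#' Mean inverse resistance ("conductance") over ordered pairs i != j.
#' Unreachable pairs contribute 0; pairs at distance exactly 0 (chains of
#' w = 1 links) are excluded from the mean and counted in attribute
#' `"n_zero_distance"`.
#'
#' @param w Weight matrix in `[0, 1]`.
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(w) {
  r <- node_distances(w)
  off <- r[offdiag(r)]
  zero <- off == 0
  denom <- length(off) - sum(zero)
  out <- if (denom == 0) 0 else sum(1 / off[!zero & is.finite(off)]) / denom
  attr(out, "n_zero_distance") <- sum(zero)
  out
}

#' Local communication efficiency
#'
#' For each node i with at least two neighbors (union of in- and
#' out-neighbors), the efficiency of communication among the neighbors once
#' node i and its links are removed: the mean inverse resistance r_{jk/i}
#' over ordered neighbor pairs, normalized by `k_i (k_i - 1)`. Nodes with
#' fewer than two neighbors contribute 0; the network value is the mean
#' over all nodes.
#'
#' @param w Weight matrix in `[0, 1]`.
#' @return Scalar efficiency.
#' @export
local_efficiency <- function(w) {
  N <- nrow(w)
  A <- (w > 0 & offdiag(w))
  eff <- numeric(N)
  for (i in seq_len(N)) {
    nb <- which(A[i, ] | A[, i])
    k <- length(nb)
    if (k < 2L) next
    sub <- w[-i, -i, drop = FALSE]
    r <- node_distances(sub)
    nb_idx <- match(nb, setdiff(seq_len(N), i))
    rr <- r[nb_idx, nb_idx, drop = FALSE]
    off <- rr[offdiag(rr)]
    good <- is.finite(off) & off > 0
    eff[i] <- sum(1 / off[good]) / (k * (k - 1))
  }
  mean(eff)
}

# Directed positive off-diagonal links ordered for deterministic removal:
# ascending (weight, source label, target label).
ordered_links <- function(w) {
  idx <- which(w > 0 & offdiag(w), arr.ind = TRUE)
  lab <- if (!is.null(rownames(w))) rownames(w) else
    sprintf("%04d", seq_len(nrow(w)))
  df <- data.frame(src = idx[, 1L], dst = idx[, 2L],
                   weight = w[idx], src_label = lab[idx[, 1L]],
                   dst_label = lab[idx[, 2L]], stringsAsFactors = FALSE)
  df[order(df$weight, df$src_label, df$dst_label), , drop = FALSE]
}

#' Efficiency as a function of density under ordered link removal
#'
#' Removes links one by one ordered by weight (weakest or strongest first;
#' ties broken by source then target label), without renormalizing the
#' surviving weights, and records global and local efficiency at each
#' requested density.
#'
#' @param w Weight matrix in `[0, 1]`.
#' @param order `"weakest_first"` or `"strongest_first"`.
#' @param density_grid Densities (fraction of N(N-1)) at which to record the
#'   efficiencies; points above the intact density are ignored. The intact
#'   network is always the first row.
#' @return data.frame with `density`, `n_links`, `global_eff`, `local_eff`.
#' @export
efficiency_vs_density <- function(w, order = c("weakest_first",
                                               "strongest_first"),
                                  density_grid = seq(0.8, 0.05, by = -0.05)) {
  order <- match.arg(order)
  N <- nrow(w)
  links <- ordered_links(w)
  if (order == "strongest_first")
    links <- links[rev(seq_len(nrow(links))), , drop = FALSE]
  M0 <- nrow(links)
  total <- N * (N - 1)
  targets <- sort(unique(c(M0, floor(density_grid * total))),
                  decreasing = TRUE)
  targets <- targets[targets <= M0 & targets >= 0]
  out <- data.frame(density = numeric(0), n_links = integer(0),
                    global_eff = numeric(0), local_eff = numeric(0))
  wk <- w
  removed <- 0L
  for (m in targets) {
    drop_n <- M0 - m - removed
    if (drop_n > 0L) {
      take <- links[(removed + 1L):(removed + drop_n), , drop = FALSE]
      wk[cbind(take$src, take$dst)] <- 0
      removed <- removed + drop_n
    }
    out <- rbind(out, data.frame(
      density = m / total, n_links = m,
      global_eff = as.numeric(global_efficiency(wk)),
      local_eff = local_efficiency(wk)))
  }
  rownames(out) <- NULL
  out
}

backbone_connected <- function(w, mode) {
  g <- graph_from_weights(w)
  igraph::is_connected(g, mode = if (mode == "strong") "strong" else "weak")
}

#' Extract the strong or weak backbone of a weighted network
#'
#' Greedily deletes the weakest remaining link whose removal preserves the
#' chosen connectivity mode (strong: directed paths both ways between every
#' pair; weak: connected ignoring directions), skipping links whose removal
#' would disconnect the network, until the target density is reached or no
#' link is removable. Because removing links can only destroy connectivity,
#' a link once skipped can never become removable, so a single ascending
#' pass suffices.
#'
#' @param w Weight matrix in `[0, 1]`.
#' @param mode `"strong"` or `"weak"`.
#' @param target_density Target fraction of N(N-1) directed links.
#' @return List with `w` (pruned weight matrix), `edges` (surviving link
#'   data.frame), `density`, and `mode`.
#' @export
extract_backbone <- function(w, mode = c("strong", "weak"), target_density) {
  mode <- match.arg(mode)
  N <- nrow(w)
  total <- N * (N - 1)
  if (!backbone_connected(w, mode))
    stop("intact network is not ", mode, "ly connected")
  links <- ordered_links(w)
  m <- nrow(links)
  target_m <- ceiling(target_density * total)
  wk <- w
  for (e in seq_len(nrow(links))) {
    if (m <= target_m) break
    i <- links$src[e]; j <- links$dst[e]
    saved <- wk[i, j]
    wk[i, j] <- 0
    if (backbone_connected(wk, mode)) {
      m <- m - 1L
    } else {
      wk[i, j] <- saved
    }
  }
  list(w = wk, edges = ordered_links(wk), density = m / total, mode = mode)
}
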