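#' Per-neuron synapse fractions by region
#'
#' The probabilistic information flow through one neuron: the fraction of
#' its postsynaptic points per region (incoming) and of its presynaptic
#' points per region (outgoing). Each vector sums to 1.
#'
#' @param neuron_rows Synapse-table rows of a single neuron (columns `role`
#'   in `{"pre","post"}` and `region`).
#' @param atlas A `region_atlas` supplying the region ordering.
#' @return List with `in_fraction` and `out_fraction`, named numeric vectors
#'   over all atlas regions.
#' @export
synapse_fractions <- function(neuron_rows, atlas) {
  unknown <- setdiff(unique(neuron_rows$region), atlas$label)
  if (length(unknown))
    stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  count_by <- function(rows) {
    v <- stats::setNames(numeric(nrow(atlas)), atlas$label)
    if (nrow(rows)) {
      tab <- table(rows$region)
      v[names(tab)] <- as.numeric(tab)
    }
    v
  }
  post <- count_by(neuron_rows[neuron_rows$role == "post", , drop = FALSE])
  pre <- count_by(neuron_rows[neuron_rows$role == "pre", , drop = FALSE])
  if (sum(post) == 0 || sum(pre) == 0)
    stop("neuron lacks synapses of one role; it contributes nothing")
  list(in_fraction = post / sum(post), out_fraction = pre / sum(pre))
}

#' Single-neuron flow matrix
#'
#' Outer product of the incoming and outgoing synapse-fraction vectors:
#' entry (i, j) is the probability of the neuron receiving in region i and
#' sending from region j, i.e. flow i -> j. Entries sum to 1.
#'
#' @param in_fraction,out_fraction Fraction vectors summing to 1.
#' @return N x N matrix.
#' @export
neuron_flow_matrix <- function(in_fraction, out_fraction) {
  stopifnot(abs(sum(in_fraction) - 1) < 1e-8,
            abs(sum(out_fraction) - 1) < 1e-8)
  outer(in_fraction, out_fraction)
}

#' Threshold neuron-to-neuron connections by synapse count
#'
#' Keeps connections supported by at least `min_synapses` synapses; weaker
#' detections are treated as prediction noise, following the five-synapse
#' convention of the connectome export.
#'
#' @param connections data.frame with a `count` column (plus any identifier
#'   columns).
#' @param min_synapses Minimum count (default 5, i.e. "more than four").
#' @return The kept rows.
#' @export
threshold_connections <- function(connections, min_synapses = 5L) {
  if (min_synapses < 1L) stop("min_synapses must be >= 1")
  connections[connections$count >= min_synapses, , drop = FALSE]
}

#' Column-normalize a nonnegative matrix
#'
#' Divides every column with positive sum by that sum; zero columns are left
#' zero and reported with a warning.
#'
#' @param W_raw Nonnegative matrix.
#' @return Matrix whose nonzero columns sum to 1.
#' @export
column_normalize <- function(W_raw) {
  if (any(W_raw < 0)) stop("invalid matrix: negative entries")
  cs <- colSums(W_raw)
  zero <- cs == 0
  if (any(zero))
    warning(sum(zero), " zero column(s) left unnormalized")
  cs[zero] <- 1
  sweep(W_raw, 2L, cs, `/`)
}

#' Build the region-level projectome from a synapse table
#'
#' Sums per-neuron flow matrices (outer products of incoming and outgoing
#' synapse fractions) over all neurons classed `"intrinsic"`, then
#' column-normalizes, so that `w[i, j]` is the probability of information
#' from region i flowing to region j.
#'
#' @param synapses Synapse table (`neuron_id`, `role`, `region`).
#' @param classes Class table (`neuron_id`, `class`); only `"intrinsic"`
#'   neurons contribute.
#' @param atlas A `region_atlas`.
#' @param include_diagonal Diagonal (within-region flow) policy:
#'   `"normalize-only"` (default: diagonal mass participates in column sums
#'   but the diagonal is excluded from `A` and the link count `M`),
#'   `"drop"` (zeroed before normalization), or `"keep"` (also counted in
#'   `A`/`M`).
#' @return Object of class `projectome`: list with `labels`, `W_raw`, `w`,
#'   `A` (binary adjacency), `M` (directed link count), `n_neurons`.
#' @export
build_projectome <- function(synapses, classes, atlas,
                             include_diagonal = c("normalize-only", "drop",
                                                  "keep")) {
  include_diagonal <- match.arg(include_diagonal)
  intrinsic <- classes$neuron_id[classes$class == "intrinsic"]
  syn <- synapses[synapses$neuron_id %in% intrinsic, , drop = FALSE]
  ids <- unique(syn$neuron_id)
  if (length(ids) == 0L) stop("empty projectome: no intrinsic neurons")
  N <- nrow(atlas)
  W <- matrix(0, N, N, dimnames = list(atlas$label, atlas$label))
  n_used <- 0L
  for (id in ids) {
    rows <- syn[syn$neuron_id == id, , drop = FALSE]
    fr <- tryCatch(synapse_fractions(rows, atlas), error = function(e) e)
    if (inherits(fr, "error")) {
      if (grepl("unknown region", conditionMessage(fr))) stop(fr)
      warning("neuron ", id, " skipped: ", conditionMessage(fr))
      next
    }
    W <- W + neuron_flow_matrix(fr$in_fraction, fr$out_fraction)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("empty projectome: no usable intrinsic neurons")
  as_projectome(W, include_diagonal = include_diagonal, n_neurons = n_used)
}

#' Wrap a raw weight matrix as a projectome
#'
#' @param W_raw Nonnegative labeled N x N matrix of summed flow.
#' @param include_diagonal See [build_projectome()].
#' @param n_neurons Optional count of contributing neurons (metadata).
#' @return `projectome` object.
#' @export
as_projectome <- function(W_raw, include_diagonal = "normalize-only",
                          n_neurons = NA_integer_) {
  if (include_diagonal == "drop") diag(W_raw) <- 0
  w <- suppressWarnings(column_normalize(W_raw))
  A <- (w > 0) * 1L
  if (include_diagonal != "keep") diag(A) <- 0L
  structure(list(labels = colnames(W_raw), W_raw = W_raw, w = w, A = A,
                 M = sum(A), n_neurons = n_neurons,
                 include_diagonal = include_diagonal),
            class = "projectome")
}

#' @export
print.projectome <- function(x, ...) {
  N <- length(x$labels)
  cat(sprintf(
    "projectome: %d regions, M = %d directed links (density %.1f%%)\n",
    N, x$M, 100 * x$M / (N * (N - 1))))
  invisible(x)
}

#' Binary link density as a percentage
#'
#' `100 * M / (N * (N - 1))` for a directed graph without self-loops.
#'
#' @param A Binary adjacency matrix (or a `projectome`).
#' @return Density in percent.
#' @export
network_density <- function(A) {
  if (inherits(A, "projectome")) A <- A$A
  N <- nrow(A)
  100 * sum(A != 0) / (N * (N - 1))
}
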