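check_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("adjacency must be a square matrix")
  if (any(diag(A) != 0)) stop("adjacency rejected: nonzero diagonal")
  (A != 0) * 1L
}

graph_from_adjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "directed")
}

#' Sorted in-/out-degree spectra
#'
#' @param A Square binary adjacency matrix with zero diagonal (entry
#'   `A[i, j] = 1` means a link i -> j).
#' @return List with `in_degree` and `out_degree`, each sorted
#'   non-increasing.
#' @export
degree_spectra <- function(A) {
  A <- check_adjacency(A)
  list(in_degree = sort(colSums(A), decreasing = TRUE),
       out_degree = sort(rowSums(A), decreasing = TRUE))
}

#' Counts of uni- and bidirectional region pairs
#'
#' @param A Binary adjacency matrix, zero diagonal.
#' @return Named vector `c(unidirectional, bidirectional)` over unordered
#'   pairs.
#' @export
reciprocity_counts <- function(A) {
  A <- check_adjacency(A)
  up <- upper.tri(A)
  both <- (A == 1 & t(A) == 1)[up]
  any_ <- (A == 1 | t(A) == 1)[up]
  c(unidirectional = sum(any_) - sum(both), bidirectional = sum(both))
}

#' Average binary (hop-count) path length
#'
#' Mean directed hop distance over ordered pairs i != j with a finite
#' distance; the number of unreachable ordered pairs is attached as
#' attribute `"n_unreachable"`.
#'
#' @param A Binary adjacency matrix, zero diagonal.
#' @return Scalar APL (NaN if no pair is reachable).
#' @export
average_binary_path_length <- function(A) {
  A <- check_adjacency(A)
  dm <- igraph::distances(graph_from_adjacency(A), mode = "out")
  off <- dm[row(dm) != col(dm)]
  out <- mean(off[is.finite(off)])
  attr(out, "n_unreachable") <- sum(is.infinite(off))
  out
}

#' Directed clustering coefficient
#'
#' Per node, the neighborhood is the union of in- and out-neighbors with
#' size k; the node coefficient is the number of directed links among the
#' neighbors divided by `k (k - 1)` (the probability that two neighbors are
#' connected); nodes with k < 2 contribute 0. The network value is the mean
#' over all nodes.
#'
#' @param A Binary adjacency matrix, zero diagonal.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(A) {
  A <- check_adjacency(A)
  N <- nrow(A)
  cc <- numeric(N)
  for (i in seq_len(N)) {
    nb <- which(A[i, ] == 1L | A[, i] == 1L)
    k <- length(nb)
    if (k >= 2L)
      cc[i] <- sum(A[nb, nb]) / (k * (k - 1))
  }
  mean(cc)
}

# Canonical form of a 3-node digraph code under label permutation. Codes are
# 6-bit integers over the ordered node pairs (1,2),(2,1),(1,3),(3,1),(2,3),
# (3,2); the canonical representative is the orbit minimum.
triad_code_bits <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 3L), c(3L, 1L),
                         c(2L, 3L), c(3L, 2L))

triad_canonical_map <- function() {
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  pair_index <- matrix(0L, 3L, 3L)
  for (b in seq_len(6L))
    pair_index[triad_code_bits[b, 1L], triad_code_bits[b, 2L]] <- b
  canon <- integer(64L)
  for (code in 0:63) {
    bits <- as.integer(intToBits(code))[1:6]
    orbit <- vapply(perms, function(p) {
      newbits <- integer(6L)
      for (b in seq_len(6L)) {
        i <- p[triad_code_bits[b, 1L]]
        j <- p[triad_code_bits[b, 2L]]
        newbits[pair_index[i, j]] <- bits[b]
      }
      sum(newbits * 2L^(0:5))
    }, numeric(1))
    canon[code + 1L] <- min(orbit)
  }
  canon
}

#' Isomorphism classes of 3-node digraphs
#'
#' Enumerates all 64 labeled 3-node digraphs and groups them by directed
#' isomorphism (label permutation). There are exactly 16 classes.
#'
#' @return List with `n_classes`, `canonical` (length-64 map from edge code
#'   to canonical code), and `class_id` (length-64 map to class index 1..16
#'   ordered by canonical code).
#' @export
triad_classes <- function() {
  canon <- triad_canonical_map()
  reps <- sort(unique(canon))
  list(n_classes = length(reps), canonical = canon,
       class_id = match(canon, reps))
}

#' Directed triad census (16 classes)
#'
#' Classifies every unordered node triple into one of the 16 directed
#' 3-node configurations. Counts are returned in the standard census order
#' 003, 012, 102, 021D, 021U, 021C, 111D, 111U, 030T, 030C, 201, 120D,
#' 120U, 120C, 210, 300 and sum to `choose(N, 3)`.
#'
#' @param A Binary adjacency matrix, zero diagonal.
#' @return Named numeric vector of 16 counts.
#' @export
triad_census <- function(A) {
  A <- check_adjacency(A)
  cls <- c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
           "030T", "030C", "201", "120D", "120U", "120C", "210", "300")
  out <- igraph::triad_census(graph_from_adjacency(A))
  stats::setNames(as.numeric(out), cls)
}

#' Clique counts on the reciprocal (bidirectional) graph
#'
#' A directed k-clique requires links in both directions between every node
#' pair, so cliques are counted on the undirected graph of bidirectional
#' pairs. Counts are of *all* complete subgraphs of each requested size (not
#' only maximal ones); maximal-clique counts and the maximum-clique summary
#' are also returned.
#'
#' @param A Binary adjacency matrix, zero diagonal.
#' @param sizes Integer clique sizes to count.
#' @return List with `counts` (named by size; sizes above N count 0),
#'   `max_size`, `n_max_cliques`, and `max_clique_nodes` (union of member
#'   node indices of all maximum cliques).
#' @export
clique_counts <- function(A, sizes = 3:8) {
  A <- check_adjacency(A)
  N <- nrow(A)
  B <- (A == 1L & t(A) == 1L) * 1L
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  counts <- vapply(sizes, function(s) {
    if (s > N) return(0)
    if (s == 1L) return(as.numeric(N))
    if (s == 2L) return(as.numeric(igraph::ecount(g)))
    length(igraph::cliques(g, min = s, max = s))
  }, numeric(1))
  if (igraph::ecount(g) == 0L) {
    max_size <- 1L
    n_max <- N
    members <- seq_len(N)
  } else {
    lc <- igraph::largest_cliques(g)
    max_size <- length(lc[[1L]])
    n_max <- length(lc)
    members <- sort(unique(unlist(lapply(lc, as.integer))))
  }
  list(counts = stats::setNames(counts, sizes), max_size = max_size,
       n_max_cliques = n_max, max_clique_nodes = members)
}

#' Root-mean-square deviation between two equal-length vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmsd <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch in rmsd")
  if (length(x) < 1L) stop("rmsd needs n >= 1")
  sqrt(mean((x - y)^2))
}
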