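# Brute-force reference implementations, independent of the package's
# (igraph-backed) code paths. Kept deliberately naive.

random_digraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(A) <- 0L
  A
}

random_weight_matrix <- function(n, p, seed) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n) * (stats::runif(n * n) < p), n, n)
  diag(w) <- 0
  w * 0.9  # keep strictly below 1
}

oracle_degrees <- function(A) {
  n <- nrow(A)
  ink <- outk <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (A[i, j] != 0) {
      outk[i] <- outk[i] + 1L
      ink[j] <- ink[j] + 1L
    }
  }
  list(in_degree = sort(ink, decreasing = TRUE),
       out_degree = sort(outk, decreasing = TRUE))
}

oracle_reciprocity <- function(A) {
  uni <- bi <- 0L
  n <- nrow(A)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    f <- A[i, j] != 0; b <- A[j, i] != 0
    if (f && b) bi <- bi + 1L else if (f || b) uni <- uni + 1L
  }
  c(unidirectional = uni, bidirectional = bi)
}

# hop distances by hand-rolled BFS from every source
oracle_hop_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in which(A[v, ] != 0)) {
        if (is.infinite(D[s, u])) {
          D[s, u] <- D[s, v] + 1
          queue <- c(queue, u)
        }
      }
    }
  }
  D
}

oracle_apl <- function(A) {
  D <- oracle_hop_distances(A)
  off <- D[row(D) != col(D)]
  list(apl = mean(off[is.finite(off)]), n_unreachable = sum(is.infinite(off)))
}

oracle_cc <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n))
      if (j != i && (A[i, j] != 0 || A[j, i] != 0)) nb <- c(nb, j)
    k <- length(nb)
    if (k < 2L) next
    links <- 0L
    for (j in nb) for (l in nb) if (j != l && A[j, l] != 0) links <- links + 1L
    cc[i] <- links / (k * (k - 1))
  }
  mean(cc)
}

# 3-node digraph code over pairs (1,2),(2,1),(1,3),(3,1),(2,3),(3,2)
oracle_triad_code <- function(A3) {
  bits <- c(A3[1, 2], A3[2, 1], A3[1, 3], A3[3, 1], A3[2, 3], A3[3, 2])
  sum(bits * 2^(0:5))
}

# Map each canonical triad code to the igraph census slot using the 64
# single-triad graphs; also asserts igraph's grouping coincides with the
# package's own permutation-orbit enumeration.
oracle_triad_slot_map <- function() {
  cls <- triad_classes()
  slot_of_code <- integer(64)
  for (code in 0:63) {
    bits <- as.integer(intToBits(code))[1:6]
    A3 <- matrix(0L, 3, 3)
    A3[rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))] <- bits
    slot_of_code[code + 1] <- which(as.numeric(
      igraph::triad_census(igraph::graph_from_adjacency_matrix(
        A3, mode = "directed"))) == 1)
  }
  # codes in the same orbit must land in the same igraph slot, and the 16
  # orbits must cover 16 distinct slots
  stopifnot(all(tapply(slot_of_code, cls$class_id,
                       function(v) length(unique(v))) == 1L),
            length(unique(slot_of_code)) == 16L)
  slot_of_code
}

oracle_triad_census <- function(A, slot_map = oracle_triad_slot_map()) {
  cls <- triad_classes()
  n <- nrow(A)
  out <- numeric(16)
  if (n >= 3) {
    combs <- utils::combn(n, 3)
    for (c_i in seq_len(ncol(combs))) {
      tri <- combs[, c_i]
      code <- oracle_triad_code(A[tri, tri])
      out[slot_map[code + 1]] <- out[slot_map[code + 1]] + 1
    }
  }
  out
}

oracle_clique_counts <- function(A, sizes) {
  n <- nrow(A)
  B <- (A != 0 & t(A) != 0)
  vapply(sizes, function(s) {
    if (s > n) return(0)
    if (s == 1) return(as.numeric(n))
    combs <- utils::combn(n, s)
    cnt <- 0
    for (c_i in seq_len(ncol(combs))) {
      sub <- B[combs[, c_i], combs[, c_i]]
      if (all(sub[upper.tri(sub)])) cnt <- cnt + 1
    }
    cnt
  }, numeric(1))
}

# weighted shortest paths by exhaustive simple-path enumeration (N <= 8)
oracle_node_distances <- function(w) {
  n <- nrow(w)
  l <- matrix(Inf, n, n)
  pos <- w > 0 & row(w) != col(w)
  l[pos] <- -log(w[pos])
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  extend <- function(path, cost, target) {
    v <- path[length(path)]
    if (v == target) {
      if (cost < best[path[1L], target])
        best[path[1L], target] <<- cost
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (!is.infinite(l[v, u]) && !(u %in% path))
        extend(c(path, u), cost + l[v, u], target)
    }
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t) extend(s, 0, t)
  }
  best
}

oracle_global_efficiency <- function(w) {
  r <- oracle_node_distances(w)
  off <- r[row(r) != col(r)]
  zero <- off == 0
  denom <- length(off) - sum(zero)
  if (denom == 0) return(0)
  sum(1 / off[!zero & is.finite(off)]) / denom
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  A <- w > 0 & row(w) != col(w)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] | A[, i])
    k <- length(nb)
    if (k < 2) next
    sub <- w[-i, -i, drop = FALSE]
    r <- oracle_node_distances(sub)
    map <- match(nb, setdiff(seq_len(n), i))
    tot <- 0
    for (a in map) for (b in map) {
      if (a != b && is.finite(r[a, b]) && r[a, b] > 0)
        tot <- tot + 1 / r[a, b]
    }
    eff[i] <- tot / (k * (k - 1))
  }
  mean(eff)
}

# small Dijkstra on an undirected tree from the root, for path lengths
oracle_root_distances <- function(tree) {
  n <- nrow(tree$nodes)
  adj <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (p > 0) {
      d <- sqrt(sum((tree$nodes[i, ] - tree$nodes[p, ])^2))
      adj[i, p] <- adj[p, i] <- d
    }
  }
  dist <- rep(Inf, n)
  root <- which(tree$parent == 0L)
  dist[root] <- 0
  visited <- rep(FALSE, n)
  for (step in seq_len(n)) {
    u <- which(!visited)[which.min(dist[!visited])]
    visited[u] <- TRUE
    for (v in which(is.finite(adj[u, ]))) {
      if (dist[u] + adj[u, v] < dist[v]) dist[v] <- dist[u] + adj[u, v]
    }
  }
  dist
}
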