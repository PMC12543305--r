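complete_digraph <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}
cycle_digraph <- function(n) {
  A <- matrix(0L, n, n)
  A[cbind(seq_len(n), c(2:n, 1L))] <- 1L
  A
}

test_that("degree spectra match hand cases and the brute-force oracle", {
  ds <- degree_spectra(complete_digraph(4))
  expect_equal(unname(ds$in_degree), rep(3, 4))
  expect_equal(unname(ds$out_degree), rep(3, 4))
  dc <- degree_spectra(cycle_digraph(3))
  expect_equal(unname(dc$in_degree), rep(1, 3))
  for (s in 1:5) {
    A <- random_digraph(12, 0.3, s)
    o <- oracle_degrees(A)
    d <- degree_spectra(A)
    expect_equal(unname(d$in_degree), o$in_degree)
    expect_equal(unname(d$out_degree), o$out_degree)
  }
  Abad <- complete_digraph(3); diag(Abad) <- 1L
  expect_error(degree_spectra(Abad), "diagonal")
})

test_that("reciprocity counts match hand cases and the pair-scan oracle", {
  expect_equal(reciprocity_counts(complete_digraph(3)),
               c(unidirectional = 0L, bidirectional = 3L))
  expect_equal(reciprocity_counts(cycle_digraph(3)),
               c(unidirectional = 3L, bidirectional = 0L))
  for (s in 1:5) {
    A <- random_digraph(10, 0.4, s + 10)
    expect_equal(reciprocity_counts(A), oracle_reciprocity(A))
  }
})

test_that("average binary path length matches hand cases and BFS oracle", {
  expect_equal(as.numeric(average_binary_path_length(complete_digraph(4))), 1)
  expect_equal(as.numeric(average_binary_path_length(cycle_digraph(3))), 1.5)
  for (s in 1:5) {
    A <- random_digraph(9, 0.25, s + 20)
    got <- average_binary_path_length(A)
    want <- oracle_apl(A)
    expect_equal(as.numeric(got), want$apl)
    expect_equal(attr(got, "n_unreachable"), want$n_unreachable)
  }
})

test_that("clustering coefficient matches hand cases and triple-loop oracle", {
  expect_equal(clustering_coefficient(complete_digraph(5)), 1)
  star <- matrix(0L, 5, 5); star[1, 2:5] <- 1L
  expect_equal(clustering_coefficient(star), 0)
  for (s in 1:5) {
    A <- random_digraph(10, 0.3, s + 30)
    expect_equal(clustering_coefficient(A), oracle_cc(A))
  }
})

test_that("the 64 labeled 3-node digraphs group into exactly 16 classes", {
  cls <- triad_classes()
  expect_equal(cls$n_classes, 16L)
  expect_equal(length(unique(cls$class_id)), 16L)
  expect_equal(length(cls$canonical), 64L)
})

test_that("triad census matches the permutation-orbit oracle and conserves triples", {
  slot_map <- oracle_triad_slot_map()
  empty <- matrix(0L, 5, 5)
  cen <- triad_census(empty)
  expect_equal(unname(cen["003"]), 10)
  expect_equal(sum(cen), choose(5, 3))
  for (s in 1:5) {
    A <- random_digraph(8, 0.35, s + 40)
    got <- triad_census(A)
    expect_equal(unname(got), oracle_triad_census(A, slot_map))
    expect_equal(sum(got), choose(8, 3))
  }
})

test_that("clique counts match hand cases and exhaustive enumeration", {
  cc5 <- clique_counts(complete_digraph(5), sizes = 3)
  expect_equal(unname(cc5$counts), choose(5, 3))
  expect_equal(cc5$max_size, 5L)
  norec <- cycle_digraph(4)
  ccn <- clique_counts(norec, sizes = 2:4)
  expect_equal(unname(ccn$counts), c(0, 0, 0))
  for (s in 1:4) {
    A <- random_digraph(11, 0.5, s + 50)
    got <- clique_counts(A, sizes = 3:5)
    expect_equal(unname(got$counts), oracle_clique_counts(A, 3:5))
    # size-2 cliques are exactly the bidirectional pairs
    got2 <- clique_counts(A, sizes = 2)
    expect_equal(unname(got2$counts),
                 unname(reciprocity_counts(A)["bidirectional"]))
  }
  expect_equal(unname(clique_counts(complete_digraph(3), sizes = 7)$counts), 0)
})

test_that("rmsd follows its formula", {
  expect_equal(rmsd(1:5, 1:5), 0)
  expect_equal(rmsd(c(0, 0), c(3, 4)), sqrt(25 / 2))
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(rmsd(x, y), sqrt(mean((x - y)^2)))
  expect_error(rmsd(1:3, 1:4), "mismatch")
})

test_that("link lengths are -log w with boundary flags and additivity", {
  w <- labelled(rbind(c(0, exp(-1)), c(1, 0)))
  l <- link_lengths(w)
  expect_equal(l[1, 2], 1)
  expect_equal(l[2, 1], 0)
  expect_equal(attr(l, "n_zero_length"), 1L)
  expect_true(is.na(l[1, 1]))
  expect_error(link_lengths(matrix(1.5, 2, 2)), "above 1")
  # additivity: l(w1 w2) = l(w1) + l(w2)
  expect_equal(-log(0.3 * 0.2), -log(0.3) + -log(0.2))
})

test_that("node distances choose the most probable route", {
  w2 <- labelled(rbind(c(0, 0.1), c(0.1, 0)))
  r2 <- node_distances(w2)
  expect_equal(r2[1, 2], -log(0.1))
  expect_equal(r2[2, 1], -log(0.1))
  # indirect route with higher product probability wins
  w3 <- labelled(rbind(c(0, 0.2, 0.01),
                       c(0, 0, 0.2),
                       c(0, 0, 0)))
  r3 <- node_distances(w3)
  expect_equal(r3[1, 3], -log(0.04))
  for (s in 1:4) {
    w <- random_weight_matrix(7, 0.4, s + 60)
    expect_equal(node_distances(w), oracle_node_distances(w),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("global efficiency averages inverse resistance", {
  w2 <- labelled(rbind(c(0, 0.1), c(0.1, 0)))
  expect_equal(as.numeric(global_efficiency(w2)), 1 / (-log(0.1)))
  expect_equal(as.numeric(global_efficiency(matrix(0, 3, 3))), 0)
  for (s in 1:4) {
    w <- random_weight_matrix(7, 0.4, s + 70)
    expect_equal(as.numeric(global_efficiency(w)),
                 oracle_global_efficiency(w), tolerance = 1e-10)
  }
})

test_that("local efficiency matches the remove-and-measure oracle", {
  # reciprocal triangle, all weights 0.1
  w3 <- labelled(matrix(0.1, 3, 3)); diag(w3) <- 0
  expect_equal(local_efficiency(w3), 1 / (-log(0.1)))
  star <- labelled(matrix(0, 4, 4)); star[1, 2:4] <- 0.5
  expect_equal(local_efficiency(star), 0)
  for (s in 1:3) {
    w <- random_weight_matrix(7, 0.45, s + 80)
    expect_equal(local_efficiency(w), oracle_local_efficiency(w),
                 tolerance = 1e-10)
  }
})

test_that("uniform weight scaling shifts distances by hops times -log c", {
  # directed path 1 -> 2 -> 3 -> 4 with known hop counts
  w <- matrix(0, 4, 4)
  w[cbind(1:3, 2:4)] <- c(0.5, 0.4, 0.3)
  r1 <- node_distances(w)
  cfac <- 0.6
  r2 <- node_distances(w * cfac)
  hops <- rbind(c(0, 1, 2, 3), c(Inf, 0, 1, 2),
                c(Inf, Inf, 0, 1), c(Inf, Inf, Inf, 0))
  fin <- is.finite(hops) & hops > 0
  expect_equal(r2[fin], r1[fin] - log(cfac) * hops[fin])
})

test_that("efficiencies are invariant under node relabeling", {
  w <- random_weight_matrix(8, 0.5, 91)
  perm <- sample(8)
  wp <- w[perm, perm]
  expect_equal(as.numeric(global_efficiency(w)),
               as.numeric(global_efficiency(wp)))
  expect_equal(local_efficiency(w), local_efficiency(wp))
})

test_that("property suite agrees with oracles on all 4-node digraphs", {
  # exhaustive over the 4096 labeled digraphs on 4 nodes for the cheap
  # binary properties; oracle parity on every one
  slot_map <- oracle_triad_slot_map()
  idx <- which(row(matrix(0, 4, 4)) != col(matrix(0, 4, 4)))
  mismatch <- 0L
  for (code in 0:4095) {
    A <- matrix(0L, 4, 4)
    A[idx] <- as.integer(intToBits(code))[1:12]
    ok <- isTRUE(all.equal(as.numeric(average_binary_path_length(A)),
                           oracle_apl(A)$apl)) &&
      isTRUE(all.equal(clustering_coefficient(A), oracle_cc(A))) &&
      identical(unname(reciprocity_counts(A)),
                unname(oracle_reciprocity(A))) &&
      isTRUE(all.equal(unname(triad_census(A)),
                       oracle_triad_census(A, slot_map)))
    if (!ok) mismatch <- mismatch + 1L
  }
  expect_equal(mismatch, 0L)
})

test_that("property suite agrees with oracles on sampled 5-node digraphs", {
  slot_map <- oracle_triad_slot_map()
  set.seed(123)
  for (rep in 1:150) {
    A <- random_digraph(5, runif(1, 0.1, 0.9), seed = 5000 + rep)
    expect_equal(as.numeric(average_binary_path_length(A)),
                 oracle_apl(A)$apl)
    expect_equal(clustering_coefficient(A), oracle_cc(A))
    expect_equal(unname(triad_census(A)),
                 oracle_triad_census(A, slot_map))
    expect_equal(unname(clique_counts(A, 3:5)$counts),
                 oracle_clique_counts(A, 3:5))
  }
})
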