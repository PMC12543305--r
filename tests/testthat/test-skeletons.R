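test_that("path length to a node sums edge lengths along the root path", {
  tr <- chain_tree()
  expect_equal(path_length_to_node(tr, 3L), 0.3)
  expect_equal(path_length_to_node(tr, 1L), 0)
  expect_error(path_length_to_node(tr, 9L), "unknown node")
})

test_that("root-path lengths agree with a Dijkstra oracle on random trees", {
  for (seed in 1:5) {
    tr <- random_tree(50, seed)
    d_oracle <- oracle_root_distances(tr)
    d_pkg <- vapply(seq_len(50), function(i) path_length_to_node(tr, i),
                    numeric(1))
    expect_equal(d_pkg, d_oracle, tolerance = 1e-12)
  }
})

test_that("measure_neuron reproduces the hand-computed toy cable", {
  rec <- measure_neuron(toy_branched_tree())
  expect_equal(rec$post_min_mm, 0.08)
  expect_equal(rec$pre_min_mm, 0.30)
  expect_equal(rec$cable_mm, 0.28)
})

test_that("coincident closest pre and post give zero cable", {
  tr <- skeleton_tree(rbind(c(0, 0, 0), c(0.1, 0, 0)),
                      parent = c(0L, 1L), presyn = 2L, postsyn = 2L)
  rec <- measure_neuron(tr)
  expect_equal(rec$cable_mm, 0)
  expect_equal(rec$euclid_mm, 0)
})

test_that("missing synaptic points raise errors naming the empty set", {
  tr <- skeleton_tree(rbind(c(0, 0, 0), c(0.1, 0, 0)),
                      parent = c(0L, 1L), presyn = integer(), postsyn = 2L)
  expect_error(measure_neuron(tr), "presynaptic")
  tr2 <- skeleton_tree(rbind(c(0, 0, 0), c(0.1, 0, 0)),
                       parent = c(0L, 1L), presyn = 2L, postsyn = integer())
  expect_error(measure_neuron(tr2), "postsynaptic")
})

test_that("measured cable and Euclidean lengths equal the generator's truth", {
  atl <- small_atlas()
  truth <- synthetic_truth(25, 1.5, seed = 5)
  sk <- make_skeletons(atl, truth, 300, seed = 11)
  rec <- measure_skeletons(sk$skeletons)
  expect_equal(rec$cable_mm, sk$truth_table$cable_true_mm, tolerance = 1e-9)
  expect_equal(rec$euclid_mm, sk$truth_table$euclid_true_mm,
               tolerance = 1e-9)
  # triangle inequality on the tree path
  expect_true(all(rec$cable_mm >= rec$euclid_mm - 1e-12))
  expect_true(all(rec$hemi_class %in% c("intra", "inter")))
  expect_true(all(rec$pre_min_mm <= rec$pre_mean_mm))
  expect_true(all(rec$post_min_mm <= rec$post_mean_mm))
})

test_that("unit tortuosity without jitter makes cable equal Euclidean", {
  atl <- small_atlas()
  truth <- synthetic_truth(25, 1, seed = 5)
  sk <- make_skeletons(atl, truth, 20, jitter_rel = 0, seed = 2)
  rec <- measure_skeletons(sk$skeletons)
  expect_equal(rec$cable_mm, rec$euclid_mm, tolerance = 1e-9)
})

test_that("skeleton generation is seed-deterministic and trees are valid", {
  atl <- small_atlas()
  truth <- synthetic_truth(30, 1.4, seed = 5)
  s1 <- make_skeletons(atl, truth, 10, seed = 7)
  s2 <- make_skeletons(atl, truth, 10, seed = 7)
  expect_identical(s1, s2)
  for (tr in s1$skeletons) {
    # connected & acyclic: |edges| = |nodes| - 1 with parents preceding
    expect_equal(sum(tr$parent > 0L), nrow(tr$nodes) - 1L)
    expect_gte(length(tr$presyn), 1L)
    expect_gte(length(tr$postsyn), 1L)
  }
})

test_that("arbor-consistency filter applies the threshold rule", {
  rec <- data.frame(neuron_id = c("a", "b", "c"),
                    pre_min_mm = c(0.1, 0.1, 0.1),
                    pre_mean_mm = c(0.3, 0.1, 0.12),
                    post_min_mm = c(0.1, 0.1, 0.1),
                    post_mean_mm = c(0.1, 0.1, 0.3))
  out <- arbor_consistency_filter(rec, threshold_mm = 0.15)
  # 0.2 mm pre difference exceeds the 0.15 mm threshold; zero difference kept
  expect_equal(out$kept, c(FALSE, TRUE, FALSE))
  expect_equal(attr(out, "kept_fraction"), 1 / 3)
  all_kept <- arbor_consistency_filter(rec, threshold_mm = Inf)
  expect_true(all(all_kept$kept))
  expect_error(arbor_consistency_filter(rec, threshold_mm = 0), "positive")
})

test_that("filter kept-set is monotone in the threshold", {
  atl <- small_atlas()
  truth <- synthetic_truth(25, 1.5, seed = 5)
  rec <- measure_skeletons(make_skeletons(atl, truth, 100, seed = 3)$skeletons)
  # inject synthetic inconsistencies
  set.seed(1)
  rec$pre_mean_mm <- rec$pre_mean_mm + rexp(100, 10)
  thresholds <- c(0.05, 0.1, 0.2, 0.5)
  kept_sets <- lapply(thresholds, function(t)
    which(arbor_consistency_filter(rec, t)$kept))
  for (i in seq_len(length(thresholds) - 1L))
    expect_true(all(kept_sets[[i]] %in% kept_sets[[i + 1L]]))
})

test_that("synapse table rows follow roles and regions; decoys are classed", {
  # neuron with 4 postsynaptic points near region A and 8 presynaptic near B
  atl <- data.frame(label = c("A", "B"), base = c("A", "B"),
                    hemisphere = c("C", "C"),
                    x = c(-0.2, 0.2), y = c(0, 0), z = c(0, 0))
  class(atl) <- c("region_atlas", "data.frame")
  nodes <- rbind(c(0, 0, 0),
                 matrix(rep(c(-0.2, 0, 0), 4), 4, 3, byrow = TRUE) +
                   0.001 * matrix(seq_len(12), 4, 3),
                 matrix(rep(c(0.2, 0, 0), 8), 8, 3, byrow = TRUE) +
                   0.001 * matrix(seq_len(24), 8, 3))
  tr <- skeleton_tree(nodes, parent = c(0L, rep(1L, 12L)),
                      presyn = 6:13, postsyn = 2:5, id = "n1")
  tab <- make_synapse_table(list(tr), atl)
  expect_equal(nrow(tab$synapses), 12L)
  expect_equal(sum(tab$synapses$role == "post" & tab$synapses$region == "A"), 4L)
  expect_equal(sum(tab$synapses$role == "pre" & tab$synapses$region == "B"), 8L)
  expect_equal(tab$classes$class, "intrinsic")

  with_decoys <- make_synapse_table(list(tr), atl, n_decoys = 3L)
  expect_setequal(unique(with_decoys$classes$class),
                  c("intrinsic", "afferent", "efferent"))
})

test_that("empty skeleton set yields empty tables without error", {
  atl <- small_atlas()
  tab <- make_synapse_table(list(), atl)
  expect_equal(nrow(tab$synapses), 0L)
  expect_equal(nrow(tab$classes), 0L)
})
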