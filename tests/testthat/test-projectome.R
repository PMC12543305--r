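three_region_atlas <- function() {
  atl <- data.frame(label = c("R1", "R2", "R3"),
                    base = c("R1", "R2", "R3"),
                    hemisphere = c("C", "C", "C"),
                    x = c(0, 0.1, 0.2), y = 0, z = 0)
  class(atl) <- c("region_atlas", "data.frame")
  atl
}

test_that("synapse fractions follow counts per region", {
  atl <- three_region_atlas()
  rows <- data.frame(
    neuron_id = "n",
    role = c(rep("post", 8), rep("pre", 8)),
    region = c(rep(c("R1", "R2"), each = 4), rep("R3", 8)))
  fr <- synapse_fractions(rows, atl)
  expect_equal(unname(fr$in_fraction), c(0.5, 0.5, 0))
  expect_equal(unname(fr$out_fraction), c(0, 0, 1))

  one <- synapse_fractions(
    data.frame(neuron_id = "n", role = c("post", "pre"),
               region = c("R2", "R2")), atl)
  expect_equal(unname(one$in_fraction), c(0, 1, 0))

  expect_error(synapse_fractions(
    data.frame(neuron_id = "n", role = "post", region = "R1"), atl),
    "lacks synapses")
  expect_error(synapse_fractions(
    data.frame(neuron_id = "n", role = c("post", "pre"),
               region = c("R1", "XX")), atl), "unknown region")
})

test_that("neuron flow matrix is the outer product with unit mass", {
  m <- neuron_flow_matrix(c(0.5, 0.5, 0), c(0, 0, 1))
  expect_equal(m[1, 3], 0.5)
  expect_equal(m[2, 3], 0.5)
  expect_equal(sum(m), 1)
  one_hot <- neuron_flow_matrix(c(1, 0, 0), c(0, 1, 0))
  expect_equal(sum(one_hot == 1), 1L)
  expect_equal(one_hot[1, 2], 1)
  for (s in 1:3) {
    set.seed(s)
    a <- runif(4); a <- a / sum(a)
    b <- runif(4); b <- b / sum(b)
    expect_equal(sum(neuron_flow_matrix(a, b)), 1)
  }
})

test_that("connection thresholding keeps counts of at least min_synapses", {
  conn <- data.frame(pre = c("a", "a", "b"), post = c("b", "c", "c"),
                     count = c(4L, 5L, 12L))
  out <- threshold_connections(conn, 5L)
  expect_equal(out$count, c(5L, 12L))
  expect_equal(threshold_connections(conn, 1L), conn)
  expect_error(threshold_connections(conn, 0L), ">= 1")
})

test_that("single-neuron projectome places fractions in the source column", {
  atl <- three_region_atlas()
  syn <- data.frame(
    neuron_id = "n1",
    role = c(rep("post", 8), rep("pre", 8)),
    region = c(rep(c("R1", "R2"), each = 4), rep("R3", 8)))
  cls <- data.frame(neuron_id = "n1", class = "intrinsic")
  pj <- build_projectome(syn, cls, atl)
  expect_equal(pj$w["R1", "R3"], 0.5)
  expect_equal(pj$w["R2", "R3"], 0.5)
  expect_equal(sum(pj$w), 1)
})

test_that("duplicating every neuron leaves the normalized matrix unchanged", {
  atl <- small_atlas(4, 1, seed = 3)
  truth <- synthetic_truth(25, 1.5, seed = 5)
  tab <- make_synapse_table(make_skeletons(atl, truth, 30, seed = 4)$skeletons,
                            atl)
  pj1 <- build_projectome(tab$synapses, tab$classes, atl)
  dup_syn <- rbind(tab$synapses,
                   transform(tab$synapses,
                             neuron_id = paste0(neuron_id, "_copy")))
  dup_cls <- rbind(tab$classes,
                   transform(tab$classes,
                             neuron_id = paste0(neuron_id, "_copy")))
  pj2 <- build_projectome(dup_syn, dup_cls, atl)
  expect_equal(pj2$w, pj1$w, tolerance = 1e-12)
  # mass conservation: raw flow sums to the number of contributing neurons
  expect_equal(sum(pj1$W_raw), 30)
  expect_equal(sum(pj2$W_raw), 60)
})

test_that("projectome matches a brute-force summation oracle", {
  atl <- small_atlas(3, 0, seed = 9)
  truth <- synthetic_truth(25, 1.5, seed = 5)
  tab <- make_synapse_table(make_skeletons(atl, truth, 25, seed = 6)$skeletons,
                            atl, n_decoys = 4L)
  pj <- build_projectome(tab$synapses, tab$classes, atl)
  # oracle: naive per-neuron tabulation over intrinsic neurons only
  W <- matrix(0, nrow(atl), nrow(atl), dimnames = list(atl$label, atl$label))
  keep <- tab$classes$neuron_id[tab$classes$class == "intrinsic"]
  for (id in keep) {
    rows <- tab$synapses[tab$synapses$neuron_id == id, ]
    post <- table(factor(rows$region[rows$role == "post"],
                         levels = atl$label))
    pre <- table(factor(rows$region[rows$role == "pre"],
                        levels = atl$label))
    W <- W + outer(as.numeric(post) / sum(post),
                   as.numeric(pre) / sum(pre))
  }
  expect_equal(unname(pj$W_raw), unname(W), tolerance = 1e-12)
  # decoy afferent/efferent neurons were excluded by the class filter
  expect_equal(sum(pj$W_raw), length(keep))
})

test_that("empty intrinsic set is an error", {
  atl <- three_region_atlas()
  syn <- data.frame(neuron_id = "d", role = c("pre", "post"),
                    region = c("R1", "R2"))
  cls <- data.frame(neuron_id = "d", class = "afferent")
  expect_error(build_projectome(syn, cls, atl), "empty projectome")
})

test_that("column normalization handles zero columns and rejects negatives", {
  m <- cbind(c(2, 2, 0), c(0, 0, 0), c(1, 1, 2))
  expect_warning(out <- column_normalize(m), "zero column")
  expect_equal(out[, 1], c(0.5, 0.5, 0))
  expect_equal(out[, 2], c(0, 0, 0))
  expect_equal(colSums(out)[c(1, 3)], c(1, 1), ignore_attr = TRUE)
  expect_error(column_normalize(cbind(c(-1, 1))), "negative")
})

test_that("log weights of EDR-generated projectomes are near-normal in shape", {
  # lognormality of w under the exponential rule + Gaussian-like distances
  atl <- make_atlas(37, 1, seed = 42)
  D <- distance_matrix(atl)
  skews <- vapply(1:10, function(s) {
    net <- edr_generate(D, edr_spec(33, 4733), seed = 500 + s)
    lw <- log10(net$w[net$w > 0 & row(net$w) != col(net$w)])
    mean((lw - mean(lw))^3) / sd(lw)^3
  }, numeric(1))
  expect_lt(abs(mean(skews)), 0.5)
})
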