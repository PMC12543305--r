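test_that("distance-bin sampling follows the exponential law", {
  # single nonempty bin: always chosen
  set.seed(1)
  expect_true(all(sample_distance(33, c(0.1, 0.2, 0.3), c(0, 5, 0),
                                  n = 50) == 2L))
  # lambda = 0: two equally occupied bins drawn uniformly (3 sigma binomial)
  set.seed(2)
  draws <- sample_distance(0, c(0.1, 0.2), c(3, 7), n = 10000)
  p_hat <- mean(draws == 1L)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 10000))
  # large lambda: nearest nonempty bin dominates
  set.seed(3)
  draws <- sample_distance(200, c(0.1, 0.2, 0.3), c(2, 2, 2), n = 1000)
  expect_gte(mean(draws == 1L), 0.99)
})

test_that("saturated generation yields the complete digraph", {
  atl <- small_atlas(1, 1, seed = 5)
  D <- distance_matrix(atl)
  net <- edr_generate(D, edr_spec(10, 6), seed = 1)
  expect_equal(net$M_realized, 6L)
  expect_true(all(net$A[row(net$A) != col(net$A)] == 1L))
  expect_equal(colSums(net$w), rep(1, 3), ignore_attr = TRUE)
})

test_that("dominant bin at huge lambda links the closest pair first", {
  atl <- data.frame(label = c("a", "b", "c"), x = c(0, 0.01, 0.5),
                    y = 0, z = 0)
  D <- distance_matrix(atl)
  for (s in 1:5) {
    net <- edr_generate(D, edr_spec(500, 2), seed = s)
    expect_equal(sum(net$A[1:2, 1:2]), 2L)  # both links inside pair (a,b)
  }
})

test_that("generation is deterministic given the seed and respects M", {
  atl <- small_atlas(6, 1, seed = 8)
  D <- distance_matrix(atl)
  n1 <- edr_generate(D, edr_spec(33, 100), seed = 3)
  n2 <- edr_generate(D, edr_spec(33, 100), seed = 3)
  expect_identical(n1$counts, n2$counts)
  for (m in c(1L, 13L, 77L, 156L)) {
    net <- edr_generate(D, edr_spec(20, m), seed = m)
    expect_equal(net$M_realized, m)
  }
})

test_that("infeasible M raises a capacity error before sampling", {
  atl <- small_atlas(1, 0, seed = 1)
  D <- distance_matrix(atl)
  expect_error(edr_generate(D, edr_spec(33, 3)), "capacity")
})

test_that("race and literal samplers agree in distribution", {
  atl <- small_atlas(2, 1, seed = 4)
  D <- distance_matrix(atl)
  spec <- edr_spec(40, 12)
  n_rep <- 300
  stat <- function(method) {
    sapply(seq_len(n_rep), function(s) {
      net <- edr_generate(D, spec, method = method, seed = 10000 + s)
      c(total = sum(net$counts), onpair = sum(net$counts[1:2, 1:2]))
    })
  }
  race <- stat("race")
  direct <- stat("direct")
  # stopping-time multi-edge totals and placement concentration agree
  expect_lt(abs(mean(race["total", ]) - mean(direct["total", ])) /
              mean(direct["total", ]), 0.1)
  expect_lt(abs(mean(race["onpair", ]) - mean(direct["onpair", ])) /
              max(mean(direct["onpair", ]), 1), 0.15)
})

test_that("placed-edge distances at lambda 0 are uniform over nonempty bins", {
  atl <- small_atlas(10, 2, seed = 6)
  D <- distance_matrix(atl)
  pp <- edrnet:::edr_pair_probs(D, 0)
  pe <- edr_place_edges(D, 0, 20000, seed = 2)
  obs <- as.numeric(table(factor(pe$bin, levels = pp$occupied_bins)))
  expd <- rep(20000 / length(pp$occupied_bins), length(pp$occupied_bins))
  chi <- sum((obs - expd)^2 / expd)
  p <- 1 - pchisq(chi, df = length(obs) - 1)
  expect_gt(p, 0.01)
})

test_that("region relabeling commutes with generation in distribution", {
  atl <- small_atlas(3, 1, seed = 2)
  D <- distance_matrix(atl)
  perm <- c(3L, 1L, 4L, 2L, 7L, 5L, 6L)
  Dp <- D[perm, perm]
  mean_bi <- function(Dm, seed0) {
    mean(vapply(1:60, function(s) {
      net <- edr_generate(Dm, edr_spec(30, 25), seed = seed0 + s)
      reciprocity_counts(net$A)[["bidirectional"]]
    }, numeric(1)))
  }
  b1 <- mean_bi(D, 100)
  b2 <- mean_bi(Dp, 4000)
  expect_lt(abs(b1 - b2), 1)
})

test_that("single-network ensemble summary equals the network's properties", {
  atl <- small_atlas(4, 0, seed = 3)
  D <- distance_matrix(atl)
  spec <- edr_spec(25, 30, n_networks = 1L, seed = 9)
  ens <- edr_ensemble(D, spec, properties = c("reciprocity", "apl", "cc"))
  net <- edr_generate(D, spec, seed = spec$seed + 1L)
  expect_equal(ens$summary$sd, rep(0, nrow(ens$summary)))
  expect_equal(
    ens$summary$mean[ens$summary$property == "cc"],
    clustering_coefficient(net$A))
  # same base seed twice: identical summaries
  ens2 <- edr_ensemble(D, spec, properties = c("reciprocity", "apl", "cc"))
  expect_identical(ens$summary, ens2$summary)
})

test_that("reciprocity rises with lambda at matched density", {
  atl <- make_atlas(37, 1, seed = 42)
  D <- distance_matrix(atl)
  bi_at <- function(lambda) {
    mean(vapply(1:20, function(s) {
      net <- edr_generate(D, edr_spec(lambda, 4733), seed = 300 + s)
      reciprocity_counts(net$A)[["bidirectional"]]
    }, numeric(1)))
  }
  expect_gt(bi_at(50), bi_at(0))
})
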