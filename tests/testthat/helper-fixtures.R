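# Shared small fixtures built in code.

# chain soma -- A (0.1 mm) -- B (0.2 mm)
chain_tree <- function() {
  skeleton_tree(
    nodes = rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.1, 0.2, 0)),
    parent = c(0L, 1L, 2L),
    presyn = 3L, postsyn = 2L, id = "chain")
}

# Branch point at soma-path 0.05 mm; closest postsynaptic point at path
# 0.08 mm on the dendrite; closest presynaptic point at path 0.30 mm on the
# axon. Main cable = 0.03 + 0.25 = 0.28 mm.
toy_branched_tree <- function() {
  skeleton_tree(
    nodes = rbind(
      c(0, 0, 0),          # 1 soma
      c(0.05, 0, 0),       # 2 branch point (path 0.05)
      c(0.05, 0.03, 0),    # 3 dendrite post (path 0.08)
      c(0.05, -0.25, 0)),  # 4 axon pre (path 0.30)
    parent = c(0L, 1L, 2L, 2L),
    presyn = 4L, postsyn = 3L, id = "toy")
}

random_tree <- function(n, seed) {
  set.seed(seed)
  nodes <- matrix(stats::runif(3 * n, -0.2, 0.2), n, 3)
  parent <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  skeleton_tree(nodes, parent,
                presyn = sample.int(n, 2), postsyn = sample.int(n, 2),
                id = sprintf("rt%d", seed))
}

small_atlas <- function(n_pairs = 8, n_central = 1, seed = 42)
  make_atlas(n_pairs, n_central, seed = seed)

# labelled weight matrix helper
labelled <- function(w, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("V%d", seq_len(nrow(w)))
  dimnames(w) <- list(labels, labels)
  w
}
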