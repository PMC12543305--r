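#' Synthetic ground-truth parameters for the data generator
#'
#' Bundles the quantities the generator treats as known truth: the
#' exponential decay rate of main-cable lengths, the tortuosity factor
#' relating tree-path length to straight-line length, and a per-region
#' hierarchy score driving directional weight asymmetry.
#'
#' @param lambda_true_per_mm Decay rate (mm^-1) of the main-cable (tree-path)
#'   length distribution; must be > 0. Euclidean cable lengths then decay at
#'   approximately `tortuosity_a * lambda_true_per_mm`.
#' @param tortuosity_a Path-to-Euclidean scaling factor, >= 1.
#' @param asym_profile Optional numeric vector of hierarchy scores in `[0, 1]`,
#'   one per region *base name* (bilateral partners share a score). If `NULL`,
#'   scores are drawn uniformly when first needed.
#' @param seed Integer RNG seed.
#' @return Object of class `synthetic_truth` (a list).
#' @export
synthetic_truth <- function(lambda_true_per_mm = 20, tortuosity_a = 1.5,
                            asym_profile = NULL, seed = 1L) {
  if (lambda_true_per_mm <= 0) stop("lambda_true_per_mm must be > 0")
  if (tortuosity_a < 1) stop("tortuosity_a must be >= 1")
  if (!is.null(asym_profile) &&
      (any(asym_profile < 0) || any(asym_profile > 1)))
    stop("asym_profile scores must lie in [0, 1]")
  structure(list(lambda_true_per_mm = lambda_true_per_mm,
                 tortuosity_a = tortuosity_a,
                 asym_profile = asym_profile,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3L * n), n, 3L)
  v / sqrt(rowSums(v^2))
}

#' Generate synthetic neuron skeletons with known cable lengths
#'
#' Each skeleton mimics the insect neuron layout: a soma on the surface of
#' the brain domain, a primary neurite to an interior branch point, a
#' dendritic branch ending in a star-like arbor of postsynaptic points and an
#' axonal branch ending in a star of presynaptic points. The tree-path length
#' between the closest postsynaptic and closest presynaptic point (the main
#' cable) is drawn from Exp(`lambda_true_per_mm`); the straight-line distance
#' between those two points equals the main cable length divided by
#' `tortuosity_a`, up to a relative jitter.
#'
#' @param atlas A `region_atlas` defining the spatial domain.
#' @param truth A [synthetic_truth()] object.
#' @param n_neurons Number of skeletons to generate (>= 1).
#' @param jitter_rel Maximum relative jitter on the Euclidean cable length
#'   (default 0.05, i.e. <= 5%).
#' @param seed Integer RNG seed (defaults to `truth$seed`).
#' @return A list with `skeletons` (list of `skeleton_tree`) and `truth_table`
#'   (data.frame: `neuron_id`, `cable_true_mm`, `euclid_true_mm`).
#' @export
make_skeletons <- function(atlas, truth, n_neurons, jitter_rel = 0.05,
                           seed = truth$seed) {
  if (length(n_neurons) != 1L || is.na(n_neurons) || n_neurons < 1)
    stop("n_neurons must be a positive count")
  n_neurons <- as.integer(n_neurons)
  lambda <- truth$lambda_true_per_mm
  a <- truth$tortuosity_a
  scale_mm <- attr(atlas, "spatial_scale_mm")
  if (is.null(scale_mm)) scale_mm <- max(stats::dist(atlas[, c("x", "y", "z")]))
  semi <- scale_mm * c(0.5, 0.35, 0.25)

  set.seed(as.integer(seed))
  L <- stats::rexp(n_neurons, rate = lambda)
  jit <- stats::runif(n_neurons, -jitter_rel, jitter_rel)
  # Euclidean separation of the two closest synaptic points; never longer
  # than the tree path between them.
  E <- pmin(L / a * (1 + jit), L)
  k_d <- sample(3:20, n_neurons, replace = TRUE)
  k_a <- sample(3:20, n_neurons, replace = TRUE)
  soma_dir <- unit_vectors(n_neurons)
  arbor_ctr <- unit_vectors(n_neurons) *
    (0.8 * stats::runif(n_neurons)^(1 / 3))
  axis_dir <- unit_vectors(n_neurons)

  skeletons <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    p_post <- arbor_ctr[i, ] * semi
    u <- axis_dir[i, ]
    p_pre <- p_post + E[i] * u
    # Branch point placed so the two straight branch edges sum to the main
    # cable length: offset the midpoint perpendicular to the post--pre axis.
    h <- sqrt(max(L[i]^2 - E[i]^2, 0)) / 2
    perp <- c(-u[2L], u[1L], 0)
    if (sum(perp^2) < 1e-12) perp <- c(0, -u[3L], u[2L])
    perp <- perp / sqrt(sum(perp^2))
    b <- (p_post + p_pre) / 2 + h * perp
    soma <- soma_dir[i, ] * semi
    q <- (soma + b) / 2

    star_d <- unit_vectors(k_d[i]) * stats::runif(k_d[i], 0.005, 0.02)
    star_a <- unit_vectors(k_a[i]) * stats::runif(k_a[i], 0.005, 0.02)
    nodes <- rbind(soma, q, b, p_post, p_pre,
                   sweep(star_d, 2L, p_post, `+`),
                   sweep(star_a, 2L, p_pre, `+`))
    dimnames(nodes) <- NULL
    parent <- c(0L, 1L, 2L, 3L, 3L,
                rep(4L, k_d[i]), rep(5L, k_a[i]))
    postsyn <- c(4L, 5L + seq_len(k_d[i]))
    presyn <- c(5L, 5L + k_d[i] + seq_len(k_a[i]))
    skeletons[[i]] <- skeleton_tree(nodes, parent, presyn, postsyn,
                                    id = sprintf("n%06d", i))
  }
  truth_table <- data.frame(
    neuron_id = vapply(skeletons, function(s) s$id, character(1)),
    cable_true_mm = L, euclid_true_mm = E, stringsAsFactors = FALSE)
  list(skeletons = skeletons, truth_table = truth_table)
}

#' Construct a skeleton tree
#'
#' @param nodes Numeric n x 3 matrix of node coordinates in mm.
#' @param parent Integer parent index per node (0 for the soma root); parents
#'   must precede children.
#' @param presyn,postsyn Integer node indices carrying pre-/postsynaptic
#'   points.
#' @param id Neuron identifier string.
#' @return Object of class `skeleton_tree`.
#' @export
skeleton_tree <- function(nodes, parent, presyn = integer(), postsyn = integer(),
                          id = "neuron") {
  nodes <- as.matrix(nodes)
  parent <- as.integer(parent)
  n <- nrow(nodes)
  if (length(parent) != n) stop("parent must have one entry per node")
  if (sum(parent == 0L) != 1L) stop("skeleton must have exactly one root")
  if (any(parent > n) || any(parent < 0L)) stop("orphan parent index")
  if (any(parent >= seq_len(n) & parent != 0L))
    stop("parents must precede children (no cycles)")
  bad <- setdiff(c(presyn, postsyn), seq_len(n))
  if (length(bad)) stop("synaptic node ids not in tree: ",
                        paste(bad, collapse = ", "))
  structure(list(nodes = nodes, parent = parent,
                 presyn = as.integer(presyn), postsyn = as.integer(postsyn),
                 id = id),
            class = "skeleton_tree")
}

#' @export
print.skeleton_tree <- function(x, ...) {
  cat(sprintf("skeleton_tree '%s': %d nodes, %d presynaptic, %d postsynaptic\n",
              x$id, nrow(x$nodes), length(x$presyn), length(x$postsyn)))
  invisible(x)
}

# Soma-path distance for every node: cumulative Euclidean edge lengths from
# the root. Parents precede children, so a single forward pass suffices.
node_path_lengths <- function(tree) {
  n <- nrow(tree$nodes)
  d <- numeric(n)
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (p > 0L)
      d[i] <- d[p] + sqrt(sum((tree$nodes[i, ] - tree$nodes[p, ])^2))
  }
  d
}

#' Path length from the soma to a node
#'
#' Sum of Euclidean edge lengths along the unique root-to-node path.
#'
#' @param tree A `skeleton_tree`.
#' @param node Node index.
#' @return Length in mm.
#' @export
path_length_to_node <- function(tree, node) {
  n <- nrow(tree$nodes)
  if (length(node) != 1L || is.na(node) || node < 1L || node > n)
    stop("unknown node id: ", node)
  node_path_lengths(tree)[node]
}

ancestors_of <- function(parent, node) {
  path <- node
  while (parent[node] > 0L) {
    node <- parent[node]
    path <- c(path, node)
  }
  path
}

side_of <- function(x, midline_mm) {
  ifelse(abs(x) <= midline_mm, "C", ifelse(x > 0, "R", "L"))
}

#' Measure main-cable and Euclidean cable length of one neuron
#'
#' Computes soma-path distances of all synaptic points, identifies the
#' closest presynaptic and closest postsynaptic point, and measures the
#' tree path between them (the main transmission cable; the soma and primary
#' neurite drop out automatically because the path between two non-root
#' nodes does not traverse the root) and the straight-line distance between
#' the same two points. The neuron is labelled intra- or interhemispheric
#' according to whether the two closest points lie on the same side.
#'
#' @param tree A `skeleton_tree` with at least one pre- and one postsynaptic
#'   node.
#' @param midline_mm Half-width of the midline band counted as "center"
#'   (default 0.005 mm).
#' @return One-row data.frame (a cable record): `neuron_id`, `pre_min_mm`,
#'   `pre_mean_mm`, `post_min_mm`, `post_mean_mm`, `cable_mm`, `euclid_mm`,
#'   `hemi_class` (`"intra"` or `"inter"`).
#' @export
measure_neuron <- function(tree, midline_mm = 0.005) {
  if (length(tree$presyn) == 0L)
    stop(sprintf("neuron %s has no presynaptic points", tree$id))
  if (length(tree$postsyn) == 0L)
    stop(sprintf("neuron %s has no postsynaptic points", tree$id))
  d <- node_path_lengths(tree)
  dpre <- d[tree$presyn]
  dpost <- d[tree$postsyn]
  cp <- tree$presyn[which.min(dpre)]
  cq <- tree$postsyn[which.min(dpost)]

  anc_p <- ancestors_of(tree$parent, cp)
  anc_q <- ancestors_of(tree$parent, cq)
  lca <- anc_p[match(TRUE, anc_p %in% anc_q)]
  cable <- d[cp] + d[cq] - 2 * d[lca]
  euclid <- sqrt(sum((tree$nodes[cp, ] - tree$nodes[cq, ])^2))

  side_p <- side_of(tree$nodes[cp, 1L], midline_mm)
  side_q <- side_of(tree$nodes[cq, 1L], midline_mm)
  data.frame(neuron_id = tree$id,
             pre_min_mm = min(dpre), pre_mean_mm = mean(dpre),
             post_min_mm = min(dpost), post_mean_mm = mean(dpost),
             cable_mm = cable, euclid_mm = euclid,
             hemi_class = if (side_p == side_q) "intra" else "inter",
             stringsAsFactors = FALSE)
}

#' Measure a collection of skeletons
#'
#' @param skeletons List of `skeleton_tree` objects.
#' @param midline_mm Passed to [measure_neuron()].
#' @return data.frame of cable records, one row per neuron.
#' @export
measure_skeletons <- function(skeletons, midline_mm = 0.005) {
  do.call(rbind, lapply(skeletons, measure_neuron, midline_mm = midline_mm))
}

#' Arbor-consistency filter on cable records
#'
#' Discards neurons whose closest synaptic point is suspiciously far from the
#' bulk of its arbor: a neuron is kept iff both `pre_mean - pre_min` and
#' `post_mean - post_min` are at or below the threshold. Mis-predicted or
#' nontraditional synapses (dendro-dendritic, axo-axonic) inflate these
#' differences.
#'
#' @param records Cable-record data.frame from [measure_skeletons()].
#' @param threshold_mm Positive threshold in mm (default 0.15 mm).
#' @return `records` with a logical `kept` column; the kept fraction is
#'   attached as attribute `"kept_fraction"`.
#' @export
arbor_consistency_filter <- function(records, threshold_mm = 0.15) {
  if (threshold_mm <= 0) stop("threshold_mm must be positive")
  records$kept <- (records$pre_mean_mm - records$pre_min_mm) <= threshold_mm &
    (records$post_mean_mm - records$post_min_mm) <= threshold_mm
  attr(records, "kept_fraction") <- mean(records$kept)
  records
}

#' Build synapse and neuron-class tables from skeletons
#'
#' Assigns every synaptic point of every skeleton to its nearest region
#' centroid and emits one row per synaptic point. All generated neurons are
#' classed `"intrinsic"`; optional decoy afferent/efferent neurons (excluded
#' downstream by the class filter) can be appended.
#'
#' @param skeletons List of `skeleton_tree` objects (may be empty).
#' @param atlas A `region_atlas`.
#' @param n_decoys Number of decoy neurons to append, each classed
#'   alternately `"afferent"`/`"efferent"` with a few synapse rows.
#' @return List with `synapses` (data.frame: `neuron_id`, `role`, `region`)
#'   and `classes` (data.frame: `neuron_id`, `class`).
#' @export
make_synapse_table <- function(skeletons, atlas, n_decoys = 0L) {
  cent <- as.matrix(atlas[, c("x", "y", "z")])
  nearest_region <- function(pts) {
    if (nrow(pts) == 0L) return(character())
    idx <- apply(pts, 1L, function(p)
      which.min(colSums((t(cent) - p)^2)))
    atlas$label[idx]
  }
  rows <- lapply(skeletons, function(s) {
    pre <- s$nodes[s$presyn, , drop = FALSE]
    post <- s$nodes[s$postsyn, , drop = FALSE]
    data.frame(
      neuron_id = s$id,
      role = c(rep("pre", nrow(pre)), rep("post", nrow(post))),
      region = c(nearest_region(pre), nearest_region(post)),
      stringsAsFactors = FALSE)
  })
  syn <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron_id = character(), role = character(),
               region = character(), stringsAsFactors = FALSE)
  cls <- data.frame(
    neuron_id = vapply(skeletons, function(s) s$id, character(1)),
    class = rep("intrinsic", length(skeletons)), stringsAsFactors = FALSE)
  if (n_decoys > 0L) {
    decoy_ids <- sprintf("decoy%03d", seq_len(n_decoys))
    decoy_cls <- rep(c("afferent", "efferent"), length.out = n_decoys)
    reg <- atlas$label[1L + (seq_len(n_decoys) - 1L) %% nrow(atlas)]
    syn <- rbind(syn, data.frame(
      neuron_id = rep(decoy_ids, each = 2L),
      role = rep(c("pre", "post"), n_decoys),
      region = rep(reg, each = 2L), stringsAsFactors = FALSE))
    cls <- rbind(cls, data.frame(neuron_id = decoy_ids, class = decoy_cls,
                                 stringsAsFactors = FALSE))
  }
  rownames(syn) <- rownames(cls) <- NULL
  list(synapses = syn, classes = cls)
}
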