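#' Write a skeleton to an SWC file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent), coordinates
#' written in micrometers with a header comment declaring the scale.
#'
#' @param tree A `skeleton_tree` (coordinates in mm).
#' @param path Output file path.
#' @param unit_scale Micrometers per millimeter (default 1000).
#' @return `path`, invisibly. A companion data.frame of synaptic points
#'   (`node_id`, `role`) can be recovered via attribute-free export with
#'   [write_synapse_points()].
#' @export
write_swc <- function(tree, path, unit_scale = 1000) {
  n <- nrow(tree$nodes)
  type <- rep(0L, n)
  type[tree$parent == 0L] <- 1L
  df <- data.frame(id = seq_len(n), type = type,
                   x = tree$nodes[, 1L] * unit_scale,
                   y = tree$nodes[, 2L] * unit_scale,
                   z = tree$nodes[, 3L] * unit_scale,
                   radius = 0.1,
                   parent = ifelse(tree$parent == 0L, -1L, tree$parent))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# neuron %s", tree$id),
               sprintf("# coordinates in um (%g um per mm)", unit_scale),
               "# id type x y z radius parent"), con)
  utils::write.table(df, con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write synaptic-point assignments keyed by SWC node id
#'
#' @param tree A `skeleton_tree`.
#' @param path Output TSV path.
#' @export
write_synapse_points <- function(tree, path) {
  df <- data.frame(
    node_id = c(tree$presyn, tree$postsyn),
    role = c(rep("pre", length(tree$presyn)),
             rep("post", length(tree$postsyn))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a skeleton from an SWC file
#'
#' Accepts standard 7-column SWC with a single root; node ids may be
#' arbitrary and are remapped so parents precede children. Coordinates are
#' scaled from file units to mm.
#'
#' @param path SWC file path.
#' @param unit_scale File units per mm (default 1000, i.e. micrometers).
#' @param synapse_points Optional data.frame (`node_id`, `role`) in the
#'   file's node-id numbering, e.g. read back from
#'   [write_synapse_points()] output.
#' @param id Neuron id (default: file name without extension).
#' @return A `skeleton_tree` in mm.
#' @export
read_swc <- function(path, unit_scale = 1000, synapse_points = NULL,
                     id = sub("\\.swc$", "", basename(path))) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  n <- nrow(raw)
  roots <- which(raw$parent == -1L)
  if (length(roots) != 1L)
    stop("SWC parse error: expected exactly 1 root, found ", length(roots))
  idx <- match(raw$parent, raw$id)
  orphan <- which(raw$parent != -1L & is.na(idx))
  if (length(orphan))
    stop("SWC parse error: orphan parent id at line(s) ",
         paste(orphan, collapse = ", "))
  # topological order: repeatedly append nodes whose parent is placed
  order_new <- integer(0)
  placed <- logical(n)
  frontier <- roots
  while (length(frontier)) {
    order_new <- c(order_new, frontier)
    placed[frontier] <- TRUE
    frontier <- which(!placed & idx %in% frontier)
  }
  if (length(order_new) != n)
    stop("SWC parse error: cycle or disconnected component detected")
  rank <- match(seq_len(n), order_new)
  nodes <- as.matrix(raw[order_new, c("x", "y", "z")]) / unit_scale
  dimnames(nodes) <- NULL
  parent <- ifelse(raw$parent[order_new] == -1L, 0L,
                   rank[idx[order_new]])
  presyn <- postsyn <- integer()
  if (!is.null(synapse_points)) {
    pos <- rank[match(synapse_points$node_id, raw$id)]
    if (any(is.na(pos))) stop("synapse point references unknown SWC node id")
    presyn <- pos[synapse_points$role == "pre"]
    postsyn <- pos[synapse_points$role == "post"]
  }
  skeleton_tree(nodes, parent, presyn, postsyn, id = id)
}

#' Write a labeled weight matrix
#'
#' @param w Labeled square matrix.
#' @param path Output path.
#' @param format `"csv"` (dense, header labels, first column = source
#'   label) or `"edgelist"` (TSV `src`, `dst`, `weight`, positive
#'   off-diagonal entries only).
#' @export
write_network <- function(w, path, format = c("csv", "edgelist")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(label = rownames(w), as.data.frame(w),
                     check.names = FALSE)
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
  } else {
    idx <- which(w > 0 & row(w) != col(w), arr.ind = TRUE)
    df <- data.frame(src = rownames(w)[idx[, 1L]],
                     dst = colnames(w)[idx[, 2L]],
                     weight = w[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a labeled weight matrix
#'
#' Dense CSV (header labels, first column = source label) and 3-column
#' edge-list TSV dialects produce identical matrices for the same network.
#'
#' @param path Input path.
#' @param labels Label set for the edge-list dialect (required there if the
#'   file does not cover all regions; ignored for dense CSV).
#' @return Labeled square numeric matrix.
#' @export
read_network <- function(path, labels = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first)) {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    return(m[, rownames(m), drop = FALSE])
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(labels)) labels <- sort(unique(c(df$src, df$dst)))
  if (length(labels) == 0L)
    stop("empty edge list and no labels declared")
  key <- paste(df$src, df$dst)
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- any(tapply(df$weight, key, function(v)
      length(unique(v)) > 1L))
    if (conflict) stop("duplicate edges with conflicting weights")
    df <- df[!dup, , drop = FALSE]
  }
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  m[cbind(match(df$src, labels), match(df$dst, labels))] <- df$weight
  m
}

#' Write a region atlas as CSV (coordinates in micrometers)
#'
#' @param atlas A `region_atlas` (mm).
#' @param path Output CSV path.
#' @param unit_scale Micrometers per mm (default 1000).
#' @export
write_atlas <- function(atlas, path, unit_scale = 1000) {
  df <- data.frame(label = atlas$label, hemisphere = atlas$hemisphere,
                   x = atlas$x * unit_scale, y = atlas$y * unit_scale,
                   z = atlas$z * unit_scale)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region atlas from CSV
#'
#' @param path CSV with columns `label`, `hemisphere`, `x`, `y`, `z` (file
#'   units per `unit_scale`).
#' @param unit_scale File units per mm (default 1000).
#' @return A `region_atlas` in mm.
#' @export
read_atlas <- function(path, unit_scale = 1000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  atlas <- data.frame(label = df$label,
                      base = sub("_[LR]$", "", df$label),
                      hemisphere = df$hemisphere,
                      x = df$x / unit_scale, y = df$y / unit_scale,
                      z = df$z / unit_scale, stringsAsFactors = FALSE)
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}
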