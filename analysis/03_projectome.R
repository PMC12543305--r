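#!/usr/bin/env Rscript
# Stage 3: build the region-level networks. First the synapse-table route
# (per-neuron synapse-fraction outer products, intrinsic neurons only),
# then the study's main synthetic projectome (EDR process + hierarchy
# bias), its distance matrix, weight distribution, and the Ward clustering
# of incoming-flow profiles.

source("analysis/00_config.R")

## projectome from the raw synapse table ----------------------------------
syn <- read.table(res_path("synapses.tsv"), header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
cls <- read.table(res_path("neuron_classes.tsv"), header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
pj_syn <- build_projectome(syn, cls, atlas)
message("Synapse-table projectome: ", pj_syn$n_neurons,
        " intrinsic neurons, M = ", pj_syn$M,
        sprintf(" (density %.1f%%)", network_density(pj_syn)))
write_network(pj_syn$w, res_path("projectome_from_synapses.csv"))

## main synthetic projectome ----------------------------------------------
pj <- make_projectome(atlas, truth, M = cfg$M, beta = cfg$beta,
                      seed = cfg$seed + 2L)
message("Synthetic projectome: M = ", pj$M,
        sprintf(" (density %.1f%%), generator lambda = %.1f mm^-1",
                network_density(pj), pj$lambda_per_mm))
write_network(pj$w, res_path("projectome.csv"))
write_network(pj$w, res_path("projectome_edges.tsv"), format = "edgelist")
write.table(pj$hierarchy, res_path("hierarchy_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

D <- distance_matrix(atlas)
write_network(D, res_path("distance_matrix.csv"))

lw <- log10(pj$w[pj$w > 0 & row(pj$w) != col(pj$w)])
message(sprintf("log10 w over %d links: mean %.2f, sd %.2f, skewness %.2f",
                length(lw), mean(lw), sd(lw),
                mean((lw - mean(lw))^3) / sd(lw)^3))

## hierarchical clustering of incoming-flow profiles ----------------------
ff <- feature_matrix(pj$w)
message("Feature matrix: ", ff$n_filled, " absent links filled with ",
        round(ff$fill, 2))
dend <- hier_cluster(ff, "ward", "euclidean")
for (k in c(4, 6, 8)) {
  cl <- cut_clusters(dend, k)
  write.table(data.frame(label = names(cl), cluster = cl),
              res_path(sprintf("clusters_ward_k%d.tsv", k)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # bilateral coherence: fraction of pairs whose two sides share a cluster
  sides <- split(cl, sub("_[LR]$", "", names(cl)))
  both <- vapply(sides[vapply(sides, length, 1L) == 2L],
                 function(v) v[1] == v[2], logical(1))
  message(sprintf("k = %d: %d/%d bilateral pairs cluster together",
                  k, sum(both), length(both)))
}
# alternative linkage/metric combinations
alt1 <- cut_clusters(hier_cluster(ff, "average", "correlation"), 4)
alt2 <- cut_clusters(hier_cluster(ff, "complete", "cosine"), 4)
ward4 <- cut_clusters(dend, 4)
agree <- function(a, b) {
  pa <- outer(a, a, `==`); pb <- outer(b, b, `==`)
  mean(pa[upper.tri(pa)] == pb[upper.tri(pb)])
}
message(sprintf("pairwise cluster agreement ward vs average+correlation: %.2f",
                agree(ward4, alt1)))
message(sprintf("pairwise cluster agreement ward vs complete+cosine:      %.2f",
                agree(ward4, alt2)))
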