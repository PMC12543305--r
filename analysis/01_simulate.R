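#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs -- the bilaterally symmetric
# region atlas, a cohort of neuron skeletons with known cable lengths, and
# the synapse/class tables derived from them. Writes the atlas, a sample of
# skeletons as SWC, the tables, and the ground-truth cable lengths.

source("analysis/00_config.R")

message("Atlas: ", nrow(atlas), " regions inside a ",
        cfg$spatial_scale_mm, " mm domain")
write_atlas(atlas, res_path("atlas.csv"))

sk <- make_skeletons(atlas, truth, cfg$n_neurons, seed = cfg$seed + 1L)
message("Generated ", length(sk$skeletons), " skeletons; true lambda_d = ",
        cfg$lambda_d_true, " mm^-1, tortuosity a = ", cfg$tortuosity_a)
write.table(sk$truth_table, res_path("skeleton_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# a small SWC sample for inspection / format round-trip
swc_dir <- res_path("swc_sample")
dir.create(swc_dir, showWarnings = FALSE)
for (tr in sk$skeletons[1:20]) {
  write_swc(tr, file.path(swc_dir, paste0(tr$id, ".swc")))
  write_synapse_points(tr, file.path(swc_dir, paste0(tr$id, "_synapses.tsv")))
}

# synapse/class tables from a sub-cohort (kept small: the synapse table is
# only needed to exercise projectome construction from raw points)
tab <- make_synapse_table(sk$skeletons[1:2000], atlas, n_decoys = 50L)
write.table(tab$synapses, res_path("synapses.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tab$classes, res_path("neuron_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Synapse table: ", nrow(tab$synapses), " synaptic points from ",
        nrow(tab$classes), " neurons (incl. 50 afferent/efferent decoys)")
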