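#!/usr/bin/env Rscript
# Stage 2: measure main-cable and Euclidean cable lengths on the skeleton
# cohort, apply the arbor-consistency filter, fit the exponential decay
# rates (lambda_d on tree-path lengths, lambda_ED on Euclidean lengths) and
# the tortuosity scaling factor.

source("analysis/00_config.R")

sk <- make_skeletons(atlas, truth, cfg$n_neurons, seed = cfg$seed + 1L)
rec <- measure_skeletons(sk$skeletons)
rec <- arbor_consistency_filter(rec, cfg$consistency_threshold_mm)
message(sprintf("Kept %.1f%% of %d neurons after the %.2f mm consistency filter",
                100 * attr(rec, "kept_fraction"), nrow(rec),
                cfg$consistency_threshold_mm))
write.table(rec, res_path("cable_records.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

kept <- rec[rec$kept, ]
fit_d <- fit_edr(kept$cable_mm)
fit_ed <- fit_edr(kept$euclid_mm)
sf <- scaling_factor(kept$cable_mm, kept$euclid_mm)

message(sprintf("lambda_d  = %.2f mm^-1, interval [%.2f, %.2f] (truth %.1f)",
                fit_d$lambda_per_mm, fit_d$lambda_interval[1],
                fit_d$lambda_interval[2], cfg$lambda_d_true))
message(sprintf("lambda_ED = %.2f mm^-1, interval [%.2f, %.2f] (truth ~%.1f)",
                fit_ed$lambda_per_mm, fit_ed$lambda_interval[1],
                fit_ed$lambda_interval[2],
                cfg$lambda_d_true * cfg$tortuosity_a))
message(sprintf("scaling factor a = %.3f (truth %.1f), Pearson r = %.3f",
                sf$slope_a, cfg$tortuosity_a, sf$pearson_r))
message(sprintf("intra/inter-hemispheric neurons: %d / %d",
                sum(kept$hemi_class == "intra"),
                sum(kept$hemi_class == "inter")))

fits <- list(
  lambda_d = list(lambda_per_mm = fit_d$lambda_per_mm,
                  interval = fit_d$lambda_interval,
                  per_bin_size = fit_d$per_bin_size),
  lambda_ED = list(lambda_per_mm = fit_ed$lambda_per_mm,
                   interval = fit_ed$lambda_interval,
                   per_bin_size = fit_ed$per_bin_size),
  scaling = sf,
  kept_fraction = attr(rec, "kept_fraction"))
jsonlite::write_json(fits, res_path("edr_fits.json"), auto_unbox = TRUE,
                     digits = NA)
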