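# Shared study conditions for the analysis workflow.
#
# The synthetic study emulates the fly projectome's scale: 75 regions
# (37 bilateral pairs + 1 central), M = 4,733 directed links (85% density),
# a path-length decay rate of 22 mm^-1 with tortuosity 1.5 (so Euclidean
# cable lengths decay at ~33 mm^-1, the rate used by the region-level
# model), and the lambda grid 0, 5, ..., 60 mm^-1.

library(edrnet)

cfg <- list(
  seed = 42L,
  n_pairs = 37L,
  n_central = 1L,
  spatial_scale_mm = 0.6,
  lambda_d_true = 22,        # path-length decay rate, mm^-1
  tortuosity_a = 1.5,        # Euclidean rate ~ a * lambda_d ~ 33 mm^-1
  n_neurons = 10000L,
  consistency_threshold_mm = 0.15,
  M = 4733L,
  beta = 12,                 # hierarchy bias strength of the synthetic data
  lambda_grid = seq(0, 60, by = 5),
  n_networks = 100L,         # ensemble size per lambda (scaled from 1000)
  results_dir = "results"
)

dir.create(cfg$results_dir, showWarnings = FALSE)
res_path <- function(...) file.path(cfg$results_dir, ...)

atlas <- make_atlas(cfg$n_pairs, cfg$n_central, cfg$spatial_scale_mm,
                    seed = cfg$seed)
truth <- synthetic_truth(cfg$lambda_d_true, cfg$tortuosity_a,
                         seed = cfg$seed)
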