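# Shared configuration for the analysis drivers: a study-scale synthetic
# population mirroring a California-style clonal strawberry program —
# 27 elite + 3 exotic founders, 356 elite x elite and 113 elite x exotic F1
# hybrids, 31 S1 selfs of 9 elite parents, 5,000 array SNPs on 28
# chromosomes, and a 2-year x 3-block trial with 12 weekly harvests.
# Two traits: a yield-like trait with directional dominance and genetic
# load, and an anthocyanin-like unselected trait with no directional bias.

library(hetsim)

results_dir <- file.path("results")          # small summary tables
sim_dir <- file.path("scratch", "sim")        # bulk simulated data
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(sim_dir, showWarnings = FALSE, recursive = TRUE)

study_config <- sim_config(
  n_elite_founders = 27, n_exotic_founders = 3,
  n_markers = 5000, n_chromosomes = 28, divergence = 0.2,
  n_elite_hybrids = 356, n_exotic_hybrids = 113,
  n_s1 = 31, n_s1_parents = 9,
  n_years = 2, n_blocks = 3, n_harvests = 12, harvest_sd = 0.5,
  traits = default_trait_specs(),
  seed = 20260920
)
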