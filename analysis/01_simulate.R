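#!/usr/bin/env Rscript
# Generate the synthetic study system: a dated phylogeny, range evolution on
# the hotspot/non-hotspot/elsewhere state space, a gridded occurrence table
# with clustered narrow-ranged hotspot endemics, and environmental layers
# with known hotspot effects.  All downstream scripts read these files.
library(hotspotdiv)

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = 20260920L)
dat <- simulate_dataset(cfg)

write_tree_newick(dat$tree, file.path(outdir, "tree.nwk"))
write_cells_csv(dat$cells, file.path(outdir, "cells.csv"))
write_occurrence_csv(dat$occ, file.path(outdir, "occurrence.csv"))
write_env_csv(dat$env, file.path(outdir, "env.csv"))
write_partition_csv(dat$true_partition, file.path(outdir, "true_partition.csv"))
write_ground_truth_json(list(
  seed = cfg$seed, d_true = cfg$d_true, e_true = cfg$e_true,
  j_true = cfg$j_true, family = cfg$family, birth = cfg$birth,
  death = cfg$death, sar_lambda = cfg$sar_lambda,
  env_effects = as.list(cfg$env_effects),
  true_event_counts = as.list(table(dat$history$node_events$type)),
  resimulations = dat$history$resimulations),
  file.path(outdir, "ground_truth.json"))

message(sprintf(
  "simulated %d species on a %dx%d grid; root age %.1f Ma; %d branch resimulations",
  cfg$n_species, cfg$grid_nx, cfg$grid_ny,
  max(ape::node.depth.edgelength(dat$tree)), dat$history$resimulations))
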