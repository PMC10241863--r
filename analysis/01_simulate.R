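#!/usr/bin/env Rscript
# Generate the full synthetic study: puddle geometries, scale traces,
# probe traces, embryo landmark series and fibre images, each with a
# truth.csv sidecar. Everything downstream (02-05) reads from results/synth.

suppressPackageStartupMessages(library(vitmech))

seed <- 20260923
cfg <- sim_config(seed = seed)
out <- file.path("results", "synth")

message("Simulating all input types under seed ", seed, " ...")
paths <- simulate_all(cfg, out)
message("Wrote ", length(paths), " files under ", out)

by_kind <- table(basename(dirname(paths)))
for (k in names(by_kind)) message(sprintf("  %-10s %3d files", k, by_kind[[k]]))
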