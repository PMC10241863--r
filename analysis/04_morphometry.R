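#!/usr/bin/env Rscript
# Embryo morphometrics: axis speeds from the synthetic landmark series and
# fibre density across the synthetic coverage grid.

suppressPackageStartupMessages(library(vitmech))

synth <- file.path("results", "synth")
out_dir <- file.path("results", "morphometry")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## landmark series ----------------------------------------------------------
lm_files <- setdiff(list.files(file.path(synth, "landmarks"),
                               pattern = "\\.csv$", full.names = TRUE),
                    file.path(synth, "landmarks", "truth.csv"))
speeds <- do.call(rbind, lapply(lm_files, function(f) {
  s <- read_landmark_series(f)
  cbind(data.frame(sample_id = sub("\\.csv$", "", basename(f))),
        axis_speeds(s))
}))
speeds$group <- sub("_[0-9]+$", "", speeds$sample_id)
write.csv(speeds, file.path(out_dir, "axis_speeds.csv"), row.names = FALSE)

truth <- read.csv(file.path(synth, "landmarks", "truth.csv"))
cmp <- merge(speeds, truth, by = "sample_id")
for (g in unique(cmp$group.x)) {
  sub <- cmp[cmp$group.x == g, ]
  message(sprintf(
    "%s (n = %d): elongation %.1f um/h (true %.1f), convergence %.1f um/h (true %.1f), segmentation %.2f pairs/h (true %.2f)",
    g, nrow(sub), mean(sub$elongation_um_per_h), sub$elong[1],
    mean(sub$convergence_um_per_h), sub$conv[1],
    mean(sub$segmentation_pairs_per_h), sub$seg_rate[1]))
}

long <- do.call(rbind, lapply(
  c(elongation = "elongation_um_per_h", convergence = "convergence_um_per_h",
    segmentation = "segmentation_pairs_per_h"),
  function(col) data.frame(sample_id = speeds$sample_id,
                           group = speeds$group, metric = col,
                           value = speeds[[col]])))
write.csv(long, file.path(out_dir, "metric_speeds.csv"), row.names = FALSE)

## fibre density ------------------------------------------------------------
fb_files <- setdiff(list.files(file.path(synth, "fibre"),
                               pattern = "\\.csv$", full.names = TRUE),
                    file.path(synth, "fibre", "truth.csv"))
dens <- do.call(rbind, lapply(fb_files, function(f) {
  img <- as.matrix(read.csv(f))
  data.frame(sample_id = sub("\\.csv$", "", basename(f)),
             density = as.numeric(
               fibre_density(img, n_rois = 8,
                             roi_size = min(192, nrow(img)), seed = 1)))
}))
ftruth <- read.csv(file.path(synth, "fibre", "truth.csv"))
fcmp <- merge(dens, ftruth, by = "sample_id")
rho <- cor(fcmp$density, fcmp$target_coverage, method = "spearman")
message(sprintf("Fibre density: %d images, Spearman rho vs generated coverage = %.2f",
                nrow(fcmp), rho))
write.csv(fcmp, file.path(out_dir, "fibre_density.csv"), row.names = FALSE)
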