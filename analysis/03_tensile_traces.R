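#!/usr/bin/env Rscript
# Tensile measurements: native/maximum tension from the synthetic scale
# traces and stiffness slopes from the synthetic probe traces.

suppressPackageStartupMessages(library(vitmech))

synth <- file.path("results", "synth")
out_dir <- file.path("results", "tensile")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## scale traces -------------------------------------------------------------
scale_files <- setdiff(list.files(file.path(synth, "scale"),
                                  pattern = "\\.csv$", full.names = TRUE),
                       file.path(synth, "scale", "truth.csv"))
traces <- lapply(scale_files, read_scale_trace)
names(traces) <- sub("\\.csv$", "", basename(scale_files))
res <- analyse_scale_traces(traces, jump_tol = 0.3)
res$group <- sub("_[0-9]+$", "", res$sample_id)
write.csv(res, file.path(out_dir, "scale_tensions.csv"), row.names = FALSE)

truth <- read.csv(file.path(synth, "scale", "truth.csv"))
cmp <- merge(res, truth, by = "sample_id")
message(sprintf("Scale traces: %d analysed, native-tension RMSE %.4f N/m, max-tension RMSE %.4f N/m",
                nrow(cmp),
                sqrt(mean((cmp$gamma_native_N_per_m - cmp$gamma_native)^2)),
                sqrt(mean((cmp$gamma_max_N_per_m - cmp$gamma_max)^2))))
message(sprintf("gamma_max >= gamma_native in %d/%d traces",
                sum(cmp$gamma_max_N_per_m >= cmp$gamma_native_N_per_m),
                nrow(cmp)))

long <- rbind(
  data.frame(sample_id = res$sample_id, group = res$group,
             metric = "gamma_native", value = res$gamma_native_N_per_m),
  data.frame(sample_id = res$sample_id, group = res$group,
             metric = "gamma_max", value = res$gamma_max_N_per_m))
write.csv(long, file.path(out_dir, "metric_scale.csv"), row.names = FALSE)

## probe traces -------------------------------------------------------------
probe_files <- setdiff(list.files(file.path(synth, "probe"),
                                  pattern = "\\.csv$", full.names = TRUE),
                       file.path(synth, "probe", "truth.csv"))
stiff <- do.call(rbind, lapply(probe_files, function(f) {
  r <- analyse_probe_trace(read_probe_trace(f))
  data.frame(sample_id = sub("\\.csv$", "", basename(f)),
             slope_mN_per_s = r$slope_mN_per_s,
             window_start_s = r$window_start_s, qc = r$qc)
}))
stiff$group <- sub("_[0-9]+$", "", stiff$sample_id)
write.csv(stiff, file.path(out_dir, "probe_stiffness.csv"), row.names = FALSE)

ptruth <- read.csv(file.path(synth, "probe", "truth.csv"))
pcmp <- merge(stiff[stiff$qc == "ok", ], ptruth, by = "sample_id")
message(sprintf("Probe traces: %d/%d pass QC; slope recovery within %.1f%% (worst case)",
                sum(stiff$qc == "ok"), nrow(stiff),
                100 * max(abs(pcmp$slope_mN_per_s / pcmp$slope - 1))))

write.csv(data.frame(sample_id = stiff$sample_id, group = stiff$group,
                     metric = "stiffness_slope", value = stiff$slope_mN_per_s),
          file.path(out_dir, "metric_stiffness.csv"), row.names = FALSE)
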