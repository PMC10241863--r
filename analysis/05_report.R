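#!/usr/bin/env Rscript
# Assemble the summary report: per-group mean +/- SD for every metric the
# earlier stages produced, plus pairwise two-tailed Welch t-tests.

suppressPackageStartupMessages(library(vitmech))

rep <- build_report("results", out_dir = file.path("results", "report"))
message("Report over ", rep$n_files, " metric tables:")
s <- rep$summary
for (i in seq_len(nrow(s)))
  message(sprintf("  %-26s %-8s n=%2d  %8.3f +/- %.3f",
                  s$metric[i], s$group[i], s$n[i], s$mean[i], s$sd[i]))

t <- rep$tests
message(attr(t, "n_comparisons"), " pairwise comparisons (no multiplicity correction):")
for (i in seq_len(nrow(t)))
  message(sprintf("  %-26s %s vs %s: t = %6.2f, p = %.2g",
                  t$metric[i], t$group_a[i], t$group_b[i], t$t[i], t$p[i]))
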