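# vitmech

Quantitative mechanics of the avian vitelline membrane (VM) — the
glycoprotein envelope that encloses the yolk and mechanically supports the
early blastoderm — and of the embryo phenotypes that respond to it.

The package is built for researchers measuring tissue-scale tension in
early avian development. It implements four measurement modalities behind
one tested API, plus synthetic-data generators with known ground truth so
every estimator can be validated end to end:

* **Drop-shape tension model.** A yolk on a flat plate is a uniform liquid
  of density ρ and volume V wrapped by a membrane under isotropic tension
  γ. Its equilibrium shape solves the axisymmetric Young–Laplace balance
  γ(κ₁+κ₂) = p₀ + ρgu with contact angle π at the plate, governed by the
  Bond number Bo = ρgV^(2/3)/γ. `solve_drop_shape()` computes the shape by
  a shooting method; `invert_tension()` root-finds the γ that reproduces
  an observed *yolk index* (puddle height / maximum diameter);
  `energy_oracle_shape()` is an independent energy-minimization
  cross-check.
* **Scale tensile traces.** `detect_events()` locates the cut, after-cut
  plateau, breaking point and detached weight in a balance reading;
  `native_tension()` and `max_tension()` apply
  γ = |Δm|·g/L over the strip width L.
* **Probe stiffness.** `analyse_probe_trace()` baseline-corrects,
  averages to 1 Hz, QC-screens (early rupture, holder hits, no contact)
  and extracts the rate of force increase over the most linear 20-s
  window.
* **Embryo morphometrics.** Elongation / convergence / segmentation
  speeds from landmark time series; glycoprotein fibre density by Otsu
  binarization and random-ROI averaging.
* **Statistics.** Two-tailed Welch/pooled t-tests, one-way ANOVA, and
  `build_report()` for mean ± SD summary panels.

## Worked example

Invert VM tension from the two characteristic puddle geometries of early
incubation — a round, freshly laid (day-0-like) yolk with index 0.45 and a
flattened day-2-like yolk with index 0.25, both at 17 mL and 1.035 g/cm³:

```r
library(vitmech)

prof <- solve_drop_shape(drop_params(tension = 0.3))
prof
#> drop profile: H = 11.434 mm, D = 48.577 mm, yolk index = 0.2354 (Bo = 22.4)

g_round <- invert_tension(0.45)   # 0.955 N/m
g_flat  <- invert_tension(0.25)   # 0.328 N/m
100 * g_flat / g_round
#> [1] 34.4
```

Both tensions fall in the 0.1–1 N/m band, and the flattened puddle carries
roughly 40% of the round puddle's tension — the model's statement of how
much the membrane weakens over the first two days, driven purely by the
change in puddle shape.

The tensile formulas are exact closed forms:

```r
ev <- list(m_detached_g = 10, m_after_cut_g = 9.2, m_breaking_g = 6)
native_tension(ev)  # |9.2 - 10| g over 2 cm -> 0.392 N/m
max_tension(ev)     # |6 - 10| g  over 2 cm -> 1.96 N/m
```

And a full synthetic study runs through the numbered scripts:

```sh
Rscript analysis/01_simulate.R        # all input types + truth sidecars
Rscript analysis/02_drop_model.R      # forward curve, inversion, recovery
Rscript analysis/03_tensile_traces.R  # scale + probe pipelines
Rscript analysis/04_morphometry.R     # speeds + fibre density
Rscript analysis/05_report.R          # mean +/- SD panels and t-tests
```

`02_drop_model.R` reports, for example, group-mean recovered tensions of
0.958 ± 0.043 N/m (true 0.95) and 0.379 ± 0.014 N/m (true 0.38) from 20
noisy observations per group.

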