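---
title: "Membrane tension from yolk puddle shape, tensile traces and embryo morphometrics"
author: "vitmech"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

The avian vitelline membrane (VM) is the glycoprotein envelope around the
yolk and the mechanical substrate of the early blastoderm. Its tension
cannot be read off directly in ovo, but it leaves three quantitative
signatures that this package turns into numbers:

1. **Puddle shape.** A yolk opened onto a flat plate spreads into a puddle
   whose flatness is set by the balance between gravity and the tension of
   the membrane wrapping it. The *yolk index* (height / maximum diameter)
   is the classical egg-quality metric for this shape and falls as the
   membrane weakens.
2. **Tensile traces.** A VM strip suspending a calibrated weight inside a
   balance reads out the force the membrane carries before and at rupture.
3. **Indentation stiffness.** A probe pushed into the membrane at constant
   speed produces a force ramp whose rate of increase reflects membrane
   stiffness.

Around these sit embryo-phenotype morphometrics (axis elongation,
convergence and segmentation speeds, fibre density of the stained
membrane) and the group statistics that compare conditions.

# The drop-shape model

## Physics and assumptions

The yolk is modelled as a uniform liquid of density $\rho$ and volume $V$,
enclosed by a membrane carrying a uniform isotropic tension $\gamma$,
resting on a rigid horizontal plate in a massless exterior. The model
deliberately omits: bending stiffness (the VM is thin relative to the
puddle), strain-dependent elasticity (a single equilibrium shape cannot
constrain a constitutive law), adhesion to the plate, and any
time-dependence of $\gamma$. With these assumptions the membrane obeys the
axisymmetric Young–Laplace balance

$$\gamma\,(\kappa_1 + \kappa_2) = p_0 + \rho g u,$$

where $u$ is depth below the apex, $p_0$ the apex pressure and
$\kappa_1, \kappa_2$ the meridional and azimuthal curvatures. Because the
membrane wraps the yolk completely and the plate is non-adhesive, the free
meridian meets the plate tangentially — contact angle $\pi$ — at the rim
of a flat contact disk. The single dimensionless control parameter is the
Bond number

$$\mathrm{Bo} = \frac{\rho g V^{2/3}}{\gamma},$$

with the sphere limit at $\mathrm{Bo}\to 0$ and the pancake limit
($H \to 2\sqrt{\gamma/\rho g}$, twice the capillary length) at
$\mathrm{Bo}\to\infty$. For a 17 mL chicken yolk, tensions of 1 and
0.1 N/m correspond to $\mathrm{Bo} \approx 7$ and $67$: the physiological
regime sits squarely between the two limits, which is why the full
boundary-value problem is solved rather than either asymptote.

## Numerical solution

All computation is nondimensionalized by $V^{1/3}$ (lengths) and $\gamma$
(pressure $\times$ length), which keeps the problem well conditioned over
the supported range $\mathrm{Bo} \in [10^{-3}, 10^{4}]$. The meridian is
integrated from the apex in arc length,

$$\frac{dr}{ds} = \cos\phi,\quad \frac{du}{ds} = \sin\phi,\quad
\frac{d\phi}{ds} = (p_0 + \mathrm{Bo}\,u) - \frac{\sin\phi}{r},$$

with L'Hôpital regularization $\sin\phi/r \to p_0/2$ at the apex and a
series start a distance $10^{-7}$ from $r = 0$. Integration
(`deSolve::lsodar`) stops at the root $\phi = \pi$; the enclosed volume is
accumulated as a fourth state. The only shooting unknown is the apex
pressure, root-found on $\log p_0$ so that the enclosed volume equals 1
(default relative tolerance $10^{-6}$).

Two numerical points deserve note:

* **The flat-apex regime.** At high Bond number the apex pressure decays
  like $\exp(-R/\lambda)$ with $R$ the puddle radius and $\lambda$ the
  capillary length; at $\mathrm{Bo} = 10^3$–$10^4$ the root lies around
  $10^{-28}$–$10^{-170}$. These values are still representable in double
  precision, so a single shooting formulation covers the whole range —
  provided the integrator's absolute tolerances on $\phi$ and $u$ are set
  far below those magnitudes (we use $10^{-300}$, letting the relative
  tolerance govern), and the bracket search runs on $\log p_0$.
* **The diameter.** The maximum horizontal extent of the meridian — what a
  side photograph of the puddle measures — lies strictly above the contact
  rim and between output samples; it is located by cubic-spline
  interpolation around the largest sample, which removes an
  $O(h^2)$ grid bias that would otherwise dominate the inversion error.

A session cache keyed by $\log \mathrm{Bo}$ stores solved apex pressures:
an exact key hit returns the stored root (making repeat solves bitwise
reproducible), and a nearby key seeds the bracket, which speeds up the
root-finding loops of the inversion considerably.

## Inversion and its conditioning

`invert_tension()` root-finds the tension whose forward solution matches
an observed yolk index, on $\log\gamma$ over a default bracket of
$(10^{-3}, 10)$ N/m. The yolk index is strictly increasing in $\gamma$
(verified as a test invariant on a 10-point grid), so the root is unique.
The inversion is specified on the yolk index rather than absolute height:
the index is dimensionless, insensitive to volume error (both $H$ and $D$
shift together), and is the quantity actually recorded in egg-quality
practice. Height-based inversion at fixed volume is available implicitly
by passing `c(H, D)`.

A noiseless round trip (forward solve, then invert) recovers $\gamma$ to
better than 0.1%. Near-spherical observations (index $\to 1$) need
unboundedly large tension; the bracket error is raised rather than
extrapolating.

## The energy-minimization oracle

`energy_oracle_shape()` solves the same physics by a disjoint route:
direct minimization of $\gamma\,A + \rho g \int z\,dV$ over profiles
discretized as $r(z)$ on a uniform height grid (default 160 intervals),
with the volume constraint enforced exactly by uniform rescaling (an
energy-equivalent reparameterization). L-BFGS-B with an analytic gradient
is run from both a sphere start and a pancake start, keeping the lower
energy. The two methods share no code beyond the parameter container and
agree in height and diameter to within 0.3% across
$\mathrm{Bo} \in \{0.5, 5, 50\}$ — comfortably inside the 2% agreement the
tests demand. The oracle exists for validation; it is slower and less
accurate than the shooting solver and is not used in any pipeline.

# Tensile trace analysis

The scale protocol yields the event weights feeding two exact formulas:
$\gamma_{\text{native}} = |m_{\text{after-cut}} - m_{\text{detached}}|\,g/L$
and
$\gamma_{\text{max}} = |m_{\text{breaking}} - m_{\text{detached}}|\,g/L$
($L$ = 2 cm strip width, $g$ = 9.8 m/s²). The printed difference is
negative under the sign convention of the reading (the reading falls as
the membrane takes load), so the magnitude is reported — tension is
non-negative by definition.

Event detection is ours to define (no published algorithm): the trace is
median-smoothed over ~0.5 s; the cut and the rupture are reading changes
exceeding `jump_tol` over a 1.5 s lag (spanning the cut transient), the
after-cut plateau is the first smoothed segment of spread below
`plateau_tol` lasting at least 2 s between cut and rupture, and the
detached weight is the mean of the terminal post-rupture plateau — the
one moment the protocol guarantees the weight rests fully on the scale.
A trace with no rupture still yields the native tension (with an
`incomplete` flag); a trace with no stable after-cut plateau is a QC
failure. Defaults (`plateau_tol` 0.2 g, `jump_tol` 1 g) suit a gram-scale
protocol with centigram noise; batch analyses of low-tension samples
(weight differences below 1 g) should lower `jump_tol` accordingly, as the
analysis scripts do.

# Probe stiffness

Processing follows the measurement chain: per-trace baseline subtraction
(mean force over the 5 s before probe movement), averaging to one value
per second (bin centers), QC, then the stiffness metric — the slope of the
force curve over a 20-s window in its approximately linear phase. Where
that window sits is a judgment call the protocol leaves open; we select,
among all contiguous 20-s windows after contact, the one maximizing the
$R^2$ of a straight-line fit (earliest on ties). This makes the choice
reproducible and automatically excludes a soft contact onset, at the cost
of a slight optimism bias that is identical across groups. Contact is the
first 1-Hz sample exceeding 3 baseline residual SDs for 3 consecutive
samples. QC flags early rupture (force drop > `drop_tol` below its running
maximum during the push), holder collisions (force above `force_cap`,
default 20 mN, or a discontinuous slope jump) and absent contact.

# Morphometrics

Axis speeds are least-squares slopes over all frames — elongation from the
Euclidean distance between the reference somite pair and the posterior
end, convergence as minus the slope of the posterior neural tube width,
segmentation from the somite count. Regression uses every frame rather
than endpoint differences because landmark noise (µm-scale) is large
relative to per-frame displacement; negative speeds (shortening, widening)
are meaningful and pass through. Fibre density binarizes the stained
image with a global Otsu threshold on the min-max-normalized image
(scale-invariant, parameter-free, in place of irreproducible manual
thresholding; `fibres_dark` flips polarity) and averages the white
fraction over randomly placed square ROIs with a recorded seed. ROI count
and size default to 10 and 128 px and are configurable — the reported
experiments state only per-figure ROI counts.

# Synthetic data: what it emulates, what it does not

The generators produce every input type with known truth under the study
conditions: true tensions 0.95/0.38 N/m for the two puddle groups (inside
the 0.1–1 N/m range, ratio 0.4), geometry noise 0.3 mm, scale cohorts of
15 and 19, probe cohorts of 15 and 17 with slope 0.08 vs 0.03 mN/s and
0.01 mN sensor noise at 100 Hz, landmark noise 5 µm at 0.5 h frames,
segmentation clock 0.667 pairs/h (one pair per 1.5 h). All noise is
Gaussian and independent across samples; identical configurations write
byte-identical files.

What the generators do **not** emulate: viscoelastic relaxation during the
loading ramp, spatial heterogeneity of the membrane, drift or 1/f sensor
noise, landmark mis-tracking, uneven staining background, or correlated
biological variability between metrics of one embryo. Passing the
recovery tests therefore shows the estimators are correct and unbiased
under the stated noise model — not that real traces cannot fail QC in ways
the generators never produce.

# Statistics

Group comparisons are two-tailed t-tests and one-way ANOVA via the stock R
implementations; Welch's test is the default because group SDs of these
measurements differ visibly, with a pooled-variance switch for
comparability. Both are cross-checked in the tests against explicit
sums-of-squares arithmetic to $10^{-10}$, and the simulated null type-I
error is checked against the binomial interval at 1000 replicates. No
multiplicity correction is applied (matching reporting practice in this
field); the report records the number of comparisons. The all-constant
degenerate case (zero variance in both groups) returns $t = 0, p = 1$ for
equal means rather than erroring, so noiseless pipelines summarize
cleanly.

# Problem sizes and runtimes

The shipped analyses use 20 samples per group for puddle inversion and
landmarks, the reported cohort sizes for scale and probe, 512 px fibre
images over an 8-step coverage grid, and meridians of 400 points; the full
test suite (including every limit check and the oracle comparisons) runs
in about a minute and a half, and the acceptance script in ~15 s. These
sizes were chosen so a complete replication runs on a laptop in minutes
while keeping Monte-Carlo error well below the 2-SE recovery bands.

# Known limitations

* The drop-shape model identifies the tension of an *effective* isotropic
  membrane; if the real VM is anisotropically stressed or partially
  adhered, the inverted value is an aggregate.
* The tension ratio between two geometries is less model-sensitive than
  either absolute tension (constitutive details largely cancel), which is
  why the ratio is the more robust headline number.
* Above $\mathrm{Bo} \approx 10^4$ the apex pressure underflows double
  precision and the solver reports a domain error instead of switching to
  an asymptotic construction.
* The stiffness slope is a rate of force increase (mN/s), not an elastic
  modulus; converting it would require a contact-mechanics model and probe
  geometry outside this package's scope.
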