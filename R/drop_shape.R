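## Axisymmetric sessile-drop model of the yolk puddle.
##
## A yolk of volume V and density rho rests on a rigid horizontal plate,
## enclosed by a membrane carrying uniform isotropic tension gamma (no
## bending stiffness, no strain dependence). The surrounding medium is
## treated as massless. At mechanical equilibrium the membrane satisfies
## the Young-Laplace balance
##
##     gamma * (k1 + k2) = p0 + rho * g * u
##
## where u is depth below the apex, p0 the apex pressure, and k1, k2 the
## meridional and azimuthal curvatures. The membrane wraps the yolk
## completely and the plate is non-adhesive, so the free meridian meets the
## plate tangentially (contact angle pi) at the rim of a flat contact disk.
##
## Everything is nondimensionalized by a = V^(1/3) (lengths) and gamma
## (pressures x a); the single control parameter is the Bond number
## Bo = rho * g * V^(2/3) / gamma. The shape is found by shooting from the
## apex on log(p0): integrating the arc-length equations
##
##     dr/ds = cos(phi),  du/ds = sin(phi),
##     dphi/ds = (p0 + Bo * u) - sin(phi)/r          (phi: tangent angle)
##
## until phi = pi, and root-finding p0 so the enclosed volume is 1. At high
## Bo the apex flattens and p0 decays like exp(-R/lambda) (lambda the
## capillary length), reaching ~1e-170 at Bo = 1e4; this stays within
## double range, so a single shooting formulation covers the whole
## supported Bo range provided the integrator uses tiny absolute
## tolerances on phi and u.

BO_MIN <- 1e-3
BO_MAX <- 1e4

#' Physical parameters of a membrane-enclosed yolk puddle
#'
#' Bundles the quantities that define one drop-shape problem: membrane
#' tension, interior density, enclosed volume and gravitational
#' acceleration. Units follow lab practice (N/m, g/cm^3, mL); conversion
#' to SI happens internally.
#'
#' @param tension Membrane tension gamma in N/m. Must be positive.
#' @param volume_ml Enclosed yolk volume in mL (default 17, a typical
#'   chicken yolk).
#' @param density_g_cm3 Yolk density in g/cm^3 (default 1.035).
#' @param gravity Gravitational acceleration in m/s^2 (default 9.8).
#'
#' @return An object of class `membrane_drop_params`: a list with the
#'   given fields plus the derived capillary length `capillary_length_mm`
#'   and Bond number `bond_number` (= rho g V^(2/3) / gamma).
#' @examples
#' p <- drop_params(tension = 0.3)
#' p$bond_number
#' @export
drop_params <- function(tension, volume_ml = 17, density_g_cm3 = 1.035,
                        gravity = 9.8) {
  if (!is.numeric(tension) || length(tension) != 1L || !is.finite(tension) ||
      tension <= 0)
    vm_abort("`tension` must be a single positive number (N/m)",
             "vitmech_domain_error")
  if (volume_ml <= 0 || density_g_cm3 <= 0 || gravity <= 0)
    vm_abort("volume, density and gravity must all be positive",
             "vitmech_domain_error")
  V <- volume_ml * 1e-6           # m^3
  rho <- density_g_cm3 * 1000     # kg/m^3
  bo <- rho * gravity * V^(2 / 3) / tension
  structure(
    list(tension = tension, volume_ml = volume_ml,
         density_g_cm3 = density_g_cm3, gravity = gravity,
         volume_m3 = V, density_kg_m3 = rho,
         capillary_length_mm = sqrt(tension / (rho * gravity)) * 1000,
         bond_number = bo),
    class = "membrane_drop_params")
}

#' @export
print.membrane_drop_params <- function(x, ...) {
  cat(sprintf(
    "membrane drop: gamma = %.4g N/m, V = %.4g mL, rho = %.4g g/cm^3, Bo = %.4g\n",
    x$tension, x$volume_ml, x$density_g_cm3, x$bond_number))
  invisible(x)
}

## -- nondimensional shooting core -------------------------------------------

## Integrate the meridian from the apex for a given apex pressure p0.
## Returns the deSolve matrix; last row is the contact point if phi reached
## pi within the arc-length horizon.
shoot_meridian <- function(p0, bo, n_out = 2L) {
  smax <- 10 + 8 * bo^0.25
  deriv <- function(s, y, parms) {
    r <- y[1L]; u <- y[2L]; phi <- y[3L]
    k2 <- if (r < 1e-12) p0 / 2 else sin(phi) / r
    list(c(cos(phi), sin(phi), (p0 + bo * u) - k2, pi * r^2 * sin(phi)))
  }
  rootf <- function(s, y, parms) y[3L] - pi
  s0 <- 1e-7
  b <- p0 / 2  # apex curvature (k1 = k2 = p0/2); series start avoids r = 0
  y0 <- c(r = s0, u = b * s0^2 / 2, phi = b * s0, vol = 0)
  times <- if (n_out <= 2L) c(s0, smax) else seq(s0, smax, length.out = n_out)
  suppressWarnings(deSolve::lsodar(
    y0, times, deriv, parms = NULL, rootfunc = rootf,
    rtol = 1e-9, atol = c(1e-13, 1e-300, 1e-300, 1e-13),
    maxsteps = 500000))
}

meridian_closed <- function(out) {
  abs(out[nrow(out), "phi"] - pi) < 1e-6
}

## volume residual (enclosed volume - 1) as a function of log(p0);
## +Inf when the meridian never turns tangent within the horizon (the
## candidate drop is larger than any shape that fits, i.e. volume too big).
vol_residual <- function(lp0, bo) {
  out <- shoot_meridian(exp(lp0), bo)
  if (!meridian_closed(out)) return(Inf)
  out[nrow(out), "vol"] - 1
}

## Session cache of solved apex pressures keyed by log(Bo). An exact-key
## hit returns the stored root (repeat solves are bitwise reproducible); a
## nearby key only seeds the root bracket.
.p0_cache <- new.env(parent = emptyenv())

cache_key <- function(bo) sprintf("%.17g", log(bo))

cached_lp0_near <- function(bo) {
  keys <- ls(.p0_cache)
  if (length(keys) == 0L) return(NULL)
  lbos <- as.numeric(keys)
  i <- which.min(abs(lbos - log(bo)))
  if (abs(lbos[i] - log(bo)) > 1.0) return(NULL)
  get(keys[i], envir = .p0_cache)
}

## Find log(p0) giving unit enclosed volume. Bracket expands multiplicatively
## from either a cached neighbour or the unit-volume-sphere pressure.
solve_apex_pressure <- function(bo) {
  key <- cache_key(bo)
  if (exists(key, envir = .p0_cache, inherits = FALSE))
    return(get(key, envir = .p0_cache))
  f <- function(lp) vol_residual(lp, bo)
  seed <- cached_lp0_near(bo)
  lp_start <- if (!is.null(seed)) seed else log(2 / (3 / (4 * pi))^(1 / 3))
  step <- 0.75
  lp_hi <- lp_start; f_hi <- f(lp_hi); it <- 0L
  while (is.finite(f_hi) && f_hi > 0 && it < 600L) {  # need volume < 1: raise p0
    lp_hi <- lp_hi + step; f_hi <- f(lp_hi); it <- it + 1L
  }
  lp_lo <- lp_start; f_lo <- f(lp_lo); it <- 0L
  while (f_lo < 0 && it < 600L) {                     # need volume > 1: lower p0
    lp_lo <- lp_lo - step; f_lo <- f(lp_lo); it <- it + 1L
  }
  if (!(f_lo > 0 || is.infinite(f_lo)) || !(is.finite(f_hi) && f_hi < 0))
    vm_abort(
      sprintf("drop-shape shooting failed to bracket apex pressure (Bo = %g); last bracket log p0 in [%.3f, %.3f]",
              bo, lp_lo, lp_hi),
      "vitmech_solver_failure", bracket = c(lp_lo, lp_hi))
  r <- uniroot(function(lp) { v <- f(lp); if (is.infinite(v)) 1e6 else v },
               c(lp_lo, lp_hi), tol = 1e-10)
  assign(key, r$root, envir = .p0_cache)
  r$root
}

## Maximum of a sampled smooth curve: cubic-spline interpolation in a
## window around the largest sample; removes the O(h^2) bias of taking the
## discrete max (the meridian bulge is what the puddle diameter measures).
interp_max <- function(s, r) {
  i <- which.max(r)
  if (i <= 2L || i >= length(r) - 1L) return(r[i])
  j <- max(1L, i - 5L):min(length(r), i + 5L)
  sp <- stats::splinefun(s[j], r[j])
  stats::optimize(sp, range(s[j]), maximum = TRUE, tol = 1e-10)$objective
}

## Full nondimensional solution at a given Bond number.
solve_profile_nd <- function(bo, rtol = 1e-6, n_out = 400L) {
  if (!is.finite(bo) || bo < BO_MIN || bo > BO_MAX)
    vm_abort(sprintf("Bond number %g outside supported range [%g, %g]",
                     bo, BO_MIN, BO_MAX), "vitmech_domain_error")
  lp0 <- solve_apex_pressure(bo)
  out <- shoot_meridian(exp(lp0), bo, n_out = n_out)
  vol <- out[nrow(out), "vol"]
  if (!meridian_closed(out) || abs(vol - 1) > rtol)
    vm_abort(sprintf("drop-shape solve did not meet volume tolerance (|V-1| = %.3g > %g)",
                     abs(vol - 1), rtol), "vitmech_solver_failure")
  list(s = out[, "time"], r = out[, "r"], u = out[, "u"],
       vol = vol, p0 = exp(lp0), bo = bo)
}

## -- public API --------------------------------------------------------------

#' Solve the tensed-membrane sessile-drop shape
#'
#' Computes the equilibrium shape of a uniform-density drop enclosed by a
#' membrane under isotropic tension resting on a rigid horizontal plate
#' (contact angle pi: the membrane wraps the yolk completely and meets the
#' plate tangentially at the rim of a flat contact disk). The shape is the
#' solution of the axisymmetric Young-Laplace equation, obtained by a
#' shooting method on the apex pressure with the enclosed volume as the
#' matching condition.
#'
#' @param params A [drop_params()] object.
#' @param rtol Relative tolerance on the enclosed volume (default `1e-6`;
#'   must lie in `(0, 1e-2]`).
#' @param n_points Number of meridian points returned.
#'
#' @return An object of class `drop_profile`: a list with
#'   * `meridian`: data frame `s_mm`, `r_mm`, `z_mm` from the apex
#'     (`r = 0`, `z = H`) to the contact circle (`z = 0`), arc length `s`;
#'   * `height_mm` (H), `diameter_mm` (D, maximum horizontal extent of the
#'     meridian), `base_radius_mm`, `yolk_index` (H/D),
#'   * `volume_ml` (enclosed volume of the solution), `bond_number`,
#'     `apex_pressure_Pa`, and the input `params`.
#'
#' Errors: condition class `vitmech_domain_error` if the Bond number falls
#' outside `[1e-3, 1e4]`; `vitmech_solver_failure` (carrying the last
#' bracket) if the shooting iteration fails to converge.
#'
#' @examples
#' prof <- solve_drop_shape(drop_params(tension = 0.3))
#' prof$yolk_index
#' @seealso [invert_tension()], [yolk_index()], [energy_oracle_shape()]
#' @export
solve_drop_shape <- function(params, rtol = 1e-6, n_points = 400L) {
  stopifnot(inherits(params, "membrane_drop_params"))
  if (!is.numeric(rtol) || rtol <= 0 || rtol > 1e-2)
    vm_abort("`rtol` must lie in (0, 1e-2]", "vitmech_domain_error")
  nd <- solve_profile_nd(params$bond_number, rtol = rtol, n_out = n_points)
  a_mm <- (params$volume_m3)^(1 / 3) * 1000  # length scale V^(1/3) in mm
  H <- nd$u[length(nd$u)] * a_mm
  r_mm <- nd$r * a_mm
  z_mm <- H - nd$u * a_mm
  D <- 2 * interp_max(nd$s, nd$r) * a_mm
  structure(
    list(meridian = data.frame(s_mm = nd$s * a_mm, r_mm = r_mm, z_mm = z_mm),
         height_mm = H, diameter_mm = D,
         base_radius_mm = r_mm[length(r_mm)],
         yolk_index = H / D,
         volume_ml = nd$vol * params$volume_ml,
         bond_number = nd$bo,
         apex_pressure_Pa = nd$p0 * params$tension / (a_mm / 1000),
         params = params),
    class = "drop_profile")
}

#' @export
print.drop_profile <- function(x, ...) {
  cat(sprintf(
    "drop profile: H = %.3f mm, D = %.3f mm, yolk index = %.4f (Bo = %.4g)\n",
    x$height_mm, x$diameter_mm, x$yolk_index, x$bond_number))
  invisible(x)
}

#' Yolk index of a solved drop profile
#'
#' The yolk index is the puddle height divided by its maximum diameter, the
#' standard egg-quality metric used as a shape proxy for membrane tension.
#' The diameter is the maximum horizontal extent of the meridian, which is
#' what a side-view photograph of the puddle measures (it exceeds the
#' contact-disk diameter because the tangentially wrapping membrane bulges
#' outward above the plate).
#'
#' @param profile A `drop_profile` from [solve_drop_shape()] or
#'   [energy_oracle_shape()].
#' @return H/D, a dimensionless number in (0, 1].
#' @export
yolk_index <- function(profile) {
  stopifnot(inherits(profile, "drop_profile"))
  if (profile$diameter_mm <= 0)
    vm_abort("degenerate profile: zero diameter", "vitmech_degenerate_profile")
  profile$height_mm / profile$diameter_mm
}

#' Invert membrane tension from observed puddle geometry
#'
#' Root-finds the tension whose forward drop-shape solution reproduces an
#' observed yolk index at the given volume and density. The yolk index of
#' the model is strictly increasing in tension (more tension pulls the
#' puddle toward a sphere), so the root is unique within any bracket that
#' spans a sign change.
#'
#' @param observed Either a single yolk index in (0, 1), or a length-2
#'   numeric vector `c(H, D)` of height and diameter in mm from which the
#'   index is formed.
#' @param volume_ml,density_g_cm3,gravity Puddle parameters as in
#'   [drop_params()].
#' @param bracket Tension search interval in N/m (default `c(1e-3, 10)`).
#' @param rtol Forward-solver volume tolerance, also used (relative) as the
#'   convergence tolerance on tension.
#'
#' @return The tension in N/m.
#'
#' Errors: `vitmech_bracket_error` if the residual does not change sign over
#' the bracket (e.g. a near-spherical observation needing tension beyond the
#' bracket); forward-solver failures propagate.
#'
#' @examples
#' \donttest{
#' invert_tension(0.25)  # flattened (D2-like) puddle, ~0.1-0.2 N/m
#' }
#' @export
invert_tension <- function(observed, volume_ml = 17, density_g_cm3 = 1.035,
                           gravity = 9.8, bracket = c(1e-3, 10),
                           rtol = 1e-6) {
  yi <- if (length(observed) == 2L) {
    if (any(observed <= 0))
      vm_abort("H and D must be positive", "vitmech_domain_error")
    observed[[1L]] / observed[[2L]]
  } else observed[[1L]]
  if (!is.finite(yi) || yi <= 0 || yi >= 1)
    vm_abort("observed yolk index must lie in (0, 1)", "vitmech_domain_error")
  if (length(bracket) != 2L || bracket[1L] <= 0 || diff(bracket) <= 0)
    vm_abort("`bracket` must be an increasing positive pair (N/m)",
             "vitmech_domain_error")
  resid <- function(gam) {
    p <- drop_params(gam, volume_ml, density_g_cm3, gravity)
    nd <- solve_profile_nd(p$bond_number, rtol = rtol, n_out = 400L)
    H <- nd$u[length(nd$u)]
    H / (2 * interp_max(nd$s, nd$r)) - yi
  }
  f_lo <- resid(bracket[1L]); f_hi <- resid(bracket[2L])
  if (f_lo * f_hi > 0)
    vm_abort(sprintf(
      "no sign change of the yolk-index residual over [%g, %g] N/m (residuals %.4g, %.4g); widen the bracket",
      bracket[1L], bracket[2L], f_lo, f_hi), "vitmech_bracket_error")
  ## root on log(gamma): residual is monotone and better conditioned there
  r <- uniroot(function(lg) resid(exp(lg)), log(bracket),
               f.lower = f_lo, f.upper = f_hi, tol = 1e-7)
  exp(r$root)
}

#' Ratio of inverted tensions between two puddle observations
#'
#' Inverts the drop-shape model for two observations sharing volume and
#' density and returns `gamma(B) / gamma(A)`. With A a round (early, D0-like)
#' puddle and B a flattened (later, D2-like) one, this is the model's
#' prediction of how much the membrane tension has dropped.
#'
#' @param observed_A,observed_B Yolk index (or `c(H, D)` in mm) for the
#'   reference and comparison observations.
#' @inheritParams invert_tension
#' @return Dimensionless tension ratio gamma_B / gamma_A.
#' @examples
#' \donttest{
#' tension_ratio(0.45, 0.25)  # ~0.4: flattened puddle has ~40% of the tension
#' }
#' @export
tension_ratio <- function(observed_A, observed_B, volume_ml = 17,
                          density_g_cm3 = 1.035, gravity = 9.8,
                          bracket = c(1e-3, 10), rtol = 1e-6) {
  g_a <- invert_tension(observed_A, volume_ml, density_g_cm3, gravity,
                        bracket, rtol)
  g_b <- invert_tension(observed_B, volume_ml, density_g_cm3, gravity,
                        bracket, rtol)
  g_b / g_a
}

#' Read a puddle-geometry table
#'
#' Reads a CSV with columns `sample_id, day, height_mm, diameter_mm,
#' volume_ml, density_g_per_cm3`; missing volume/density entries are filled
#' with the defaults (17 mL, 1.035 g/cm^3).
#'
#' @param path CSV file path.
#' @param default_volume_ml,default_density Fill-in values for missing
#'   volume/density columns or cells.
#' @return A data frame with the full column set.
#' @export
read_puddle_table <- function(path, default_volume_ml = 17,
                              default_density = 1.035) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "day", "height_mm", "diameter_mm")
  if (!all(need %in% names(tab)))
    vm_abort(paste("puddle table must contain columns:",
                   paste(need, collapse = ", ")), "vitmech_domain_error")
  if (is.null(tab$volume_ml)) tab$volume_ml <- NA_real_
  if (is.null(tab$density_g_per_cm3)) tab$density_g_per_cm3 <- NA_real_
  tab$volume_ml[is.na(tab$volume_ml)] <- default_volume_ml
  tab$density_g_per_cm3[is.na(tab$density_g_per_cm3)] <- default_density
  tab
}

#' Invert tension for every row of a puddle-geometry table
#'
#' @param tab Data frame as returned by [read_puddle_table()] or
#'   [gen_puddle_observations()].
#' @inheritParams invert_tension
#' @return The table with an added `gamma_N_per_m` column.
#' @export
invert_tension_table <- function(tab, bracket = c(1e-3, 10), rtol = 1e-6) {
  tab$gamma_N_per_m <- vapply(seq_len(nrow(tab)), function(i) {
    invert_tension(c(tab$height_mm[i], tab$diameter_mm[i]),
                   volume_ml = tab$volume_ml[i],
                   density_g_cm3 = tab$density_g_per_cm3[i],
                   bracket = bracket, rtol = rtol)
  }, numeric(1))
  tab
}
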