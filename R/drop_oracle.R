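## Energy-minimization oracle for the drop shape.
##
## Independent check on the shooting solver: instead of integrating the
## Young-Laplace equation, directly minimize the total energy
##
##     E = gamma * (membrane area)  +  rho * g * integral(z dV)
##
## over discretized axisymmetric profiles at fixed enclosed volume. The
## profile is represented by its radius on a uniform height grid,
## r(z_j), z_j = H (1 - j/n), with the apex pinned at r = 0 and the base
## radius free (the flat contact disk also carries membrane, contributing
## pi r_base^2 of area). The volume constraint is enforced exactly by
## uniform rescaling of the candidate shape, which is an energy-equivalent
## reparameterization of the constrained problem. Minimization uses
## L-BFGS-B from two starts (sphere and pancake) and keeps the lower
## energy; it shares no code with the shooting path.

oracle_energy <- function(x, n, bo) {
  H <- x[1L]
  r <- c(0, x[-1L])                      # apex pinned at r = 0
  z <- H * (1 - (0:n) / n)
  dz <- H / n
  rbar <- (r[-1L] + r[-length(r)]) / 2
  dr <- diff(r)
  seg <- sqrt(dr^2 + dz^2)
  area <- 2 * pi * sum(rbar * seg) + pi * r[length(r)]^2
  zbar <- (z[-1L] + z[-length(z)]) / 2
  v0 <- pi * sum(rbar^2) * dz
  if (!is.finite(v0) || v0 <= 0) return(1e10)
  pe <- pi * sum(zbar * rbar^2) * dz
  k <- v0^(-1 / 3)                       # rescale to unit volume
  k^2 * area + bo * k^4 * pe
}

## analytic gradient of oracle_energy wrt (H, r_1..r_n)
oracle_energy_grad <- function(x, n, bo) {
  H <- x[1L]
  r <- c(0, x[-1L])
  dz <- H / n
  rbar <- (r[-1L] + r[-length(r)]) / 2
  dr <- diff(r)
  seg <- sqrt(dr^2 + dz^2)
  seg <- pmax(seg, 1e-300)
  cj <- 1 - (2 * seq_len(n) - 1) / (2 * n)
  zbar <- H * cj
  area <- 2 * pi * sum(rbar * seg) + pi * r[n + 1L]^2
  v0 <- pi * sum(rbar^2) * dz
  pe <- pi * sum(zbar * rbar^2) * dz
  k <- v0^(-1 / 3)

  ## partials wrt r_i: segments i and i+1 touch r_i
  dA <- numeric(n)
  dV <- numeric(n)
  dPE <- numeric(n)
  for (i in seq_len(n)) {
    dA[i] <- 2 * pi * (0.5 * seg[i] + rbar[i] * dr[i] / seg[i])
    dV[i] <- pi * dz * rbar[i]
    dPE[i] <- pi * dz * zbar[i] * rbar[i]
    if (i < n) {
      dA[i] <- dA[i] + 2 * pi * (0.5 * seg[i + 1L] - rbar[i + 1L] * dr[i + 1L] / seg[i + 1L])
      dV[i] <- dV[i] + pi * dz * rbar[i + 1L]
      dPE[i] <- dPE[i] + pi * dz * zbar[i + 1L] * rbar[i + 1L]
    } else {
      dA[i] <- dA[i] + 2 * pi * r[n + 1L]
    }
  }
  ## partials wrt H
  dA_H <- 2 * pi * sum(rbar * dz / seg) / n
  dV_H <- pi * sum(rbar^2) / n
  dPE_H <- 2 * pi * sum(zbar * rbar^2) / n

  dk <- function(dv) -(1 / 3) * v0^(-4 / 3) * dv
  chain <- function(da, dv, dpe) {
    k^2 * da + bo * k^4 * dpe + (2 * k * area + 4 * bo * k^3 * pe) * dk(dv)
  }
  c(chain(dA_H, dV_H, dPE_H), chain(dA, dV, dPE))
}

#' Drop shape by direct energy minimization (validation oracle)
#'
#' Solves the same physical problem as [solve_drop_shape()] by a completely
#' different route: gradient-based minimization of membrane area plus
#' gravitational potential energy over discretized axisymmetric profiles at
#' fixed volume. Intended as an independent cross-check of the shooting
#' solver (the two should agree in height and diameter to within the
#' discretization error, ~1-2% at the default grid); it is slower and less
#' accurate, and not meant for production inversion.
#'
#' @param params A [drop_params()] object.
#' @param n_grid Number of height intervals in the discretization
#'   (minimum 50; default 160).
#'
#' @return A `drop_profile` (see [solve_drop_shape()]); its `meridian` has
#'   `n_grid + 1` rows and carries an `energy` attribute (nondimensional
#'   minimized energy).
#'
#' Errors: `vitmech_oracle_failure` if neither optimizer start converges.
#' @export
energy_oracle_shape <- function(params, n_grid = 160L) {
  stopifnot(inherits(params, "membrane_drop_params"))
  n <- as.integer(n_grid)
  if (n < 50L)
    vm_abort("`n_grid` must be at least 50", "vitmech_domain_error")
  bo <- params$bond_number

  sphere_start <- function() {
    R <- (3 / (4 * pi))^(1 / 3)
    H <- 2 * R
    z <- H * (1 - (1:n) / n)
    c(H, sqrt(pmax(R^2 - (z - R)^2, 1e-8)))
  }
  pancake_start <- function() {
    H <- max(2 / sqrt(max(bo, 1)), 0.05)
    Rd <- sqrt(1 / (pi * H))
    z <- H * (1 - (1:n) / n)
    ## disk with rounded (elliptic) edge
    c(H, Rd * sqrt(pmax(1 - ((2 * z / H - 1))^2 * 0.15, 0.2)))
  }

  run <- function(x0) {
    optim(x0, oracle_energy, oracle_energy_grad, n = n, bo = bo,
          method = "L-BFGS-B", lower = c(1e-4, rep(0, n)),
          control = list(maxit = 5000L, factr = 10))
  }
  fits <- lapply(list(sphere_start(), pancake_start()),
                 function(x0) tryCatch(run(x0), error = function(e) NULL))
  fits <- Filter(function(f) !is.null(f) && f$convergence %in% c(0L, 1L), fits)
  if (length(fits) == 0L)
    vm_abort("energy minimization failed from all starts",
             "vitmech_oracle_failure")
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  H <- fit$par[1L]
  r <- c(0, fit$par[-1L])
  z <- H * (1 - (0:n) / n)
  rbar <- (r[-1L] + r[-length(r)]) / 2
  v0 <- pi * sum(rbar^2) * (H / n)
  k <- v0^(-1 / 3)
  a_mm <- (params$volume_m3)^(1 / 3) * 1000
  r_mm <- r * k * a_mm
  z_mm <- z * k * a_mm
  seg <- sqrt(diff(r_mm)^2 + diff(z_mm)^2)
  meridian <- data.frame(s_mm = c(0, cumsum(seg)), r_mm = r_mm, z_mm = z_mm)
  attr(meridian, "energy") <- fit$value
  structure(
    list(meridian = meridian,
         height_mm = H * k * a_mm,
         diameter_mm = 2 * max(r_mm),
         base_radius_mm = r_mm[length(r_mm)],
         yolk_index = (H * k * a_mm) / (2 * max(r_mm)),
         volume_ml = params$volume_ml,
         bond_number = bo,
         apex_pressure_Pa = NA_real_,
         params = params),
    class = "drop_profile")
}
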