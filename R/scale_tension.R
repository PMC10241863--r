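## Scale-based tensile measurement of the vitelline membrane.
##
## A VM strip of width L, held in a windowed filter-paper frame, suspends a
## clipped weight inside a digital balance. The protocol produces a
## weight-reading time series with a characteristic event structure:
##
##   pre-cut plateau -> cut (reading drops: the VM now carries part of the
##   weight) -> after-cut plateau -> ramp (holder raised, VM loaded further,
##   reading falls) -> rupture (reading jumps back up to the full weight of
##   the detached assembly) -> terminal plateau.
##
## The two tensions follow from weight differences over the strip width:
##   gamma_native = |m_after_cut - m_detached| * g / L
##   gamma_max    = |m_breaking  - m_detached| * g / L
## with masses in kg. The printed-form differences are negative under this
## sign convention (the reading decreases as the VM takes load), so the
## magnitude is reported: tension is non-negative by definition.

#' Construct a scale weight-reading trace
#'
#' @param time_s Time stamps in seconds, strictly increasing.
#' @param reading_g Scale readings in grams, non-negative.
#' @param width_m Width of the VM strip in m (default 0.02).
#' @return An object of class `scale_trace` (a data frame with attributes).
#' @export
scale_trace <- function(time_s, reading_g, width_m = 0.02) {
  if (length(time_s) != length(reading_g))
    vm_abort("time and reading must have equal length", "vitmech_domain_error")
  if (any(diff(time_s) <= 0))
    vm_abort("time must be strictly increasing", "vitmech_domain_error")
  if (any(reading_g < 0))
    vm_abort("readings must be non-negative", "vitmech_domain_error")
  structure(data.frame(time_s = time_s, reading_g = reading_g),
            width_m = width_m, class = c("scale_trace", "data.frame"))
}

#' Read a scale trace CSV (`time_s,reading_g`)
#' @param path CSV path.
#' @param width_m Strip width in m.
#' @return A [scale_trace()].
#' @export
read_scale_trace <- function(path, width_m = 0.02) {
  tab <- read.csv(path)
  scale_trace(tab$time_s, tab$reading_g, width_m = width_m)
}

## rolling spread (max - min) over a centered window of k samples
roll_spread <- function(x, k) {
  n <- length(x)
  out <- rep(NA_real_, n)
  h <- k %/% 2
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    out[i] <- max(x[j]) - min(x[j])
  }
  out
}

#' Detect protocol events in a scale trace
#'
#' Locates the cut, the after-cut plateau, the pre-rupture extremal reading
#' and the terminal (post-rupture) plateau, and returns the three event
#' weights feeding the tension formulas. Plateaus are stable segments of the
#' rolling-median-smoothed trace whose local spread stays below
#' `plateau_tol` for at least 2 s; the cut and rupture are reading changes
#' exceeding `jump_tol` over a short lag (downward and upward
#' respectively). The detached weight is taken from the terminal
#' post-rupture plateau, when the weight rests fully on the scale.
#'
#' @param trace A [scale_trace()].
#' @param plateau_tol Maximum within-plateau spread in grams (default 0.2).
#' @param jump_tol Minimum reading change counting as a cut/rupture jump in
#'   grams (default 1).
#'
#' @return An object of class `scale_events`: list with `m_detached_g`,
#'   `m_after_cut_g`, `m_breaking_g`, event times `t_cut_s`, `t_rupture_s`,
#'   and `qc` (`"ok"` or `"incomplete"`).
#'
#' A trace with a cut but no rupture jump yields a warning of class
#' `vitmech_incomplete_trace` and `m_breaking_g = NA` (native tension is
#' still computable). A trace with no cut at all raises an error of the
#' same class; a cut followed by an immediate ramp with no stable after-cut
#' plateau raises `vitmech_qc_failure`.
#' @export
detect_events <- function(trace, plateau_tol = 0.2, jump_tol = 1) {
  stopifnot(inherits(trace, "scale_trace"))
  t <- trace$time_s
  x <- trace$reading_g
  n <- length(x)
  dt <- median(diff(t))
  ksm <- max(3L, 2L * floor(0.25 / dt) + 1L)   # ~0.5 s median filter
  sm <- stats::runmed(x, ksm)
  lag <- max(1L, ceiling(1.5 / dt))            # change over 1.5 s: spans the
                                               # cut transient fully
  dlag <- sm[(lag + 1L):n] - sm[1L:(n - lag)]

  cut_i <- which(dlag < -jump_tol)
  rup_i <- which(dlag > jump_tol)
  if (length(cut_i) == 0L)
    vm_abort("no cut transition found: trace does not span the protocol",
             "vitmech_incomplete_trace")
  t_cut_end <- t[max(1L, min(cut_i)) ] + lag * dt + 0.5  # end of cut transient

  incomplete <- length(rup_i) == 0L
  if (incomplete) {
    t_rupture <- NA_real_
    m_breaking <- NA_real_
    seg_end <- t[n]
  } else {
    i_rup <- max(rup_i)          # last big upward jump = rupture
    t_rupture <- t[i_rup]
    ## extremal (minimum) smoothed reading just before the jump
    pre <- which(t >= t_rupture - 2 & t <= t_rupture + lag * dt)
    m_breaking <- min(sm[pre])
    seg_end <- t_rupture
  }

  w2 <- max(3L, 2L * floor(1 / dt) + 1L)       # 2 s spread window
  spread <- roll_spread(sm, w2)
  stable <- spread < plateau_tol

  ## after-cut plateau: first stable stretch of >= 2 s after the cut
  ## transient and before the ramp/rupture
  cand <- which(stable & t > t_cut_end & t < seg_end)
  m_after_cut <- NA_real_
  if (length(cand) > 0L) {
    runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
    runs <- Filter(function(ix) t[ix[length(ix)]] - t[ix[1L]] >= 2, runs)
    if (length(runs) > 0L) {
      ix <- runs[[1L]]
      m_after_cut <- mean(x[ix])
    }
  }
  if (is.na(m_after_cut))
    vm_abort("no stable after-cut plateau (>= 2 s) found before the ramp",
             "vitmech_qc_failure")

  ## detached weight: terminal post-rupture plateau (or the pre-cut plateau
  ## when the trace ends before rupture)
  if (!incomplete) {
    post <- which(t > t_rupture + lag * dt + 0.5)
    if (length(post) < 2L || max(roll_spread(sm[post], w2)) > plateau_tol)
      vm_abort("no stable terminal plateau after rupture",
               "vitmech_qc_failure")
    m_detached <- mean(x[post])
  } else {
    pre <- which(t < t[min(cut_i)])
    m_detached <- mean(x[pre])
    vm_warn("no rupture jump found: maximum tension undefined for this trace",
            "vitmech_incomplete_trace")
  }

  structure(list(m_detached_g = m_detached,
                 m_after_cut_g = m_after_cut,
                 m_breaking_g = m_breaking,
                 t_cut_s = t[min(cut_i)],
                 t_rupture_s = t_rupture,
                 qc = if (incomplete) "incomplete" else "ok"),
            class = "scale_events")
}

#' @export
print.scale_events <- function(x, ...) {
  cat(sprintf(
    "scale events [%s]: detached %.3f g, after-cut %.3f g, breaking %s g\n",
    x$qc, x$m_detached_g, x$m_after_cut_g,
    ifelse(is.na(x$m_breaking_g), "NA", sprintf("%.3f", x$m_breaking_g))))
  invisible(x)
}

tension_from_dm <- function(dm_g, width_m, gravity) {
  if (width_m <= 0)
    vm_abort("strip width must be positive", "vitmech_domain_error")
  abs(dm_g) * 1e-3 * gravity / width_m
}

#' Native VM tension from scale events
#'
#' `|m_after_cut - m_detached| * g / L` with masses in kg: the tension the
#' membrane carries in its endogenous stretched state, per unit strip width.
#'
#' @param events A [detect_events()] result (or any list with the weight
#'   fields).
#' @param width_m Strip width L in m (default 0.02).
#' @param gravity Gravitational acceleration in m/s^2 (default 9.8).
#' @return Tension in N/m.
#' @examples
#' ev <- list(m_detached_g = 10, m_after_cut_g = 9.2, m_breaking_g = 6)
#' native_tension(ev)  # 0.392 N/m
#' @export
native_tension <- function(events, width_m = 0.02, gravity = 9.8) {
  tension_from_dm(events$m_after_cut_g - events$m_detached_g,
                  width_m, gravity)
}

#' Maximum (breaking) VM tension from scale events
#'
#' `|m_breaking - m_detached| * g / L`: the tension at rupture.
#'
#' @inheritParams native_tension
#' @return Tension in N/m (`NA` for an incomplete trace).
#' @export
max_tension <- function(events, width_m = 0.02, gravity = 9.8) {
  if (is.na(events$m_breaking_g)) return(NA_real_)
  tension_from_dm(events$m_breaking_g - events$m_detached_g,
                  width_m, gravity)
}

#' Analyse a batch of scale traces
#'
#' Runs [detect_events()] + tension formulas over a list of traces.
#'
#' @param traces Named list of [scale_trace()] objects.
#' @param plateau_tol,jump_tol Passed to [detect_events()].
#' @param gravity Gravitational acceleration in m/s^2.
#' @return Data frame `sample_id, m_detached_g, m_after_cut_g,
#'   m_breaking_g, gamma_native_N_per_m, gamma_max_N_per_m, qc`.
#' @export
analyse_scale_traces <- function(traces, plateau_tol = 0.2, jump_tol = 1,
                                 gravity = 9.8) {
  ids <- names(traces)
  if (is.null(ids)) ids <- sprintf("trace%03d", seq_along(traces))
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    ev <- withCallingHandlers(
      detect_events(tr, plateau_tol, jump_tol),
      vitmech_incomplete_trace = function(w) invokeRestart("muffleWarning"))
    L <- attr(tr, "width_m")
    data.frame(sample_id = ids[i],
               m_detached_g = ev$m_detached_g,
               m_after_cut_g = ev$m_after_cut_g,
               m_breaking_g = ev$m_breaking_g,
               gamma_native_N_per_m = native_tension(ev, L, gravity),
               gamma_max_N_per_m = max_tension(ev, L, gravity),
               qc = ev$qc)
  })
  do.call(rbind, rows)
}
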