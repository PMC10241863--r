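## Force-probe stiffness analysis.
##
## A probe descends onto the membrane at constant speed (nominally
## 0.1 mm/s) while force is sampled at high frequency. The stiffness metric
## is the average rate of force increase over a 20-s stretch of the
## approximately linear phase of the force curve. Processing order follows
## the measurement protocol: per-trace baseline subtraction (pre-movement
## mean), averaging to one value per second, QC to exclude early membrane
## rupture and holder collisions, then slope extraction.

#' Construct a force-probe trace
#'
#' @param time_s Time in s, strictly increasing.
#' @param position_mm Probe position in mm, non-decreasing during the push.
#' @param force_mN Force in mN.
#' @return Object of class `probe_trace` (data frame).
#' @export
probe_trace <- function(time_s, position_mm, force_mN) {
  if (length(time_s) != length(position_mm) ||
      length(time_s) != length(force_mN))
    vm_abort("time, position and force must have equal length",
             "vitmech_domain_error")
  if (any(diff(time_s) <= 0))
    vm_abort("time must be strictly increasing", "vitmech_domain_error")
  structure(data.frame(time_s = time_s, position_mm = position_mm,
                       force_mN = force_mN),
            class = c("probe_trace", "data.frame"))
}

#' Read a probe trace CSV (`time_s,position_mm,force_mN`)
#' @param path CSV path.
#' @return A [probe_trace()].
#' @export
read_probe_trace <- function(path) {
  tab <- read.csv(path)
  probe_trace(tab$time_s, tab$position_mm, tab$force_mN)
}

## first time the probe position departs from its initial value
movement_onset <- function(trace, eps = 1e-6) {
  moved <- abs(trace$position_mm - trace$position_mm[1L]) > eps
  if (!any(moved)) return(Inf)
  trace$time_s[which(moved)[1L]]
}

#' Baseline-correct a probe trace
#'
#' Shifts the force so its mean over the `pre_window` seconds preceding
#' probe movement is zero (each trace is adjusted with its own baseline).
#'
#' @param trace A [probe_trace()].
#' @param pre_window Seconds of pre-movement data used for the baseline
#'   (default 5).
#' @return The trace with corrected force; attributes `baseline_mN`,
#'   `baseline_sd_mN` (residual SD of the baseline segment) and `onset_s`.
#'
#' Errors: `vitmech_insufficient_baseline` if fewer than `pre_window`
#' seconds precede movement onset.
#' @export
baseline_correct <- function(trace, pre_window = 5) {
  stopifnot(inherits(trace, "probe_trace"))
  onset <- movement_onset(trace)
  pre <- trace$time_s < onset
  if (!any(pre) || (min(onset, max(trace$time_s)) - trace$time_s[1L]) < pre_window)
    vm_abort(sprintf("need >= %g s of pre-movement data for the baseline",
                     pre_window), "vitmech_insufficient_baseline")
  use <- pre & trace$time_s >= onset - pre_window
  b <- mean(trace$force_mN[use])
  out <- trace
  out$force_mN <- trace$force_mN - b
  attr(out, "baseline_mN") <- b
  attr(out, "baseline_sd_mN") <- sd(trace$force_mN[use])
  attr(out, "onset_s") <- onset
  out
}

#' Average a probe trace to one value per second
#'
#' High-frequency samples are averaged within consecutive 1-s bins;
#' timestamps are placed at bin centers. Empty bins are dropped.
#'
#' @param trace A [probe_trace()].
#' @return A [probe_trace()] at 1 Hz (attributes are preserved).
#' @export
downsample_1hz <- function(trace) {
  stopifnot(inherits(trace, "probe_trace"))
  t0 <- trace$time_s[1L]
  bin <- floor(trace$time_s - t0)
  agg <- function(v) as.numeric(tapply(v, bin, mean))
  out <- probe_trace(time_s = t0 + sort(unique(bin)) + 0.5,
                     position_mm = agg(trace$position_mm),
                     force_mN = agg(trace$force_mN))
  for (a in c("baseline_mN", "baseline_sd_mN", "onset_s"))
    attr(out, a) <- attr(trace, a)
  out
}

## first 1-Hz sample where force exceeds 3x the baseline residual SD for
## 3 consecutive samples
contact_time <- function(trace_1hz, sd_floor = 1e-6) {
  s <- max(attr(trace_1hz, "baseline_sd_mN"), sd_floor, na.rm = TRUE)
  above <- trace_1hz$force_mN > 3 * s
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run == 3L) return(trace_1hz$time_s[i - 2L])
  }
  Inf
}

#' QC a baseline-corrected probe trace
#'
#' Flags traces that must be excluded from stiffness analysis:
#' `early_rupture` when the force drops by more than `drop_tol` during the
#' push phase (the membrane broke under the probe), `holder_hit` when the
#' force exceeds `force_cap` or its 1-s slope jumps discontinuously by more
#' than `slope_jump_factor`, `no_contact` when the force never clears the
#' contact threshold. Otherwise `ok`.
#'
#' @param trace_1hz Baseline-corrected, 1-Hz [probe_trace()].
#' @param drop_tol Force drop counting as rupture, mN (default 0.05).
#' @param force_cap Force ceiling indicating a holder collision, mN
#'   (default 20: a holder collision drives force far above any membrane push).
#' @param slope_jump_factor Ratio of consecutive 1-s force increments
#'   flagged as a collision (default 8).
#' @return One of `"ok"`, `"early_rupture"`, `"holder_hit"`, `"no_contact"`.
#' @export
qc_trace <- function(trace_1hz, drop_tol = 0.05, force_cap = 20,
                     slope_jump_factor = 8) {
  stopifnot(inherits(trace_1hz, "probe_trace"))
  tc <- contact_time(trace_1hz)
  if (!is.finite(tc)) return("no_contact")
  push <- trace_1hz$time_s >= tc
  f <- trace_1hz$force_mN[push]
  if (max(f) > force_cap) return("holder_hit")
  ## drop below running maximum = rupture
  if (any(cummax(f) - f > drop_tol)) return("early_rupture")
  df <- diff(f)
  big <- which(df[-1L] > slope_jump_factor * pmax(abs(df[-length(df)]), 1e-3))
  if (length(big) > 0L && any(df[big + 1L] > 10 * drop_tol))
    return("holder_hit")
  "ok"
}

#' Stiffness slope over the most linear 20-s window
#'
#' Among all contiguous `window`-second stretches of the 1-Hz force curve
#' after contact, selects the one maximizing the R-squared of a
#' straight-line fit (earliest window on ties) and returns the fitted slope
#' as the stiffness metric. A soft (e.g. quadratic) contact onset thereby
#' excludes itself: the fully linear stretch fits better.
#'
#' @param trace_1hz Baseline-corrected 1-Hz [probe_trace()].
#' @param window Window length in s (default 20).
#' @param qc QC flag for this trace; slopes are only reported for `"ok"`
#'   (pass the [qc_trace()] result, or leave as `"ok"` for pre-screened
#'   traces).
#' @return Object of class `stiffness_result`: list with `slope_mN_per_s`,
#'   `window_start_s`, `window_end_s`, `r_squared`, `contact_time_s`,
#'   `baseline_mN`, `qc`. The slope is `NA` unless `qc == "ok"`.
#'
#' Errors: `vitmech_insufficient_data` when fewer than `window` seconds of
#' push-phase data follow contact.
#' @export
linear_phase_slope <- function(trace_1hz, window = 20, qc = "ok") {
  stopifnot(inherits(trace_1hz, "probe_trace"))
  res <- list(slope_mN_per_s = NA_real_, window_start_s = NA_real_,
              window_end_s = NA_real_, r_squared = NA_real_,
              contact_time_s = NA_real_,
              baseline_mN = attr(trace_1hz, "baseline_mN"), qc = qc)
  class(res) <- "stiffness_result"
  if (qc != "ok") return(res)
  tc <- contact_time(trace_1hz)
  if (!is.finite(tc))
    vm_abort("no contact found in trace", "vitmech_insufficient_data")
  res$contact_time_s <- tc
  idx <- which(trace_1hz$time_s >= tc)
  t <- trace_1hz$time_s[idx]
  f <- trace_1hz$force_mN[idx]
  w <- as.integer(window)            # samples per window at 1 Hz
  if (length(t) < w)
    vm_abort(sprintf("push phase shorter than the %g s window", window),
             "vitmech_insufficient_data")
  best <- NULL
  for (i in seq_len(length(t) - w + 1L)) {
    j <- i:(i + w - 1L)
    tt <- t[j]; ff <- f[j]
    sxx <- sum((tt - mean(tt))^2)
    sxy <- sum((tt - mean(tt)) * (ff - mean(ff)))
    syy <- sum((ff - mean(ff))^2)
    r2 <- if (syy < 1e-300) 1 else (sxy^2 / sxx) / syy
    if (is.null(best) || r2 > best$r2 + 1e-12) {
      best <- list(r2 = r2, slope = sxy / sxx, t0 = tt[1L], t1 = tt[w])
    }
  }
  res$slope_mN_per_s <- best$slope
  res$window_start_s <- best$t0
  res$window_end_s <- best$t1
  res$r_squared <- best$r2
  res
}

#' @export
print.stiffness_result <- function(x, ...) {
  cat(sprintf("stiffness [%s]: k = %s mN/s (window %s-%s s, R^2 = %s)\n",
              x$qc,
              format(x$slope_mN_per_s, digits = 4),
              format(x$window_start_s), format(x$window_end_s),
              format(x$r_squared, digits = 4)))
  invisible(x)
}

#' Full probe-trace pipeline
#'
#' Baseline correction, 1-Hz averaging, QC and slope extraction in one call.
#'
#' @param trace Raw [probe_trace()].
#' @param pre_window,window,drop_tol,force_cap See the stage functions.
#' @return A `stiffness_result`.
#' @export
analyse_probe_trace <- function(trace, pre_window = 5, window = 20,
                                drop_tol = 0.05, force_cap = 20) {
  corr <- baseline_correct(trace, pre_window = pre_window)
  hz1 <- downsample_1hz(corr)
  flag <- qc_trace(hz1, drop_tol = drop_tol, force_cap = force_cap)
  linear_phase_slope(hz1, window = window, qc = flag)
}
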