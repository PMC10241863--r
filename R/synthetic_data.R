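## Synthetic-data generators.
##
## Every input type the analysis consumes can be generated with known
## ground truth, so parameter recovery is testable end to end without any
## experimental data. All noise is Gaussian unless stated. Each generator
## is deterministic given its seed and attaches (or writes) a truth table
## recording the hidden parameters.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators never perturb the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Default study conditions for the full synthetic cohort. Cohort sizes
#' follow the reported experiments (scale tension n = 15 on day 0 vs 19 on
#' day 2; probe stiffness n = 15 vs 17); tension levels are
#' model-consistent values inside the 0.1-1 N/m range with the day-2/day-0
#' ratio at 0.4.
#'
#' @param seed Master integer seed; per-generator seeds are derived from it.
#' @param ... Named overrides of any default block.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    puddle = list(
      gamma_by_group = c(D0 = 0.95, D2 = 0.38),  # N/m, ratio 0.4
      volume_ml = 17, density_g_cm3 = 1.035,
      geom_noise_sd_mm = 0.3, n_per_group = 20),
    scale = list(
      gamma_native = c(D0 = 0.6, D2 = 0.24),     # N/m
      gamma_max = c(D0 = 2.4, D2 = 1.0),
      n_per_group = c(D0 = 15, D2 = 19),
      width_m = 0.02, clip_weight_g = 10, noise_sd_g = 0.02),
    probe = list(
      slope_by_group = c(D0 = 0.08, D2 = 0.03),  # mN/s
      n_per_group = c(D0 = 15, D2 = 17),
      baseline_mN = 0.3, contact_time_s = 12, onset_dur_s = 3,
      noise_sd_mN = 0.01, rate_hz = 100),
    landmarks = list(
      elong_by_group = c(control = 90, SW = 30),   # um/h
      conv_by_group = c(control = 25, SW = -10),   # um/h (negative: widening)
      seg_rate = c(control = 0.667, SW = 0.4),     # pairs/h
      n_per_group = 20, duration_h = 8, frame_interval_h = 0.5,
      noise_sd_um = 5),
    fibre = list(
      coverage_grid = seq(0.05, 0.4, by = 0.05),
      size_px = 512, fibre_width_px = 3, noise_sd = 0.05))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#' @param path YAML file with any subset of the [sim_config()] blocks.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1
  y$seed <- NULL
  y <- lapply(y, function(b) lapply(b, function(v) {
    if (is.list(v)) unlist(v) else v
  }))
  do.call(sim_config, c(list(seed = seed), y))
}

## deterministic sub-seed, kept below 2^31 (double arithmetic: exact and
## overflow-free for any plausible master seed)
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9176) %% 2000000011)
}

#' Generate noisy puddle-geometry observations
#'
#' Solves the forward drop-shape model at each group's true tension and
#' perturbs height and diameter with additive Gaussian measurement noise.
#'
#' @param gamma_by_group Named numeric vector of true tensions (N/m); names
#'   become the `day` column.
#' @param volume_ml,density_g_cm3 Shared puddle parameters.
#' @param geom_noise_sd_mm SD of the measurement noise on H and D (mm).
#' @param n_per_group Observations per group.
#' @param seed Integer seed.
#' @return Puddle-geometry data frame (`sample_id, day, height_mm,
#'   diameter_mm, volume_ml, density_g_per_cm3`) with hidden-truth columns
#'   `true_gamma_N_per_m`, `true_height_mm`, `true_diameter_mm`.
#' @export
gen_puddle_observations <- function(gamma_by_group = c(D0 = 0.95, D2 = 0.38),
                                    volume_ml = 17, density_g_cm3 = 1.035,
                                    geom_noise_sd_mm = 0.3,
                                    n_per_group = 20, seed = 1) {
  groups <- names(gamma_by_group)
  if (is.null(groups)) groups <- sprintf("g%d", seq_along(gamma_by_group))
  clean <- lapply(gamma_by_group, function(g) {
    prof <- solve_drop_shape(drop_params(g, volume_ml, density_g_cm3))
    c(H = prof$height_mm, D = prof$diameter_mm)
  })
  with_seed(seed, {
    rows <- lapply(seq_along(groups), function(i) {
      hd <- clean[[i]]
      data.frame(
        sample_id = sprintf("%s_%02d", groups[i], seq_len(n_per_group)),
        day = groups[i],
        height_mm = hd[["H"]] + rnorm(n_per_group, sd = geom_noise_sd_mm),
        diameter_mm = hd[["D"]] + rnorm(n_per_group, sd = geom_noise_sd_mm),
        volume_ml = volume_ml,
        density_g_per_cm3 = density_g_cm3,
        true_gamma_N_per_m = gamma_by_group[[i]],
        true_height_mm = hd[["H"]],
        true_diameter_mm = hd[["D"]])
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic scale weight-reading trace
#'
#' Piecewise trace matching the tensile protocol: detached plateau, cut
#' transient, after-cut plateau at `clip_weight - gamma_native * L / g`,
#' linear ramp down to the breaking weight `clip_weight - gamma_max * L / g`,
#' instantaneous rupture jump back, terminal detached plateau.
#'
#' @param gamma_native,gamma_max True tensions (N/m); set
#'   `gamma_max = NULL` to omit the ramp and rupture (incomplete trace).
#' @param width_m Strip width L (m).
#' @param clip_weight_g Weight of the clipped assembly (g).
#' @param noise_sd_g Gaussian reading noise SD (g).
#' @param seed Integer seed.
#' @param rate_hz Sampling rate (default 10).
#' @param gravity m/s^2.
#' @return A [scale_trace()] with attribute `truth` (list of the event
#'   weights and tensions).
#' @export
gen_scale_trace <- function(gamma_native, gamma_max, width_m = 0.02,
                            clip_weight_g = 10, noise_sd_g = 0.02, seed = 1,
                            rate_hz = 10, gravity = 9.8) {
  dm_native <- gamma_native * width_m / gravity * 1000   # g
  m_after <- clip_weight_g - dm_native
  complete <- !is.null(gamma_max)
  if (complete) {
    if (gamma_max < gamma_native)
      vm_abort("gamma_max must be >= gamma_native", "vitmech_domain_error")
    m_break <- clip_weight_g - gamma_max * width_m / gravity * 1000
    if (m_break < 0)
      vm_abort("breaking weight below zero: reduce gamma_max or raise clip weight",
               "vitmech_domain_error")
  }
  dt <- 1 / rate_hz
  seg <- function(dur, from, to = from) {
    n <- round(dur * rate_hz)
    seq(from, to, length.out = n)
  }
  reading <- c(
    seg(10, clip_weight_g),                 # pre-cut (detached on holder path)
    seg(1, clip_weight_g, m_after),         # cut transient
    seg(10, m_after),                       # after-cut plateau
    if (complete) seg(15, m_after, m_break),# loading ramp
    if (complete) seg(8, clip_weight_g))    # rupture jump + terminal plateau
  n <- length(reading)
  time_s <- seq(0, by = dt, length.out = n)
  reading <- with_seed(seed, pmax(reading + rnorm(n, sd = noise_sd_g), 0))
  tr <- scale_trace(time_s, reading, width_m = width_m)
  attr(tr, "truth") <- list(
    m_detached_g = clip_weight_g, m_after_cut_g = m_after,
    m_breaking_g = if (complete) m_break else NA_real_,
    gamma_native = gamma_native,
    gamma_max = if (complete) gamma_max else NA_real_)
  tr
}

#' Generate a synthetic force-probe trace
#'
#' Pre-movement baseline, descent at constant speed, smooth (quadratic)
#' contact onset of duration `onset_dur_s` blending into a linear force
#' ramp of the true slope, plus Gaussian sensor noise; optionally an abrupt
#' force drop simulating early membrane rupture.
#'
#' @param true_slope Linear-phase force rate (mN/s).
#' @param baseline_mN Constant force offset before correction.
#' @param contact_time_s Time of probe-membrane contact after movement
#'   onset (s).
#' @param onset_dur_s Duration of the soft quadratic onset (s).
#' @param noise_sd_mN Sensor noise SD.
#' @param rupture Optional `list(time = , drop = )`: at `time` s the force
#'   drops by `drop` mN.
#' @param seed Integer seed.
#' @param rate_hz Sampling rate (default 100).
#' @param duration_s Total trace length (default 90).
#' @param speed_mm_s Probe speed (default 0.1).
#' @param premove_s Pre-movement baseline duration (default 10).
#' @return A [probe_trace()] with attribute `truth`.
#' @export
gen_probe_trace <- function(true_slope = 0.08, baseline_mN = 0.3,
                            contact_time_s = 12, onset_dur_s = 3,
                            noise_sd_mN = 0.01, rupture = NULL, seed = 1,
                            rate_hz = 100, duration_s = 90,
                            speed_mm_s = 0.1, premove_s = 10) {
  dt <- 1 / rate_hz
  time_s <- seq(0, duration_s, by = dt)
  pos <- pmax(time_s - premove_s, 0) * speed_mm_s
  t_c <- premove_s + contact_time_s
  tau <- time_s - t_c
  ## quadratic onset reaching the ramp slope at onset_dur, then linear
  f <- ifelse(tau <= 0, 0,
              ifelse(tau < onset_dur_s,
                     true_slope * tau^2 / (2 * onset_dur_s),
                     true_slope * (tau - onset_dur_s / 2)))
  if (!is.null(rupture))
    f <- ifelse(time_s >= t_c + rupture$time, pmax(f - rupture$drop, 0), f)
  f <- f + baseline_mN
  f <- with_seed(seed, f + rnorm(length(f), sd = noise_sd_mN))
  tr <- probe_trace(time_s, pos, f)
  attr(tr, "truth") <- list(slope = true_slope, baseline = baseline_mN,
                            contact_time_s = t_c, onset_dur_s = onset_dur_s,
                            ruptured = !is.null(rupture))
  tr
}

#' Generate a synthetic embryo landmark series
#'
#' Posterior end recedes from the reference somite at the elongation
#' speed, pNT walls approach at the convergence speed, somites accrue at
#' the segmentation rate (count = floor of the linear clock); landmark
#' positions carry Gaussian noise.
#'
#' @param elong,conv Elongation and convergence speeds (um/h; negatives
#'   allowed: shortening / widening).
#' @param seg_rate Somite pairs per hour.
#' @param duration_h,frame_interval_h Series length and frame spacing.
#' @param noise_sd_um Landmark position noise SD.
#' @param seed Integer seed.
#' @param start_length_um,start_width_um Initial somite-to-posterior
#'   distance and pNT width.
#' @param start_pairs Initial somite pair count.
#' @return A [landmark_series()] with attribute `truth`.
#' @export
gen_landmark_series <- function(elong = 90, conv = 25, seg_rate = 0.667,
                                duration_h = 8, frame_interval_h = 0.5,
                                noise_sd_um = 5, seed = 1,
                                start_length_um = 2000,
                                start_width_um = 400, start_pairs = 8) {
  t <- seq(0, duration_h, by = frame_interval_h)
  len <- start_length_um + elong * t
  wid <- start_width_um - conv * t
  if (any(wid <= 0))
    vm_abort("convergence closes the pNT within the duration; shorten it",
             "vitmech_domain_error")
  with_seed(seed, {
    series <- landmark_series(
      time_h = t,
      somite_ref_x = rnorm(length(t), 0, noise_sd_um),
      somite_ref_y = rnorm(length(t), 0, noise_sd_um),
      post_end_x = len + rnorm(length(t), 0, noise_sd_um),
      post_end_y = rnorm(length(t), 0, noise_sd_um),
      pnt_left_x = -wid / 2 + rnorm(length(t), 0, noise_sd_um) / 2,
      pnt_right_x = wid / 2 + rnorm(length(t), 0, noise_sd_um) / 2,
      somite_pairs = start_pairs + floor(seg_rate * t))
    attr(series, "truth") <- list(elong = elong, conv = conv,
                                  seg_rate = seg_rate)
    series
  })
}

#' Generate a synthetic fibre-stain image
#'
#' Rasterizes random oriented bright line segments onto a noisy dark
#' background until the target foreground coverage is reached.
#'
#' @param coverage Target fibre pixel fraction in `[0, 1)`.
#' @param size_px Image side length.
#' @param fibre_width_px Fibre thickness in pixels.
#' @param noise_sd Background Gaussian noise SD (intensity units; fibres
#'   are at 1, background at 0).
#' @param seed Integer seed.
#' @param seg_len_px Segment length (default half the image side).
#' @return Numeric matrix with attribute `truth` (achieved coverage).
#' @export
gen_fibre_image <- function(coverage = 0.2, size_px = 512,
                            fibre_width_px = 3, noise_sd = 0.05, seed = 1,
                            seg_len_px = size_px / 2) {
  if (coverage < 0 || coverage >= 1)
    vm_abort("`coverage` must lie in [0, 1)", "vitmech_domain_error")
  img <- matrix(0, size_px, size_px)
  half <- max(0L, floor(fibre_width_px / 2))
  offs <- expand.grid(dx = -half:half, dy = -half:half)
  with_seed(seed, {
    while (mean(img >= 0.5) < coverage) {
      x0 <- runif(1, 1, size_px); y0 <- runif(1, 1, size_px)
      th <- runif(1, 0, pi)
      tt <- seq(0, seg_len_px, by = 0.5)
      xs <- round(x0 + tt * cos(th)); ys <- round(y0 + tt * sin(th))
      for (k in seq_len(nrow(offs))) {
        xi <- xs + offs$dx[k]; yi <- ys + offs$dy[k]
        ok <- xi >= 1 & xi <= size_px & yi >= 1 & yi <= size_px
        img[cbind(xi[ok], yi[ok])] <- 1
      }
    }
    truth <- mean(img >= 0.5)
    img <- img + matrix(rnorm(size_px^2, sd = noise_sd), size_px)
    attr(img, "truth") <- list(coverage = truth)
    img
  })
}

#' Write the full synthetic fixture set
#'
#' Generates every input type under a [sim_config()] and writes them (plus
#' a `truth.csv` per generator) beneath `out_dir`. Identical configurations
#' produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
simulate_all <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, rel) {
    p <- file.path(out_dir, rel)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }

  pud <- do.call(gen_puddle_observations,
                 c(config$puddle, list(seed = sub_seed(config$seed, 1L))))
  emit(pud[, 1:6], "puddle/observations.csv")
  emit(unique(pud[, c("day", "true_gamma_N_per_m",
                      "true_height_mm", "true_diameter_mm")]),
       "puddle/truth.csv")

  sc <- config$scale
  truth_rows <- list(); k <- 0L
  for (g in names(sc$gamma_native)) {
    for (i in seq_len(sc$n_per_group[[g]])) {
      k <- k + 1L
      tr <- gen_scale_trace(sc$gamma_native[[g]], sc$gamma_max[[g]],
                            width_m = sc$width_m,
                            clip_weight_g = sc$clip_weight_g,
                            noise_sd_g = sc$noise_sd_g,
                            seed = sub_seed(config$seed, 100L + k))
      id <- sprintf("%s_%02d", g, i)
      emit(as.data.frame(tr), file.path("scale", paste0(id, ".csv")))
      truth_rows[[k]] <- data.frame(sample_id = id, group = g,
                                    gamma_native = sc$gamma_native[[g]],
                                    gamma_max = sc$gamma_max[[g]])
    }
  }
  emit(do.call(rbind, truth_rows), "scale/truth.csv")

  pr <- config$probe
  truth_rows <- list(); k <- 0L
  for (g in names(pr$slope_by_group)) {
    for (i in seq_len(pr$n_per_group[[g]])) {
      k <- k + 1L
      tr <- gen_probe_trace(pr$slope_by_group[[g]],
                            baseline_mN = pr$baseline_mN,
                            contact_time_s = pr$contact_time_s,
                            onset_dur_s = pr$onset_dur_s,
                            noise_sd_mN = pr$noise_sd_mN,
                            rate_hz = pr$rate_hz,
                            seed = sub_seed(config$seed, 200L + k))
      id <- sprintf("%s_%02d", g, i)
      emit(as.data.frame(tr), file.path("probe", paste0(id, ".csv")))
      truth_rows[[k]] <- data.frame(sample_id = id, group = g,
                                    slope = pr$slope_by_group[[g]])
    }
  }
  emit(do.call(rbind, truth_rows), "probe/truth.csv")

  lm_ <- config$landmarks
  truth_rows <- list(); k <- 0L
  for (g in names(lm_$elong_by_group)) {
    for (i in seq_len(lm_$n_per_group)) {
      k <- k + 1L
      s <- gen_landmark_series(lm_$elong_by_group[[g]],
                               lm_$conv_by_group[[g]],
                               lm_$seg_rate[[g]],
                               duration_h = lm_$duration_h,
                               frame_interval_h = lm_$frame_interval_h,
                               noise_sd_um = lm_$noise_sd_um,
                               seed = sub_seed(config$seed, 300L + k))
      id <- sprintf("%s_%02d", g, i)
      emit(as.data.frame(s), file.path("landmarks", paste0(id, ".csv")))
      truth_rows[[k]] <- data.frame(sample_id = id, group = g,
                                    elong = lm_$elong_by_group[[g]],
                                    conv = lm_$conv_by_group[[g]],
                                    seg_rate = lm_$seg_rate[[g]])
    }
  }
  emit(do.call(rbind, truth_rows), "landmarks/truth.csv")

  fb <- config$fibre
  truth_rows <- lapply(seq_along(fb$coverage_grid), function(i) {
    img <- gen_fibre_image(fb$coverage_grid[i], size_px = fb$size_px,
                           fibre_width_px = fb$fibre_width_px,
                           noise_sd = fb$noise_sd,
                           seed = sub_seed(config$seed, 400L + i))
    id <- sprintf("cov%03.0f", 100 * fb$coverage_grid[i])
    emit(as.data.frame(round(img, 4)), file.path("fibre", paste0(id, ".csv")))
    data.frame(sample_id = id, target_coverage = fb$coverage_grid[i],
               achieved_coverage = attr(img, "truth")$coverage)
  })
  emit(do.call(rbind, truth_rows), "fibre/truth.csv")

  invisible(paths)
}
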