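## Embryo morphometrics: axis speeds from landmark time series and
## glycoprotein fibre density from stained VM images.
##
## Speeds are least-squares slopes over all frames rather than endpoint
## differences: the frame-to-frame landmark noise is large relative to the
## per-frame displacement, and regression uses every frame.

#' Construct an embryo axis landmark series
#'
#' One row per frame: position of a fixed reference somite pair (usually
#' somite 3 or 4), the posterior end of the body axis, the outer boundaries
#' of the posterior neural tube (pNT) walls, and the somite pair count.
#'
#' @param time_h Frame times in hours, strictly increasing.
#' @param somite_ref_x,somite_ref_y Reference-somite position (micrometres).
#' @param post_end_x,post_end_y Posterior-end position (micrometres).
#' @param pnt_left_x,pnt_right_x Outer pNT wall positions (micrometres);
#'   width = right - left must be positive.
#' @param somite_pairs Somite pair count per frame, non-decreasing.
#' @return Object of class `landmark_series` (data frame).
#' @export
landmark_series <- function(time_h, somite_ref_x, somite_ref_y,
                            post_end_x, post_end_y,
                            pnt_left_x, pnt_right_x, somite_pairs) {
  if (any(diff(time_h) <= 0))
    vm_abort("time must be strictly increasing", "vitmech_domain_error")
  if (any(diff(somite_pairs) < 0))
    vm_abort("somite count must be non-decreasing", "vitmech_domain_error")
  if (any(pnt_right_x - pnt_left_x <= 0))
    vm_abort("pNT width (right - left) must be positive",
             "vitmech_domain_error")
  structure(data.frame(time_h = time_h,
                       somite_ref_x = somite_ref_x,
                       somite_ref_y = somite_ref_y,
                       post_end_x = post_end_x, post_end_y = post_end_y,
                       pnt_left_x = pnt_left_x, pnt_right_x = pnt_right_x,
                       somite_pairs = somite_pairs),
            class = c("landmark_series", "data.frame"))
}

#' Read a landmark series CSV
#'
#' Columns `time_h,somite_ref_x,somite_ref_y,post_end_x,post_end_y,
#' pnt_left_x,pnt_right_x,somite_pairs`.
#' @param path CSV path.
#' @return A [landmark_series()].
#' @export
read_landmark_series <- function(path) {
  tab <- read.csv(path)
  do.call(landmark_series, as.list(tab))
}

ls_slope <- function(t, y) {
  if (length(t) < 2L)
    vm_abort("need at least 2 frames", "vitmech_insufficient_data")
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Body-axis elongation speed
#'
#' Least-squares slope of the Euclidean distance between the reference
#' somite pair and the posterior end of the body axis against time.
#' Negative values indicate axis shortening.
#'
#' @param series A [landmark_series()].
#' @return Speed in micrometres/h.
#' @export
elongation_speed <- function(series) {
  d <- sqrt((series$post_end_x - series$somite_ref_x)^2 +
              (series$post_end_y - series$somite_ref_y)^2)
  ls_slope(series$time_h, d)
}

#' Posterior neural tube convergence speed
#'
#' Minus the least-squares slope of the pNT width (distance between the
#' outer boundaries of the neural tube walls) against time: a narrowing
#' tube gives a positive convergence speed, a widening tube a negative one.
#'
#' @param series A [landmark_series()].
#' @return Speed in micrometres/h.
#' @export
convergence_speed <- function(series) {
  -ls_slope(series$time_h, series$pnt_right_x - series$pnt_left_x)
}

#' Segmentation (somitogenesis) speed
#'
#' Least-squares slope of the somite pair count against time.
#'
#' @param series A [landmark_series()].
#' @return Somite pairs per hour.
#' @export
segmentation_speed <- function(series) {
  ls_slope(series$time_h, series$somite_pairs)
}

#' Summarize all axis speeds of a landmark series
#' @param series A [landmark_series()].
#' @return One-row data frame with the three speeds and the mean pNT width.
#' @export
axis_speeds <- function(series) {
  data.frame(elongation_um_per_h = elongation_speed(series),
             convergence_um_per_h = convergence_speed(series),
             segmentation_pairs_per_h = segmentation_speed(series),
             pnt_width_um = mean(series$pnt_right_x - series$pnt_left_x))
}

#' Fibre density of a stained VM image
#'
#' Converts a grayscale fibre-stain image to binary (fibres white) with a
#' global Otsu threshold and averages the white-pixel fraction over
#' randomly placed square regions of interest. The Otsu threshold is
#' computed on the min-max-normalized image, so the result is invariant
#' under affine intensity rescaling.
#'
#' @param image Numeric matrix of intensities (or a path readable by
#'   [EBImage::readImage()]; multichannel images are averaged to gray).
#' @param n_rois Number of ROIs (default 10).
#' @param roi_size ROI side length in pixels (default 128; capped at the
#'   image size).
#' @param seed Integer seed for ROI placement.
#' @param fibres_dark Set `TRUE` when fibres are darker than background;
#'   the image is inverted before thresholding.
#' @return Mean white-pixel fraction across ROIs, in `[0, 1]`, with
#'   attributes `threshold` (on the normalized scale), `roi_fractions` and
#'   `seed`. A constant image has no threshold; it yields 0 with a warning
#'   of class `vitmech_degenerate_image`.
#' @export
fibre_density <- function(image, n_rois = 10, roi_size = 128, seed = 0,
                          fibres_dark = FALSE) {
  if (is.character(image)) {
    img <- EBImage::readImage(image)
    image <- EBImage::imageData(img)
    if (length(dim(image)) == 3L) image <- apply(image, c(1L, 2L), mean)
  }
  if (!is.matrix(image) || !is.numeric(image) || !all(is.finite(image)))
    vm_abort("image must be a finite numeric matrix", "vitmech_domain_error")
  if (n_rois < 1L)
    vm_abort("`n_rois` must be >= 1", "vitmech_domain_error")
  rng <- diff(range(image))
  if (rng == 0) {
    vm_warn("constant image: Otsu threshold undefined, density 0 by convention",
            "vitmech_degenerate_image")
    return(structure(0, threshold = NA_real_, roi_fractions = NA_real_,
                     seed = seed))
  }
  norm <- (image - min(image)) / rng
  if (fibres_dark) norm <- 1 - norm
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  binary <- norm > th

  roi <- min(as.integer(roi_size), nrow(binary), ncol(binary))
  fractions <- with_seed(seed, {
    x0 <- sample.int(nrow(binary) - roi + 1L, n_rois, replace = TRUE)
    y0 <- sample.int(ncol(binary) - roi + 1L, n_rois, replace = TRUE)
    vapply(seq_len(n_rois), function(i) {
      mean(binary[x0[i]:(x0[i] + roi - 1L), y0[i]:(y0[i] + roi - 1L)])
    }, numeric(1))
  })
  structure(mean(fractions), threshold = th, roi_fractions = fractions,
            seed = seed)
}
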