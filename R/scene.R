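#' Linear ratio-pH calibration line
#'
#' Linear map R = a * pH + b between a dual-excitation fluorescence ratio
#' and pH, valid over a stated pH range.
#'
#' @param slope,intercept line coefficients (slope != 0).
#' @param pH_lo,pH_hi validity range (pH_lo < pH_hi).
#' @param se optional named vector of coefficient standard errors.
#' @return object of class `calibration_line`.
#' @export
calibration_line <- function(slope, intercept, pH_lo = 5, pH_hi = 8,
                             se = c(slope = NA_real_, intercept = NA_real_)) {
  stopifnot(slope != 0, pH_lo < pH_hi)
  structure(list(slope = slope, intercept = intercept,
                 pH_lo = pH_lo, pH_hi = pH_hi, se = se),
            class = "calibration_line")
}

#' Evaluate a calibration line (pH -> ratio)
#'
#' @param line a [calibration_line()].
#' @param pH pH values.
#' @return predicted ratios.
#' @export
predict_ratio <- function(line, pH) line$slope * pH + line$intercept

#' Specification of a synthetic vesicle scene
#'
#' Defines a multi-channel fluorescence scene of diffraction-limited
#' vesicles: isotropic Gaussian spots whose 488/405 integrated-intensity
#' ratio is linear in luminal pH, a pH-independent 561 channel (membrane
#'-protein tag proxy), uniform background and Poisson shot noise.
#'
#' @param image_shape length-2 integer (rows, cols), px.
#' @param n_vesicles number of spots (>= 0).
#' @param spot_sigma_px PSF standard deviation, px.
#' @param pH_mean,pH_sd luminal pH distribution (draws are clipped to the
#'   calibration line's validity range).
#' @param ratio_line forward [calibration_line()].
#' @param background_level uniform background, counts.
#' @param photon_scale photons per intensity unit; `Inf` disables shot
#'   noise.
#' @param amp_405 mean 405-channel spot amplitude, counts.
#' @param amp_561 mean 561-channel spot amplitude, counts.
#' @param min_sep_factor minimum pairwise center distance, in units of
#'   `spot_sigma_px` (default 4).
#' @param seed RNG seed.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(128, 128), n_vesicles = 50,
                       spot_sigma_px = 1.3, pH_mean = 6.3, pH_sd = 0.2,
                       ratio_line = calibration_line(0.5, -2.0, 5, 8),
                       background_level = 20, photon_scale = 1,
                       amp_405 = 150, amp_561 = 200,
                       min_sep_factor = 4, seed = NULL) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 16),
            n_vesicles >= 0, spot_sigma_px > 0, pH_sd >= 0,
            inherits(ratio_line, "calibration_line"),
            background_level >= 0, photon_scale > 0, amp_405 > 0,
            amp_561 > 0, min_sep_factor > 0)
  structure(list(image_shape = as.integer(image_shape),
                 n_vesicles = as.integer(n_vesicles),
                 spot_sigma_px = spot_sigma_px, pH_mean = pH_mean,
                 pH_sd = pH_sd, ratio_line = ratio_line,
                 background_level = background_level,
                 photon_scale = photon_scale, amp_405 = amp_405,
                 amp_561 = amp_561, min_sep_factor = min_sep_factor,
                 seed = seed),
            class = "scene_spec")
}

# rejection-sample spot centers respecting border margin and min separation
draw_centers <- function(shape, n, margin, min_sep, max_tries = 2000L) {
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("spot placement failed min-distance constraint after bounded retries")
    x <- stats::runif(1, 1 + margin, shape[2] - margin)
    y <- stats::runif(1, 1 + margin, shape[1] - margin)
    if (length(xs) == 0 ||
        min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x_px = xs, y_px = ys)
}

# add one Gaussian spot (amplitude at peak) to an image matrix;
# pixel (r, c) has its center at (x = c, y = r)
add_spot <- function(img, x, y, amp, sigma) {
  r0 <- max(1, floor(y - 5 * sigma)); r1 <- min(nrow(img), ceiling(y + 5 * sigma))
  c0 <- max(1, floor(x - 5 * sigma)); c1 <- min(ncol(img), ceiling(x + 5 * sigma))
  rr <- r0:r1; cc <- c0:c1
  g <- outer(exp(-(rr - y)^2 / (2 * sigma^2)),
             exp(-(cc - x)^2 / (2 * sigma^2)))
  img[rr, cc] <- img[rr, cc] + amp * g
  img
}

#' Render a three-channel synthetic vesicle scene
#'
#' Forward model for ratiometric vesicular pH imaging: every vesicle is an
#' isotropic Gaussian spot in all channels; the 405-channel amplitude is
#' drawn per vesicle, the 488-channel amplitude is amp405 * ratio_line(pH)
#' so that the integrated-intensity ratio F488/F405 equals the calibration
#' line exactly before noise; the 561 channel carries an independent
#' amplitude. Uniform background is added and, unless `photon_scale` is
#' infinite, pixel values are Poisson-distributed photon counts divided by
#' `photon_scale`.
#'
#' @param spec a [scene_spec()].
#' @param pH_fixed optional single pH clamping every vesicle (calibration
#'   scenes); overrides the pH distribution.
#' @return object of class `vesicle_scene`: list with `channels` (named
#'   list of matrices `ch405`, `ch488`, `ch561`), `truth` (data.frame
#'   x_px, y_px, pH, amp_405, amp_488, amp_561) and the `spec`.
#' @export
render_vesicle_scene <- function(spec, pH_fixed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  shape <- spec$image_shape
  sig <- spec$spot_sigma_px
  n <- spec$n_vesicles
  line <- spec$ratio_line
  if (n > 0) {
    ctr <- draw_centers(shape, n, margin = 3 * sig,
                        min_sep = spec$min_sep_factor * sig)
    pH <- if (!is.null(pH_fixed)) rep(pH_fixed, n)
          else pmin(pmax(stats::rnorm(n, spec$pH_mean, spec$pH_sd),
                         line$pH_lo), line$pH_hi)
    a405 <- spec$amp_405 * stats::runif(n, 0.7, 1.3)
    a488 <- a405 * predict_ratio(line, pH)
    a561 <- spec$amp_561 * stats::runif(n, 0.7, 1.3)
    truth <- data.frame(x_px = ctr$x_px, y_px = ctr$y_px, pH = pH,
                        amp_405 = a405, amp_488 = a488, amp_561 = a561)
  } else {
    truth <- data.frame(x_px = numeric(0), y_px = numeric(0), pH = numeric(0),
                        amp_405 = numeric(0), amp_488 = numeric(0),
                        amp_561 = numeric(0))
  }
  mk <- function(col) {
    img <- matrix(spec$background_level, shape[1], shape[2])
    if (n > 0)
      for (i in seq_len(n))
        img <- add_spot(img, truth$x_px[i], truth$y_px[i], truth[[col]][i], sig)
    if (is.finite(spec$photon_scale))
      img <- matrix(stats::rpois(length(img), img * spec$photon_scale) /
                      spec$photon_scale, shape[1], shape[2])
    img
  }
  structure(list(channels = list(ch405 = mk("amp_405"), ch488 = mk("amp_488"),
                                 ch561 = mk("amp_561")),
                 truth = truth, spec = spec),
            class = "vesicle_scene")
}

#' Simulate a nigericin-clamp calibration series
#'
#' One scene per listed pH, with every vesicle's lumen clamped at that pH
#' (emulating ionophore equilibration of intra- and extracellular acidity).
#'
#' @param pH_list pH values, each within the forward line's validity range.
#' @param scene_template a [scene_spec()] used for every scene.
#' @param n_replicates scenes per pH (default 1).
#' @param seed base seed; scene i of pH j uses `seed + 100*j + i`.
#' @return list of `vesicle_scene` objects with elements named
#'   `pH<value>_rep<i>`; attribute `pH` carries the per-scene pH.
#' @export
simulate_calibration_series <- function(pH_list, scene_template,
                                        n_replicates = 1, seed = 1) {
  line <- scene_template$ratio_line
  if (any(pH_list < line$pH_lo | pH_list > line$pH_hi))
    stop("pH values outside the forward line's validity range")
  out <- list(); ph_tags <- numeric(0)
  for (j in seq_along(pH_list)) {
    for (i in seq_len(n_replicates)) {
      sp <- scene_template
      sp$seed <- seed + 100 * j + i
      nm <- sprintf("pH%.2f_rep%d", pH_list[j], i)
      out[[nm]] <- render_vesicle_scene(sp, pH_fixed = pH_list[j])
      ph_tags <- c(ph_tags, pH_list[j])
    }
  }
  attr(out, "pH") <- ph_tags
  out
}
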