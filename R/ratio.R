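#' Per-vesicle dual-excitation ratio measurement
#'
#' For every detected particle, integrates background-subtracted intensity
#' over a disc of radius `r_meas_px` in the 488- and 405-excitation
#' channels and forms R = F488/F405. Background per vesicle is the median
#' of an annulus (r_meas+1 .. r_meas+3 px) around the centroid, robust to
#' neighboring spots. Vesicles with a non-positive denominator are excluded
#' and reported in the `excluded` attribute.
#'
#' @param channels named list with matrices `ch405` and `ch488` (e.g. a
#'   `vesicle_scene`'s `channels`).
#' @param particles a `particle_set` (x_px, y_px).
#' @param r_meas_px measurement disc radius, px.
#' @param background one of "annulus" (default) or "none".
#' @return data.frame with `x_px`, `y_px`, `F405`, `F488`, `R`; excluded
#'   vesicles (if any) in `attr(, "excluded")`.
#' @export
measure_ratio <- function(channels, particles, r_meas_px = 3,
                          background = c("annulus", "none")) {
  background <- match.arg(background)
  if (inherits(channels, "vesicle_scene")) channels <- channels$channels
  ch405 <- channels$ch405; ch488 <- channels$ch488
  stopifnot(identical(dim(ch405), dim(ch488)))
  integ <- function(img, x, y) {
    w <- r_meas_px
    rr0 <- round(y); cc0 <- round(x)
    offs <- expand.grid(dr = -(w + 3):(w + 3), dc = -(w + 3):(w + 3))
    d2 <- offs$dr^2 + offs$dc^2
    rr <- rr0 + offs$dr; cc <- cc0 + offs$dc
    ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
    vals <- rep(NA_real_, nrow(offs))
    vals[ok] <- img[cbind(rr[ok], cc[ok])]
    disc <- d2 <= w^2 & ok
    ann <- d2 > (w + 1)^2 & d2 <= (w + 3)^2 & ok
    bg <- if (background == "annulus") stats::median(vals[ann]) else 0
    sum(vals[disc] - bg)
  }
  n <- nrow(particles)
  F405 <- F488 <- numeric(n)
  for (i in seq_len(n)) {
    F405[i] <- integ(ch405, particles$x_px[i], particles$y_px[i])
    F488[i] <- integ(ch488, particles$x_px[i], particles$y_px[i])
  }
  out <- data.frame(x_px = particles$x_px, y_px = particles$y_px,
                    F405 = F405, F488 = F488, R = F488 / F405)
  bad <- !is.finite(out$R) | out$F405 <= 0
  excluded <- out[bad, , drop = FALSE]
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Fit a straight-line ratio-pH calibration
#'
#' Ordinary least squares of mean ratio against pH; the validity range is
#' the span of the calibration pH values.
#'
#' @param pH_values clamped pH per calibration point (>= 3 distinct values
#'   required for a meaningful line; >= 2 for an exact fit).
#' @param mean_ratios measured mean ratio per point.
#' @return a [calibration_line()] with coefficient standard errors.
#' @export
fit_calibration_line <- function(pH_values, mean_ratios) {
  stopifnot(length(pH_values) == length(mean_ratios))
  if (length(unique(pH_values)) < 2)
    stop("rank-deficient calibration: need >= 2 distinct pH values")
  fit <- stats::lm(mean_ratios ~ pH_values)
  cf <- coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) c(NA_real_, NA_real_))
  calibration_line(slope = unname(cf[2]), intercept = unname(cf[1]),
                   pH_lo = min(pH_values), pH_hi = max(pH_values),
                   se = c(slope = unname(se[2]), intercept = unname(se[1])))
}

#' Convert fluorescence ratios to pH via a calibration line
#'
#' pH = (R - b)/a. Results outside the line's validity range are flagged
#' as extrapolated, not dropped.
#'
#' @param R ratio values.
#' @param line a [calibration_line()].
#' @return data.frame with `R`, `pH`, `extrapolated` (logical).
#' @export
ratios_to_pH <- function(R, line) {
  stopifnot(inherits(line, "calibration_line"))
  pH <- (R - line$intercept) / line$slope
  data.frame(R = R, pH = pH,
             extrapolated = pH < line$pH_lo | pH > line$pH_hi)
}

#' Pixelwise colocalization of two channels
#'
#' Pearson correlation over a mask plus a binary overlap map of pixels
#' exceeding both channels' per-channel brightness percentile within the
#' mask.
#'
#' @param channel_a,channel_b co-registered matrices.
#' @param mask logical matrix (default: all pixels).
#' @param threshold_percentile percentile (0-100) for the overlap map.
#' @return list with `pearson_r`, `overlap` (logical matrix, FALSE outside
#'   the mask) and `overlap_fraction` (overlap pixels / mask pixels).
#' @export
colocalize <- function(channel_a, channel_b, mask = NULL,
                       threshold_percentile = 80) {
  stopifnot(identical(dim(channel_a), dim(channel_b)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel_a), ncol(channel_a))
  if (!any(mask)) stop("empty mask")
  a <- channel_a[mask]; b <- channel_b[mask]
  r <- stats::cor(a, b)
  ta <- stats::quantile(a, threshold_percentile / 100, names = FALSE)
  tb <- stats::quantile(b, threshold_percentile / 100, names = FALSE)
  overlap <- mask & channel_a > ta & channel_b > tb
  list(pearson_r = r, overlap = overlap,
       overlap_fraction = sum(overlap) / sum(mask))
}

#' Compare vesicular pH between experimental groups
#'
#' Per-group mean and SEM of per-cell mean pH, with pairwise two-sample
#' t-tests (Welch by default) and significance at the given level.
#'
#' @param groups named list of numeric vectors (per-cell mean pH; >= 2
#'   cells per group).
#' @param alpha significance level (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return list with `summary` (data.frame group, n, mean, sem) and
#'   `tests` (data.frame group_a, group_b, t, df, p, significant).
#' @export
compare_vesicular_ph <- function(groups, alpha = 0.05, var_equal = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  if (any(vapply(groups, length, 1L) < 2))
    stop("need >= 2 cells per group")
  summ <- data.frame(group = names(groups),
                     n = vapply(groups, length, 1L),
                     mean = vapply(groups, mean, 1),
                     sem = vapply(groups, function(g)
                       stats::sd(g) / sqrt(length(g)), 1))
  rownames(summ) <- NULL
  pairs <- utils::combn(names(groups), 2)
  tests <- apply(pairs, 2, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      data.frame(group_a = pr[1], group_b = pr[2], t = 0, df = NA_real_,
                 p = 1, significant = FALSE)
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
      data.frame(group_a = pr[1], group_b = pr[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, significant = tt$p.value < alpha)
    }
  })
  list(summary = summ, tests = do.call(rbind, tests))
}

#' Vesicular pH of one scene, end to end
#'
#' Detect vesicles in the reference channel, measure F488/F405 and convert
#' to pH through the calibration line.
#'
#' @param scene a `vesicle_scene`.
#' @param line a [calibration_line()].
#' @param channel detection channel ("ch561" if the transporter tag is
#'   present, "ch405" otherwise).
#' @param w_px,percentile_threshold,r_meas_px detector/measurement settings.
#' @return data.frame per vesicle (x_px, y_px, R, pH, extrapolated) plus
#'   attribute `mean_pH` (the per-cell mean over in-range vesicles).
#' @export
scene_vesicle_ph <- function(scene, line, channel = "ch561", w_px = 3,
                             percentile_threshold = 90, r_meas_px = 3) {
  det <- detect_vesicles(scene, channel = channel, w_px = w_px,
                         percentile_threshold = percentile_threshold)
  rat <- measure_ratio(scene$channels, det, r_meas_px = r_meas_px)
  ph <- ratios_to_pH(rat$R, line)
  out <- cbind(rat[, c("x_px", "y_px", "R")],
               ph[, c("pH", "extrapolated")])
  attr(out, "mean_pH") <- mean(out$pH[!out$extrapolated])
  out
}
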