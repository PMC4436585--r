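# separable band-limited convolution with edge renormalization:
# constant images map to the same constant, so bandpass(const) == 0
conv_sep_norm <- function(img, k) {
  n <- length(k)
  half <- (n - 1) / 2
  band <- function(m) {
    # banded convolution matrix for one dimension, rows renormalized
    B <- matrix(0, m, m)
    for (j in seq_len(n)) {
      off <- j - 1 - half
      idx <- seq_len(m)
      src <- idx + off
      ok <- src >= 1 & src <= m
      B[cbind(idx[ok], src[ok])] <- B[cbind(idx[ok], src[ok])] + k[j]
    }
    B / rowSums(B) * sum(k)   # edge rows renormalized to full kernel mass
  }
  Br <- band(nrow(img)); Bc <- band(ncol(img))
  Br %*% img %*% t(Bc)
}

#' Crocker-Grier spatial band-pass filter
#'
#' Difference of a Gaussian blur (sigma = `noise_sigma_px`, suppressing
#' pixel noise) and a boxcar mean over a (2w+1) x (2w+1) window
#' (suppressing slowly varying background), with negative values clipped
#' to zero. A constant image maps to all zeros.
#'
#' @param image numeric matrix.
#' @param object_w_px object half-size w, px (>= 2 * noise_sigma_px).
#' @param noise_sigma_px Gaussian noise-smoothing scale, px.
#' @return filtered matrix, non-negative.
#' @export
bandpass <- function(image, object_w_px = 3, noise_sigma_px = 1) {
  if (object_w_px < 2 * noise_sigma_px)
    stop("object_w_px must be >= 2 * noise_sigma_px")
  hg <- ceiling(3 * noise_sigma_px)
  kg <- exp(-((-hg):hg)^2 / (2 * noise_sigma_px^2))
  kg <- kg / sum(kg)
  kb <- rep(1, 2 * object_w_px + 1)
  kb <- kb / sum(kb)
  out <- conv_sep_norm(image, kg) - conv_sep_norm(image, kb)
  out[out < 0] <- 0
  out
}

# square-window running maximum via shifted pmax (radius w)
local_max_map <- function(img, w) {
  shift <- function(m, dr, dc) {
    out <- matrix(-Inf, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + dr; cs <- seq_len(ncol(m)) + dc
    okr <- rs >= 1 & rs <= nrow(m); okc <- cs >= 1 & cs <= ncol(m)
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  mx <- img
  for (d in seq_len(w)) mx <- pmax(mx, shift(img, d, 0), shift(img, -d, 0))
  mx2 <- mx
  for (d in seq_len(w)) mx2 <- pmax(mx2, shift(mx, 0, d), shift(mx, 0, -d))
  mx2
}

#' Locate particles by local maxima and iterated centroid refinement
#'
#' Candidate pixels are local maxima within a (2w+1) square neighborhood
#' lying above the given brightness percentile of the filtered image. Each
#' candidate is refined by an iterated intensity centroid over a disc of
#' radius w (at most `max_iter` iterations, stopping when the shift falls
#' below `tol_px`). Integrated brightness m0 and radius-of-gyration squared
#' Rg2 are computed over the final disc. Candidates closer than w are
#' merged, keeping the brighter.
#'
#' @param filtered band-passed image (from [bandpass()]).
#' @param w_px disc/neighborhood radius, px.
#' @param percentile_threshold brightness percentile (0-100) of the
#'   filtered image a candidate must exceed; an absolute 6-sigma noise
#'   floor is applied in addition.
#' @param max_iter,tol_px refinement controls.
#' @return object of class `particle_set`: data.frame with `x_px`, `y_px`
#'   (sub-pixel centroids, x = column, y = row, pixel centers at integers),
#'   `m0`, `Rg2`.
#' @export
locate_particles <- function(filtered, w_px = 3, percentile_threshold = 90,
                             max_iter = 10, tol_px = 0.05) {
  w <- w_px
  if (max(filtered) <= 0) {
    out <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      m0 = numeric(0), Rg2 = numeric(0))
    class(out) <- c("particle_set", "data.frame")
    return(out)
  }
  thr <- stats::quantile(filtered, percentile_threshold / 100, names = FALSE)
  # absolute noise floor: the clipped band-passed background is half-normal,
  # so its 84th percentile estimates one sigma of the underlying noise;
  # candidates must clear 6 sigma, which silences background-only images
  noise_floor <- 6 * stats::quantile(filtered, 0.84, names = FALSE)
  thr <- max(thr, noise_floor)
  mx <- local_max_map(filtered, w)
  cand <- which(filtered >= mx & filtered > thr, arr.ind = TRUE)
  # drop candidates whose disc would leave the image
  keep <- cand[, 1] > w & cand[, 1] <= nrow(filtered) - w &
    cand[, 2] > w & cand[, 2] <= ncol(filtered) - w
  cand <- cand[keep, , drop = FALSE]

  offs <- expand.grid(dr = -w:w, dc = -w:w)
  offs <- offs[offs$dr^2 + offs$dc^2 <= w^2, ]
  res <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    for (it in seq_len(max_iter)) {
      rr <- r + offs$dr; cc <- c + offs$dc
      ok <- rr >= 1 & rr <= nrow(filtered) & cc >= 1 & cc <= ncol(filtered)
      vals <- filtered[cbind(rr[ok], cc[ok])]
      m0 <- sum(vals)
      if (m0 <= 0) break
      dy <- sum(vals * offs$dr[ok]) / m0
      dx <- sum(vals * offs$dc[ok]) / m0
      if (abs(dx) <= 0.5 && abs(dy) <= 0.5) {
        if (sqrt(dx^2 + dy^2) < tol_px) break
        break  # sub-pixel offset accepted; window centered
      }
      r <- r + round(dy); c <- c + round(dx)
      r <- min(max(r, w + 1), nrow(filtered) - w)
      c <- min(max(c, w + 1), ncol(filtered) - w)
    }
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= nrow(filtered) & cc >= 1 & cc <= ncol(filtered)
    vals <- filtered[cbind(rr[ok], cc[ok])]
    m0 <- sum(vals)
    if (m0 <= 0) next
    dy <- sum(vals * offs$dr[ok]) / m0
    dx <- sum(vals * offs$dc[ok]) / m0
    rg2 <- sum(vals * ((offs$dr[ok] - dy)^2 + (offs$dc[ok] - dx)^2)) / m0
    res[[length(res) + 1]] <- data.frame(x_px = c + dx, y_px = r + dy,
                                         m0 = m0, Rg2 = rg2)
  }
  if (length(res) == 0) {
    out <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      m0 = numeric(0), Rg2 = numeric(0))
  } else {
    out <- do.call(rbind, res)
    # merge duplicates closer than w, keeping the brighter
    ord <- order(-out$m0)
    out <- out[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      if (i < nrow(out)) {
        later <- (i + 1):nrow(out)
        d <- sqrt((out$x_px[later] - out$x_px[i])^2 +
                    (out$y_px[later] - out$y_px[i])^2)
        keep[later[d < w]] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("particle_set", "data.frame")
  out
}

#' Detect vesicles in a scene's reference channel
#'
#' Convenience wrapper: band-pass the detection channel (561 when a tagged
#' transporter is present, 405 otherwise) and locate particles.
#'
#' @param scene a `vesicle_scene` or named list of channel matrices.
#' @param channel detection channel, `"ch561"` or `"ch405"`.
#' @param w_px,percentile_threshold,noise_sigma_px detector parameters.
#' @return a `particle_set`.
#' @export
detect_vesicles <- function(scene, channel = c("ch561", "ch405"),
                            w_px = 3, percentile_threshold = 90,
                            noise_sigma_px = 1) {
  channel <- match.arg(channel)
  img <- if (inherits(scene, "vesicle_scene")) scene$channels[[channel]]
         else scene[[channel]]
  locate_particles(bandpass(img, object_w_px = w_px,
                            noise_sigma_px = noise_sigma_px),
                   w_px = w_px, percentile_threshold = percentile_threshold)
}

#' Match detected particles to ground-truth positions
#'
#' Greedy nearest-neighbor matching within a tolerance radius; each truth
#' position is matched at most once.
#'
#' @param detected a `particle_set` (or data.frame with x_px, y_px).
#' @param truth data.frame with x_px, y_px.
#' @param max_dist_px matching radius (default 2).
#' @return list with `recall`, `false_positive_rate` (unmatched detections /
#'   detections), `rmse_px` over matched pairs, and the match index table.
#' @export
match_particles <- function(detected, truth, max_dist_px = 2) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nt == 0)
    return(list(recall = NA_real_,
                false_positive_rate = if (nd > 0) 1 else 0,
                rmse_px = NA_real_, matches = NULL))
  if (nd == 0)
    return(list(recall = 0, false_positive_rate = 0, rmse_px = NA_real_,
                matches = NULL))
  d <- outer(detected$x_px, truth$x_px, "-")^2 +
    outer(detected$y_px, truth$y_px, "-")^2
  d <- sqrt(d)
  matches <- NULL
  used_d <- rep(FALSE, nd); used_t <- rep(FALSE, nt)
  repeat {
    d[used_d, ] <- Inf; d[, used_t] <- Inf
    m <- which.min(d)
    if (!length(m) || d[m] > max_dist_px || !is.finite(d[m])) break
    i <- (m - 1) %% nd + 1; j <- (m - 1) %/% nd + 1
    matches <- rbind(matches, data.frame(det = i, truth = j, dist = d[m]))
    used_d[i] <- TRUE; used_t[j] <- TRUE
  }
  n_match <- if (is.null(matches)) 0 else nrow(matches)
  list(recall = n_match / nt,
       false_positive_rate = if (nd > 0) (nd - n_match) / nd else 0,
       rmse_px = if (n_match > 0) sqrt(mean(matches$dist^2)) else NA_real_,
       matches = matches)
}
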