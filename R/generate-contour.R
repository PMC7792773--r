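## Synthetic equatorial-contour time series for flicker-noise spectroscopy,
## plus a simple fluorescence-ring renderer so that image-based contour
## detection can be exercised end to end.

#' Configuration for the contour-series generator
#'
#' @param kappa Bending rigidity, J.
#' @param sigma_bar Reduced tension (dimensionless).
#' @param radius Mean vesicle radius, micrometres.
#' @param l_max Largest generated degree (modes l = 2..l_max).
#' @param n_frames Number of frames.
#' @param n_angles Contour points per frame, uniform on \[0, 2pi).
#' @param temperature Temperature, K.
#' @param pixel_size Image pixel size, micrometres (default 0.133).
#' @param detection_noise Per-point radial detection noise, micrometres.
#' @param dt Frame interval, s.
#' @param seed Integer seed.
#' @return A validated list of class `contour_config`.
#' @export
contour_config <- function(kappa = 10.5e-20, sigma_bar = 0, radius = 10,
                           l_max = 20, n_frames = 1000, n_angles = 512,
                           temperature = 296.15, pixel_size = 0.133,
                           detection_noise = 0.02, dt = 0.03, seed = 1) {
  stopifnot(kappa > 0, l_max >= 2, n_frames >= 1, n_angles >= 16,
            radius > 0, pixel_size > 0, detection_noise >= 0, dt > 0)
  helfrich_mode_variance(2:l_max, kappa, sigma_bar, temperature)
  structure(list(
    kappa = kappa, sigma_bar = sigma_bar, radius = radius,
    l_max = as.integer(l_max), n_frames = as.integer(n_frames),
    n_angles = as.integer(n_angles), temperature = temperature,
    pixel_size = pixel_size, detection_noise = detection_noise,
    dt = dt, seed = as.integer(seed)
  ), class = "contour_config")
}

#' Construct a contour series object
#'
#' @param rho `n_frames` x `n_angles` matrix of contour radii (micrometres)
#'   sampled at uniform azimuths.
#' @param time Frame timestamps, s (default equally spaced).
#' @param pixel_size Pixel size, micrometres (metadata).
#' @param qc_pass Logical frame mask (default all `TRUE`).
#' @return An object of class `contour_series`: list with `rho`, `angles`,
#'   `time`, `radius_mean` (per-frame mean radius), `qc_pass`,
#'   `pixel_size`.
#' @export
contour_series <- function(rho, time = NULL, pixel_size = 0.133,
                           qc_pass = NULL) {
  stopifnot(is.matrix(rho), all(is.finite(rho)), all(rho > 0))
  n_frames <- nrow(rho); n_angles <- ncol(rho)
  time <- time %||% (seq_len(n_frames) - 1)
  qc_pass <- qc_pass %||% rep(TRUE, n_frames)
  stopifnot(length(time) == n_frames, length(qc_pass) == n_frames)
  structure(list(
    rho = rho,
    angles = 2 * pi * (seq_len(n_angles) - 1) / n_angles,
    time = time,
    radius_mean = rowMeans(rho),
    qc_pass = qc_pass,
    pixel_size = pixel_size
  ), class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf(
    "<contour_series> %d frames x %d angles, mean radius %.3f um, %d frame(s) QC-masked\n",
    nrow(x$rho), ncol(x$rho), mean(x$radius_mean), sum(!x$qc_pass)))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.contour_series <- function(x, ...) {
  n_frames <- nrow(x$rho); n_angles <- ncol(x$rho)
  tibble(
    frame = rep(seq_len(n_frames) - 1L, each = n_angles),
    time = rep(x$time, each = n_angles),
    angle = rep(x$angles, n_frames),
    rho = as.vector(t(x$rho)),
    qc_pass = rep(x$qc_pass, each = n_angles)
  )
}

#' Generate an equatorial contour time series
#'
#' Samples, per frame, the same spherical-mode model as
#' [gen_vesicle_ensemble()] evaluated on the equator
#' (\eqn{\theta = \pi/2}): \eqn{\rho(\phi) = R\,(1 + \sum a_{lm}
#' Y_{lm}(\pi/2, \phi))} with independent zero-mean Gaussian `a_lm` at the
#' Helfrich variance, plus optional per-point Gaussian detection noise. By
#' the addition theorem the ensemble Legendre spectrum of the relative
#' displacement obeys \eqn{B_l = \frac{2l+1}{4\pi}\langle a_{lm}^2\rangle}.
#'
#' @param config A [contour_config()].
#' @return A [contour_series()] with attribute `config`.
#' @export
#' @examples
#' cs <- gen_contour_series(contour_config(n_frames = 10))
#' cs
gen_contour_series <- function(config) {
  stopifnot(inherits(config, "contour_config"))
  set.seed(config$seed)
  cf <- config
  modes <- sph_mode_table(cf$l_max)
  vr <- helfrich_mode_variance(modes$l, cf$kappa, cf$sigma_bar, cf$temperature)
  A <- matrix(rnorm(nrow(modes) * cf$n_frames, sd = sqrt(vr)),
              nrow = nrow(modes))
  phi <- 2 * pi * (seq_len(cf$n_angles) - 1) / cf$n_angles
  B <- real_sph_basis(rep(pi / 2, cf$n_angles), phi, modes)  # angles x modes
  U <- t(B %*% A)                                            # frames x angles
  rho <- cf$radius * (1 + U)
  if (cf$detection_noise > 0) {
    rho <- rho + matrix(rnorm(length(rho), sd = cf$detection_noise),
                        nrow = nrow(rho))
  }
  out <- contour_series(rho, time = (seq_len(cf$n_frames) - 1) * cf$dt,
                        pixel_size = cf$pixel_size)
  attr(out, "config") <- cf
  out
}

#' Render synthetic GUV ring images from a contour series
#'
#' Produces, for each requested frame, a `size` x `size` image of a bright
#' ring with a Gaussian radial cross-section centred on the contour radius
#' \eqn{\rho(\phi)}, on a dark background, with Poisson photon noise.
#'
#' @param contours A [contour_series()].
#' @param frames Which frames to render (1-based indices; default all).
#' @param psf_sigma Radial Gaussian width of the ring, pixels.
#' @param photon_budget Expected photon count at the ring crest, per pixel;
#'   `Inf` disables Poisson noise.
#' @param background Expected background photons per pixel.
#' @param size Image side, pixels (default 512).
#' @param seed Integer seed for the Poisson noise.
#' @return A `size` x `size` x `length(frames)` numeric array with
#'   attributes `pixel_size` (micrometres) and `center` (pixel coordinates
#'   of the vesicle centre).
#' @export
render_guv_images <- function(contours, frames = NULL, psf_sigma = 1.5,
                              photon_budget = 1e4, background = 2,
                              size = 512, seed = 1) {
  stopifnot(inherits(contours, "contour_series"), psf_sigma > 0,
            photon_budget > 0, background >= 0)
  frames <- frames %||% seq_len(nrow(contours$rho))
  px <- contours$pixel_size
  center <- (size + 1) / 2
  rho_px <- contours$rho / px
  if (max(rho_px[frames, ]) + 4 * psf_sigma > size / 2) {
    abort("contour exceeds the field of view at this pixel size")
  }
  set.seed(seed)
  xs <- seq_len(size) - center
  r_px <- sqrt(outer(xs^2, xs^2, "+"))
  ang <- atan2(rep(xs, each = size), rep(xs, times = size)) # atan2(y, x); x fastest
  ang <- matrix(ifelse(ang < 0, ang + 2 * pi, ang), size, size)
  n_angles <- ncol(contours$rho)
  ang_idx <- (round(ang / (2 * pi / n_angles)) %% n_angles) + 1L
  out <- array(0, dim = c(size, size, length(frames)))
  peak <- if (is.infinite(photon_budget)) 1 else photon_budget
  for (k in seq_along(frames)) {
    f <- frames[k]
    rho_here <- matrix(rho_px[f, ang_idx], size, size)
    lambda <- background +
      peak * exp(-(r_px - rho_here)^2 / (2 * psf_sigma^2))
    out[, , k] <- if (is.infinite(photon_budget)) lambda
    else matrix(rpois(size * size, lambda), size, size)
  }
  attr(out, "pixel_size") <- px
  attr(out, "center") <- c(center, center)
  out
}
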