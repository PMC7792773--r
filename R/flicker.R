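## Flicker-noise spectroscopy of GUV equatorial contours: sub-pixel ring
## detection, radius-based frame QC, angular autocorrelation, Legendre
## decomposition, and the two rigidity estimators (average-based AVB and
## statistical SA).

#' Detect a vesicle contour in one fluorescence image
#'
#' Casts `n_angles` uniformly spaced rays from the (estimated) vesicle
#' centre, samples the radial intensity profile along each ray by bilinear
#' interpolation, locates the brightest point and refines it to sub-pixel
#' precision with a parabolic fit through the peak and its two neighbours.
#' Rays whose peak does not rise above the background are failures; a frame
#' with more than 10% failed rays is marked `qc_fail`.
#'
#' @param image Numeric matrix (one frame).
#' @param center_estimate Length-2 pixel coordinates of the centre; default
#'   the intensity-weighted centroid.
#' @param n_angles Number of contour points.
#' @param pixel_size Pixel size, micrometres (default from attribute, else
#'   0.133).
#' @param r_max Largest search radius, px (default just inside the frame).
#' @param peak_snr Minimum peak height above background, in background SDs.
#' @return A tibble with columns `angle`, `rho_px`, `rho` (micrometres) and
#'   attribute `qc_pass` (FALSE when detection failed on > 10% of rays).
#' @export
detect_contour <- function(image, center_estimate = NULL, n_angles = 360,
                           pixel_size = NULL, r_max = NULL, peak_snr = 4) {
  stopifnot(is.matrix(image))
  pixel_size <- pixel_size %||% attr(image, "pixel_size", exact = TRUE) %||% 0.133
  nx <- nrow(image); ny <- ncol(image)
  if (is.null(center_estimate)) {
    tot <- sum(image)
    if (tot <= 0) {
      out <- tibble(angle = 2 * pi * (seq_len(n_angles) - 1) / n_angles,
                    rho_px = NA_real_, rho = NA_real_)
      attr(out, "qc_pass") <- FALSE
      return(out)
    }
    center_estimate <- c(sum(rowSums(image) * seq_len(nx)),
                         sum(colSums(image) * seq_len(ny))) / tot
  }
  r_max <- r_max %||% (min(nx, ny) / 2 - 2)
  rstep <- 0.25
  radii <- seq(2, r_max, by = rstep)
  angles <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  bg <- median(image)
  bg_sd <- max(mad(as.vector(image)), 1e-12)
  ## bilinear sampler on the full (angle x radius) lattice
  px <- center_estimate[1] + outer(cos(angles), radii)
  py <- center_estimate[2] + outer(sin(angles), radii)
  ix <- pmin(pmax(floor(px), 1), nx - 1)
  iy <- pmin(pmax(floor(py), 1), ny - 1)
  fx <- px - ix; fy <- py - iy
  v <- image[cbind(as.vector(ix), as.vector(iy))] * (1 - fx) * (1 - fy) +
    image[cbind(as.vector(ix + 1), as.vector(iy))] * fx * (1 - fy) +
    image[cbind(as.vector(ix), as.vector(iy + 1))] * (1 - fx) * fy +
    image[cbind(as.vector(ix + 1), as.vector(iy + 1))] * fx * fy
  prof <- matrix(v, n_angles, length(radii))
  pk <- max.col(prof, ties.method = "first")
  pk_val <- prof[cbind(seq_len(n_angles), pk)]
  half_w <- 6L                                     # +/- 1.5 px window
  ok <- pk_val > bg + peak_snr * bg_sd & pk > half_w &
    pk <= length(radii) - half_w
  ## sub-pixel refinement: least-squares parabola on the log intensity over
  ## a +/- 1.5 px window (exact vertex for a Gaussian ring cross-section;
  ## the window averages out ray-interpolation error)
  rho_px <- rep(NA_real_, n_angles)
  if (any(ok)) {
    offs <- (-half_w):half_w
    d <- offs * rstep
    X <- cbind(1, d, d^2)
    Pm <- solve(crossprod(X), t(X))                # 3 x (2*half_w+1)
    iok <- which(ok)
    idx <- outer(pk[iok], offs, "+")
    Y <- matrix(prof[cbind(rep(iok, length(offs)), as.vector(idx))],
                nrow = length(iok))
    floor_v <- 1e-3 * (pk_val[iok] - bg)
    Yl <- log(pmax(Y - bg, floor_v))
    beta <- Pm %*% t(Yl)                           # 3 x n_ok
    shift <- ifelse(beta[3, ] < 0, -beta[2, ] / (2 * beta[3, ]), 0)
    shift <- pmin(pmax(shift, -1.5), 1.5)
    rho_px[iok] <- radii[pk[iok]] + shift
  }
  out <- tibble(angle = angles, rho_px = rho_px, rho = rho_px * pixel_size)
  attr(out, "qc_pass") <- mean(!ok) <= 0.10
  out
}

#' Detect contours in an image stack
#'
#' Applies [detect_contour()] to each frame of a 3D array and assembles a
#' [contour_series()]; frames that fail detection are QC-masked (their radii
#' are filled with the frame median so the series stays rectangular).
#'
#' @param images 3D array (x, y, frame), e.g. from [render_guv_images()].
#' @param ... Passed to [detect_contour()].
#' @param dt Frame interval, s.
#' @return A [contour_series()].
#' @export
detect_contour_series <- function(images, ..., dt = 0.03) {
  stopifnot(length(dim(images)) == 3)
  px <- attr(images, "pixel_size", exact = TRUE) %||% 0.133
  n <- dim(images)[3]
  frames <- vector("list", n)
  qc <- logical(n)
  for (i in seq_len(n)) {
    d <- detect_contour(images[, , i], pixel_size = px, ...)
    qc[i] <- isTRUE(attr(d, "qc_pass")) && !anyNA(d$rho)
    frames[[i]] <- d$rho
  }
  n_angles <- length(frames[[1]])
  rho <- do.call(rbind, lapply(frames, function(r) {
    if (anyNA(r)) r[is.na(r)] <- median(r, na.rm = TRUE)
    if (anyNA(r)) r[] <- 1e-6   # fully failed frame; masked below
    r
  }))
  contour_series(rho, time = (seq_len(n) - 1) * dt, pixel_size = px,
                 qc_pass = qc)
}

#' Radius-based frame quality control
#'
#' Masks frames whose mean contour radius deviates from the series median
#' by more than `k_mad` times the median absolute deviation — the
#' outlier-discarding step applied to each recorded image series.
#'
#' @param series A [contour_series()] (>= 10 frames).
#' @param k_mad Threshold in MADs (default 3; `Inf` disables the filter).
#' @return The series with `qc_pass` updated; attribute `n_masked` reports
#'   how many frames the filter newly masked. Errors if more than half the
#'   frames end up masked.
#' @export
qc_radius_filter <- function(series, k_mad = 3) {
  stopifnot(inherits(series, "contour_series"))
  n <- nrow(series$rho)
  if (n < 10) abort("need at least 10 frames for radius-based QC")
  r <- series$radius_mean
  med <- median(r)
  m <- mad(r)
  bad <- if (is.infinite(k_mad) || m == 0) rep(FALSE, n)
  else abs(r - med) > k_mad * m
  before <- sum(!series$qc_pass)
  series$qc_pass <- series$qc_pass & !bad
  if (mean(!series$qc_pass) > 0.5) {
    abort("more than 50% of frames masked by radius QC; series unusable")
  }
  attr(series, "n_masked") <- sum(!series$qc_pass) - before
  series
}

#' Angular autocorrelation of a contour
#'
#' For one frame's contour radii at uniform azimuths, computes the circular
#' autocorrelation of the relative radial displacement,
#' \deqn{\xi(\gamma) = \langle \tilde u(\phi + \gamma)\, \tilde u(\phi)
#' \rangle_\phi, \quad \tilde u = (\rho - \bar\rho) / \bar\rho,}
#' at lags \eqn{\gamma_k = 2\pi k / n} (via FFT).
#'
#' @param rho Numeric vector of contour radii at uniform angles.
#' @return A tibble with columns `gamma` (0..2pi) and `xi`.
#' @export
#' @examples
#' phi <- 2 * pi * (0:255) / 256
#' xi <- angular_autocorrelation(10 * (1 + 0.02 * cos(2 * phi)))
angular_autocorrelation <- function(rho) {
  n <- length(rho)
  u <- (rho - mean(rho)) / mean(rho)
  xi <- Re(fft(Mod(fft(u))^2, inverse = TRUE)) / n^2
  tibble(gamma = 2 * pi * (seq_len(n) - 1) / n, xi = xi)
}

## Quadrature matrix mapping xi samples on gamma in [0, pi] (the first
## n/2 + 1 circular lags) to Legendre coefficients l = 0..l_max:
## B_l = (2l+1)/2 * int xi(gamma) P_l(cos gamma) sin(gamma) d gamma.
.legendre_quad_matrix <- function(n_angles, l_max) {
  m <- n_angles %/% 2
  gam <- pi * (0:m) / m
  wt <- rep(pi / m, m + 1); wt[c(1, m + 1)] <- pi / (2 * m)   # trapezoid
  Q <- matrix(0, m + 1, l_max + 1)
  x <- cos(gam)
  for (l in 0:l_max) {
    Q[, l + 1] <- (2 * l + 1) / 2 * legendre_poly(l, x) * sin(gam) * wt
  }
  Q
}

#' Legendre decomposition of an angular autocorrelation
#'
#' Expands \eqn{\xi(\gamma) = \sum_l B_l P_l(\cos\gamma)} and recovers the
#' coefficients by quadrature on the sampled lags,
#' \eqn{B_l = \frac{2l+1}{2}\int_0^\pi \xi(\gamma) P_l(\cos\gamma)
#' \sin\gamma \, d\gamma}.
#'
#' @param xi Autocorrelation samples: either the tibble from
#'   [angular_autocorrelation()] (full circle) or a numeric vector of
#'   samples at uniform lags covering \[0, 2pi).
#' @param l_max Largest degree (requires `l_max <= n_angles / 4`).
#' @return A tibble with columns `l` (0..l_max) and `B`.
#' @export
legendre_decompose <- function(xi, l_max = 12) {
  if (is.data.frame(xi)) xi <- xi$xi
  n <- length(xi)
  if (l_max > n / 4) abort("l_max too large for this angular sampling")
  Q <- .legendre_quad_matrix(n, l_max)
  B <- as.vector(xi[seq_len(n %/% 2 + 1)] %*% Q)
  tibble(l = 0:l_max, B = B)
}

#' Legendre spectrum of a whole contour series
#'
#' Computes, for every QC-passing frame, the angular autocorrelation and
#' its Legendre coefficients \eqn{B_l(t)}, plus their time averages with
#' standard errors.
#'
#' @param series A [contour_series()].
#' @param l_max Largest degree (default 12).
#' @return An object of class `angular_spectrum`: list with `B` (frames x
#'   (l_max+1) matrix over l = 0..l_max), `l`, `B_mean`, `B_se`, `xi0`
#'   (mean relative radial variance), `completeness` (sum of B_l over
#'   xi(0)), `n_frames_used`, `R_mean` (micrometres), `time`.
#' @export
contour_spectrum <- function(series, l_max = 12) {
  stopifnot(inherits(series, "contour_series"))
  keep <- which(series$qc_pass)
  if (length(keep) == 0) abort("no QC-passing frames")
  rho <- series$rho[keep, , drop = FALSE]
  n <- ncol(rho)
  if (l_max > n / 4) abort("l_max too large for this angular sampling")
  rbar <- rowMeans(rho)
  U <- (rho - rbar) / rbar
  ## circular autocorrelation per frame via FFT across columns
  F <- t(stats::mvfft(t(U)))
  xiM <- Re(t(stats::mvfft(t(Mod(F)^2), inverse = TRUE))) / n^2
  Q <- .legendre_quad_matrix(n, l_max)
  B <- xiM[, seq_len(n %/% 2 + 1), drop = FALSE] %*% Q
  B_mean <- colMeans(B)
  B_se <- apply(B, 2, sd) / sqrt(nrow(B))
  xi0 <- mean(xiM[, 1])
  structure(list(
    B = B, l = 0:l_max, B_mean = B_mean, B_se = B_se,
    xi0 = xi0, completeness = sum(B_mean) / xi0,
    n_frames_used = length(keep),
    R_mean = mean(rbar), time = series$time[keep]
  ), class = "angular_spectrum")
}

#' @export
print.angular_spectrum <- function(x, ...) {
  cat(sprintf(
    "<angular_spectrum> l = 0..%d over %d frames; completeness sum(B_l)/xi(0) = %.3f\n",
    max(x$l), x$n_frames_used, x$completeness))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.angular_spectrum <- function(x, ...) {
  tibble(l = x$l, B_mean = x$B_mean, B_se = x$B_se,
         n_frames = x$n_frames_used)
}

#' @rdname autoplot-vesimech
#' @exportS3Method ggplot2::autoplot
autoplot.angular_spectrum <- function(object, ...) {
  df <- filter(tidy(object), .data$l >= 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$l, y = .data$B_mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$B_mean - .data$B_se,
                                        ymax = .data$B_mean + .data$B_se),
                           width = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree l", y = expression(B[l])) +
    ggplot2::theme_minimal()
}

## Closed-form inversion: kappa from one B_l given sigma_bar.
.kappa_from_Bl <- function(B, l, sigma_bar, temperature) {
  (2 * l + 1) / (4 * pi) * .kB * temperature /
    (B * (l - 1) * (l + 2) * (l * (l + 1) + sigma_bar))
}

#' Average-based (AVB) flicker estimate of the bending rigidity
#'
#' Weighted least-squares fit of the time-averaged Legendre coefficients
#' \eqn{\langle B_l\rangle} to the Helfrich form
#' \eqn{B_l = \frac{2l+1}{4\pi} \frac{k_B T}{\kappa(l-1)(l+2)[l(l+1)+\bar\sigma]}}
#' over `l_range`, weighted by the inverse squared standard errors.
#'
#' @param spectrum An `angular_spectrum` from [contour_spectrum()], or a
#'   data frame with columns `l`, `B_mean` and optionally `B_se`.
#' @param temperature Temperature, K.
#' @param l_range Degrees used (default 2:10, at least 3).
#' @param fix_sigma Optional fixed reduced tension.
#' @return An object of class `flicker_estimate` with `kappa` (J),
#'   `kappa_sd`, `sigma_bar`, `method = "AVB"`, `l_range`,
#'   `n_frames_used`, `fitted`.
#' @export
estimate_kappa_avb <- function(spectrum, temperature = 296.15,
                               l_range = 2:10, fix_sigma = NULL) {
  df <- if (inherits(spectrum, "angular_spectrum")) tidy(spectrum)
  else as_tibble(spectrum)
  df <- filter(df, .data$l %in% l_range, .data$B_mean > 0)
  if (nrow(df) < 3) abort("need at least 3 degrees with positive B in l_range")
  ## reuse the spectrum fitter: B_l = (2l+1)/(4 pi) <a_lm^2>
  power <- df$B_mean * 4 * pi / (2 * df$l + 1)
  power_se <- if ("B_se" %in% names(df)) df$B_se * 4 * pi / (2 * df$l + 1)
  else rep(NA_real_, nrow(df))
  spec_tbl <- tibble(l = df$l, power = power, power_se = power_se)
  hf <- fit_helfrich_sphere(spec_tbl, temperature, l_range, fix_sigma)
  structure(list(
    kappa = hf$kappa, kappa_sd = hf$kappa_sd,
    sigma_bar = hf$sigma_bar, sigma_bar_sd = hf$sigma_bar_sd,
    method = "AVB", l_range = hf$l_range, temperature = temperature,
    n_frames_used = if (inherits(spectrum, "angular_spectrum"))
      spectrum$n_frames_used else NA_integer_,
    fitted = mutate(hf$fitted,
                    B = .data$power * (2 * .data$l + 1) / (4 * pi),
                    B_fit = .data$fit * (2 * .data$l + 1) / (4 * pi)),
    helfrich = hf
  ), class = "flicker_estimate")
}

#' Statistical (SA) flicker estimate of the bending rigidity
#'
#' For each degree l the empirical distribution of the instantaneous
#' Legendre coefficients \eqn{B_l(t)} is fit with a gamma-family model
#' whose shape is fixed at \eqn{(2l+1)/2} (the quadratic form of 2l+1
#' independent Gaussian mode amplitudes) and whose scale carries
#' \eqn{\kappa}: the scale is estimated from the gamma likelihood's
#' estimating equation at fixed shape, \eqn{\hat s = \bar B_l / k}, which
#' stays well defined for the slightly-negative samples that cross-degree
#' leakage of a single frame's autocorrelation can produce at weakly
#' excited degrees (their fraction is reported per degree). The per-l
#' rigidity estimates are combined by inverse-variance weighting, and
#' per-degree histograms with the fitted gamma density are emitted for
#' inspection.
#'
#' @param spectrum An `angular_spectrum` from [contour_spectrum()] (needs
#'   the per-frame `B` matrix; >= 100 frames).
#' @param temperature Temperature, K.
#' @param l_range Degrees used (default 2:10).
#' @param sigma_bar Reduced tension used in the per-l inversion; default
#'   (`NULL`) it is taken from an AVB fit of the same spectrum.
#' @return A `flicker_estimate` with `method = "SA"`, a `per_l` tibble
#'   (l, shape, scale, B_fit, kappa_l, kappa_l_sd, n_used,
#'   frac_negative) and a `histograms` tibble (l, B_mid, density,
#'   density_fit).
#' @export
estimate_kappa_sa <- function(spectrum, temperature = 296.15,
                              l_range = 2:10, sigma_bar = NULL) {
  stopifnot(inherits(spectrum, "angular_spectrum"))
  if (spectrum$n_frames_used < 100) {
    abort("SA estimator needs at least 100 QC-passing frames")
  }
  if (is.null(sigma_bar)) {
    sigma_bar <- estimate_kappa_avb(spectrum, temperature, l_range)$sigma_bar
  }
  hists <- list()
  per_l <- purrr::map_dfr(intersect(l_range, spectrum$l), function(l) {
    x <- spectrum$B[, which(spectrum$l == l)]
    frac_negative <- mean(x <= 0)
    if (length(x) < 100 || var(x) == 0 || mean(x) <= 0) {
      return(tibble(l = l, shape = NA_real_, scale = NA_real_,
                    B_fit = NA_real_, kappa_l = NA_real_,
                    kappa_l_sd = NA_real_, n_used = length(x),
                    frac_negative = frac_negative, ok = FALSE))
    }
    shape <- (2 * l + 1) / 2
    scale <- mean(x) / shape
    B_fit <- shape * scale
    kappa_l <- .kappa_from_Bl(B_fit, l, sigma_bar, temperature)
    ## delta method: var(kappa_l) = kappa_l^2 var(B) / (n B^2)
    kappa_l_sd <- kappa_l * sd(x) / (sqrt(length(x)) * B_fit)
    h <- graphics::hist(x, breaks = 40, plot = FALSE)
    hists[[as.character(l)]] <<- tibble(
      l = l, B_mid = h$mids, density = h$density,
      density_fit = stats::dgamma(pmax(h$mids, 0), shape = shape,
                                  scale = scale))
    tibble(l = l, shape = shape, scale = scale, B_fit = B_fit,
           kappa_l = kappa_l, kappa_l_sd = kappa_l_sd,
           n_used = length(x), frac_negative = frac_negative, ok = TRUE)
  })
  dropped <- filter(per_l, !.data$ok)
  if (nrow(dropped) > 0) {
    warn(paste0("SA: dropped degree(s) ",
                paste(dropped$l, collapse = ", "),
                " (degenerate or non-positive-mean distribution)"))
  }
  use <- filter(per_l, .data$ok, is.finite(.data$kappa_l),
                is.finite(.data$kappa_l_sd), .data$kappa_l_sd > 0)
  if (nrow(use) == 0) abort("SA estimator failed at every degree (degenerate distributions?)")
  w <- 1 / use$kappa_l_sd^2
  kappa <- sum(w * use$kappa_l) / sum(w)
  kappa_sd <- sqrt(1 / sum(w))
  structure(list(
    kappa = kappa, kappa_sd = kappa_sd, sigma_bar = sigma_bar,
    sigma_bar_sd = NA_real_, method = "SA",
    l_range = use$l, temperature = temperature,
    n_frames_used = spectrum$n_frames_used,
    per_l = select(per_l, -"ok"),
    histograms = bind_rows(hists)
  ), class = "flicker_estimate")
}

#' @export
print.flicker_estimate <- function(x, ...) {
  cat(sprintf(
    "<flicker_estimate:%s> kappa = %.3e +/- %.2e J, sigma_bar = %.3g, l = %d..%d, %s frames\n",
    x$method, x$kappa, x$kappa_sd, x$sigma_bar,
    min(x$l_range), max(x$l_range),
    ifelse(is.na(x$n_frames_used), "?", x$n_frames_used)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flicker_estimate <- function(x, ...) {
  tibble(term = c("kappa", "sigma_bar"),
         estimate = c(x$kappa, x$sigma_bar),
         std.error = c(x$kappa_sd, x$sigma_bar_sd),
         method = x$method)
}

#' @exportS3Method generics::glance
glance.flicker_estimate <- function(x, ...) {
  tibble(method = x$method, kappa = x$kappa, kappa_sd = x$kappa_sd,
         sigma_bar = x$sigma_bar, n_frames_used = x$n_frames_used,
         l_min = min(x$l_range), l_max = max(x$l_range))
}

#' Full flicker pipeline on a contour series
#'
#' Radius QC ([qc_radius_filter()]), Legendre spectrum
#' ([contour_spectrum()]), then the AVB and/or SA estimator.
#'
#' @param series A [contour_series()].
#' @param temperature Temperature, K.
#' @param l_max Spectrum degree range top (default 12).
#' @param l_range Fit range (default 2:10).
#' @param method `"AVB"`, `"SA"`, or `"both"`.
#' @param k_mad Radius-QC threshold (default 3).
#' @return For a single method the `flicker_estimate`; for `"both"`, a
#'   named list with elements `AVB` and `SA` and the shared `spectrum`.
#' @export
flicker_kappa <- function(series, temperature = 296.15, l_max = 12,
                          l_range = 2:10, method = c("both", "AVB", "SA"),
                          k_mad = 3) {
  method <- match.arg(method)
  series <- qc_radius_filter(series, k_mad)
  spec <- contour_spectrum(series, l_max)
  if (method == "AVB") return(estimate_kappa_avb(spec, temperature, l_range))
  if (method == "SA") return(estimate_kappa_sa(spec, temperature, l_range))
  avb <- estimate_kappa_avb(spec, temperature, l_range)
  sa <- estimate_kappa_sa(spec, temperature, l_range, sigma_bar = avb$sigma_bar)
  list(AVB = avb, SA = sa, spectrum = spec)
}
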