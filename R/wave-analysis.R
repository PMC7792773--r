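## Pressure-wave analysis of a planar membrane: the impulse-derived water
## velocity kick, per-frame binning of head-particle heights along x, sine
## fitting, and tracking of the wave amplitude over time.

#' Water-slab velocity change from a pressure impulse
#'
#' \deqn{\Delta v_z = \frac{I \cdot A}{m \cdot N}} where `I` is the pressure
#' impulse (Pa s), `A` the area of the kicked water slab (m^2), `m` the
#' mass of one water particle (kg) and `N` the number of kicked particles.
#'
#' @param I Pressure impulse, Pa s (>= 0).
#' @param A Slab area, m^2 (> 0).
#' @param m Mass of one water particle, kg (> 0; 2.99e-26 kg for water).
#' @param N Number of kicked particles (>= 1).
#' @return Velocity change, m/s.
#' @export
#' @examples
#' water_velocity_kick(1e-5, 1e-16, 2.99e-26, 1000)  # ~33.4 m/s
water_velocity_kick <- function(I, A, m = 2.99e-26, N) {
  if (any(I < 0)) abort("pressure impulse I must be >= 0")
  if (any(A <= 0) || any(m <= 0)) abort("A and m must be positive")
  if (any(N < 1)) abort("N must be >= 1")
  I * A / (m * N)
}

#' Bin membrane height along x
#'
#' Means the z-positions of head particles in `n_bins` uniform x-bins over
#' `[0, box_length)` (y is averaged over). Empty bins are filled by linear
#' interpolation across x (periodic) and flagged.
#'
#' @param frame Single-frame trajectory table (head particles are used) or
#'   a data frame with columns `x` and `z`.
#' @param n_bins Number of bins (default 50).
#' @param box_length Periodic box length along x, nm.
#' @return A tibble with columns `x` (bin centres), `z` (mean height, nm),
#'   `n` (occupancy) and `interpolated`. Errors when more than 25% of bins
#'   are empty.
#' @export
bin_membrane_profile <- function(frame, n_bins = 50, box_length) {
  stopifnot(box_length > 0, n_bins >= 2)
  if ("role" %in% names(frame)) frame <- frame[frame$role == "head", ]
  if (nrow(frame) == 0) abort("no particles to bin")
  ib <- floor((frame$x %% box_length) / (box_length / n_bins)) + 1L
  ib <- pmin(ib, n_bins)
  occ <- tabulate(ib, n_bins)
  zs <- numeric(n_bins)
  agg <- rowsum(frame$z, ib)
  zs[as.integer(rownames(agg))] <- agg[, 1]
  zbar <- ifelse(occ > 0, zs / pmax(occ, 1L), NA_real_)
  if (mean(occ == 0) > 0.25) {
    abort("more than 25% of bins are empty; binning too fine for this frame")
  }
  empty <- which(occ == 0)
  if (length(empty) > 0) {
    ## periodic linear interpolation: triple the profile and interpolate
    xc <- (seq_len(n_bins) - 0.5) * box_length / n_bins
    x3 <- c(xc - box_length, xc, xc + box_length)
    z3 <- rep(zbar, 3)
    ok <- !is.na(z3)
    zbar[empty] <- approx(x3[ok], z3[ok], xout = xc[empty])$y
  }
  tibble(x = (seq_len(n_bins) - 0.5) * box_length / n_bins,
         z = zbar, n = occ, interpolated = occ == 0)
}

#' Fit a sine to a binned membrane profile
#'
#' Least-squares fit of \eqn{\bar z(x) = c + A \sin(2\pi x/\lambda +
#' \varphi)} with `A >= 0`, initialised from the dominant discrete Fourier
#' mode of the profile.
#'
#' @param profile Tibble from [bin_membrane_profile()] (columns `x`, `z`).
#' @param box_length Box length, nm.
#' @return A one-row tibble: `amplitude` (nm), `wavelength` (nm), `phase`
#'   (rad), `offset` (nm), `fit_rms` (nm), `degenerate` (TRUE for a flat
#'   profile where the wavelength is unidentifiable).
#' @export
fit_sine_profile <- function(profile, box_length) {
  z <- profile$z; x <- profile$x
  n <- length(z)
  if (n < 8) abort("need at least 8 bins for a sine fit")
  if (anyNA(z)) abort("profile contains NA heights")
  zc <- z - mean(z)
  if (sd(z) < 1e-10) {
    return(tibble(amplitude = 0, wavelength = NA_real_, phase = NA_real_,
                  offset = mean(z), fit_rms = sd(zc), degenerate = TRUE))
  }
  F <- fft(zc)
  k <- which.max(Mod(F[2:(n %/% 2 + 1)]))          # dominant spatial mode
  A0 <- 2 * Mod(F[k + 1]) / n
  lam0 <- box_length / k
  ## z ~ a sin + phase: F[k+1] = sum z exp(-2pi i k j / n)
  ph0 <- atan2(Re(F[k + 1]), -Im(F[k + 1])) - 2 * pi * k * x[1] / box_length
  dat <- data.frame(x = x, z = z)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ c0 + a * sin(2 * pi * x / lam + ph),
      data = dat,
      start = list(c0 = mean(z), a = A0, lam = lam0, ph = ph0),
      lower = c(c0 = -Inf, a = 0, lam = box_length / (n / 2), ph = -2 * pi),
      upper = c(c0 = Inf, a = Inf, lam = 4 * box_length, ph = 2 * pi),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ## report the Fourier initialisation as the fallback
    zfit <- mean(z) + A0 * sin(2 * pi * x / lam0 + ph0)
    return(tibble(amplitude = A0, wavelength = lam0,
                  phase = ph0 %% (2 * pi), offset = mean(z),
                  fit_rms = sqrt(mean((z - zfit)^2)), degenerate = FALSE))
  }
  cf <- coef(fit)
  tibble(amplitude = cf[["a"]], wavelength = cf[["lam"]],
         phase = cf[["ph"]] %% (2 * pi), offset = cf[["c0"]],
         fit_rms = sqrt(mean(resid(fit)^2)),
         degenerate = FALSE)
}

#' Wave amplitude evolution over a trajectory
#'
#' Bins and sine-fits every frame, assembles the amplitude series A(t), and
#' locates its extrema on a moving-average-smoothed copy with alternation
#' of maxima and minima enforced (of two same-type extrema without the
#' opposite type between them, the more extreme one is kept).
#'
#' @param traj Planar-membrane trajectory from e.g.
#'   [gen_wave_trajectory()] (head particles).
#' @param n_bins Number of x-bins (default 50).
#' @param box_length Box length, nm; default from the generator config
#'   attribute.
#' @param dt Frame interval, ps; default from the generator config.
#' @param smooth_window Moving-average window (frames) for extrema
#'   detection (default 3).
#' @param envelope_floor Extrema are only sought while the smoothed
#'   amplitude envelope stays above this fraction of its global maximum
#'   (default 0.02): once a damped wave has decayed below the floor,
#'   residual fit noise no longer produces spurious extrema.
#' @return An object of class `wave_series`: list with `profiles`
#'   (per-frame fit tibble), `amplitude` (tibble time/amplitude), `extrema`
#'   (tibble time/amplitude/type), `n_degenerate`, plus the call
#'   parameters.
#' @export
amplitude_evolution <- function(traj, n_bins = 50, box_length = NULL,
                                dt = NULL, smooth_window = 3,
                                envelope_floor = 0.02) {
  cf <- attr(traj, "config", exact = TRUE)
  box_length <- box_length %||% cf$box_length
  dt <- dt %||% cf$dt %||% 1
  if (is.null(box_length)) abort("box_length must be given (or carried by the trajectory)")
  traj <- as_trajectory(traj)
  idx <- .frame_index(traj)
  if (length(idx) < 20) abort("need at least 20 frames to track the amplitude")
  profiles <- purrr::map_dfr(seq_along(idx), function(i) {
    fr <- traj[idx[[i]], ]
    pr <- bin_membrane_profile(fr, n_bins, box_length)
    mutate(fit_sine_profile(pr, box_length),
           frame = fr$frame[1], time = fr$frame[1] * dt)
  })
  amp <- select(filter(profiles, !.data$degenerate),
                "frame", "time", "amplitude")
  if (nrow(amp) == 0) {
    extrema <- tibble(time = numeric(0), amplitude = numeric(0),
                      type = character(0))
  } else {
    ## moving-average smoothing for extrema detection only
    k <- max(1L, as.integer(smooth_window))
    a <- amp$amplitude
    sm <- if (k > 1 && length(a) >= k)
      as.vector(stats::filter(a, rep(1 / k, k), sides = 2)) else a
    sm[is.na(sm)] <- a[is.na(sm)]
    ## envelope threshold: stop the extrema search once the running envelope
    ## has decayed below envelope_floor * max (noise-dominated tail)
    n_use <- length(sm)
    if (envelope_floor > 0 && max(sm) > 0) {
      above <- which(sm >= envelope_floor * max(sm))
      if (length(above) > 0) n_use <- max(above)
    }
    extrema <- .find_extrema(amp$time[seq_len(n_use)], sm[seq_len(n_use)],
                             a[seq_len(n_use)])
  }
  structure(list(
    profiles = profiles, amplitude = amp, extrema = extrema,
    n_degenerate = sum(profiles$degenerate),
    n_bins = n_bins, box_length = box_length, dt = dt,
    smooth_window = smooth_window, envelope_floor = envelope_floor
  ), class = "wave_series")
}

## Local extrema of a smoothed series with enforced max/min alternation:
## consecutive extrema of the same type collapse to the more extreme one.
.find_extrema <- function(time, smooth, raw) {
  empty <- tibble(time = numeric(0), amplitude = numeric(0),
                  type = character(0))
  n <- length(smooth)
  if (n < 3) return(empty)
  d <- diff(smooth)
  s <- sign(d); s[s == 0] <- 1
  chg <- diff(s)
  turn <- which(chg != 0) + 1L
  if (length(turn) == 0) return(empty)
  ex <- tibble(time = time[turn], amplitude = raw[turn],
               type = ifelse(chg[turn - 1L] < 0, "max", "min"))
  out <- ex[1, ]
  for (i in seq_len(nrow(ex))[-1]) {
    last <- nrow(out)
    if (ex$type[i] == out$type[last]) {
      better <- if (ex$type[i] == "max") ex$amplitude[i] > out$amplitude[last]
      else ex$amplitude[i] < out$amplitude[last]
      if (better) out[last, ] <- ex[i, ]
    } else {
      out <- bind_rows(out, ex[i, ])
    }
  }
  out
}

#' @export
print.wave_series <- function(x, ...) {
  cat(sprintf(
    "<wave_series> %d frames, %d extrema (%d degenerate fits)\n",
    nrow(x$amplitude), nrow(x$extrema), x$n_degenerate))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wave_series <- function(x, ...) x$amplitude

#' @exportS3Method generics::glance
glance.wave_series <- function(x, ...) {
  tibble(n_frames = nrow(x$amplitude), n_extrema = nrow(x$extrema),
         n_maxima = sum(x$extrema$type == "max"),
         n_degenerate = x$n_degenerate,
         amplitude_max = max(x$amplitude$amplitude))
}

#' @rdname autoplot-vesimech
#' @exportS3Method ggplot2::autoplot
autoplot.wave_series <- function(object, ...) {
  ggplot2::ggplot(object$amplitude,
                  ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$extrema,
                        ggplot2::aes(colour = .data$type), size = 2) +
    ggplot2::labs(x = "time (ps)", y = "amplitude (nm)", colour = "extremum") +
    ggplot2::theme_minimal()
}

#' Recover damped-oscillation parameters from an amplitude series
#'
#' Nonlinear fit of \eqn{A(t) = A_0 e^{-t/\tau} |\cos(\omega t)|} to the
#' recovered amplitude series, initialised from the extrema spacing
#' (maxima of the model sit at \eqn{t = k\pi/\omega}).
#'
#' @param series A `wave_series` from [amplitude_evolution()].
#' @return A one-row tibble: `amplitude0` (nm), `damping_tau` (ps),
#'   `omega` (rad/ps), `fit_rms`.
#' @export
recover_wave_envelope <- function(series) {
  stopifnot(inherits(series, "wave_series"))
  amp <- series$amplitude
  mx <- filter(series$extrema, .data$type == "max")
  omega0 <- if (nrow(mx) >= 2) pi / median(diff(mx$time))
  else pi / (max(amp$time) / 4)
  A00 <- max(amp$amplitude)
  tau0 <- if (nrow(mx) >= 2 && mx$amplitude[1] > 0 &&
              mx$amplitude[nrow(mx)] > 0 &&
              mx$amplitude[nrow(mx)] < mx$amplitude[1]) {
    (mx$time[nrow(mx)] - mx$time[1]) /
      log(mx$amplitude[1] / mx$amplitude[nrow(mx)])
  } else max(amp$time)
  dat <- data.frame(t = amp$time, A = amp$amplitude)
  fit <- minpack.lm::nlsLM(
    A ~ A0 * exp(-t / tau) * abs(cos(omega * t)),
    data = dat,
    start = list(A0 = A00, tau = max(tau0, 1e-3), omega = omega0),
    lower = c(A0 = 0, tau = 1e-3, omega = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  tibble(amplitude0 = cf[["A0"]], damping_tau = cf[["tau"]],
         omega = cf[["omega"]], fit_rms = sqrt(mean(resid(fit)^2)))
}

#' Compare the wave response of two systems
#'
#' Pairs the first `k` amplitude maxima of two wave series (e.g. a control
#' membrane and one with incorporated peptides) and reports their times,
#' the lag between matched maxima, and the extrema rate per unit time.
#'
#' @param series_a,series_b `wave_series` objects.
#' @param k Number of leading maxima to pair (default 3).
#' @return A list of class `wave_comparison`: `maxima` (tibble with paired
#'   times and lags), `rate_a`, `rate_b` (extrema per ps), `rate_ratio`,
#'   `degenerate` (TRUE when either series has no extrema, with `reason`).
#' @export
compare_wave_response <- function(series_a, series_b, k = 3) {
  stopifnot(inherits(series_a, "wave_series"), inherits(series_b, "wave_series"))
  ma <- filter(series_a$extrema, .data$type == "max")
  mb <- filter(series_b$extrema, .data$type == "max")
  if (nrow(ma) == 0 || nrow(mb) == 0) {
    return(structure(list(
      maxima = tibble(), rate_a = NA_real_, rate_b = NA_real_,
      rate_ratio = NA_real_, degenerate = TRUE,
      reason = "at least one series has no detected maxima"
    ), class = "wave_comparison"))
  }
  kk <- min(k, nrow(ma), nrow(mb))
  span_a <- diff(range(series_a$amplitude$time))
  span_b <- diff(range(series_b$amplitude$time))
  rate_a <- nrow(series_a$extrema) / span_a
  rate_b <- nrow(series_b$extrema) / span_b
  structure(list(
    maxima = tibble(rank = seq_len(kk),
                    time_a = ma$time[seq_len(kk)],
                    time_b = mb$time[seq_len(kk)],
                    lag = mb$time[seq_len(kk)] - ma$time[seq_len(kk)]),
    rate_a = rate_a, rate_b = rate_b, rate_ratio = rate_b / rate_a,
    degenerate = FALSE, reason = NA_character_
  ), class = "wave_comparison")
}

#' @export
print.wave_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("<wave_comparison> degenerate:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<wave_comparison> extrema rate ratio b/a = %.3f\n", x$rate_ratio))
  print(x$maxima)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wave_comparison <- function(x, ...) x$maxima
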