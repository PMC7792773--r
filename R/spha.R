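## Spherical harmonics analysis (SPHA) of vesicle undulations and the
## Helfrich sphere-model fit for the bending rigidity. The pipeline is:
## lipid vectors -> per-leaflet radius-subtracted fluctuation grids ->
## leaflet-averaged grid -> real spherical-harmonic power spectrum ->
## weighted fit of the Milner-Safran/Helfrich mode variance.

#' Per-lipid head-to-tail vectors
#'
#' Pairs each head (phosphorus) particle with the midpoint of its two
#' tail-carbon particles via the `lipid` grouping column, one vector per
#' lipid. Lipids missing either endpoint are dropped; the count of dropped
#' lipids is reported in attribute `n_dropped`.
#'
#' @param frame A single-frame trajectory table with a `lipid` column.
#' @return A tibble with one row per lipid: `lipid`, `leaflet`, head and
#'   tail-midpoint coordinates, the unit head-to-tail direction, and the
#'   vector length `length` (nm).
#' @export
lipid_vectors <- function(frame) {
  frame <- as_trajectory(frame)
  if (length(unique(frame$frame)) != 1) {
    abort("`lipid_vectors()` operates on a single frame")
  }
  if (!"lipid" %in% names(frame)) {
    abort("trajectory needs a `lipid` column to pair heads with tail carbons")
  }
  heads <- filter(frame, .data$role == "head", !is.na(.data$lipid))
  tails <- filter(frame, .data$role == "tail_carbon", !is.na(.data$lipid))
  tail_mid <- summarise(group_by(tails, .data$lipid),
                        tx = mean(.data$x), ty = mean(.data$y),
                        tz = mean(.data$z), n_tc = n(), .groups = "drop")
  joined <- dplyr::inner_join(
    select(heads, "lipid", "leaflet", hx = "x", hy = "y", hz = "z"),
    tail_mid, by = "lipid")
  n_dropped <- length(union(heads$lipid, tail_mid$lipid)) - nrow(joined)
  if (nrow(joined) == 0) abort("no pairable lipids (no head + tail-carbon pairs)")
  vx <- joined$tx - joined$hx
  vy <- joined$ty - joined$hy
  vz <- joined$tz - joined$hz
  len <- sqrt(vx^2 + vy^2 + vz^2)
  out <- tibble(
    lipid = joined$lipid, leaflet = joined$leaflet,
    head_x = joined$hx, head_y = joined$hy, head_z = joined$hz,
    tail_x = joined$tx, tail_y = joined$ty, tail_z = joined$tz,
    ux = vx / len, uy = vy / len, uz = vz / len, length = len
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

## Per-leaflet radius-subtracted relative displacement grid for one frame
## of head coordinates. Returns grids plus the two sphere fits.
.undulation_grids_xyz <- function(x, y, z, leaflet, n_theta, n_phi,
                                  fill_strategy = "idw") {
  out <- list()
  for (lf in c("inner", "outer")) {
    sel <- leaflet == lf
    if (sum(sel) < 4) abort(paste0("fewer than 4 head particles in ", lf, " leaflet"))
    fit <- .fit_sphere_xyz(x[sel], y[sel], z[sel])
    sph <- to_spherical(tibble(x = x[sel], y = y[sel], z = z[sel]), fit$center)
    g <- grid_surface(tibble(theta = sph$theta, phi = sph$phi,
                             value = (sph$r - fit$radius) / fit$radius),
                      n_theta, n_phi, fill_strategy)
    out[[lf]] <- list(grid = g, fit = fit)
  }
  out
}

#' Leaflet fluctuation grids and their average for one frame
#'
#' Fits a sphere per leaflet to the head positions, converts to spherical
#' coordinates about the fitted centre, subtracts the fitted radius to get
#' the relative radial displacement \eqn{u = (r - R)/R}, grids each leaflet
#' ([grid_surface()]), and returns the element-wise mean of the two leaflet
#' grids (the bending field; the peristaltic component cancels).
#'
#' @param frame A single-frame trajectory table with inner/outer head
#'   particles, or the output of [lipid_vectors()] (head positions are
#'   used either way).
#' @param n_theta,n_phi Grid resolution (default 64 x 128).
#' @param fill_strategy Passed to [grid_surface()].
#' @return An object of class `undulation_field`: list with `average`,
#'   `inner`, `outer` (surface grids) and `fits` (the two sphere fits).
#' @export
undulation_field <- function(frame, n_theta = 64, n_phi = 128,
                             fill_strategy = c("idw", "mean", "zero")) {
  fill_strategy <- match.arg(fill_strategy)
  if (all(c("head_x", "leaflet") %in% names(frame))) {
    x <- frame$head_x; y <- frame$head_y; z <- frame$head_z
    leaflet <- frame$leaflet
  } else {
    frame <- as_trajectory(frame)
    heads <- filter(frame, .data$role == "head")
    x <- heads$x; y <- heads$y; z <- heads$z
    leaflet <- heads$leaflet
  }
  gl <- .undulation_grids_xyz(x, y, z, leaflet, n_theta, n_phi, fill_strategy)
  avg <- gl$inner$grid
  avg$values <- (gl$inner$grid$values + gl$outer$grid$values) / 2
  avg$occupancy <- gl$inner$grid$occupancy + gl$outer$grid$occupancy
  structure(list(average = avg, inner = gl$inner$grid, outer = gl$outer$grid,
                 fits = list(inner = structure(gl$inner$fit, class = "sphere_fit"),
                             outer = structure(gl$outer$fit, class = "sphere_fit"))),
            class = "undulation_field")
}

#' @export
print.undulation_field <- function(x, ...) {
  cat(sprintf(
    "<undulation_field> R_inner %.3f nm, R_outer %.3f nm, grid %d x %d, field RMS %.4g\n",
    x$fits$inner$radius, x$fits$outer$radius,
    x$average$n_theta, x$average$n_phi, sqrt(mean(x$average$values^2))))
  invisible(x)
}

#' Spherical-harmonic power spectrum of fluctuation grids
#'
#' Projects each frame's (leaflet-averaged) grid field onto the real
#' spherical-harmonic basis by solid-angle quadrature over the cells,
#' \eqn{a_{lm} = \sum_c u_c\, Y_{lm}(\theta_c, \phi_c)\, \Delta\Omega_c},
#' and averages \eqn{a_{lm}^2} over m and frames at each degree l.
#'
#' @param grids A list of `surface_grid` or `undulation_field` objects
#'   (one per frame), all with the same resolution, or a single one.
#' @param l_max Largest degree (must satisfy
#'   `l_max <= min(n_theta, n_phi / 2) - 1`).
#' @return An `undulation_spectrum` tibble with columns `l`, `power`
#'   (mean \eqn{a_{lm}^2} over m and frames), `power_se`, `n_samples`
#'   (= (2l+1) x n_frames), and attributes `n_frames`, `R_mean` (nm, when
#'   the inputs carry sphere fits), `coefficients` (modes x frames matrix).
#' @export
spherical_harmonic_power <- function(grids, l_max = 12) {
  if (inherits(grids, c("surface_grid", "undulation_field"))) grids <- list(grids)
  R_vals <- numeric(0)
  gs <- lapply(grids, function(g) {
    if (inherits(g, "undulation_field")) {
      R_vals <<- c(R_vals, (g$fits$inner$radius + g$fits$outer$radius) / 2)
      g$average
    } else g
  })
  g1 <- gs[[1]]
  if (l_max > min(g1$n_theta, g1$n_phi / 2) - 1) {
    abort("l_max too large for this grid resolution")
  }
  same <- vapply(gs, function(g) g$n_theta == g1$n_theta && g$n_phi == g1$n_phi,
                 logical(1))
  if (!all(same)) abort("all grids must share the same resolution")
  U <- vapply(gs, function(g) as.vector(g$values),
              numeric(g1$n_theta * g1$n_phi))
  U <- matrix(U, ncol = length(gs))
  th <- rep(g1$theta, times = g1$n_phi)
  ph <- rep(g1$phi, each = g1$n_theta)
  modes <- sph_mode_table(l_max)
  B <- real_sph_basis(th, ph, modes)
  A <- crossprod(B, U) * g1$cell_solid_angle       # modes x frames
  .spectrum_from_coefficients(A, modes, R_mean = if (length(R_vals)) mean(R_vals) else NA_real_)
}

## Assemble an undulation_spectrum from a modes x frames coefficient matrix.
.spectrum_from_coefficients <- function(A, modes, R_mean = NA_real_) {
  a2 <- A^2
  by_l <- rowsum(a2, modes$l)                      # per-l sums over m, per frame
  counts <- as.vector(table(modes$l))
  l_vals <- as.integer(rownames(by_l))
  n_samples <- counts * ncol(A)
  power <- unname(rowSums(by_l)) / n_samples
  ## SE of the mean square over the (2l+1) * n_frames samples
  power_se <- vapply(seq_along(l_vals), function(i) {
    v <- as.vector(a2[modes$l == l_vals[i], , drop = FALSE])
    sd(v) / sqrt(length(v))
  }, numeric(1))
  out <- tibble(l = l_vals, power = power, power_se = power_se,
                n_samples = as.integer(n_samples))
  class(out) <- c("undulation_spectrum", class(out))
  attr(out, "n_frames") <- ncol(A)
  attr(out, "R_mean") <- R_mean
  attr(out, "coefficients") <- A
  attr(out, "modes") <- modes
  out
}

#' Fit the Helfrich sphere model to an undulation spectrum
#'
#' Weighted least-squares fit of the per-degree mean-square amplitudes to
#' \deqn{\langle a_{lm}^2\rangle(l) = \frac{k_B T}
#'   {\kappa (l-1)(l+2)[l(l+1)+\bar\sigma]}}
#' over `l_range`. Weights are the inverse squared per-l sampling standard
#' errors. The fit is initialised by exact linear inversion (the reciprocal
#' spectrum is linear in \eqn{\kappa} and \eqn{\kappa\bar\sigma}) and
#' refined with Levenberg-Marquardt.
#'
#' @param spectrum An `undulation_spectrum` (or any data frame with columns
#'   `l`, `power` and optionally `power_se`).
#' @param temperature Temperature, K.
#' @param l_range Degrees used in the fit (default 2:12; at least 3).
#' @param fix_sigma Optional fixed reduced tension (e.g. 0); default both
#'   \eqn{\kappa} and \eqn{\bar\sigma} are free.
#' @return An object of class `helfrich_fit`: list with `kappa` (J),
#'   `kappa_sd`, `sigma_bar`, `sigma_bar_sd`, `sigma` (N/m, when the
#'   spectrum carries a mean radius), `covariance`, `l_range`,
#'   `temperature`, `fitted` (tibble l/power/fit), `rss_weighted`.
#' @export
fit_helfrich_sphere <- function(spectrum, temperature = 296.15,
                                l_range = 2:12, fix_sigma = NULL) {
  df <- as_tibble(spectrum)[, intersect(c("l", "power", "power_se"), names(spectrum))]
  df <- filter(df, .data$l %in% l_range, is.finite(.data$power), .data$power > 0)
  if (nrow(df) < 3) abort("need at least 3 degrees with positive power in l_range")
  kT <- .kB * temperature
  ## the fit runs on log(power): multiplicative (chi-square) sampling errors
  ## become additive and the Jacobian is well conditioned across the decades
  ## the spectrum spans; delta-method weights var(log P) = (se/P)^2
  w <- if ("power_se" %in% names(df) && all(is.finite(df$power_se)) &&
           all(df$power_se > 0)) (df$power / df$power_se)^2
  else rep(1, nrow(df))
  w <- as.numeric(w) / mean(as.numeric(w))
  l <- df$l
  ## linear initialisation: 1/P = kt * (l-1)(l+2) l(l+1) + kt*sb * (l-1)(l+2)
  x1 <- (l - 1) * (l + 2) * l * (l + 1)
  x2 <- (l - 1) * (l + 2)
  cf0 <- tryCatch(qr.coef(qr(cbind(x1, x2)), 1 / df$power),
                  error = function(e) c(NA, NA))
  kt0 <- max(cf0[1], 1e-3, na.rm = TRUE)          # kappa / kBT
  sb0 <- if (is.na(cf0[2]) || kt0 <= 0) 0 else cf0[2] / kt0
  sb0 <- min(max(sb0, -5.5), 1e4)
  ## a tiny nonzero start defeats numericDeriv's relative step size
  if (abs(sb0) < 1e-6) sb0 <- 0
  dat <- data.frame(l = l, lp = log(df$power), w = w)
  sb_fixed <- fix_sigma
  fml <- if (is.null(fix_sigma)) {
    lp ~ -log(kt * (l - 1) * (l + 2) * (l * (l + 1) + sb))
  } else {
    lp ~ -log(kt * (l - 1) * (l + 2) * (l * (l + 1) + sb_fixed))
  }
  starts <- if (is.null(fix_sigma)) list(kt = kt0, sb = sb0) else list(kt = kt0)
  lowers <- if (is.null(fix_sigma)) c(kt = 1e-8, sb = -5.999) else c(kt = 1e-8)
  run_lm <- function() minpack.lm::nlsLM(
    fml, data = dat, start = starts, weights = w, lower = lowers,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14))
  ## nlsLM can report a spurious singular gradient for some (n, scale)
  ## combinations even at the optimum; the port algorithm is the fallback
  run_port <- function() suppressWarnings(stats::nls(
    fml, data = dat, start = starts, weights = w, lower = lowers,
    algorithm = "port",
    control = stats::nls.control(maxiter = 500, warnOnly = TRUE)))
  fit <- tryCatch(run_lm(), error = function(e) e)
  if (inherits(fit, "error")) fit <- tryCatch(run_port(), error = function(e) e)
  if (inherits(fit, "error")) {
    abort(paste0("Helfrich fit did not converge: ", conditionMessage(fit),
                 " (linear-inversion iterate: kappa/kBT = ", signif(kt0, 6),
                 ", sigma_bar = ", signif(sb0, 6), ")"))
  }
  cf <- coef(fit)
  kt <- cf[["kt"]]
  sb <- if (is.null(fix_sigma)) cf[["sb"]] else fix_sigma
  V <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, length(cf), length(cf)))
  kappa <- kt * kT
  kappa_sd <- if (is.finite(V[1, 1])) sqrt(V[1, 1]) * kT else NA_real_
  sb_sd <- if (is.null(fix_sigma) && nrow(V) > 1 && is.finite(V[2, 2]))
    sqrt(V[2, 2]) else NA_real_
  R_mean <- attr(spectrum, "R_mean", exact = TRUE) %||% NA_real_
  sigma <- if (is.finite(R_mean)) sb * kappa / (R_mean * 1e-9)^2 else NA_real_
  fitted_tbl <- tibble(l = l, power = df$power,
                       fit = 1 / (kt * (l - 1) * (l + 2) * (l * (l + 1) + sb)))
  structure(list(
    kappa = kappa, kappa_sd = kappa_sd,
    sigma_bar = sb, sigma_bar_sd = sb_sd, sigma = sigma,
    covariance = V, l_range = sort(unique(l)), temperature = temperature,
    fitted = fitted_tbl,
    rss_weighted = sum(w * (fitted_tbl$power - fitted_tbl$fit)^2),
    df_residual = nrow(df) - length(cf)
  ), class = "helfrich_fit")
}

#' @export
print.helfrich_fit <- function(x, ...) {
  cat(sprintf(
    "<helfrich_fit> kappa = %.3e J (%.1f kBT at %.2f K), sigma_bar = %.3g\n  l = %d..%d, weighted RSS %.3g on %d df\n",
    x$kappa, x$kappa / (.kB * x$temperature), x$temperature, x$sigma_bar,
    min(x$l_range), max(x$l_range), x$rss_weighted, x$df_residual))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.helfrich_fit <- function(x, ...) {
  tibble(term = c("kappa", "sigma_bar"),
         estimate = c(x$kappa, x$sigma_bar),
         std.error = c(x$kappa_sd, x$sigma_bar_sd))
}

#' @exportS3Method generics::glance
glance.helfrich_fit <- function(x, ...) {
  tibble(kappa = x$kappa, kappa_sd = x$kappa_sd, sigma_bar = x$sigma_bar,
         sigma = x$sigma, temperature = x$temperature,
         l_min = min(x$l_range), l_max = max(x$l_range),
         rss_weighted = x$rss_weighted, df_residual = x$df_residual)
}

#' SPHA spectrum of a whole trajectory
#'
#' Runs the per-frame leaflet-averaged undulation-field construction
#' ([undulation_field()]) over all frames of a vesicle trajectory and
#' computes the spherical-harmonic power spectrum
#' ([spherical_harmonic_power()]) in one pass. This is the efficient
#' entry point for ensembles of thousands of frames.
#'
#' @param traj Trajectory table with inner/outer head particles.
#' @param n_theta,n_phi Grid resolution.
#' @param l_max Largest degree in the spectrum.
#' @param fill_strategy Passed to [grid_surface()].
#' @return An `undulation_spectrum` (see [spherical_harmonic_power()]).
#' @export
spha_spectrum <- function(traj, n_theta = 64, n_phi = 128, l_max = 12,
                          fill_strategy = c("idw", "mean", "zero")) {
  fill_strategy <- match.arg(fill_strategy)
  traj <- as_trajectory(traj)
  if (l_max > min(n_theta, n_phi / 2) - 1) {
    abort("l_max too large for this grid resolution")
  }
  is_head <- traj$role == "head"
  heads <- if (all(is_head)) traj else traj[is_head, ]
  rm(is_head)
  if (any(heads$leaflet == "none")) {
    abort("head particles with leaflet = 'none' are invalid for vesicle analyses")
  }
  idx <- .frame_index(heads)
  ncell <- n_theta * n_phi
  U <- matrix(0, ncell, length(idx))
  R_sum <- 0
  for (i in seq_along(idx)) {
    fr <- heads[idx[[i]], ]
    gl <- .undulation_grids_xyz(fr$x, fr$y, fr$z, fr$leaflet,
                                n_theta, n_phi, fill_strategy)
    U[, i] <- (as.vector(gl$inner$grid$values) + as.vector(gl$outer$grid$values)) / 2
    R_sum <- R_sum + (gl$inner$fit$radius + gl$outer$fit$radius) / 2
  }
  ctr <- .grid_centers(n_theta, n_phi)
  modes <- sph_mode_table(l_max)
  B <- real_sph_basis(rep(ctr$theta, times = n_phi),
                      rep(ctr$phi, each = n_theta), modes)
  A <- crossprod(B, U) * (4 * pi / ncell)
  .spectrum_from_coefficients(A, modes, R_mean = R_sum / length(idx))
}

#' Full SPHA rigidity pipeline
#'
#' Convenience wrapper: [spha_spectrum()] followed by
#' [fit_helfrich_sphere()].
#'
#' @inheritParams spha_spectrum
#' @inheritParams fit_helfrich_sphere
#' @return A `helfrich_fit` with the spectrum attached as attribute
#'   `spectrum`.
#' @export
spha_kappa <- function(traj, temperature = 296.15, n_theta = 64,
                       n_phi = 128, l_max = 12, l_range = 2:12,
                       fill_strategy = "idw", fix_sigma = NULL) {
  spec <- spha_spectrum(traj, n_theta, n_phi, l_max, fill_strategy)
  fit <- fit_helfrich_sphere(spec, temperature, l_range, fix_sigma)
  attr(fit, "spectrum") <- spec
  fit
}

#' @rdname autoplot-vesimech
#' @exportS3Method ggplot2::autoplot
autoplot.undulation_spectrum <- function(object, fit = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$l, y = .data$power)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$power - .data$power_se,
                                        ymax = .data$power + .data$power_se),
                           width = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree l", y = expression(paste("<", a[lm]^2, ">"))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(data = fit$fitted,
                                ggplot2::aes(y = .data$fit), colour = "red")
  }
  p
}
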