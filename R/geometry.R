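## Sphere fitting, spherical coordinates, and gridded surface representation.
## These primitives are shared by every coordinate-based analysis: leaflet
## radii for thickness/APL, and the radius-subtracted undulation field that
## feeds the spherical-harmonics rigidity estimator.

## Internal workhorse on bare coordinate vectors. Algebraic (Coope)
## linearised least squares followed by one geometric Gauss-Newton step, so
## the result is deterministic and needs no initial guess.
.fit_sphere_xyz <- function(x, y, z) {
  n <- length(x)
  if (n < 4) abort("sphere fit needs at least 4 points")
  ## degeneracy: points must span 3 dimensions
  M <- cbind(x - mean(x), y - mean(y), z - mean(z))
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[3] < 1e-10 * (sv[1] + 1e-300)) {
    abort("degenerate point configuration (coplanar or collinear); cannot fit a sphere")
  }
  ## algebraic stage: |p|^2 = 2 c.p + (R^2 - |c|^2), linear in (c, rho)
  A <- cbind(2 * x, 2 * y, 2 * z, 1)
  b <- x^2 + y^2 + z^2
  beta <- qr.coef(qr(A), b)
  ctr <- beta[1:3]
  R <- sqrt(max(beta[4] + sum(ctr^2), 0))
  ## one Gauss-Newton refinement on geometric residuals r_i - R
  dx <- x - ctr[1]; dy <- y - ctr[2]; dz <- z - ctr[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  r[r == 0] <- .Machine$double.eps
  J <- cbind(-dx / r, -dy / r, -dz / r, -1)
  step <- tryCatch(qr.coef(qr(J), -(r - R)), error = function(e) rep(0, 4))
  if (all(is.finite(step))) {
    ctr <- ctr + step[1:3]
    R <- R + step[4]
  }
  dx <- x - ctr[1]; dy <- y - ctr[2]; dz <- z - ctr[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  list(center = c(x = unname(ctr[1]), y = unname(ctr[2]), z = unname(ctr[3])),
       radius = R,
       rms_residual = sqrt(mean((r - R)^2)),
       n_points = n)
}

#' Least-squares sphere fit to a point cloud
#'
#' Fits a sphere to 3D points by linearised (algebraic) least squares
#' followed by one geometric Gauss-Newton refinement. Used per frame and per
#' leaflet on phosphorus (head) positions to obtain leaflet radii and the
#' vesicle centre.
#'
#' @param points A data frame with columns `x`, `y`, `z`, or a numeric
#'   matrix with 3 columns (nm).
#' @return An object of class `sphere_fit`: a list with `center` (named
#'   xyz vector, nm), `radius` (nm), `rms_residual` (RMS radial distance of
#'   the points from the fitted sphere, nm) and `n_points`.
#' @export
#' @examples
#' sph <- fibonacci_sphere(500)
#' fit_sphere(data.frame(x = 20 * sph[, 1], y = 20 * sph[, 2], z = 20 * sph[, 3]))
fit_sphere <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    points <- tibble(x = points[, 1], y = points[, 2], z = points[, 3])
  }
  if (!all(c("x", "y", "z") %in% names(points))) {
    abort("`points` must have columns x, y, z")
  }
  if (!all(is.finite(points$x) & is.finite(points$y) & is.finite(points$z))) {
    abort("coordinates must be finite")
  }
  out <- .fit_sphere_xyz(points$x, points$y, points$z)
  structure(out, class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "<sphere_fit> radius %.4f nm, rms residual %.4g nm, n = %d\n  center (%.3f, %.3f, %.3f) nm\n",
    x$radius, x$rms_residual, x$n_points, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sphere_fit <- function(x, ...) {
  tibble(radius = x$radius,
         center_x = unname(x$center[1]), center_y = unname(x$center[2]),
         center_z = unname(x$center[3]),
         rms_residual = x$rms_residual, n_points = x$n_points)
}

#' Cartesian to spherical coordinates
#'
#' Converts points to spherical coordinates about a centre: radius `r`,
#' colatitude `theta` in \eqn{[0, \pi]} (0 at +z), azimuth `phi` in
#' \eqn{[0, 2\pi)}. A point coincident with the centre maps to
#' `r = 0, theta = 0, phi = 0` by convention.
#'
#' @param points Data frame with columns `x`, `y`, `z` or a 3-column matrix.
#' @param center Numeric length-3 centre.
#' @return A tibble with columns `r`, `theta`, `phi`.
#' @export
#' @examples
#' to_spherical(data.frame(x = 3, y = 4, z = 0), c(0, 0, 0))
to_spherical <- function(points, center = c(0, 0, 0)) {
  if (is.matrix(points)) points <- tibble(x = points[, 1], y = points[, 2], z = points[, 3])
  stopifnot(length(center) == 3, all(is.finite(center)))
  dx <- points$x - center[1]
  dy <- points$y - center[2]
  dz <- points$z - center[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  theta <- ifelse(r > 0, acos(pmin(pmax(dz / pmax(r, .Machine$double.xmin), -1), 1)), 0)
  phi <- atan2(dy, dx)
  phi <- ifelse(phi < 0, phi + 2 * pi, phi)
  phi[r == 0] <- 0
  tibble(r = r, theta = theta, phi = phi)
}

#' Spherical to Cartesian coordinates
#'
#' Inverse of [to_spherical()].
#'
#' @param sph Data frame with columns `r`, `theta`, `phi`.
#' @param center Numeric length-3 centre to add back.
#' @return A tibble with columns `x`, `y`, `z`.
#' @export
from_spherical <- function(sph, center = c(0, 0, 0)) {
  st <- sin(sph$theta)
  tibble(x = center[1] + sph$r * st * cos(sph$phi),
         y = center[2] + sph$r * st * sin(sph$phi),
         z = center[3] + sph$r * cos(sph$theta))
}

## Cell index (1..n_theta*n_phi, theta fastest) for spherical points on an
## equal-area grid: latitude bands uniform in cos(theta), azimuth uniform.
.grid_cell_index <- function(theta, phi, n_theta, n_phi) {
  xc <- cos(theta)                      # 1 .. -1
  it <- ceiling((1 - xc) / (2 / n_theta))
  it <- pmin(pmax(it, 1L), n_theta)
  ip <- floor(phi %% (2 * pi) / (2 * pi / n_phi)) + 1L
  ip <- pmin(pmax(ip, 1L), n_phi)
  (ip - 1L) * n_theta + it
}

## Centres of grid cells (theta from the midpoint of the cos-theta band).
.grid_centers <- function(n_theta, n_phi) {
  x_mid <- 1 - (2 / n_theta) * (seq_len(n_theta) - 0.5)
  list(theta = acos(x_mid),
       phi = (2 * pi / n_phi) * (seq_len(n_phi) - 0.5))
}

## Ring offsets at Chebyshev radius `ring` on the (theta, phi) lattice.
.ring_offsets <- function(ring) {
  o <- expand.grid(di = -ring:ring, dj = -ring:ring)
  o[pmax(abs(o$di), abs(o$dj)) == ring, , drop = FALSE]
}

## Inverse-great-circle-distance fill of empty cells from occupied cells
## found by an expanding ring search; isolated holes fall back to the
## occupancy-weighted frame mean. Operates on vectors indexed by cell.
.fill_idw <- function(values, occ, n_theta, n_phi, max_ring = 3L) {
  ncell <- n_theta * n_phi
  ctr <- .grid_centers(n_theta, n_phi)
  cell_it <- rep(seq_len(n_theta), times = n_phi)
  cell_ip <- rep(seq_len(n_phi), each = n_theta)
  st <- sin(ctr$theta); ct <- cos(ctr$theta)
  occupied <- occ > 0
  todo <- which(!occupied)
  filled <- values
  fallback <- 0L
  if (length(todo) == 0) return(list(values = filled, n_fallback = 0L))
  frame_mean <- if (any(occupied)) {
    sum(values[occupied] * occ[occupied]) / sum(occ[occupied])
  } else 0
  for (ring in seq_len(max_ring)) {
    if (length(todo) == 0) break
    offs <- .ring_offsets(ring)
    wsum <- numeric(length(todo))
    vsum <- numeric(length(todo))
    it0 <- cell_it[todo]; ip0 <- cell_ip[todo]
    for (k in seq_len(nrow(offs))) {
      it1 <- it0 + offs$di[k]
      inside <- it1 >= 1L & it1 <= n_theta
      if (!any(inside)) next
      ip1 <- ((ip0 + offs$dj[k] - 1L) %% n_phi) + 1L
      nb <- (ip1 - 1L) * n_theta + it1
      ok <- inside & occupied[pmin(pmax(nb, 1L), ncell)]
      if (!any(ok)) next
      i_ok <- which(ok)
      nb_ok <- nb[i_ok]
      a <- todo[i_ok]
      cosd <- st[cell_it[a]] * st[cell_it[nb_ok]] *
        cos(ctr$phi[cell_ip[a]] - ctr$phi[cell_ip[nb_ok]]) +
        ct[cell_it[a]] * ct[cell_it[nb_ok]]
      d <- acos(pmin(pmax(cosd, -1), 1))
      w <- 1 / pmax(d, 1e-9)
      wsum[i_ok] <- wsum[i_ok] + w
      vsum[i_ok] <- vsum[i_ok] + w * values[nb_ok]
    }
    done <- wsum > 0
    if (any(done)) {
      filled[todo[done]] <- vsum[done] / wsum[done]
      todo <- todo[!done]
    }
  }
  if (length(todo) > 0) {
    filled[todo] <- frame_mean
    fallback <- length(todo)
  }
  list(values = filled, n_fallback = fallback)
}

#' Grid a radial displacement field on the sphere
#'
#' Bins per-particle relative radial displacements \eqn{u = (r - R)/R} onto
#' an equal-area \eqn{(\theta, \phi)} grid (latitude bands uniform in
#' \eqn{\cos\theta}, so every cell subtends the same solid angle). The cell
#' value is the mean displacement of the particles falling in the cell;
#' empty cells are filled according to `fill_strategy`.
#'
#' @param sph Data frame with columns `theta`, `phi` and `value` (the
#'   relative radial displacement of each particle).
#' @param n_theta,n_phi Grid resolution (default 64 x 128).
#' @param fill_strategy `"idw"` (inverse-great-circle-distance interpolation
#'   from the nearest occupied cells, the default), `"mean"` (fill with the
#'   occupancy-weighted frame mean) or `"zero"`.
#' @return An object of class `surface_grid`: list with matrices `values`
#'   and `occupancy` (`n_theta` x `n_phi`), vectors `theta` and `phi` of
#'   cell centres, the uniform solid angle per cell `cell_solid_angle`,
#'   `frac_empty` (fraction of cells empty before filling),
#'   `n_fallback_filled`, and `sparse_warning` (TRUE when more than half the
#'   cells were empty).
#' @export
grid_surface <- function(sph, n_theta = 64, n_phi = 128,
                         fill_strategy = c("idw", "mean", "zero")) {
  fill_strategy <- match.arg(fill_strategy)
  stopifnot(n_theta >= 2, n_phi >= 4)
  ncell <- n_theta * n_phi
  idx <- .grid_cell_index(sph$theta, sph$phi, n_theta, n_phi)
  occ <- tabulate(idx, nbins = ncell)
  sums <- numeric(ncell)
  agg <- rowsum(sph$value, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  vals <- ifelse(occ > 0, sums / pmax(occ, 1L), 0)
  frac_empty <- mean(occ == 0)
  n_fallback <- 0L
  if (any(occ == 0)) {
    if (fill_strategy == "idw") {
      fl <- .fill_idw(vals, occ, n_theta, n_phi)
      vals <- fl$values
      n_fallback <- fl$n_fallback
    } else if (fill_strategy == "mean") {
      fm <- if (any(occ > 0)) sum(vals[occ > 0] * occ[occ > 0]) / sum(occ) else 0
      vals[occ == 0] <- fm
    } # "zero": leave zeros
  }
  ctr <- .grid_centers(n_theta, n_phi)
  structure(list(
    values = matrix(vals, n_theta, n_phi),
    occupancy = matrix(occ, n_theta, n_phi),
    theta = ctr$theta, phi = ctr$phi,
    cell_solid_angle = 4 * pi / ncell,
    n_theta = n_theta, n_phi = n_phi,
    frac_empty = frac_empty,
    n_fallback_filled = n_fallback,
    sparse_warning = frac_empty > 0.5
  ), class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf(
    "<surface_grid> %d x %d (theta x phi), %.1f%% cells empty before fill%s\n",
    x$n_theta, x$n_phi, 100 * x$frac_empty,
    if (x$sparse_warning) " [sparse: >50% empty]" else ""))
  invisible(x)
}

#' Quasi-uniform directions on the unit sphere
#'
#' Fibonacci (golden-angle) lattice of `n` unit vectors, used by the vesicle
#' generator to place lipids quasi-uniformly on leaflet surfaces.
#'
#' @param n Number of directions.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- (pi * (3 - sqrt(5))) * (k - 1)
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}
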