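## Shared fixtures, all built in code.

## Two concentric noisy head shells (inner/outer), n heads per leaflet.
make_shell_traj <- function(r_inner, r_outer, n_per_leaflet = 500,
                            n_frames = 1, noise = 0, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_frames) - 1L, function(f) {
    d_in <- fibonacci_sphere(n_per_leaflet)
    d_out <- fibonacci_sphere(n_per_leaflet)
    xyz <- rbind(d_in * r_inner, d_out * r_outer)
    if (noise > 0) xyz <- xyz + matrix(rnorm(length(xyz), sd = noise),
                                       ncol = 3)
    tibble::tibble(
      frame = f,
      particle = seq_len(2L * n_per_leaflet),
      role = "head",
      leaflet = rep(c("inner", "outer"), each = n_per_leaflet),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  })
}

## Independent geometric sphere-fit oracle: direct nonlinear least squares
## on the radial residuals via optim (BFGS), deliberately sharing no code
## with fit_sphere().
oracle_sphere_fit <- function(x, y, z) {
  obj <- function(p) {
    r <- sqrt((x - p[1])^2 + (y - p[2])^2 + (z - p[3])^2)
    sum((r - p[4])^2)
  }
  p0 <- c(mean(x), mean(y), mean(z), 1)
  p0[4] <- mean(sqrt((x - p0[1])^2 + (y - p0[2])^2 + (z - p0[3])^2))
  fit <- optim(p0, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  list(center = fit$par[1:3], radius = fit$par[4])
}

## Surface grid holding an arbitrary field sampled densely and exactly at
## quasi-uniform directions (every cell occupied for n_points >> cells).
make_field_grid <- function(field_fun, n_theta = 64, n_phi = 128,
                            n_points = 2e5) {
  dirs <- fibonacci_sphere(n_points)
  sph <- to_spherical(dirs)
  grid_surface(
    tibble::tibble(theta = sph$theta, phi = sph$phi,
                   value = field_fun(sph$theta, sph$phi)),
    n_theta, n_phi)
}

## Real orthonormal Y_20 evaluated directly (independent closed form).
y20 <- function(theta, phi) {
  sqrt(5 / (16 * pi)) * (3 * cos(theta)^2 - 1)
}
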