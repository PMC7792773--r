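test_that("lipid vectors pair heads with tail-carbon midpoints", {
  fr <- tibble::tibble(
    frame = 0L, particle = 1:3, lipid = 1L,
    role = c("head", "tail_carbon", "tail_carbon"),
    leaflet = "outer",
    x = 0, y = 0, z = c(21, 19.2, 18.8))
  lv <- lipid_vectors(fr)
  expect_equal(nrow(lv), 1)
  expect_equal(lv$tail_z, 19.0)
  expect_equal(lv$uz, -1)
  expect_equal(lv$length, 2.0)
  expect_equal(attr(lv, "n_dropped"), 0)
})

test_that("generator lipids produce one vector each, none dropped", {
  traj <- gen_vesicle_ensemble(vesicle_config(n_frames = 1, seed = 3,
                                              detail = "lipids"))
  cfg <- attr(traj, "config")
  lv <- lipid_vectors(dplyr::filter(traj, frame == 0))
  expect_equal(nrow(lv), cfg$n_lipids_inner + cfg$n_lipids_outer)
  expect_equal(attr(lv, "n_dropped"), 0)
  ## a head without tails is dropped and counted
  fr <- dplyr::filter(traj, frame == 0)
  fr <- fr[!(fr$role == "tail_carbon" & fr$lipid == 1), ]
  lv2 <- lipid_vectors(fr)
  expect_equal(attr(lv2, "n_dropped"), 1)
  ## no pairable lipids at all
  expect_error(lipid_vectors(dplyr::filter(fr, role == "head")),
               "pairable")
})

test_that("stiff-limit undulation field is ~zero after leaflet averaging", {
  ## thermal RMS scales as sqrt(kBT/kappa); at 1e-15 J the averaged grid
  ## field is below 1e-3 (relative units)
  traj <- gen_vesicle_ensemble(vesicle_config(
    kappa = 1e-15, positional_noise = 0, n_frames = 1,
    detail = "heads", seed = 6))
  uf <- undulation_field(dplyr::filter(traj, frame == 0))
  expect_lt(sqrt(mean(uf$average$values^2)), 1e-3)
})

test_that("leaflet averaging keeps bending and cancels peristaltic modes", {
  ## heads placed at R(1 +/- u) with u a Y20 pattern
  n <- 4000; R <- 20; t2 <- 1.7
  d <- fibonacci_sphere(n)
  sph <- to_spherical(d)
  u <- 0.03 * y20(sph$theta, sph$phi)
  build <- function(r_in, r_out) tibble::tibble(
    frame = 0L, particle = seq_len(2 * n),
    role = "head", leaflet = rep(c("inner", "outer"), each = n),
    x = c(d[, 1] * r_in, d[, 1] * r_out),
    y = c(d[, 2] * r_in, d[, 2] * r_out),
    z = c(d[, 3] * r_in, d[, 3] * r_out))
  ## symmetric (bending): same u on both leaflets
  sym <- build((R - t2) * (1 + u), (R + t2) * (1 + u))
  uf_sym <- undulation_field(sym, 32, 64)
  centers_u <- y20(rep(uf_sym$average$theta, times = 64),
                   rep(uf_sym$average$phi, each = 32)) * 0.03
  expect_equal(as.vector(uf_sym$average$values), centers_u, tolerance = 0.1)
  ## antisymmetric (peristaltic): +u outer, -u inner cancels on average
  anti <- build((R - t2) * (1 - u), (R + t2) * (1 + u))
  uf_anti <- undulation_field(anti, 32, 64)
  expect_lt(sqrt(mean(uf_anti$average$values^2)),
            0.1 * sqrt(mean(uf_sym$average$values^2)))
})

test_that("harmonic power isolates a pure mode on a fine grid", {
  ## field evaluated exactly at the cell centres of a fine grid (quadrature
  ## oracle: no sampling error, only quadrature error)
  eps <- 0.02
  n_theta <- 512; n_phi <- 1024
  x_mid <- 1 - (2 / n_theta) * (seq_len(n_theta) - 0.5)
  centers <- tibble::tibble(
    theta = rep(acos(x_mid), times = n_phi),
    phi = rep((2 * pi / n_phi) * (seq_len(n_phi) - 0.5), each = n_theta))
  g <- grid_surface(dplyr::mutate(centers,
                                  value = eps * y20(theta, phi)),
                    n_theta, n_phi)
  spec <- spherical_harmonic_power(g, l_max = 6)
  expect_equal(spec$power[spec$l == 2], eps^2 / 5, tolerance = 1e-4)
  others <- spec$power[spec$l != 2] * (2 * spec$l[spec$l != 2] + 1)
  expect_lt(max(others), 1e-6 * eps^2)
  ## zero field has zero power
  g0 <- make_field_grid(function(th, ph) 0 * th, 32, 64, 5e4)
  s0 <- spherical_harmonic_power(g0, l_max = 6)
  expect_true(all(s0$power == 0))
})

test_that("Parseval: sum of a_lm^2 equals the field's mean square", {
  set.seed(9)
  modes <- sph_mode_table(8)
  a <- rnorm(nrow(modes), sd = 0.01)
  g <- make_field_grid(function(th, ph) {
    as.vector(real_sph_basis(th, ph, modes) %*% a)
  }, 64, 128, 4e5)
  spec <- spherical_harmonic_power(g, l_max = 10)
  total_power <- sum(spec$power * (2 * spec$l + 1))
  field_ms <- mean(g$values^2) * 4 * pi
  expect_equal(total_power, field_ms, tolerance = 0.01)
})

test_that("l_max is bounded by the grid resolution", {
  g <- make_field_grid(function(th, ph) 0 * th, 16, 32, 2e4)
  expect_error(spherical_harmonic_power(g, l_max = 20), "l_max")
  expect_error(spha_spectrum(make_shell_traj(18, 21, 200),
                             n_theta = 16, n_phi = 32, l_max = 20), "l_max")
})

test_that("noise-free Helfrich inversion is exact", {
  l <- 2:12
  kap <- 7.3e-20
  spec <- tibble::tibble(l = l,
                         power = helfrich_mode_variance(l, kap, 0),
                         power_se = helfrich_mode_variance(l, kap, 0) * 1e-3)
  fit <- fit_helfrich_sphere(spec, temperature = 296.15)
  expect_equal(fit$kappa, kap, tolerance = 1e-6)
  expect_equal(fit$sigma_bar, 0, tolerance = 1e-4)
  ## with tension
  spec2 <- tibble::tibble(l = l, power = helfrich_mode_variance(l, kap, 12),
                          power_se = helfrich_mode_variance(l, kap, 12) * 1e-3)
  fit2 <- fit_helfrich_sphere(spec2)
  expect_equal(fit2$kappa, kap, tolerance = 1e-6)
  expect_equal(fit2$sigma_bar, 12, tolerance = 1e-3)
})

test_that("kappa estimate is invariant under joint T and power scaling", {
  l <- 2:12
  pw <- helfrich_mode_variance(l, 5e-20, 0, temperature = 296.15)
  f1 <- fit_helfrich_sphere(tibble::tibble(l = l, power = pw), 296.15)
  f2 <- fit_helfrich_sphere(tibble::tibble(l = l, power = 2 * pw), 2 * 296.15)
  expect_equal(f2$kappa, f1$kappa, tolerance = 1e-9)
})

test_that("softer membranes show uniformly larger ensemble power", {
  t_soft <- gen_vesicle_ensemble(vesicle_config(kappa = 3e-20, n_frames = 30,
                                                detail = "heads", seed = 14))
  t_stiff <- gen_vesicle_ensemble(vesicle_config(kappa = 12e-20, n_frames = 30,
                                                 detail = "heads", seed = 14))
  s_soft <- spha_spectrum(t_soft, l_max = 8)
  s_stiff <- spha_spectrum(t_stiff, l_max = 8)
  expect_true(all(s_soft$power > s_stiff$power))
})

test_that("moderate ensembles recover kappa through the full pipeline", {
  traj <- gen_vesicle_ensemble(vesicle_config(kappa = 4.3e-20, n_frames = 150,
                                              detail = "heads", seed = 23))
  fit <- spha_kappa(traj)
  expect_equal(fit$kappa, 4.3e-20, tolerance = 0.10)
})
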