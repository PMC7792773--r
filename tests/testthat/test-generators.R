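test_that("stiff vesicles are near-perfect spheres", {
  ## radial RMS deviation scales as sqrt(kBT/kappa): ~0.07 nm at 1e-17 J,
  ## below 0.01 nm by 1e-15 J
  rms_dev <- function(kap) {
    traj <- gen_vesicle_ensemble(vesicle_config(
      kappa = kap, positional_noise = 0, n_frames = 1,
      detail = "heads", seed = 2))
    fr <- dplyr::filter(traj, leaflet == "outer")
    r <- sqrt(fr$x^2 + fr$y^2 + fr$z^2)
    sqrt(mean((r - mean(r))^2))
  }
  d17 <- rms_dev(1e-17)
  expect_lt(d17, 0.1)
  d15 <- rms_dev(1e-15)
  expect_lt(d15, 1e-2)
  expect_lt(d15, d17 / 5)
})

test_that("leaflet counts follow the starting-APL construction rule", {
  cnt <- leaflet_counts_from_apl(20, 3.43, 68.1, c(0.95, 1.05))
  r_in <- 20 - 3.43 / 2; r_out <- 20 + 3.43 / 2
  expect_equal(cnt[["inner"]], round(4 * pi * r_in^2 * 100 / (68.1 * 0.95)))
  expect_equal(cnt[["outer"]], round(4 * pi * r_out^2 * 100 / (68.1 * 1.05)))
  ## generated geometry reproduces the configured counts and thickness
  traj <- gen_vesicle_ensemble(vesicle_config(n_frames = 1, detail = "heads",
                                              positional_noise = 0, seed = 4))
  counts <- dplyr::count(dplyr::filter(traj, role == "head"), leaflet)
  expect_equal(counts$n[counts$leaflet == "inner"], cnt[["inner"]])
  expect_equal(counts$n[counts$leaflet == "outer"], cnt[["outer"]])
})

test_that("fitted leaflet radii differ by the configured thickness", {
  traj <- gen_vesicle_ensemble(vesicle_config(n_frames = 5, detail = "heads",
                                              seed = 8))
  st <- membrane_thickness(traj)
  expect_equal(glance(st)$thickness, 3.43, tolerance = 0.01 / 3.43)
})

test_that("generated mode amplitudes carry the Helfrich variance", {
  ## recompute a_lm from the noise-free ensemble by least squares on the
  ## known head directions, then compare sample variances per degree
  cfg <- vesicle_config(kappa = 7.3e-20, n_frames = 800, l_max = 10,
                        positional_noise = 0, detail = "heads", seed = 31)
  traj <- gen_vesicle_ensemble(cfg)
  heads <- dplyr::filter(traj, frame == 0)
  sph0 <- to_spherical(heads[, c("x", "y", "z")])
  modes <- sph_mode_table(10)
  B <- real_sph_basis(sph0$theta, sph0$phi, modes)
  P <- solve(crossprod(B), t(B))
  off <- ifelse(heads$leaflet == "inner", -cfg$thickness / 2, cfg$thickness / 2)
  r_all <- sqrt(traj$x^2 + traj$y^2 + traj$z^2)
  U <- (matrix(r_all, nrow(heads)) - off) / cfg$radius - 1
  A <- P %*% U                                    # modes x frames
  v_target <- helfrich_mode_variance(modes$l, cfg$kappa, cfg$sigma_bar,
                                     cfg$temperature)
  for (l in c(2, 4, 6, 8, 10)) {
    sel <- modes$l == l
    v_hat <- mean(A[sel, ]^2)
    expect_equal(v_hat, v_target[sel][1], tolerance = 0.05)
  }
  ## chi-square band check across all degrees (alpha = 0.01)
  for (l in 2:10) {
    sel <- modes$l == l
    n <- sum(sel) * ncol(A)
    stat <- n * mean(A[sel, ]^2) / v_target[sel][1]
    expect_gt(stat, stats::qchisq(0.005, n))
    expect_lt(stat, stats::qchisq(0.995, n))
  }
})

test_that("generators are deterministic in seed and config", {
  cfg <- vesicle_config(n_frames = 2, detail = "lipids",
                        peptide_fraction = 0.1, seed = 77)
  t1 <- gen_vesicle_ensemble(cfg)
  t2 <- gen_vesicle_ensemble(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$z, t2$z)
  c1 <- gen_contour_series(contour_config(n_frames = 4, seed = 5))
  c2 <- gen_contour_series(contour_config(n_frames = 4, seed = 5))
  expect_identical(c1$rho, c2$rho)
  c3 <- gen_contour_series(contour_config(n_frames = 4, seed = 6))
  expect_false(identical(c1$rho, c3$rho))
  w1 <- gen_wave_trajectory(wave_config(n_frames = 3, n_atoms = 50, seed = 9))
  w2 <- gen_wave_trajectory(wave_config(n_frames = 3, n_atoms = 50, seed = 9))
  expect_identical(w1$z, w2$z)
})

test_that("near-zero temperature contours are perfect circles", {
  cs <- gen_contour_series(contour_config(temperature = 1e-9,
                                          detection_noise = 0,
                                          n_frames = 3, seed = 1))
  expect_lt(max(abs(cs$rho - 10)), 1e-5)
})

test_that("ensemble angular autocorrelation matches the closed form", {
  cf <- contour_config(kappa = 8e-20, n_frames = 5000, n_angles = 256,
                       l_max = 16, detection_noise = 0, seed = 13)
  cs <- gen_contour_series(cf)
  u <- (cs$rho - rowMeans(cs$rho)) / rowMeans(cs$rho)
  n <- ncol(u)
  F <- t(stats::mvfft(t(u)))
  xi_mean <- colMeans(Re(t(stats::mvfft(t(Mod(F)^2), inverse = TRUE))) / n^2)
  gam <- 2 * pi * (seq_len(n) - 1) / n
  Bl <- helfrich_Bl(2:16, cf$kappa, cf$sigma_bar, cf$temperature)
  xi_theory <- Reduce(`+`, lapply(2:16, function(l) {
    Bl[l - 1] * legendre_poly(l, cos(gam))
  }))
  ## per-frame mean subtraction removes the azimuthal m = 0 content, a
  ## gamma-independent offset sum_l <a^2> Y_l0(pi/2)^2
  vr <- helfrich_mode_variance(2:16, cf$kappa, cf$sigma_bar, cf$temperature)
  off <- sum(vr * (2 * (2:16) + 1) / (4 * pi) *
               vapply(2:16, function(l) legendre_poly(l, 0)^2, numeric(1)))
  ## sampling error of xi(0) ~ sqrt(2/n_frames) * xi(0)
  expect_lt(max(abs(xi_mean - (xi_theory - off))),
            4 * sqrt(2 / 5000) * xi_theory[1])
})

test_that("vesicle and contour generators agree through the equatorial cut", {
  kap <- 6e-20
  traj <- gen_vesicle_ensemble(vesicle_config(
    kappa = kap, n_frames = 300, l_max = 12, detail = "heads", seed = 21))
  spec3d <- spha_spectrum(traj, l_max = 10)
  cs <- gen_contour_series(contour_config(
    kappa = kap, radius = 10, n_frames = 4000, l_max = 12,
    detection_noise = 0, seed = 22))
  spec2d <- contour_spectrum(cs, l_max = 10)
  B3d <- unname((2 * spec3d$l + 1) / (4 * pi) * spec3d$power)
  B2d <- unname(spec2d$B_mean[match(spec3d$l, spec2d$l)])
  for (i in which(spec3d$l %in% 2:8)) {
    expect_equal(B3d[i], B2d[i], tolerance = 0.10)
  }
})

test_that("rendered rings sit at the configured radius in pixels", {
  circ <- contour_series(matrix(10, 1, 256), pixel_size = 0.133)
  img <- render_guv_images(circ, frames = 1, photon_budget = Inf)
  ## radial profile along +x from the centre
  ctr <- attr(img, "center")
  prof <- img[ctr[1] + 0.5 + (0:250), ceiling(ctr[2]), 1]
  expect_equal(which.max(prof) - 0.5, 10 / 0.133, tolerance = 1 / 75)
  ## a contour larger than the field of view is rejected
  big <- contour_series(matrix(40, 1, 256), pixel_size = 0.133)
  expect_error(render_guv_images(big, frames = 1), "field of view")
})

test_that("flat-membrane wave trajectories are flat", {
  tr <- gen_wave_trajectory(wave_config(amplitude0 = 0, noise = 0,
                                        n_frames = 3, n_atoms = 100))
  expect_equal(max(abs(tr$z)), 0)
})
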