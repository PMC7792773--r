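test_that("contour detection round-trips rendered rings", {
  ## noise-free constant ring: constant radii to well under 0.05 px
  circ <- contour_series(matrix(10, 1, 256), pixel_size = 0.133)
  img <- render_guv_images(circ, frames = 1, photon_budget = Inf)
  det <- detect_contour(img[, , 1], center_estimate = attr(img, "center"),
                        n_angles = 360)
  expect_true(attr(det, "qc_pass"))
  expect_lt(diff(range(det$rho_px)), 0.05)
  expect_equal(mean(det$rho_px), 10 / 0.133, tolerance = 1e-3)
  ## fluctuating contour, noise-free: reproduced within 0.05 px RMS
  cs <- gen_contour_series(contour_config(n_frames = 2, detection_noise = 0,
                                          seed = 2))
  img2 <- render_guv_images(cs, frames = 1, photon_budget = Inf)
  det2 <- detect_contour(img2[, , 1], center_estimate = attr(img2, "center"),
                         n_angles = 512)
  err_px <- (det2$rho - cs$rho[1, ]) / cs$pixel_size
  expect_lt(sqrt(mean(err_px^2)), 0.05)
  ## Poisson noise at photon budget 1e4: RMS error < 0.2 px
  img3 <- render_guv_images(cs, frames = 1, photon_budget = 1e4, seed = 4)
  det3 <- detect_contour(img3[, , 1], center_estimate = attr(img3, "center"),
                         n_angles = 512)
  err3 <- (det3$rho - cs$rho[1, ]) / cs$pixel_size
  expect_lt(sqrt(mean(err3^2)), 0.2)
  ## blank image fails QC
  expect_false(attr(detect_contour(matrix(0, 64, 64)), "qc_pass"))
})

test_that("detection on a stack assembles a QC-aware series", {
  cs <- gen_contour_series(contour_config(n_frames = 3, detection_noise = 0,
                                          seed = 12))
  img <- render_guv_images(cs, photon_budget = 1e4, seed = 3)
  ds <- detect_contour_series(img, n_angles = 256)
  expect_s3_class(ds, "contour_series")
  expect_equal(nrow(ds$rho), 3)
  expect_true(all(ds$qc_pass))
  expect_equal(ds$radius_mean, cs$radius_mean, tolerance = 5e-3)
})

test_that("radius QC masks exactly the injected outliers", {
  ## bounded frame-to-frame radius drift (slow breathing), so the only
  ## frames beyond 3 MAD are the injected ones
  n <- 500
  rho <- matrix(10 + 0.02 * sin(seq_len(n) / 7), n, 64)
  base_mad <- mad(rowMeans(rho))
  bad <- c(17, 101, 350, 444, 499)
  rho[bad, ] <- rho[bad, ] + 10 * base_mad
  cs <- contour_series(rho)
  f <- qc_radius_filter(cs, k_mad = 3)
  expect_equal(which(!f$qc_pass), bad)
  expect_equal(attr(f, "n_masked"), length(bad))
  ## constant series: nothing masked; k_mad = Inf disables the filter
  cs0 <- contour_series(matrix(10, 50, 32))
  expect_true(all(qc_radius_filter(cs0)$qc_pass))
  expect_true(all(qc_radius_filter(cs, k_mad = Inf)$qc_pass))
  ## unusable series: too few frames survive detection QC + radius QC
  cs_pre <- contour_series(rho, qc_pass = c(rep(FALSE, 260), rep(TRUE, 240)))
  expect_error(qc_radius_filter(cs_pre, 3), "50%")
})

test_that("angular autocorrelation matches closed-form trigonometry", {
  phi <- 2 * pi * (0:511) / 512
  ## perfect circle: xi identically 0
  xi0 <- angular_autocorrelation(rep(10, 512))
  expect_true(all(abs(xi0$xi) < 1e-24))
  ## single cos(2 phi) mode: xi(gamma) = (eps^2/2) cos(2 gamma)
  eps <- 0.03
  xi <- angular_autocorrelation(10 * (1 + eps * cos(2 * phi)))
  expect_equal(xi$xi, eps^2 / 2 * cos(2 * xi$gamma), tolerance = 1e-10)
  ## xi(0) is the relative radial variance
  set.seed(2)
  rho <- 10 * (1 + 0.01 * rnorm(512))
  xi2 <- angular_autocorrelation(rho)
  expect_equal(xi2$xi[1], mean(((rho - mean(rho)) / mean(rho))^2),
               tolerance = 1e-12)
})

test_that("Legendre decomposition inverts known expansions", {
  gam <- 2 * pi * (0:511) / 512
  ## xi = P_3(cos gamma) exactly
  bl <- legendre_decompose(legendre_poly(3, cos(gam)), l_max = 8)
  expect_equal(bl$B[bl$l == 3], 1, tolerance = 1e-4)
  expect_lt(max(abs(bl$B[bl$l != 3])), 1e-3)
  ## zero in, zero out
  expect_true(all(legendre_decompose(rep(0, 512), 8)$B == 0))
  ## sampling resolution bound
  expect_error(legendre_decompose(rep(0, 16), l_max = 8), "l_max")
})

test_that("ensemble Legendre spectrum matches the generator closed form", {
  cf <- contour_config(kappa = 5e-20, n_frames = 4000, detection_noise = 0,
                       seed = 33)
  spec <- contour_spectrum(gen_contour_series(cf), l_max = 10)
  expected <- helfrich_Bl(2:8, cf$kappa, cf$sigma_bar, cf$temperature)
  for (l in 2:8) {
    i <- which(spec$l == l)
    expect_equal(spec$B_mean[i], expected[l - 1],
                 tolerance = 5 * spec$B_se[i] / expected[l - 1])
  }
})

test_that("spectrum completeness: sum of B_l reproduces xi(0) within 2%", {
  cf <- contour_config(kappa = 7e-20, n_frames = 1000, l_max = 20,
                       detection_noise = 0, seed = 17)
  spec <- contour_spectrum(gen_contour_series(cf), l_max = 20)
  expect_equal(spec$completeness, 1, tolerance = 0.02)
})

test_that("noise-free AVB inversion is exact and scale invariant", {
  l <- 2:10
  kap <- 10.5e-20
  df <- tibble::tibble(l = l, B_mean = helfrich_Bl(l, kap, 0),
                       B_se = helfrich_Bl(l, kap, 0) * 1e-3)
  est <- estimate_kappa_avb(df, temperature = 296.15)
  expect_equal(est$kappa, kap, tolerance = 1e-6)
  ## doubling all B_l with T doubled leaves kappa unchanged
  df2 <- dplyr::mutate(df, B_mean = 2 * B_mean, B_se = 2 * B_se)
  est2 <- estimate_kappa_avb(df2, temperature = 2 * 296.15)
  expect_equal(est2$kappa, est$kappa, tolerance = 1e-9)
})

test_that("SA rejects fluctuation-free series and agrees with AVB on clean data", {
  ## degenerate: zero fluctuation variance
  cs0 <- contour_series(matrix(10, 200, 128))
  spec0 <- contour_spectrum(cs0, l_max = 8)
  expect_error(suppressWarnings(estimate_kappa_sa(spec0)),
               "degenerate|every degree|positive B")
  ## clean generated series: SA and AVB agree within 10%
  cs <- gen_contour_series(contour_config(kappa = 6e-20, n_frames = 2000,
                                          detection_noise = 0, seed = 41))
  spec <- contour_spectrum(cs, l_max = 12)
  avb <- estimate_kappa_avb(spec)
  sa <- estimate_kappa_sa(spec, sigma_bar = avb$sigma_bar)
  expect_equal(sa$kappa / avb$kappa, 1, tolerance = 0.10)
  expect_equal(avb$kappa, 6e-20, tolerance = 0.15)
  ## SA needs enough frames
  short <- contour_spectrum(gen_contour_series(
    contour_config(n_frames = 50, seed = 2)), l_max = 8)
  expect_error(estimate_kappa_sa(short), "100")
})

test_that("median recovery across seeds is within one SD of truth", {
  for (kap in c(3e-20, 12e-20)) {
    est <- purrr::map_dfr(1:10, function(s) {
      cs <- gen_contour_series(contour_config(kappa = kap, n_frames = 800,
                                              seed = 100 + s))
      r <- flicker_kappa(cs)
      tibble::tibble(avb = r$AVB$kappa, avb_sd = r$AVB$kappa_sd,
                     sa = r$SA$kappa, sa_sd = r$SA$kappa_sd)
    })
    expect_lt(abs(median(est$avb) - kap), max(median(est$avb_sd), 0.1 * kap))
    expect_lt(abs(median(est$sa) - kap), max(median(est$sa_sd), 0.1 * kap))
  }
})

test_that("random 10% masking barely moves the estimate", {
  cs <- gen_contour_series(contour_config(kappa = 8e-20, n_frames = 2000,
                                          detection_noise = 0, seed = 55))
  full <- estimate_kappa_avb(contour_spectrum(cs, 10))
  set.seed(99)
  cs$qc_pass[sample(2000, 200)] <- FALSE
  masked <- estimate_kappa_avb(contour_spectrum(cs, 10))
  expect_lt(abs(masked$kappa / full$kappa - 1), 0.03)
})
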