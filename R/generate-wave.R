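## Synthetic planar membrane executing a damped standing wave after a
## pressure impulse: generator plumbing for the wave-amplitude analyzer.

#' Configuration for the standing-wave trajectory generator
#'
#' The generated head-particle height field is
#' \deqn{z(x, t) = A_0 e^{-t/\tau} \cos(\omega t)\,
#'   \sin(2\pi x/\lambda + \varphi) + \epsilon,}
#' sampled at `n_atoms` random (x, y) positions that stay fixed across
#' frames (lipids do not advect in this toy kinematics; the analyzer uses
#' equal-time statistics per frame only).
#'
#' @param amplitude0 Initial wave amplitude A0, nm.
#' @param wavelength Spatial wavelength, nm.
#' @param omega Angular temporal frequency, rad/ps.
#' @param damping_tau Exponential amplitude decay time, ps.
#' @param phase Spatial phase, rad.
#' @param n_atoms Number of head particles.
#' @param box_length Periodic box length along x, nm.
#' @param z0 Mean membrane height, nm.
#' @param dt Frame interval, ps.
#' @param n_frames Number of frames.
#' @param noise Per-particle Gaussian height noise, nm.
#' @param seed Integer seed.
#' @return A validated list of class `wave_config`.
#' @export
wave_config <- function(amplitude0 = 1, wavelength = 30, omega = 0.05,
                        damping_tau = 500, phase = 0, n_atoms = 2000,
                        box_length = 30, z0 = 0, dt = 2, n_frames = 400,
                        noise = 0.05, seed = 1) {
  stopifnot(amplitude0 >= 0, wavelength > 0, damping_tau > 0, omega > 0,
            n_atoms >= 10, box_length > 0, dt > 0, n_frames >= 1, noise >= 0)
  structure(list(
    amplitude0 = amplitude0, wavelength = wavelength, omega = omega,
    damping_tau = damping_tau, phase = phase, n_atoms = as.integer(n_atoms),
    box_length = box_length, z0 = z0, dt = dt,
    n_frames = as.integer(n_frames), noise = noise, seed = as.integer(seed)
  ), class = "wave_config")
}

#' Generate a damped standing-wave membrane trajectory
#'
#' @param config A [wave_config()].
#' @return A trajectory tibble of head particles with attribute `config`;
#'   frame timestamps are `frame * dt` ps (stored in attribute `time`).
#' @export
#' @examples
#' traj <- gen_wave_trajectory(wave_config(n_frames = 5, n_atoms = 100))
gen_wave_trajectory <- function(config) {
  stopifnot(inherits(config, "wave_config"))
  set.seed(config$seed)
  cf <- config
  x <- runif(cf$n_atoms, 0, cf$box_length)
  y <- runif(cf$n_atoms, 0, cf$box_length)
  t_ps <- (seq_len(cf$n_frames) - 1) * cf$dt
  env <- cf$amplitude0 * exp(-t_ps / cf$damping_tau) * cos(cf$omega * t_ps)
  sx <- sin(2 * pi * x / cf$wavelength + cf$phase)
  z <- cf$z0 + outer(sx, env)                       # atoms x frames
  if (cf$noise > 0) z <- z + matrix(rnorm(length(z), sd = cf$noise), nrow = cf$n_atoms)
  traj <- as_trajectory(tibble(
    frame = rep(seq_len(cf$n_frames) - 1L, each = cf$n_atoms),
    particle = rep(seq_len(cf$n_atoms), cf$n_frames),
    role = "head",
    leaflet = "none",
    x = rep(x, cf$n_frames),
    y = rep(y, cf$n_frames),
    z = as.vector(z)
  ))
  attr(traj, "config") <- cf
  attr(traj, "time") <- t_ps
  traj
}
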