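## Real orthonormal spherical harmonics and the Helfrich mode-variance model
## for a quasi-spherical vesicle. This is the spectral core shared by the
## synthetic generators (which draw mode amplitudes from the model) and the
## estimators (which invert it).

#' Spherical-harmonic mode table
#'
#' Enumerates the real-basis modes (l, m) with `l_min <= l <= l_max`.
#' Positive `m` denotes the cosine component, negative `m` the sine
#' component, `m = 0` the zonal term; each degree l contributes 2l+1 modes.
#'
#' @param l_max Maximum degree.
#' @param l_min Minimum degree (default 2: l = 0 is a volume change and
#'   l = 1 a rigid translation, neither is a shape fluctuation).
#' @return A tibble with integer columns `l` and `m`.
#' @export
sph_mode_table <- function(l_max, l_min = 2) {
  stopifnot(l_max >= l_min, l_min >= 0)
  purrr::map_dfr(l_min:l_max, function(l) {
    m <- if (l == 0) 0L else c(0L, as.integer(rbind(1:l, -(1:l))))
    tibble(l = as.integer(l), m = m)
  })
}

## Orthonormal prefactor sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!), stable for all l.
.sph_norm <- function(l, m) {
  sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
}

#' Real spherical-harmonic basis matrix
#'
#' Evaluates the real, unit-L2-normalised spherical harmonics at the given
#' directions: `Y_l0`, and for m > 0 `sqrt(2) N_lm P_l^m(cos theta)`
#' times `cos(m phi)` (mode m) or `sin(m phi)` (mode -m). Associated
#' Legendre functions come from [pracma::legendre()].
#'
#' @param theta,phi Colatitude and azimuth vectors (same length).
#' @param modes A mode table from [sph_mode_table()], or `l_max` as a single
#'   number (then `l_min = 2`).
#' @return A `length(theta)` x `nrow(modes)` matrix; columns follow `modes`.
#' @export
real_sph_basis <- function(theta, phi, modes) {
  if (is.numeric(modes) && length(modes) == 1) modes <- sph_mode_table(modes)
  stopifnot(length(theta) == length(phi))
  x <- cos(theta)
  B <- matrix(0, length(theta), nrow(modes))
  for (l in unique(modes$l)) {
    P <- pracma::legendre(l, x)          # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    sel <- which(modes$l == l)
    for (j in sel) {
      m <- modes$m[j]
      am <- abs(m)
      nl <- .sph_norm(l, am)
      plm <- P[am + 1, ]
      B[, j] <- if (m == 0) nl * plm
      else if (m > 0) sqrt(2) * nl * plm * cos(am * phi)
      else sqrt(2) * nl * plm * sin(am * phi)
    }
  }
  B
}

#' Legendre polynomial P_l(x)
#'
#' @param l Degree (single non-negative integer).
#' @param x Evaluation points in \[-1, 1\].
#' @return Numeric vector of P_l(x).
#' @export
legendre_poly <- function(l, x) {
  stopifnot(l >= 0)
  if (l == 0) return(rep(1, length(x)))
  P <- pracma::legendre(l, x)
  if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
  P[1, ]
}

#' Helfrich mode variance on a quasi-sphere
#'
#' Thermal variance of the real spherical-harmonic coefficients of the
#' relative radial displacement field of a quasi-spherical vesicle with
#' bending rigidity `kappa` and reduced tension `sigma_bar` (the
#' Milner-Safran form, vanishing spontaneous curvature):
#' \deqn{\langle a_{lm}^2 \rangle = \frac{k_B T}{\kappa (l-1)(l+2)\,[l(l+1) + \bar\sigma]}.}
#' The variance is m-independent; modes are independent and zero-mean.
#'
#' @param l Integer degree(s), l >= 2.
#' @param kappa Bending rigidity, J.
#' @param sigma_bar Reduced tension \eqn{\bar\sigma = \sigma R^2 / \kappa}
#'   (dimensionless).
#' @param temperature Temperature, K.
#' @return Numeric vector of dimensionless variances.
#' @export
#' @examples
#' helfrich_mode_variance(2:6, kappa = 7.3e-20)
helfrich_mode_variance <- function(l, kappa, sigma_bar = 0,
                                   temperature = 296.15) {
  stopifnot(all(l >= 2), kappa > 0, temperature > 0)
  denom <- l * (l + 1) + sigma_bar
  if (any(denom <= 0)) {
    abort("sigma_bar too negative: l(l+1) + sigma_bar must be positive for all requested l")
  }
  .kB * temperature / (kappa * (l - 1) * (l + 2) * denom)
}

#' Expected Legendre coefficients of the equatorial autocorrelation
#'
#' For independent Gaussian modes with the Helfrich variance, the addition
#' theorem gives the angular autocorrelation of the relative equatorial
#' contour displacement as \eqn{\xi(\gamma) = \sum_l B_l P_l(\cos\gamma)}
#' with \eqn{B_l = \frac{2l+1}{4\pi}\langle a_{lm}^2\rangle}.
#'
#' @inheritParams helfrich_mode_variance
#' @return Numeric vector of expected B_l.
#' @export
helfrich_Bl <- function(l, kappa, sigma_bar = 0, temperature = 296.15) {
  (2 * l + 1) / (4 * pi) * helfrich_mode_variance(l, kappa, sigma_bar, temperature)
}
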