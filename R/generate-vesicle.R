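## Synthetic quasi-spherical vesicle ensembles. Frames are statistically
## independent draws of the Helfrich mode amplitudes; lipid angular
## positions sit on a fixed Fibonacci lattice per leaflet so that only the
## radial field and the positional noise change between frames (all
## estimators in the package use equal-time statistics only).

## Nominal particle masses used to convert a peptide mass fraction into a
## particle count (Da): POPC lipid and an amyloid-beta monomer.
.mass_lipid_da <- 760
.mass_peptide_da <- 4330

#' Leaflet lipid counts from the starting-APL construction rule
#'
#' Implements the initial-vesicle construction rule: a mid-surface sphere of
#' radius `radius`, a starting area per lipid `apl_start` (on average), the
#' inner-leaflet APL scaled by `scaling[1]` and the outer by `scaling[2]`,
#' and leaflet spheres offset radially by half the bilayer `thickness`. The
#' per-leaflet count is the leaflet sphere area divided by the scaled APL,
#' rounded to the nearest integer.
#'
#' @param radius Mid-surface radius, nm.
#' @param thickness Bilayer (head-to-head) thickness, nm.
#' @param apl_start Mean starting area per lipid, A^2 (default 68.1).
#' @param scaling Length-2 multiplier for (inner, outer) APL
#'   (default `c(0.95, 1.05)`).
#' @return Named integer vector `c(inner =, outer =)`.
#' @export
#' @examples
#' leaflet_counts_from_apl(20, 3.43)
leaflet_counts_from_apl <- function(radius, thickness, apl_start = 68.1,
                                    scaling = c(0.95, 1.05)) {
  stopifnot(radius > 0, thickness > 0, thickness < radius, apl_start > 0,
            length(scaling) == 2, all(scaling > 0))
  r <- c(inner = radius - thickness / 2, outer = radius + thickness / 2)
  area_A2 <- 4 * pi * r^2 * 100          # nm^2 -> A^2
  counts <- round(area_A2 / (apl_start * scaling))
  storage.mode(counts) <- "integer"
  counts
}

#' Configuration for the vesicle ensemble generator
#'
#' @param kappa Bending rigidity, J.
#' @param sigma_bar Reduced tension (dimensionless).
#' @param radius Mid-surface radius, nm.
#' @param thickness Head-to-head bilayer thickness, nm.
#' @param apl_start Starting mean area per lipid, A^2, used to derive the
#'   leaflet counts when these are not given explicitly.
#' @param leaflet_scaling APL multipliers for (inner, outer) leaflets.
#' @param n_lipids_inner,n_lipids_outer Optional explicit leaflet counts;
#'   default derived from the APL rule.
#' @param l_max Largest undulation degree generated (modes l = 2..l_max).
#' @param n_frames Number of statistically independent frames.
#' @param temperature Temperature, K.
#' @param positional_noise Isotropic Gaussian positional noise per particle,
#'   nm (sub-headgroup roughness on top of the continuum surface).
#' @param peptide_fraction Peptide mass fraction with respect to lipids, in
#'   \[0, 1); converted to a particle count with nominal masses 760 Da per
#'   lipid and 4330 Da per peptide.
#' @param detail `"lipids"` (heads + two tail carbons each, the default),
#'   `"heads"` (head particles only; lean ensembles for rigidity work), or
#'   `"full"` (adds a carbonyl-glycerol particle per lipid).
#' @param tail_inset Radial distance from a head to the midpoint of its two
#'   16th-carbon tail positions, nm.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the seed and the configuration.
#' @return A validated list of class `vesicle_config`.
#' @export
vesicle_config <- function(kappa = 7.3e-20, sigma_bar = 0, radius = 20,
                           thickness = 3.43, apl_start = 68.1,
                           leaflet_scaling = c(0.95, 1.05),
                           n_lipids_inner = NULL, n_lipids_outer = NULL,
                           l_max = 14, n_frames = 100,
                           temperature = 296.15, positional_noise = 0.1,
                           peptide_fraction = 0,
                           detail = c("lipids", "heads", "full"),
                           tail_inset = 1.4, seed = 1) {
  detail <- match.arg(detail)
  stopifnot(kappa > 0, l_max >= 2, n_frames >= 1, thickness < radius,
            thickness > 0, temperature > 0, positional_noise >= 0,
            peptide_fraction >= 0, peptide_fraction < 1, tail_inset > 0)
  ## fail early if the variance model is ill-defined anywhere in 2..l_max
  helfrich_mode_variance(2:l_max, kappa, sigma_bar, temperature)
  if (is.null(n_lipids_inner) || is.null(n_lipids_outer)) {
    counts <- leaflet_counts_from_apl(radius, thickness, apl_start, leaflet_scaling)
    n_lipids_inner <- n_lipids_inner %||% counts[["inner"]]
    n_lipids_outer <- n_lipids_outer %||% counts[["outer"]]
  }
  structure(list(
    kappa = kappa, sigma_bar = sigma_bar, radius = radius,
    thickness = thickness, apl_start = apl_start,
    leaflet_scaling = leaflet_scaling,
    n_lipids_inner = as.integer(n_lipids_inner),
    n_lipids_outer = as.integer(n_lipids_outer),
    l_max = as.integer(l_max), n_frames = as.integer(n_frames),
    temperature = temperature, positional_noise = positional_noise,
    peptide_fraction = peptide_fraction, detail = detail,
    tail_inset = tail_inset, seed = as.integer(seed)
  ), class = "vesicle_config")
}

#' Generate a quasi-spherical vesicle ensemble
#'
#' Draws, for each frame, independent real-basis spherical-harmonic
#' amplitudes `a_lm` (l = 2..`l_max`) from the Helfrich variance
#' ([helfrich_mode_variance()]), builds the mid-surface radius field
#' \eqn{r(\theta,\phi) = R\,(1 + \sum a_{lm} Y_{lm})}, and places head
#' particles on the two leaflet surfaces at \eqn{r \pm} `thickness`/2 along
#' fixed quasi-uniform lattice directions. Tail-carbon particles (two per
#' lipid) are radially inset by `tail_inset`, optional carbonyl-glycerol
#' particles sit between heads and tails, and optional peptide particles are
#' placed uniformly in the interphase band between the head and acyl-chain
#' radii of a randomly chosen leaflet. Isotropic Gaussian positional noise
#' is added to every coordinate.
#'
#' @param config A [vesicle_config()].
#' @return A trajectory tibble ([as_trajectory()]) with attributes
#'   `config` and `mode_truth` (tibble of the drawn `a_lm` variances by l).
#' @export
#' @examples
#' traj <- gen_vesicle_ensemble(vesicle_config(n_frames = 2, detail = "heads"))
#' dplyr::count(traj, frame, leaflet)
gen_vesicle_ensemble <- function(config) {
  stopifnot(inherits(config, "vesicle_config"))
  set.seed(config$seed)
  cf <- config
  modes <- sph_mode_table(cf$l_max)
  vr <- helfrich_mode_variance(modes$l, cf$kappa, cf$sigma_bar, cf$temperature)
  A <- matrix(rnorm(nrow(modes) * cf$n_frames, sd = sqrt(vr)),
              nrow = nrow(modes), ncol = cf$n_frames)   # modes x frames

  dir_in <- fibonacci_sphere(cf$n_lipids_inner)
  dir_out <- fibonacci_sphere(cf$n_lipids_outer)
  dirs <- rbind(dir_in, dir_out)
  n_heads <- nrow(dirs)
  sph <- to_spherical(tibble(x = dirs[, 1], y = dirs[, 2], z = dirs[, 3]))
  B <- real_sph_basis(sph$theta, sph$phi, modes)        # heads x modes
  U <- B %*% A                                          # heads x frames
  half_t <- cf$thickness / 2
  offset <- c(rep(-half_t, cf$n_lipids_inner), rep(half_t, cf$n_lipids_outer))
  leaflet <- c(rep("inner", cf$n_lipids_inner), rep("outer", cf$n_lipids_outer))
  ## tail midpoints point toward the bilayer midplane
  tail_sign <- ifelse(leaflet == "inner", 1, -1)

  frames <- rep(seq_len(cf$n_frames) - 1L, each = n_heads)
  r_head <- cf$radius * (1 + as.vector(U)) + offset     # heads*frames
  dx <- rep(dirs[, 1], cf$n_frames)
  dy <- rep(dirs[, 2], cf$n_frames)
  dz <- rep(dirs[, 3], cf$n_frames)
  noise <- function(n) if (cf$positional_noise > 0)
    rnorm(n, sd = cf$positional_noise) else numeric(n)

  nhf <- n_heads * cf$n_frames
  blocks <- list(tibble(
    frame = frames,
    particle = rep(seq_len(n_heads), cf$n_frames),
    lipid = rep(seq_len(n_heads), cf$n_frames),
    role = "head",
    leaflet = rep(leaflet, cf$n_frames),
    x = dx * r_head + noise(nhf),
    y = dy * r_head + noise(nhf),
    z = dz * r_head + noise(nhf)
  ))

  if (cf$detail %in% c("lipids", "full")) {
    r_mid_tail <- r_head + rep(tail_sign, cf$n_frames) * cf$tail_inset
    for (k in 1:2) {
      ## the two 16th carbons straddle the tail midpoint radially
      r_tc <- r_mid_tail + (if (k == 1) -0.05 else 0.05)
      blocks[[length(blocks) + 1]] <- tibble(
        frame = frames,
        particle = rep(n_heads * k + seq_len(n_heads), cf$n_frames),
        lipid = rep(seq_len(n_heads), cf$n_frames),
        role = "tail_carbon",
        leaflet = rep(leaflet, cf$n_frames),
        x = dx * r_tc + noise(nhf),
        y = dy * r_tc + noise(nhf),
        z = dz * r_tc + noise(nhf)
      )
    }
  }
  if (cf$detail == "full") {
    r_cg <- r_head + rep(tail_sign, cf$n_frames) * 0.45
    blocks[[length(blocks) + 1]] <- tibble(
      frame = frames,
      particle = rep(3L * n_heads + seq_len(n_heads), cf$n_frames),
      lipid = rep(seq_len(n_heads), cf$n_frames),
      role = "carbonyl_glycerol",
      leaflet = rep(leaflet, cf$n_frames),
      x = dx * r_cg + noise(nhf),
      y = dy * r_cg + noise(nhf),
      z = dz * r_cg + noise(nhf)
    )
  }

  n_pep <- round(cf$peptide_fraction * n_heads * .mass_lipid_da / .mass_peptide_da)
  if (n_pep > 0) {
    pd <- fibonacci_sphere(n_pep)
    ## jitter the lattice so peptides do not shadow lipid directions
    pth <- runif(n_pep, 0, 2 * pi)
    rot <- cbind(pd[, 1] * cos(pth) - pd[, 2] * sin(pth),
                 pd[, 1] * sin(pth) + pd[, 2] * cos(pth), pd[, 3])
    pl <- sample(c("inner", "outer"), n_pep, replace = TRUE)
    psph <- to_spherical(tibble(x = rot[, 1], y = rot[, 2], z = rot[, 3]))
    BP <- real_sph_basis(psph$theta, psph$phi, modes)
    UP <- BP %*% A                                       # n_pep x frames
    ## depth within the interphase band, fixed per peptide
    depth <- runif(n_pep, 0.2, cf$tail_inset)
    p_off <- ifelse(pl == "inner", -half_t + depth, half_t - depth)
    r_pep <- cf$radius * (1 + as.vector(UP)) + rep(p_off, cf$n_frames)
    npf <- n_pep * cf$n_frames
    blocks[[length(blocks) + 1]] <- tibble(
      frame = rep(seq_len(cf$n_frames) - 1L, each = n_pep),
      particle = rep(4L * n_heads + seq_len(n_pep), cf$n_frames),
      lipid = NA_integer_,
      role = "peptide",
      leaflet = rep(pl, cf$n_frames),
      x = rep(rot[, 1], cf$n_frames) * r_pep + noise(npf),
      y = rep(rot[, 2], cf$n_frames) * r_pep + noise(npf),
      z = rep(rot[, 3], cf$n_frames) * r_pep + noise(npf)
    )
  }

  rm(U, r_head, dx, dy, dz)
  traj <- as_trajectory(if (length(blocks) == 1) blocks[[1]] else bind_rows(blocks))
  attr(traj, "config") <- cf
  attr(traj, "mode_truth") <- tibble(
    l = modes$l, m = modes$m, variance = vr,
    a = as.vector(A[, 1])   # first-frame draw, occasionally handy in checks
  )
  traj
}
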