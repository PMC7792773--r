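## Vesicle structural parameters: leaflet radii and membrane thickness from
## per-leaflet sphere fits, area per lipid from the vesicle APL formula, and
## radial density profiles of membrane zones.

#' Area per lipid of a vesicle
#'
#' Vesicle APL from the sphere area and the mean leaflet lipid count:
#' \deqn{APL = \frac{4\pi r^2}{\tfrac12 (n_{inner} + n_{outer})},}
#' reported in A^2.
#'
#' @param r_vesicle Vesicle radius, nm (sphere fit to all head particles).
#' @param n_inner,n_outer Lipid counts per leaflet.
#' @return APL in A^2 (vectorised).
#' @export
#' @examples
#' area_per_lipid(20, 7381, 7381)   # ~68.1 A^2
area_per_lipid <- function(r_vesicle, n_inner, n_outer) {
  if (any(r_vesicle <= 0)) abort("r_vesicle must be positive")
  if (any(n_inner <= 0) || any(n_outer <= 0)) abort("lipid counts must be positive")
  4 * pi * r_vesicle^2 * 100 / ((n_inner + n_outer) / 2)
}

#' Membrane thickness and vesicle geometry from head particles
#'
#' For each frame, fits spheres to the inner-leaflet, outer-leaflet and
#' pooled head (phosphorus) positions, giving the leaflet radii, the
#' vesicle radius, the thickness (outer minus inner radius), and the
#' vesicle APL recomputed via [area_per_lipid()]. Uncertainties are the SDs
#' across frames.
#'
#' @param traj A trajectory table containing head particles labelled
#'   `inner` and `outer`.
#' @return An object of class `structural_result`: list with `per_frame`
#'   (tibble: frame, r_inner, r_outer, r_vesicle, thickness, apl,
#'   n_inner, n_outer) and `summary` (tibble of mean and sd per quantity).
#' @export
membrane_thickness <- function(traj) {
  traj <- as_trajectory(traj)
  heads <- filter(traj, .data$role == "head")
  if (nrow(heads) == 0) abort("no head particles in trajectory")
  if (!all(c("inner", "outer") %in% unique(heads$leaflet))) {
    abort("head particles must carry inner/outer leaflet labels")
  }
  if (any(heads$leaflet == "none")) {
    abort("head particles with leaflet = 'none' are invalid for vesicle analyses")
  }
  idx <- .frame_index(heads)
  per_frame <- purrr::map_dfr(seq_along(idx), function(i) {
    fr <- heads[idx[[i]], ]
    inner <- fr[fr$leaflet == "inner", ]
    outer <- fr[fr$leaflet == "outer", ]
    f_in <- .fit_sphere_xyz(inner$x, inner$y, inner$z)
    f_out <- .fit_sphere_xyz(outer$x, outer$y, outer$z)
    f_all <- .fit_sphere_xyz(fr$x, fr$y, fr$z)
    tibble(
      frame = fr$frame[1],
      r_inner = f_in$radius, r_outer = f_out$radius,
      r_vesicle = f_all$radius,
      thickness = f_out$radius - f_in$radius,
      apl = area_per_lipid(f_all$radius, nrow(inner), nrow(outer)),
      n_inner = nrow(inner), n_outer = nrow(outer)
    )
  })
  num <- c("r_inner", "r_outer", "r_vesicle", "thickness", "apl")
  summary <- tibble(
    quantity = num,
    mean = unname(vapply(per_frame[num], mean, numeric(1))),
    sd = unname(vapply(per_frame[num], sd, numeric(1))),
    n_frames = nrow(per_frame)
  )
  structure(list(per_frame = per_frame, summary = summary),
            class = "structural_result")
}

#' @export
print.structural_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<structural_result> %d frame(s)\n", s$n_frames[1]))
  for (i in seq_len(nrow(s))) {
    unit <- if (s$quantity[i] == "apl") "A^2" else "nm"
    cat(sprintf("  %-10s %8.4f +/- %.4f %s\n", s$quantity[i], s$mean[i],
                if (is.na(s$sd[i])) 0 else s$sd[i], unit))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.structural_result <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.structural_result <- function(x, ...) {
  s <- x$summary
  tibble(
    thickness = s$mean[s$quantity == "thickness"],
    thickness_sd = s$sd[s$quantity == "thickness"],
    apl = s$mean[s$quantity == "apl"],
    apl_sd = s$sd[s$quantity == "apl"],
    r_vesicle = s$mean[s$quantity == "r_vesicle"],
    n_frames = s$n_frames[1]
  )
}

## Default mapping from particle roles to density-profile zones.
.default_zones <- list(
  headgroups = "head",
  carbonyl_glycerol = "carbonyl_glycerol",
  acyl_chain = c("tail_carbon", "acyl_chain"),
  peptide = "peptide"
)

#' Radial density profiles of membrane zones
#'
#' Pools, over frames, the distance of each zone's particles from the
#' vesicle centre (per-frame sphere fit to all heads), histograms the
#' distances, normalises each zone's histogram to unit probability, and
#' fits a Gaussian to the binned profile by least squares, mirroring a
#' histogram-then-normal-fit workflow.
#'
#' @param traj Trajectory table.
#' @param zones Named list mapping zone names to role vectors; default
#'   headgroups/carbonyl-glycerol/acyl-chain/peptide. Zones with no
#'   particles are skipped with a warning.
#' @param bin_width Histogram bin width, nm (default 0.1).
#' @param leaflet Optional leaflet filter (`"inner"` or `"outer"`);
#'   particles of either leaflet are pooled by default.
#' @return An object of class `density_profile_set`: named list of zone
#'   results, each with `histogram` (tibble: r, prob), `gauss_mean`,
#'   `gauss_sd`, `n`.
#' @export
density_profile <- function(traj, zones = NULL, bin_width = 0.1,
                            leaflet = NULL) {
  traj <- as_trajectory(traj)
  zones <- zones %||% .default_zones
  heads <- filter(traj, .data$role == "head")
  if (nrow(heads) == 0) abort("no head particles to define the vesicle centre")
  idx <- .frame_index(heads)
  centers <- lapply(idx, function(ii) {
    .fit_sphere_xyz(heads$x[ii], heads$y[ii], heads$z[ii])$center
  })
  frame_levels <- as.integer(names(idx))
  ## distance from per-frame centre for every particle
  ctr_row <- match(traj$frame, frame_levels)
  cx <- vapply(centers, `[[`, numeric(1), 1)[ctr_row]
  cy <- vapply(centers, `[[`, numeric(1), 2)[ctr_row]
  cz <- vapply(centers, `[[`, numeric(1), 3)[ctr_row]
  dist <- sqrt((traj$x - cx)^2 + (traj$y - cy)^2 + (traj$z - cz)^2)
  if (!is.null(leaflet)) {
    keep <- traj$leaflet == leaflet
  } else keep <- rep(TRUE, nrow(traj))

  out <- list()
  for (zn in names(zones)) {
    sel <- keep & traj$role %in% zones[[zn]]
    if (!any(sel)) {
      warn(paste0("zone '", zn, "' has no particles; skipped"))
      next
    }
    d <- dist[sel]
    edges <- seq(floor(min(d) / bin_width) * bin_width,
                 ceiling(max(d) / bin_width) * bin_width + bin_width / 2,
                 by = bin_width)
    h <- graphics::hist(d, breaks = edges, plot = FALSE)
    prob <- h$counts / sum(h$counts)
    mids <- h$mids
    mu0 <- sum(mids * prob); s0 <- sqrt(max(sum((mids - mu0)^2 * prob), bin_width^2 / 12))
    ## near-degenerate histograms (all mass in one bin) fall back to the
    ## moment estimates below
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        prob ~ a * exp(-(mids - mu)^2 / (2 * s^2)),
        start = list(a = max(prob), mu = mu0, s = s0),
        lower = c(a = 0, mu = min(mids), s = bin_width / 10),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    pars <- if (is.null(fit)) c(mu = mu0, s = s0) else coef(fit)[c("mu", "s")]
    out[[zn]] <- list(zone = zn,
                      histogram = tibble(r = mids, prob = prob),
                      gauss_mean = unname(pars[1]),
                      gauss_sd = abs(unname(pars[2])),
                      n = length(d))
  }
  structure(out, class = "density_profile_set")
}

#' @export
print.density_profile_set <- function(x, ...) {
  cat("<density_profile_set>\n")
  for (z in x) {
    cat(sprintf("  %-18s mean %7.3f nm, sd %6.3f nm, n = %d\n",
                z$zone, z$gauss_mean, z$gauss_sd, z$n))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.density_profile_set <- function(x, ...) {
  purrr::map_dfr(x, function(z) {
    tibble(zone = z$zone, gauss_mean = z$gauss_mean, gauss_sd = z$gauss_sd,
           n = z$n)
  })
}

#' @rdname autoplot-vesimech
#' @exportS3Method ggplot2::autoplot
autoplot.density_profile_set <- function(object, ...) {
  df <- purrr::map_dfr(object, function(z) {
    mutate(z$histogram, zone = z$zone)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$prob,
                                   colour = .data$zone)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from centre (nm)", y = "probability",
                  colour = "zone") +
    ggplot2::theme_minimal()
}
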