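#' Default configuration for the synthetic 4D thorax phantom
#'
#' The phantom is a piecewise-constant density thorax surrogate on a
#' regular grid: an elliptic-cylinder body (density 1.0), two ellipsoidal
#' lungs (0.26), a heart sphere, an esophagus cylinder, a vertebral column
#' (1.4) with a spinal canal, and a spherical tumor (GTV, 1.05) inside the
#' right lung.  Material edges are smoothed with an error-function profile
#' of width `edge_sigma_mm` so that densities interpolate cleanly; ROI
#' masks are exact (unsmoothed) indicators on the mid-position grid.
#'
#' Breathing is modelled as a rigid craniocaudal translation of the GTV
#' along a 1-cos trajectory, blended smoothly into the static lung by a
#' cosine-squared taper, so every per-phase deformation field is known
#' analytically and is exactly invertible.  `amplitude_mm` is the
#' peak-to-peak tumor excursion.
#'
#' @param shape integer length-3 voxel counts, default `c(64, 64, 64)`.
#' @param spacing_mm grid spacing (mm), default 2.5 (isotropic).
#' @param n_phases number of breathing phases, default 10.
#' @param amplitude_mm peak-to-peak GTV motion, default 8.
#' @param period_s breathing period in seconds, default 4.
#' @param gtv_radius_mm GTV radius, default 10.
#' @param gtv_center_mm GTV (mid-position) center, default inside the
#'   right lung.
#' @param motion_dir unit direction of tumor motion, default craniocaudal.
#' @param phase_weights per-phase time weights (sum 1), default uniform.
#' @param total_setup_mm total non-isotropic setup margin (scalar or
#'   6-vector -x,+x,-y,+y,-z,+z), default 8 mm; split between the
#'   optimizer setup-error parameter and a geometric CTV expansion.
#' @param optimizer_setup_mm isotropic part routed to the optimizer's
#'   setup-error parameter, default 5 mm.
#' @param ctv_margin_mm GTV-to-CTV isotropic margin, default 5 mm.
#' @param edge_sigma_mm density edge smoothing; default `2 * spacing_mm`.
#' @param noise_sd optional i.i.d. Gaussian density noise per phase
#'   (default 0; seeded).
#' @param seed integer seed for the optional noise.
#' @param densities named list of material densities.
#' @param ... overrides merged into the geometry list.
#' @return a named list of phantom parameters.
#' @export
phantom_config <- function(shape = c(64, 64, 64), spacing_mm = 2.5,
                           n_phases = 10, amplitude_mm = 8, period_s = 4,
                           gtv_radius_mm = 10,
                           gtv_center_mm = c(38, 0, 0),
                           motion_dir = c(0, 0, 1),
                           phase_weights = NULL,
                           total_setup_mm = 8, optimizer_setup_mm = 5,
                           ctv_margin_mm = 5,
                           edge_sigma_mm = NULL, noise_sd = 0, seed = 1L,
                           densities = list(air = 0.001, body = 1.0,
                                            lung = 0.26, bone = 1.4,
                                            canal = 1.0, tumor = 1.05),
                           ...) {
  geom <- list(
    body_radii = c(70, 60),                     # elliptic cylinder, z axis
    lung_centers = rbind(c(38, 0, 0), c(-38, 0, 0)),
    lung_radii = c(27, 42, 65),
    heart_center = c(-8, 18, -12), heart_radius = 22,
    eso_center = c(0, -20), eso_radius = 5,     # cylinder along z
    vert_center = c(0, -45), vert_radius = 10,
    canal_radius = 4,
    taper_pad_mm = 1, taper_width_mm = 11
  )
  dots <- list(...)
  geom[names(dots)] <- dots
  if (is.null(edge_sigma_mm)) edge_sigma_mm <- 2 * spacing_mm
  if (is.null(phase_weights)) phase_weights <- rep(1 / n_phases, n_phases)
  list(shape = as.integer(rep_len(shape, 3L)),
       spacing_mm = rep_len(spacing_mm, 3L),
       n_phases = as.integer(n_phases), amplitude_mm = amplitude_mm,
       period_s = period_s, gtv_radius_mm = gtv_radius_mm,
       gtv_center_mm = gtv_center_mm, motion_dir = motion_dir / sqrt(sum(motion_dir^2)),
       phase_weights = phase_weights,
       total_setup_mm = total_setup_mm,
       optimizer_setup_mm = optimizer_setup_mm,
       ctv_margin_mm = ctv_margin_mm,
       edge_sigma_mm = edge_sigma_mm, noise_sd = noise_sd, seed = seed,
       densities = densities, geom = geom)
}

#' 1-cos breathing trajectory offsets relative to the mid position
#'
#' Phase `p` of `P` sits at cycle fraction `p / P`; the raw craniocaudal
#' 1-cos path is `-A/2 * (1 - cos(2*pi*f))`, and offsets are re-centered
#' on the time-weighted mean position so that the weighted mean offset is
#' zero.
#'
#' @param amplitude_mm peak-to-peak excursion.
#' @param n_phases number of phases.
#' @param phase_weights time weights (sum 1).
#' @return numeric vector of per-phase scalar offsets (mm) along the
#'   motion direction.
#' @export
trajectory_offsets <- function(amplitude_mm, n_phases,
                               phase_weights = rep(1 / n_phases, n_phases)) {
  f <- (seq_len(n_phases) - 1) / n_phases
  raw <- -amplitude_mm / 2 * (1 - cos(2 * pi * f))
  raw - sum(phase_weights * raw)
}

## ---- analytic geometry -----------------------------------------------

sd_sphere <- function(pts, c, r) sqrt(rowSums(sweep(pts, 2, c)^2)) - r

sd_ellipsoid <- function(pts, c, radii) {
  u <- sweep(pts, 2, c)
  (sqrt(rowSums(sweep(u, 2, radii, `/`)^2)) - 1) * min(radii)
}

sd_cyl_z <- function(pts, cxy, r) {
  sqrt((pts[, 1] - cxy[1])^2 + (pts[, 2] - cxy[2])^2) - r
}

sd_ellcyl_z <- function(pts, radii) {
  (sqrt((pts[, 1] / radii[1])^2 + (pts[, 2] / radii[2])^2) - 1) * min(radii)
}

# smooth occupancy of a region from its signed distance
occ <- function(sd, sigma) stats::pnorm(-sd / sigma)

# analytic mid-position density at arbitrary points
midp_density_fn <- function(cfg) {
  g <- cfg$geom; dn <- cfg$densities; s <- cfg$edge_sigma_mm
  function(pts) {
    rho <- dn$air + (dn$body - dn$air) * occ(sd_ellcyl_z(pts, g$body_radii), s)
    ol <- pmax(occ(sd_ellipsoid(pts, g$lung_centers[1, ], g$lung_radii), s),
               occ(sd_ellipsoid(pts, g$lung_centers[2, ], g$lung_radii), s))
    rho <- rho + (dn$lung - rho) * ol
    rho <- rho + (dn$bone - rho) * occ(sd_cyl_z(pts, g$vert_center, g$vert_radius), s)
    rho <- rho + (dn$canal - rho) * occ(sd_cyl_z(pts, g$vert_center, g$canal_radius), s)
    rho <- rho + (dn$body - rho) * occ(sd_sphere(pts, g$heart_center, g$heart_radius), s)
    rho <- rho + (dn$body - rho) * occ(sd_cyl_z(pts, g$eso_center, g$eso_radius), s)
    rho + (dn$tumor - rho) * occ(sd_sphere(pts, cfg$gtv_center_mm, cfg$gtv_radius_mm), s)
  }
}

# motion blending weight: 1 on the rigid core around the mid-position GTV
# center, cosine^2 taper to 0 at the outer radius
motion_weight_fn <- function(cfg) {
  r_in <- cfg$gtv_radius_mm + cfg$amplitude_mm / 2 + cfg$geom$taper_pad_mm
  r_out <- r_in + cfg$geom$taper_width_mm
  c0 <- cfg$gtv_center_mm
  function(pts) {
    d <- sqrt(rowSums(sweep(pts, 2, c0)^2))
    w <- numeric(length(d))
    w[d <= r_in] <- 1
    mid <- d > r_in & d < r_out
    w[mid] <- cos(pi / 2 * (d[mid] - r_in) / (r_out - r_in))^2
    w
  }
}

# inverse of the forward motion map T(y) = y + delta * w0(y), by damped
# fixed-point iteration (contraction since |delta| * max|grad w0| < 1)
invert_motion <- function(pts, delta, w0, tol = 1e-10, maxit = 60) {
  y <- pts
  for (i in seq_len(maxit)) {
    ynew <- pts - outer(w0(y), delta)
    if (max(abs(ynew - y)) < tol) { y <- ynew; break }
    y <- ynew
  }
  y
}

#' Build a synthetic 4D breathing thorax phantom
#'
#' Generates `P` breathing-phase density volumes, the exact per-phase
#' deformation fields to and from the time-weighted mid-position (MidP)
#' volume, and the structure set (Body, Lungs, Heart, Esophagus,
#' SpinalCanal, GTV, CTV, CTVexp, Lungs-GTV) on the MidP grid.
#'
#' Phase `p` is the analytic MidP density composed with the inverse of the
#' forward motion map `T_p(y) = y + delta_p * w0(y)`, so
#' `dvf_to_midp[[p]]` (defined on the phase grid, phase -> MidP
#' displacement) is exact, and `dvf_from_midp[[p]]` (MidP grid,
#' MidP -> phase) is the analytic forward field used for pull-back dose
#' warping.
#'
#' @param config a list from [phantom_config()].
#' @return a list with elements `phases` (a `phase_4d` object) and
#'   `structures` (a `structure_set`).
#' @export
build_phantom <- function(config = phantom_config()) {
  cfg <- config
  P <- cfg$n_phases
  if (P < 1) stop("need at least one phase")
  if (cfg$amplitude_mm < 0) stop("amplitude must be >= 0")
  if (abs(sum(cfg$phase_weights) - 1) > 1e-9) stop("phase_weights must sum to 1")

  grid <- voxel_volume(array(0, cfg$shape), cfg$spacing_mm)
  pts <- grid_points(grid)
  offs <- trajectory_offsets(cfg$amplitude_mm, P, cfg$phase_weights)
  delta <- outer(offs, cfg$motion_dir)          # P x 3 offsets from MidP

  ## feasibility: rigid core + taper must stay inside the host lung and
  ## the moving GTV inside the grid at every phase
  r_out <- cfg$gtv_radius_mm + cfg$amplitude_mm / 2 + cfg$geom$taper_pad_mm +
    cfg$geom$taper_width_mm
  dirs <- fib_sphere(120)
  shell <- sweep(dirs * r_out, 2, cfg$gtv_center_mm, `+`)
  in_lung <- pmin(sd_ellipsoid(shell, cfg$geom$lung_centers[1, ], cfg$geom$lung_radii),
                  sd_ellipsoid(shell, cfg$geom$lung_centers[2, ], cfg$geom$lung_radii))
  if (any(in_lung > 0))
    stop("motion amplitude too large: moving GTV region exits the lung")
  lo <- grid$origin; hi <- grid$origin + (dim(grid) - 1) * grid$spacing
  for (p in seq_len(P)) {
    cp <- cfg$gtv_center_mm + delta[p, ]
    if (any(cp - cfg$gtv_radius_mm < lo) || any(cp + cfg$gtv_radius_mm > hi))
      stop("GTV leaves the grid at phase ", p)
  }

  rho <- midp_density_fn(cfg)
  w0 <- motion_weight_fn(cfg)
  midp <- voxel_volume(array(rho(pts), cfg$shape), cfg$spacing_mm, grid$origin)

  near <- sqrt(rowSums(sweep(pts, 2, cfg$gtv_center_mm)^2)) <
    r_out + cfg$amplitude_mm / 2 + 1
  set.seed(cfg$seed)
  phases <- vector("list", P); dvf_to <- vector("list", P); dvf_from <- vector("list", P)
  for (p in seq_len(P)) {
    d <- delta[p, ]
    y <- pts
    if (any(d != 0)) y[near, ] <- invert_motion(pts[near, , drop = FALSE], d, w0)
    vals <- rho(y)
    if (cfg$noise_sd > 0) vals <- vals + stats::rnorm(length(vals), 0, cfg$noise_sd)
    phases[[p]] <- voxel_volume(array(pmax(vals, 0), cfg$shape),
                                cfg$spacing_mm, grid$origin)
    dvf_to[[p]] <- array(y - pts, c(cfg$shape, 3L))           # phase -> MidP
    dvf_from[[p]] <- array(outer(w0(pts), d), c(cfg$shape, 3L)) # MidP -> phase
  }

  p4d <- structure(list(phases = phases, dvf_to_midp = dvf_to,
                        dvf_from_midp = dvf_from,
                        phase_weights = cfg$phase_weights,
                        period = cfg$period_s, midp = midp,
                        motion = list(center = cfg$gtv_center_mm,
                                      delta = delta, r_out = r_out),
                        config = cfg),
                   class = "phase_4d")

  structures <- build_structures(cfg, grid)
  list(phases = p4d, structures = structures)
}

# quasi-uniform directions on the unit sphere (Fibonacci lattice)
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

#' @export
print.phase_4d <- function(x, ...) {
  cat("<phase_4d> ", length(x$phases), " phases, period ", x$period,
      " s, grid ", paste(dim(x$midp$values), collapse = "x"), "\n", sep = "")
  invisible(x)
}

# exact ROI masks on the MidP grid
build_structures <- function(cfg, grid) {
  g <- cfg$geom
  pts <- grid_points(grid)
  shp <- cfg$shape
  msk <- function(v) array(v, shp)
  body <- msk(sd_ellcyl_z(pts, g$body_radii) <= 0)
  lung_r <- msk(sd_ellipsoid(pts, g$lung_centers[1, ], g$lung_radii) <= 0)
  lung_l <- msk(sd_ellipsoid(pts, g$lung_centers[2, ], g$lung_radii) <= 0)
  heart <- msk(sd_sphere(pts, g$heart_center, g$heart_radius) <= 0)
  lung_r <- lung_r & !heart
  lung_l <- lung_l & !heart
  lungs <- lung_r | lung_l
  eso <- msk(sd_cyl_z(pts, g$eso_center, g$eso_radius) <= 0)
  canal <- msk(sd_cyl_z(pts, g$vert_center, g$canal_radius) <= 0)
  gtv <- msk(sd_sphere(pts, cfg$gtv_center_mm, cfg$gtv_radius_mm) <= 0)
  ctv <- expand_isotropic(gtv, cfg$ctv_margin_mm, grid)
  split <- split_margin(margin_spec(cfg$total_setup_mm), cfg$optimizer_setup_mm)
  ctvexp <- expand_anisotropic(ctv, split$geometric, grid)
  rois <- list(Body = body, Lungs = lungs, Lung_L = lung_l, Lung_R = lung_r,
               Heart = heart, Esophagus = eso,
               SpinalCanal = canal, GTV = gtv, CTV = ctv, CTVexp = ctvexp,
               `Lungs-GTV` = lungs & !gtv)
  structure_set(rois, grid, margins = list(total = margin_spec(cfg$total_setup_mm),
                                           split = split))
}

#' Reconstruct the time-weighted mid-position volume from a 4D phase set
#'
#' Each phase density is pulled back to the MidP grid with its deformation
#' field and the results are averaged with the phase time weights.
#'
#' @param p4d a `phase_4d` object.
#' @return a `voxel_volume` on the MidP grid.
#' @export
reconstruct_midp <- function(p4d) {
  if (length(p4d$phases) < 1) stop("empty phase set")
  ref <- p4d$phases[[1]]
  pts <- grid_points(ref)
  acc <- 0
  for (p in seq_along(p4d$phases)) {
    u <- matrix(p4d$dvf_from_midp[[p]], ncol = 3)
    acc <- acc + p4d$phase_weights[p] * interp_volume(p4d$phases[[p]], pts + u)
  }
  voxel_volume(array(acc, dim(ref$values)), ref$spacing, ref$origin)
}

#' Density-weighted centroid of the GTV in a density volume
#'
#' Intended for phantom volumes, where the tumor is the only
#' above-threshold material inside the lung: the centroid is computed on
#' `density - lung` excess over voxels above `threshold`, restricted to a
#' ball around `center` of radius `radius_mm`.
#'
#' @param vol density `voxel_volume`.
#' @param center search-ball center (mm), e.g. the configured GTV center.
#' @param radius_mm search-ball radius.
#' @param threshold density threshold separating tumor from lung.
#' @return length-3 centroid (mm).
#' @export
gtv_centroid <- function(vol, center, radius_mm, threshold = 0.6) {
  pts <- grid_points(vol)
  v <- as.numeric(vol$values)
  sel <- sqrt(rowSums(sweep(pts, 2, center)^2)) <= radius_mm & v >= threshold
  if (!any(sel)) stop("no tumor voxels found in search region")
  w <- v[sel]
  colSums(pts[sel, , drop = FALSE] * w) / sum(w)
}
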