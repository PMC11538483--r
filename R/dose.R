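#' Single-spot dose distribution
#'
#' Dose of one pencil-beam spot on a density grid:
#' `weight * D(WEPL) * exp(-r^2 / (2 sigma(WEPL)^2))`, where `D` is the
#' analytic Bragg curve with range `range_mm * range_scale` and `r` the
#' lateral distance to the (shifted) spot ray.  A positive `setup_shift`
#' displaces the patient; equivalently the spot ray moves by its
#' negative.  Rays that miss the grid give zero dose.
#'
#' @param spot list or one-row data.frame with `gantry_deg`, `bx`, `by`
#'   (lateral beam's-eye-view position, mm), `range_mm`, `weight`.
#' @param density a density `voxel_volume`.
#' @param setup_shift_mm length-3 patient shift, mm.
#' @param range_scale multiplicative range perturbation (> 0), e.g. 1.03
#'   for a +3% range error.
#' @param machine a [machine_config()].
#' @param isocenter length-3 mm, beam isocenter.
#' @param points optional `n x 3` matrix; if given, returns dose values
#'   at those points instead of a full volume.
#' @return a dose `voxel_volume` (Gy-like units), or a numeric vector if
#'   `points` is given.
#' @export
spot_dose <- function(spot, density, setup_shift_mm = c(0, 0, 0),
                      range_scale = 1, machine = machine_config(),
                      isocenter = c(0, 0, 0), points = NULL) {
  if (range_scale <= 0) stop("range_scale must be > 0")
  sm <- spot_rows_matrix(as.data.frame(spot), isocenter, setup_shift_mm)
  dose_from_matrix(sm, density, range_scale, machine, points)
}

# spots data.frame -> engine matrix [ox oy oz ux uy uz range weight]
spot_rows_matrix <- function(spots, isocenter, setup_shift_mm) {
  g <- spots$gantry_deg * pi / 180
  u <- cbind(sin(g), -cos(g), 0)
  b1 <- cbind(cos(g), sin(g), 0)
  o <- matrix(rep(isocenter - setup_shift_mm, each = nrow(spots)), ncol = 3) +
    spots$bx * b1 + cbind(0, 0, spots$by)
  cbind(o, u, spots$range_mm, spots$weight)
}

dose_from_matrix <- function(sm, density, range_scale, machine, points,
                             want_matrix = FALSE) {
  full <- is.null(points)
  if (full) points <- grid_points(density)
  out <- cpp_dose_points(as.numeric(density$values), dim(density$values),
                         density$spacing, density$origin, sm,
                         as.matrix(points), range_scale, dose_pars(machine),
                         want_matrix)
  if (want_matrix || !full) return(out)
  voxel_volume(array(out, dim(density$values)), density$spacing, density$origin)
}

#' Total plan dose under a scenario
#'
#' Superposition of all spot doses (linear in the spot weights) on the
#' scenario's density with its setup shift and range scaling.
#'
#' @param plan a `treatment_plan`.
#' @param density density `voxel_volume` (the scenario's phase).
#' @param scenario one row of an [enumerate_scenarios()] grid, or `NULL`
#'   for nominal geometry.
#' @param machine a [machine_config()]; defaults to the plan's.
#' @param points optional evaluation points (`n x 3` mm).
#' @param weights optional spot-weight override.
#' @return dose `voxel_volume`, or numeric vector if `points` is given.
#' @export
compute_dose <- function(plan, density, scenario = NULL,
                         machine = plan$machine, points = NULL,
                         weights = NULL) {
  shift <- c(0, 0, 0); rs <- 1
  if (!is.null(scenario)) {
    shift <- c(scenario$shift_x, scenario$shift_y, scenario$shift_z)
    rs <- scenario$range_scale
  }
  if (rs <= 0) stop("range_scale must be > 0")
  spots <- plan$spots
  if (!is.null(weights)) spots$weight <- weights
  sm <- spot_rows_matrix(spots, plan$isocenter, shift)
  dose_from_matrix(sm, density, rs, machine, points)
}

#' Dose-influence matrix at evaluation points
#'
#' Per-spot unit-weight dose at each point (`n_points x n_spots`), so
#' that `D %*% w` is the plan dose — the standard linear model used by
#' the robust optimizer.
#'
#' @inheritParams compute_dose
#' @param points `n x 3` matrix of evaluation points (mm).
#' @return dense numeric matrix.
#' @export
dose_influence <- function(plan, density, points, scenario = NULL,
                           machine = plan$machine) {
  shift <- c(0, 0, 0); rs <- 1
  if (!is.null(scenario)) {
    shift <- c(scenario$shift_x, scenario$shift_y, scenario$shift_z)
    rs <- scenario$range_scale
  }
  sm <- spot_rows_matrix(plan$spots, plan$isocenter, shift)
  dose_from_matrix(sm, density, rs, machine, points, want_matrix = TRUE)
}

#' Density volume of a scenario phase
#'
#' Phase index 0 denotes the mid-position reference volume; indices
#' `1..P` the breathing phases.
#'
#' @param p4d a `phase_4d`.
#' @param phase integer phase index (0 = MidP).
#' @return a density `voxel_volume`.
#' @export
phase_density <- function(p4d, phase) {
  if (phase == 0) return(p4d$midp)
  if (phase < 0 || phase > length(p4d$phases))
    stop("phase index outside the 4D set")
  p4d$phases[[phase]]
}

#' Map mid-position points into a breathing phase
#'
#' Applies the analytic MidP-to-phase deformation so that structures
#' delineated on the MidP grid follow the tumor in each phase (the exact
#' counterpart of contour propagation).  Phase 0 is the identity.
#'
#' @inheritParams phase_density
#' @param pts `n x 3` MidP coordinates (mm).
#' @return `n x 3` phase coordinates (mm).
#' @export
phase_points <- function(p4d, phase, pts) {
  if (phase == 0) return(pts)
  if (phase < 0 || phase > length(p4d$phases))
    stop("phase index outside the 4D set")
  ref <- p4d$midp
  u <- vapply(1:3, function(a)
    cpp_trilinear(as.numeric(p4d$dvf_from_midp[[phase]][, , , a]),
                  dim(ref$values), ref$spacing, ref$origin, as.matrix(pts)),
    numeric(nrow(pts)))
  pts + u
}
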