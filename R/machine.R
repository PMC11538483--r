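#' Machine / beam model configuration
#'
#' All physical and timing constants of the simplified pencil-beam engine
#' and the delivery-time models.  The defaults are generic surrogate
#' values for a modern 360-degree PBS gantry; none are vendor
#' measurements, and every one can be overridden (or loaded from YAML via
#' [read_machine()]).
#'
#' Geometry: gantry angle `g` (degrees) rotates in the axial (x, y) plane
#' about the craniocaudal z axis; the beam axis unit vector is
#' `(sin g, -cos g, 0)` (at `g = 0` the beam travels from anterior +y
#' towards -y), with lateral beam's-eye-view axes
#' `b1 = (cos g, sin g, 0)` and `b2 = (0, 0, 1)`.  Rays are parallel
#' (infinite source-axis distance).
#'
#' Depth dose: an analytic Bragg-like curve whose nominal range is the
#' distal 80% falloff point (see [bragg_curve()]).  Lateral profile: a
#' Gaussian whose sigma grows linearly with WEPL depth.
#'
#' @param ... overrides of the default fields:
#'   `ranges_mm` (energy table as nominal ranges, mm water-equivalent),
#'   `p0` (entrance-to-peak dose ratio), `dist_sigma_frac`,
#'   `dist_sigma_min` (distal falloff width, fraction of range + mm),
#'   `prox_ratio` (proximal/distal width ratio), `sigma0` (lateral sigma
#'   at surface, mm), `sigma_slope` (mm sigma per mm WEPL), `step_mm`
#'   (ray-marching step), `lateral_cutoff` (Gaussian truncation, sigmas),
#'   `mu_rate` (weight units per second), `spot_switch_s`,
#'   `energy_down_s`, `energy_up_s` (layer switching times),
#'   `gantry_speed_dps` (deg/s), `couch_overhead_s` (fixed per IMPT beam
#'   transition).
#' @return a named list of machine parameters.
#' @export
machine_config <- function(...) {
  m <- list(
    ranges_mm = seq(10, 320, by = 2),
    p0 = 0.35, dist_sigma_frac = 0.01, dist_sigma_min = 0.5, prox_ratio = 6,
    sigma0 = 5, sigma_slope = 0.03, step_mm = 1, lateral_cutoff = 4.5,
    mu_rate = 50, spot_switch_s = 0.002,
    energy_down_s = 0.6, energy_up_s = 5,
    gantry_speed_dps = 6, couch_overhead_s = 20
  )
  dots <- list(...)
  m[names(dots)] <- dots
  m
}

#' @rdname machine_config
#' @param path YAML file with machine fields.
#' @export
read_machine <- function(path) do.call(machine_config, yaml::read_yaml(path))

#' Analytic Bragg-like depth-dose curve
#'
#' Entrance plateau (`p0` of the peak) blended into a Gaussian peak with
#' an asymmetric, sharper distal side; the nominal range `R` is defined
#' as the distal 80% falloff depth.  This is a desk-scale surrogate for a
#' measured pristine Bragg curve, not a transport calculation.
#'
#' @param z depth, mm water-equivalent (vector).
#' @param range_mm nominal range `R`, mm.
#' @param machine a [machine_config()] list (Bragg shape parameters).
#' @return relative dose (1 at the peak).
#' @export
bragg_curve <- function(z, range_mm, machine = machine_config()) {
  cpp_bragg(as.numeric(z), range_mm,
            machine[c("p0", "dist_sigma_frac", "dist_sigma_min", "prox_ratio")])
}

# beam's-eye-view frame for a gantry angle (degrees)
beam_frame <- function(gantry_deg) {
  g <- gantry_deg * pi / 180
  list(u = c(sin(g), -cos(g), 0),
       b1 = c(cos(g), sin(g), 0),
       b2 = c(0, 0, 1))
}

dose_pars <- function(machine) {
  machine[c("p0", "dist_sigma_frac", "dist_sigma_min", "prox_ratio",
            "sigma0", "sigma_slope", "step_mm", "lateral_cutoff")]
}

#' Water-equivalent path length at points along a beam direction
#'
#' Integrates relative density from the grid entry to each point along
#' the given direction (trapezoidal rule on a fixed marching step).
#'
#' @param density a density `voxel_volume`.
#' @param gantry_deg gantry angle, degrees.
#' @param pts `n x 3` matrix of mm coordinates.
#' @param machine a [machine_config()] (for `step_mm`).
#' @return WEPL in mm at each point.
#' @export
wepl_at <- function(density, gantry_deg, pts, machine = machine_config()) {
  u <- beam_frame(gantry_deg)$u
  cpp_wepl_points(as.numeric(density$values), dim(density$values),
                  density$spacing, density$origin, u, as.matrix(pts),
                  machine$step_mm)
}
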