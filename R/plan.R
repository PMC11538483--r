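#' Treatment plan container
#'
#' A plan holds its modality, spot table, prescription and machine
#' reference.  Spots are rows of `(gantry_deg, bx, by, range_mm,
#' weight)`; an energy layer is the set of spots sharing one gantry angle
#' and one range.  Invariants enforced here: nonnegative weights, ranges
#' within the machine table; PAT plans additionally must be a single
#' revolution with gantry spacing in [1, 2] degrees and exactly one
#' energy layer per direction.
#'
#' @param modality `"IMPT"` or `"PAT"`.
#' @param spots data.frame with columns `gantry_deg`, `bx`, `by`,
#'   `range_mm`, `weight`.
#' @param isocenter length-3 mm.
#' @param prescription_gy total prescription dose, default 60.
#' @param fractions fraction count, default 30.
#' @param machine a [machine_config()].
#' @param beam_angles IMPT beam gantry angles.
#' @param arc PAT arc description `list(start, stop, spacing)` degrees.
#' @param allow_spacing_override skip the [1, 2] degree spacing check.
#' @return a `treatment_plan`.
#' @export
treatment_plan <- function(modality, spots, isocenter,
                           prescription_gy = 60, fractions = 30,
                           machine = machine_config(),
                           beam_angles = NULL, arc = NULL,
                           allow_spacing_override = FALSE) {
  modality <- match.arg(modality, c("IMPT", "PAT"))
  need <- c("gantry_deg", "bx", "by", "range_mm", "weight")
  if (!all(need %in% names(spots))) stop("spot table must have columns: ",
                                         paste(need, collapse = ", "))
  if (any(spots$weight < 0)) stop("spot weights must be >= 0")
  if (nrow(spots) &&
      (min(spots$range_mm) < min(machine$ranges_mm) - 1e-9 ||
       max(spots$range_mm) > max(machine$ranges_mm) + 1e-9))
    stop("spot range outside the machine energy table")
  if (modality == "PAT") {
    if (is.null(arc)) stop("PAT plans need an arc description")
    if (!allow_spacing_override &&
        (arc$spacing < 1 || arc$spacing > 2))
      stop("arc gantry spacing must be within [1, 2] degrees")
    if (abs((arc$stop - arc$start) + arc$spacing - 360) > 1e-6 &&
        abs(arc$stop - arc$start) > 360)
      stop("PAT arc must span exactly one revolution")
    npd <- tapply(spots$range_mm, spots$gantry_deg,
                  function(r) length(unique(r)))
    if (nrow(spots) && any(npd != 1))
      stop("PAT plans must carry exactly one energy layer per direction")
  } else {
    if (is.null(beam_angles)) beam_angles <- sort(unique(spots$gantry_deg))
  }
  structure(list(modality = modality, spots = spots, isocenter = isocenter,
                 prescription_gy = prescription_gy, fractions = fractions,
                 machine = machine, beam_angles = beam_angles, arc = arc),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  nl <- nrow(unique(x$spots[c("gantry_deg", "range_mm")]))
  cat("<treatment_plan> ", x$modality, ": ",
      length(unique(x$spots$gantry_deg)), " directions, ", nl,
      " energy layers, ", nrow(x$spots), " spots; ",
      x$prescription_gy, " Gy / ", x$fractions, " fx\n", sep = "")
  invisible(x)
}

#' Energy layers of a plan
#' @param plan a `treatment_plan`.
#' @return data.frame of unique `(gantry_deg, range_mm)` with spot counts.
#' @export
energy_layers <- function(plan) {
  ag <- stats::aggregate(weight ~ gantry_deg + range_mm, plan$spots, length)
  names(ag)[3] <- "n_spots"
  ag[order(ag$gantry_deg, -ag$range_mm), ]
}

# lateral spot positions covering the BEV projection of target points
lateral_grid <- function(proj, spacing, margin) {
  gx <- seq(min(proj[, 1]) - margin, max(proj[, 1]) + margin, by = spacing)
  gy <- seq(min(proj[, 2]) - margin, max(proj[, 2]) + margin, by = spacing)
  unname(as.matrix(expand.grid(bx = gx, by = gy)))
}

#' Place spots for a 3-beam IMPT plan
#'
#' For each beam: energy layers cover the water-equivalent depth extent
#' of the expanded CTV (plus margins) in steps of `layer_spacing_mm`
#' snapped to the machine energy table, and spots sit on a rectangular
#' lateral grid covering the target's beam's-eye-view projection.  A
#' spot (position, layer) is kept when some target voxel projects within
#' one grid step laterally and its depth interval reaches the layer.
#'
#' @param structures a `structure_set` (needs `CTVexp`).
#' @param density planning (MidP) density `voxel_volume`.
#' @param beams gantry angles in degrees, default three beams.
#' @param machine a [machine_config()].
#' @param isocenter beam isocenter; default the CTVexp centroid.
#' @param spot_spacing_mm lateral grid step, default the spot sigma.
#' @param layer_spacing_mm energy layer spacing in WEPL, default 5.
#' @param lateral_margin_mm extra lateral coverage, default 5.
#' @param range_margin_mm extra proximal/distal WEPL coverage, default 2.
#' @param prescription_gy,fractions passed to [treatment_plan()].
#' @return an IMPT `treatment_plan` with uniform unit weights.
#' @export
place_spots_impt <- function(structures, density, beams = c(225, 270, 315),
                             machine = machine_config(), isocenter = NULL,
                             spot_spacing_mm = machine$sigma0,
                             layer_spacing_mm = 5, lateral_margin_mm = 5,
                             range_margin_mm = 2,
                             prescription_gy = 60, fractions = 30) {
  tgt <- roi_mask(structures, "CTVexp")
  if (!any(tgt)) stop("CTVexp is empty")
  pts <- mask_points(structures$grid, tgt)
  if (is.null(isocenter)) isocenter <- colMeans(pts)
  spots <- NULL
  for (g in beams) {
    sp <- beam_spots_one_direction(g, pts, density, machine, isocenter,
                                   spot_spacing_mm, layer_spacing_mm,
                                   lateral_margin_mm, range_margin_mm)
    spots <- rbind(spots, sp)
  }
  if (is.null(spots) || !nrow(spots))
    stop("target is not reachable by any configured beam")
  treatment_plan("IMPT", spots, isocenter, prescription_gy, fractions,
                 machine, beam_angles = beams)
}

beam_spots_one_direction <- function(g, pts, density, machine, isocenter,
                                     spot_spacing, layer_spacing,
                                     lateral_margin, range_margin,
                                     layers = NULL, depth_tol = NULL) {
  fr <- beam_frame(g)
  rel <- sweep(pts, 2, isocenter)
  proj <- cbind(rel %*% fr$b1, rel %*% fr$b2)
  w <- wepl_at(density, g, pts, machine)
  if (is.null(layers)) {
    wlo <- max(min(w) - range_margin, min(machine$ranges_mm))
    whi <- max(max(w) + range_margin, wlo)
    layers <- unique(vapply(seq(wlo, whi, by = layer_spacing),
                            function(x) machine$ranges_mm[which.min(abs(machine$ranges_mm - x))],
                            numeric(1)))
  }
  if (is.null(depth_tol)) depth_tol <- layer_spacing
  grid <- lateral_grid(proj, spot_spacing, lateral_margin)
  # association window: at least the voxel half-diagonal, so coarse grids
  # cannot leave uncovered lateral positions
  win <- max(spot_spacing, 0.87 * max(density$spacing))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    nearby <- abs(proj[, 1] - grid[i, 1]) <= win &
      abs(proj[, 2] - grid[i, 2]) <= win
    if (!any(nearby)) next
    wr <- range(w[nearby])
    keep <- layers >= wr[1] - depth_tol & layers <= wr[2] + depth_tol
    if (!any(keep)) next
    out[[i]] <- data.frame(gantry_deg = g, bx = grid[i, 1], by = grid[i, 2],
                           range_mm = layers[keep], weight = 1)
  }
  do.call(rbind, out)
}

#' Place spots for a one-revolution arc plan (single layer per direction)
#'
#' Gantry directions step through one revolution at 1-2 degree spacing.
#' Per direction one energy layer is chosen geometrically: the energy
#' whose Bragg peak sits at the mid water-equivalent depth of the
#' expanded CTV along that direction, subject to a bounded energy step
#' between consecutive directions, snapped to the machine table.  This
#' honors the contract of early energy-layer-and-spot assignment (one
#' geometry-driven layer per direction) without reproducing any
#' proprietary selection algorithm.  Directions whose entry path crosses
#' the avoidance ROI carry no spots.
#'
#' @inheritParams place_spots_impt
#' @param arc `list(start, stop, spacing)` in degrees; default a full
#'   revolution at 2 degrees.
#' @param avoid_roi optional ROI name (e.g. contralateral lung) to avoid
#'   on the entry path.
#' @param max_energy_step_mm bound on the range change between adjacent
#'   directions, default 10 mm.
#' @param depth_tol_mm spots are kept where the target depth interval is
#'   within this WEPL distance of the layer, default 8.
#' @param allow_spacing_override permit spacing outside [1, 2] degrees.
#' @return a PAT `treatment_plan` with uniform unit weights.
#' @export
place_spots_pat_elsa <- function(structures, density,
                                 arc = list(start = 0, stop = 358, spacing = 2),
                                 machine = machine_config(), isocenter = NULL,
                                 avoid_roi = NULL,
                                 spot_spacing_mm = machine$sigma0,
                                 lateral_margin_mm = 5,
                                 max_energy_step_mm = 10, depth_tol_mm = 8,
                                 prescription_gy = 60, fractions = 30,
                                 allow_spacing_override = FALSE) {
  if (!allow_spacing_override && (arc$spacing < 1 || arc$spacing > 2))
    stop("arc gantry spacing must be within [1, 2] degrees")
  tgt <- roi_mask(structures, "CTVexp")
  if (!any(tgt)) stop("CTVexp is empty")
  pts <- mask_points(structures$grid, tgt)
  if (is.null(isocenter)) isocenter <- colMeans(pts)
  dirs <- seq(arc$start, arc$stop, by = arc$spacing)
  avoid <- if (!is.null(avoid_roi)) roi_mask(structures, avoid_roi)
  spots <- NULL
  prevR <- NA
  for (g in dirs) {
    if (!is.null(avoid) &&
        entry_crosses(g, isocenter, pts, avoid, structures$grid)) next
    w <- wepl_at(density, g, pts, machine)
    R <- (min(w) + max(w)) / 2
    if (!is.na(prevR))
      R <- prevR + max(-max_energy_step_mm, min(max_energy_step_mm, R - prevR))
    R <- machine$ranges_mm[which.min(abs(machine$ranges_mm - R))]
    prevR <- R
    sp <- beam_spots_one_direction(g, pts, density, machine, isocenter,
                                   spot_spacing_mm, NA, lateral_margin_mm,
                                   NA, layers = R, depth_tol = depth_tol_mm)
    spots <- rbind(spots, sp)
  }
  if (is.null(spots) || !nrow(spots))
    stop("target is not reachable from any arc direction")
  treatment_plan("PAT", spots, isocenter, prescription_gy, fractions,
                 machine, arc = arc,
                 allow_spacing_override = allow_spacing_override)
}

# does the entry path (upstream of the target's proximal edge) cross an
# avoidance ROI?
entry_crosses <- function(g, isocenter, target_pts, avoid_mask, grid) {
  fr <- beam_frame(g)
  tmin <- min(sweep(target_pts, 2, isocenter) %*% fr$u)
  ts <- seq(tmin - 400, tmin - 1, by = 2)
  line <- matrix(rep(isocenter, each = length(ts)), ncol = 3) + ts %*% t(fr$u)
  any(cpp_trilinear(as.numeric(avoid_mask), dim(avoid_mask),
                    grid$spacing, grid$origin, line) > 0.5)
}

#' Normalize a plan to a target DVH point
#'
#' Scales all spot weights by one global factor so that the target ROI's
#' D(percent)% equals `value_gy` exactly (dose is linear in the weights,
#' so a single exact rescaling suffices).
#'
#' @param plan a `treatment_plan`.
#' @param dose dose values at the target ROI voxels, or a dose
#'   `voxel_volume` plus `target_mask`.
#' @param target_mask logical array selecting the target ROI (needed
#'   when `dose` is a volume).
#' @param percent DVH percentage point, default 50.
#' @param value_gy target dose, default 60.
#' @return the plan with rescaled weights; the factor is stored in
#'   `plan$normalization`.
#' @export
normalize_plan <- function(plan, dose, target_mask = NULL, percent = 50,
                           value_gy = 60) {
  dv <- if (inherits(dose, "voxel_volume")) {
    if (is.null(target_mask)) stop("target_mask needed with a dose volume")
    dose$values[target_mask]
  } else as.numeric(dose)
  if (!length(dv)) stop("target ROI is empty")
  cur <- dvh_metric(dvh_curve(dv, 1), sprintf("D%g%%", percent))
  if (cur <= 0) stop("target D", percent, "% is zero; cannot normalize")
  f <- value_gy / cur
  plan$spots$weight <- plan$spots$weight * f
  plan$normalization <- list(percent = percent, value_gy = value_gy, factor = f)
  plan
}

#' Write / read a plan as JSON
#'
#' The JSON dialect stores modality, prescription, isocenter, arc or
#' beam list, the machine parameters and the flat spot table.
#'
#' @param plan a `treatment_plan`.
#' @param path output path.
#' @export
write_plan <- function(plan, path) {
  obj <- unclass(plan)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  treatment_plan(o$modality, as.data.frame(o$spots), unlist(o$isocenter),
                 o$prescription_gy, o$fractions, o$machine,
                 beam_angles = o$beam_angles, arc = o$arc,
                 allow_spacing_override = TRUE)
}
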