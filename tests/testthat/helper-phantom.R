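# shared small phantoms, built once per test run

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# coarse moving phantom: 32^3 at 5 mm, 4 phases, 6 mm motion
coarse_phantom <- function() {
  cached("coarse", build_phantom(phantom_config(
    shape = c(32, 32, 32), spacing_mm = 5, n_phases = 4, amplitude_mm = 6)))
}

# static phantom (zero amplitude), 10 phases
static_phantom <- function() {
  cached("static", build_phantom(phantom_config(
    shape = c(32, 32, 32), spacing_mm = 5, n_phases = 10, amplitude_mm = 0)))
}

# small water box for engine-level tests
water_box <- function(n = c(21, 120, 21), spacing = c(2, 1, 2)) {
  voxel_volume(array(1, n), spacing)
}

# quick IMPT plan on a phantom, optionally optimized on a tiny scenario set
coarse_impt_plan <- function(optimized = TRUE) {
  key <- paste0("impt", optimized)
  cached(key, {
    ph <- coarse_phantom()
    plan <- place_spots_impt(ph$structures, ph$phases$midp)
    if (optimized) {
      scen <- enumerate_scenarios(5, 0.03, 0)
      plan <- optimize_minimax(plan, default_objectives(60), scen,
                               ph$phases, ph$structures,
                               temperatures = c(50, 500), maxit = 40)
    }
    pts <- mask_points(ph$structures$grid, roi_mask(ph$structures, "CTV"))
    normalize_plan(plan, compute_dose(plan, ph$phases$midp, points = pts))
  })
}

# unoptimized, normalized plan on the static phantom
static_impt_plan <- function() {
  cached("static_plan", {
    ph <- static_phantom()
    p <- place_spots_impt(ph$structures, ph$phases$midp)
    pts <- mask_points(ph$structures$grid, roi_mask(ph$structures, "CTV"))
    normalize_plan(p, compute_dose(p, ph$phases$midp, points = pts))
  })
}

coarse_pat_plan <- function() {
  cached("pat", {
    ph <- coarse_phantom()
    plan <- place_spots_pat_elsa(ph$structures, ph$phases$midp)
    pts <- mask_points(ph$structures$grid, roi_mask(ph$structures, "CTV"))
    normalize_plan(plan, compute_dose(plan, ph$phases$midp, points = pts))
  })
}
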