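#' Enumerate the setup x range x phase scenario grid
#'
#' Setup scenarios are the nominal (zero) shift plus the six axis-aligned
#' directions, each at that direction's configured magnitude; range
#' scenarios are `{1 - r, 1, 1 + r}`; phases are given as indices into
#' the 4D set (0 = mid-position reference).  With a 5 mm setup error, 3%
#' range error and four phases this yields the 84-scenario grid
#' `7 x 3 x 4` used for both robust optimization and robustness
#' evaluation.
#'
#' @param setup_mm scalar isotropic setup error, or a [margin_spec()]
#'   (6 directional magnitudes, mm).  0 collapses to the nominal shift.
#' @param range_pct fractional range error (e.g. 0.03); 0 collapses to
#'   the nominal scale.
#' @param phases integer vector of phase indices (0 = MidP).
#' @return data.frame with one row per scenario: `id`, `shift_x/y/z`,
#'   `range_scale`, `phase`, `nominal_geometry` (zero shift, scale 1)
#'   and `is_nominal` (nominal geometry on the first listed phase).
#' @export
enumerate_scenarios <- function(setup_mm, range_pct, phases) {
  if (length(phases) < 1) stop("at least one phase is required")
  if (range_pct < 0 || range_pct >= 1) stop("range_pct must be in [0, 1)")
  m <- unclass(margin_spec(setup_mm))
  if (any(m < 0)) stop("setup_mm must be >= 0")
  shifts <- rbind(c(0, 0, 0),
                  c(-m[1], 0, 0), c(m[2], 0, 0),
                  c(0, -m[3], 0), c(0, m[4], 0),
                  c(0, 0, -m[5]), c(0, 0, m[6]))
  shifts <- unique(shifts)
  scales <- sort(unique(c(1 - range_pct, 1, 1 + range_pct)))
  g <- expand.grid(shift = seq_len(nrow(shifts)), scale = scales,
                   phase = phases)
  out <- data.frame(id = seq_len(nrow(g)),
                    shift_x = shifts[g$shift, 1],
                    shift_y = shifts[g$shift, 2],
                    shift_z = shifts[g$shift, 3],
                    range_scale = g$scale, phase = g$phase)
  out$nominal_geometry <- out$shift_x == 0 & out$shift_y == 0 &
    out$shift_z == 0 & out$range_scale == 1
  out$is_nominal <- out$nominal_geometry & out$phase == phases[1]
  out
}

#' Evaluate a plan's DVHs over a scenario grid
#'
#' For each scenario, the plan dose is computed on the scenario's phase
#' density with its setup shift and range scaling, at the evaluation
#' ROI's voxels mapped into that phase by the exact deformation field
#' (the phantom counterpart of contour propagation).  The evaluation ROI
#' defaults to the raw CTV even when optimization used the expanded CTV.
#'
#' @param plan a normalized `treatment_plan`.
#' @param scenarios data.frame from [enumerate_scenarios()].
#' @param phases a `phase_4d`.
#' @param structures a `structure_set`.
#' @param rois ROI names to evaluate, default `"CTV"`.
#' @param machine a [machine_config()].
#' @return data.frame with the scenario columns plus `roi` and a
#'   list-column `dvh` of [dvh_curve()] objects.
#' @export
evaluate_scenarios <- function(plan, scenarios, phases, structures,
                               rois = "CTV", machine = plan$machine) {
  vcc <- voxel_cc(structures$grid)
  pts0 <- lapply(rois, function(r) mask_points(structures$grid,
                                               roi_mask(structures, r)))
  names(pts0) <- rois
  rows <- list(); k <- 0
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    dens <- phase_density(phases, sc$phase)
    for (r in rois) {
      pts <- phase_points(phases, sc$phase, pts0[[r]])
      d <- compute_dose(plan, dens, sc, machine, points = pts)
      k <- k + 1
      rows[[k]] <- cbind(sc, data.frame(roi = r))
      rows[[k]]$dvh <- list(dvh_curve(d, vcc, roi = r))
    }
  }
  do.call(rbind, rows)
}

#' Default clinical goal table for lung planning
#'
#' Target coverage and OAR limits: CTV D98% >= 57 Gy (worst case D95% >=
#' 57 Gy) and D1% < 63 Gy; esophagus and heart D0.04cc < 60 Gy; heart
#' and healthy lung mean dose < 20 Gy; lung V30Gy < 20%; spinal canal
#' D0.04cc < 50 Gy and body D1cc < 63 Gy in both nominal and worst case.
#'
#' @return data.frame with columns `roi`, `metric`, `op` (`">="` or
#'   `"<"`), `limit`, `scope` (`nominal`, `worst` or `both`).
#' @export
default_clinical_goals <- function() {
  data.frame(
    roi = c("CTV", "CTV", "CTV", "Esophagus", "Heart", "Heart",
            "Lungs-GTV", "Lungs-GTV", "SpinalCanal", "Body"),
    metric = c("D98%", "D95%", "D1%", "D0.04cc", "Dmean", "D0.04cc",
               "Dmean", "V30Gy", "D0.04cc", "D1cc"),
    op = c(">=", ">=", "<", "<", "<", "<", "<", "<", "<", "<"),
    limit = c(57, 57, 63, 60, 20, 60, 20, 20, 50, 63),
    scope = c("nominal", "worst", "nominal", "nominal", "nominal",
              "nominal", "nominal", "nominal", "both", "both"),
    stringsAsFactors = FALSE
  )
}

#' Nominal and worst-case metrics against clinical goals
#'
#' The worst case is taken per metric across all scenarios (minimum for
#' `>=` goals, maximum for `<` goals), the standard composite worst-case
#' convention of TPS robustness evaluation; the nominal value comes from
#' the nominal scenario.  Goals scoped `nominal` are judged on the
#' nominal value only, `worst` on the worst value, `both` on each.
#'
#' @param table output of [evaluate_scenarios()].
#' @param goals data.frame as [default_clinical_goals()].
#' @return data.frame: `roi`, `metric`, `op`, `limit`, `scope`,
#'   `nominal`, `worst`, `pass`.
#' @export
worst_case_metrics <- function(table, goals = default_clinical_goals()) {
  if (!nrow(table)) stop("empty scenario table")
  if (!all(goals$op %in% c(">=", "<")))
    stop("unknown goal operator: ", paste(setdiff(goals$op, c(">=", "<")),
                                          collapse = ", "))
  out <- goals
  out$nominal <- out$worst <- NA_real_
  out$pass <- NA
  for (i in seq_len(nrow(goals))) {
    g <- goals[i, ]
    rows <- table[table$roi == g$roi, ]
    if (!nrow(rows)) stop("ROI not present in scenario table: ", g$roi)
    vals <- vapply(rows$dvh, dvh_metric, numeric(1), query = g$metric)
    nomv <- vals[rows$is_nominal]
    nom <- if (length(nomv)) nomv[1] else vals[which(rows$nominal_geometry)[1]]
    worst <- if (g$op == ">=") min(vals) else max(vals)
    cmp <- function(v) if (g$op == ">=") v >= g$limit else v < g$limit
    out$nominal[i] <- nom
    out$worst[i] <- worst
    out$pass[i] <- switch(g$scope,
                          nominal = cmp(nom),
                          worst = cmp(worst),
                          both = cmp(nom) && cmp(worst),
                          stop("unknown goal scope: ", g$scope))
  }
  out
}
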