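#' Objective set for robust spot-weight optimization
#'
#' Each term is a quadratic one-sided penalty on an ROI's dose,
#' normalized by the squared dose level so terms are comparable:
#' * `min_dose`: `mean(pmax(level - d, 0)^2) / level^2`
#' * `max_dose`: `mean(pmax(d - level, 0)^2) / level^2`
#' * `max_mean`: `pmax(mean(d) - level, 0)^2 / level^2`
#'
#' Terms flagged `robust` enter the worst-case composite and are
#' evaluated under every scenario; non-robust terms are evaluated on the
#' nominal scenario only.  Robust terms conventionally reference the
#' expanded CTV.
#'
#' @param terms data.frame with columns `roi`, `type`, `level_gy`,
#'   `weight`, `robust`.
#' @return an `objective_set`.
#' @export
objective_set <- function(terms) {
  stopifnot(all(c("roi", "type", "level_gy", "weight", "robust") %in%
                  names(terms)))
  if (any(terms$weight < 0)) stop("objective weights must be >= 0")
  if (!all(terms$type %in% c("min_dose", "max_dose", "max_mean")))
    stop("unknown objective type")
  structure(terms, class = c("objective_set", "data.frame"))
}

#' @rdname objective_set
#' @param prescription_gy prescription dose for the default trade-off
#'   set (target coverage on CTVexp, OAR sparing mirroring the clinical
#'   goals).
#' @export
default_objectives <- function(prescription_gy = 60) {
  objective_set(data.frame(
    roi = c("CTVexp", "CTVexp", "Heart", "Lungs-GTV", "Esophagus",
            "SpinalCanal", "Body"),
    type = c("min_dose", "max_dose", "max_mean", "max_mean", "max_dose",
             "max_dose", "max_dose"),
    level_gy = c(prescription_gy, 1.05 * prescription_gy, 20, 20, 60, 50,
                 1.05 * prescription_gy),
    weight = c(100, 50, 2, 2, 2, 5, 1),
    robust = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  ))
}

# penalty value and d-gradient for one term at dose vector d
term_value <- function(type, d, L) {
  switch(type,
         min_dose = mean(pmax(L - d, 0)^2) / L^2,
         max_dose = mean(pmax(d - L, 0)^2) / L^2,
         max_mean = max(mean(d) - L, 0)^2 / L^2)
}

term_grad <- function(type, d, L) {
  n <- length(d)
  switch(type,
         min_dose = -2 * pmax(L - d, 0) / (n * L^2),
         max_dose = 2 * pmax(d - L, 0) / (n * L^2),
         max_mean = rep(2 * max(mean(d) - L, 0) / (n * L^2), n))
}

#' Worst-case minimax robust optimization of spot weights
#'
#' Minimizes, over nonnegative spot weights, the worst-case (maximum
#' over scenarios) weighted sum of the robust objective terms, plus the
#' non-robust terms evaluated on the nominal scenario.  The max is
#' smoothed by log-sum-exp with an increasing temperature schedule and
#' each stage is solved by bound-constrained L-BFGS-B with analytic
#' gradients on precomputed per-scenario dose-influence matrices.  Ties
#' between equally bad scenarios are resolved by the fixed scenario
#' ordering.  With a single scenario the composite reduces exactly to
#' ordinary (non-robust) optimization.
#'
#' @param plan a `treatment_plan` (initial weights are the start point).
#' @param objectives an [objective_set()].
#' @param scenarios data.frame from [enumerate_scenarios()].
#' @param phases a `phase_4d`.
#' @param structures a `structure_set`.
#' @param machine a [machine_config()].
#' @param max_roi_voxels subsample cap per ROI (deterministic strided
#'   subsampling), default 1500.
#' @param temperatures log-sum-exp temperature schedule.
#' @param maxit L-BFGS-B iterations per stage.
#' @return the plan with optimized weights; diagnostics (worst-case and
#'   nominal composite objective, per-scenario values, convergence) in
#'   `plan$optimization`.
#' @export
optimize_minimax <- function(plan, objectives, scenarios, phases,
                             structures, machine = plan$machine,
                             max_roi_voxels = 1500,
                             temperatures = c(10, 100, 1000), maxit = 60) {
  if (!nrow(scenarios)) stop("at least one scenario is required")
  obj <- as.data.frame(objectives)
  rob <- obj[obj$robust, , drop = FALSE]
  nom <- obj[!obj$robust, , drop = FALSE]
  nomsc <- scenarios[which(scenarios$is_nominal)[1], ]
  if (!nrow(nomsc) || is.na(nomsc$id[1]))
    nomsc <- scenarios[which(scenarios$nominal_geometry)[1], ]
  if (is.na(nomsc$id[1])) nomsc <- scenarios[1, ]

  roi_pts <- function(name) {
    pts <- mask_points(structures$grid, roi_mask(structures, name))
    if (nrow(pts) > max_roi_voxels)
      pts <- pts[seq(1, nrow(pts), length.out = max_roi_voxels), , drop = FALSE]
    pts
  }
  rob_pts <- lapply(unique(rob$roi), roi_pts)
  names(rob_pts) <- unique(rob$roi)
  nom_pts <- lapply(unique(nom$roi), roi_pts)
  names(nom_pts) <- unique(nom$roi)

  # per-scenario influence for robust ROIs (points follow the phase
  # deformation); nominal-scenario influence for the non-robust ROIs
  infl <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    dens <- phase_density(phases, sc$phase)
    infl[[i]] <- lapply(rob_pts, function(p)
      dose_influence(plan, dens, phase_points(phases, sc$phase, p), sc, machine))
  }
  dens_nom <- phase_density(phases, nomsc$phase)
  infl_nom <- lapply(nom_pts, function(p)
    dose_influence(plan, dens_nom, phase_points(phases, nomsc$phase, p),
                   nomsc, machine))

  f_scen <- function(w, i) {
    v <- 0
    for (t in seq_len(nrow(rob))) {
      d <- drop(infl[[i]][[rob$roi[t]]] %*% w)
      v <- v + rob$weight[t] * term_value(rob$type[t], d, rob$level_gy[t])
    }
    v
  }
  g_scen <- function(w, i) {
    g <- numeric(length(w))
    for (t in seq_len(nrow(rob))) {
      D <- infl[[i]][[rob$roi[t]]]
      d <- drop(D %*% w)
      g <- g + rob$weight[t] *
        drop(crossprod(D, term_grad(rob$type[t], d, rob$level_gy[t])))
    }
    g
  }
  f_nom <- function(w) {
    v <- 0
    for (t in seq_len(nrow(nom))) {
      d <- drop(infl_nom[[nom$roi[t]]] %*% w)
      v <- v + nom$weight[t] * term_value(nom$type[t], d, nom$level_gy[t])
    }
    v
  }
  g_nom <- function(w) {
    g <- numeric(length(w))
    for (t in seq_len(nrow(nom))) {
      D <- infl_nom[[nom$roi[t]]]
      d <- drop(D %*% w)
      g <- g + nom$weight[t] *
        drop(crossprod(D, term_grad(nom$type[t], d, nom$level_gy[t])))
    }
    g
  }

  ns <- nrow(scenarios)
  make_fg <- function(tau) {
    fn <- function(w) {
      fs <- vapply(seq_len(ns), function(i) f_scen(w, i), numeric(1))
      m <- max(fs)
      m + log(sum(exp(tau * (fs - m)))) / tau + f_nom(w)
    }
    gr <- function(w) {
      fs <- vapply(seq_len(ns), function(i) f_scen(w, i), numeric(1))
      p <- exp(tau * (fs - max(fs))); p <- p / sum(p)
      g <- g_nom(w)
      for (i in seq_len(ns)) if (p[i] > 1e-12) g <- g + p[i] * g_scen(w, i)
      g
    }
    list(fn = fn, gr = gr)
  }

  # start: uniform weights scaled so the mean robust-target dose matches
  # the highest min_dose level under the nominal scenario
  w <- plan$spots$weight
  if (all(w == w[1])) {
    tgt <- rob$roi[rob$type == "min_dose"][1]
    if (!is.na(tgt)) {
      i0 <- which(scenarios$id == nomsc$id)[1]
      d1 <- drop(infl[[i0]][[tgt]] %*% rep(1, length(w)))
      md <- mean(d1)
      if (md > 0) w <- rep(max(rob$level_gy[rob$type == "min_dose"]) / md,
                           length(w))
    }
  }
  conv <- integer(0)
  for (tau in temperatures) {
    fg <- make_fg(tau)
    res <- stats::optim(w, fg$fn, fg$gr, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = maxit, factr = 1e9))
    w <- res$par
    conv <- c(conv, res$convergence)
  }
  fs <- vapply(seq_len(ns), function(i) f_scen(w, i), numeric(1))
  plan$spots$weight <- w
  plan$optimization <- list(
    worst_objective = max(fs) + f_nom(w),
    worst_robust = max(fs),
    worst_scenario = scenarios$id[which.max(fs)],
    nominal_objective = fs[which(scenarios$id == nomsc$id)[1]] + f_nom(w),
    per_scenario = fs, convergence = conv)
  if (any(conv > 1))
    warning("L-BFGS-B did not fully converge (codes ",
            paste(conv, collapse = "/"), ")")
  plan
}
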