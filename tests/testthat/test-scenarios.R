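test_that("the 5 mm / 3% / 4-phase grid has exactly 84 scenarios", {
  sc <- enumerate_scenarios(5, 0.03, c(0, 2, 5, 7))
  expect_equal(nrow(sc), 84)
  # 7 setup x 3 range per phase
  for (p in c(0, 2, 5, 7)) {
    sp <- sc[sc$phase == p, ]
    expect_equal(nrow(sp), 21)
    expect_equal(nrow(unique(sp[c("shift_x", "shift_y", "shift_z")])), 7)
    expect_setequal(unique(sp$range_scale), c(0.97, 1, 1.03))
  }
  expect_equal(sum(sc$nominal_geometry), 4)      # one per phase
  expect_equal(sum(sc$is_nominal), 1)
  expect_true(all(abs(sc$shift_x) %in% c(0, 5)))
})

test_that("degenerate grids collapse and the count formula holds", {
  expect_equal(nrow(enumerate_scenarios(0, 0, 0)), 1)
  # brute-force product-count oracle
  count_oracle <- function(setup, rpct, nphase) {
    ns <- if (setup > 0) 7 else 1
    nr <- if (rpct > 0) 3 else 1
    ns * nr * nphase
  }
  for (setup in c(0, 5)) for (r in c(0, 0.03)) for (np in c(1, 4, 10)) {
    sc <- enumerate_scenarios(setup, r, seq_len(np))
    expect_equal(nrow(sc), count_oracle(setup, r, np))
  }
  expect_equal(nrow(enumerate_scenarios(5, 0.03, 1:10)), 210)
  expect_error(enumerate_scenarios(5, 0.03, integer(0)), "phase")
})

test_that("anisotropic evaluation shifts use the per-direction magnitudes", {
  sc <- enumerate_scenarios(margin_spec(c(3, 4, 5, 6, 7, 8)), 0, 0)
  expect_equal(sort(unique(sc$shift_x)), c(-3, 0, 4))
  expect_equal(sort(unique(sc$shift_y)), c(-5, 0, 6))
  expect_equal(sort(unique(sc$shift_z)), c(-7, 0, 8))
})

test_that("scenario evaluation returns one DVH per scenario and ROI", {
  ph <- static_phantom()
  plan <- static_impt_plan()
  sc <- enumerate_scenarios(0, 0, 0)
  tab <- evaluate_scenarios(plan, sc, ph$phases, ph$structures,
                            rois = c("CTV", "Heart"))
  expect_equal(nrow(tab), 2)
  expect_s3_class(tab$dvh[[1]], "dvh_curve")
  expect_error(evaluate_scenarios(plan, sc, ph$phases, ph$structures,
                                  rois = "Nope"), "unknown ROI")
})

test_that("opposed shifts give mirrored CTV DVHs on a z-symmetric static phantom", {
  ph <- static_phantom()                          # symmetric about z = 0
  plan <- static_impt_plan()
  sc <- enumerate_scenarios(5, 0, 0)
  sc <- sc[sc$shift_z != 0, ]
  tab <- evaluate_scenarios(plan, sc, ph$phases, ph$structures)
  d98 <- vapply(tab$dvh, dvh_metric, numeric(1), query = "D98%")
  expect_equal(d98[tab$shift_z == 5], d98[tab$shift_z == -5], tolerance = 0.02)
})

test_that("per-scenario CTV D98% matches an independent dose-sort-percentile recomputation", {
  ph <- coarse_phantom()
  plan <- coarse_impt_plan()
  sc <- enumerate_scenarios(5, 0.03, c(0, 2))
  pick <- sc[c(3, 17, 30), ]
  tab <- evaluate_scenarios(plan, pick, ph$phases, ph$structures)
  for (i in seq_len(nrow(pick))) {
    s <- pick[i, ]
    pts <- mask_points(ph$structures$grid, roi_mask(ph$structures, "CTV"))
    pts <- phase_points(ph$phases, s$phase, pts)
    d <- compute_dose(plan, phase_density(ph$phases, s$phase), s, points = pts)
    sd_ <- sort(d, decreasing = TRUE)
    oracle <- stats::approx((seq_along(sd_) - 0.5) / length(sd_), sd_,
                            xout = 0.98, rule = 2)$y
    expect_equal(dvh_metric(tab$dvh[[i]], "D98%"), oracle, tolerance = 1e-9)
  }
})

test_that("worst case is the per-metric composite over scenarios", {
  vcc <- 0.1
  mk <- function(val) dvh_curve(rep(val, 100), vcc, "CTV")
  tab <- data.frame(id = 1:3, is_nominal = c(TRUE, FALSE, FALSE),
                    nominal_geometry = c(TRUE, FALSE, FALSE),
                    roi = "CTV")
  tab$dvh <- list(mk(57.5), mk(58.2), mk(56.9))
  goals <- data.frame(roi = "CTV", metric = "D98%", op = ">=", limit = 57,
                      scope = "worst")
  res <- worst_case_metrics(tab, goals)
  expect_equal(res$worst, 56.9)
  expect_equal(res$nominal, 57.5)
  expect_false(res$pass)

  # single scenario: worst equals nominal
  res1 <- worst_case_metrics(tab[1, ], goals)
  expect_equal(res1$worst, res1$nominal)

  # Heart Dmean 19 Gy passes the < 20 Gy goal
  tabh <- data.frame(id = 1, is_nominal = TRUE, nominal_geometry = TRUE,
                     roi = "Heart")
  tabh$dvh <- list(mk(19))
  gh <- data.frame(roi = "Heart", metric = "Dmean", op = "<", limit = 20,
                   scope = "nominal")
  expect_true(worst_case_metrics(tabh, gh)$pass)

  expect_error(worst_case_metrics(tab, data.frame(roi = "CTV", metric = "D98%",
                                                  op = "~", limit = 1,
                                                  scope = "worst")),
               "operator")
})

test_that("worst-case dominance holds across a full scenario evaluation", {
  ph <- coarse_phantom()
  plan <- coarse_impt_plan()
  sc <- enumerate_scenarios(5, 0.03, c(0, 2))
  tab <- evaluate_scenarios(plan, sc, ph$phases, ph$structures,
                            rois = c("CTV", "SpinalCanal"))
  for (r in c("CTV", "SpinalCanal")) {
    rows <- tab[tab$roi == r, ]
    d98 <- vapply(rows$dvh, dvh_metric, numeric(1), query = "D98%")
    dmax <- vapply(rows$dvh, dvh_metric, numeric(1), query = "D0.04cc")
    nom <- which(rows$is_nominal)
    expect_lte(min(d98), d98[nom])
    expect_gte(max(dmax), dmax[nom])
  }
})
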