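test_that("empty plans deliver in zero time", {
  plan <- treatment_plan("IMPT", data.frame(gantry_deg = numeric(0),
                                            bx = numeric(0), by = numeric(0),
                                            range_mm = numeric(0),
                                            weight = numeric(0)),
                         c(0, 0, 0), beam_angles = c(0, 120))
  sch <- simulate_timing(plan)
  expect_equal(sch$bdt_s, 0)
  expect_equal(sch$travel_s, 0)
})

test_that("IMPT timing matches a hand-summed arithmetic oracle", {
  mach <- machine_config(mu_rate = 10, spot_switch_s = 0.1,
                         energy_down_s = 2, couch_overhead_s = 30,
                         gantry_speed_dps = 6)
  # one beam, two layers (descending), three spots
  spots <- data.frame(gantry_deg = 0, bx = c(0, 5, 0), by = 0,
                      range_mm = c(100, 100, 80), weight = c(2, 4, 6))
  plan <- treatment_plan("IMPT", spots, c(0, 0, 0), machine = mach,
                         beam_angles = 0)
  sch <- simulate_timing(plan)
  # layer 100: spots (0,0) w=2 then (5,0) w=4; switch 2 s; layer 80: w=6
  want <- (2 / 10 + 0.1) + (4 / 10 + 0.1) + 2 + (6 / 10 + 0.1)
  expect_equal(sch$bdt_s, want, tolerance = 1e-12)
  expect_equal(sch$spots$time_s[sch$spots$range_mm == 80],
               (2 / 10 + 0.1) + (4 / 10 + 0.1) + 2)

  # two beams: travel = couch overhead + rotation at max speed
  spots2 <- rbind(spots, data.frame(gantry_deg = 90, bx = 0, by = 0,
                                    range_mm = 90, weight = 1))
  plan2 <- treatment_plan("IMPT", spots2, c(0, 0, 0), machine = mach,
                          beam_angles = c(0, 90))
  sch2 <- simulate_timing(plan2)
  expect_length(sch2$beam_travel_s, 1)
  expect_equal(sch2$beam_travel_s, 30 + 90 / 6)
  expect_gt(sch2$travel_s, 0)
})

test_that("PAT delivery has zero inter-beam travel and IMPT does not", {
  pat <- coarse_pat_plan()
  impt <- coarse_impt_plan(optimized = FALSE)
  expect_equal(simulate_timing(pat)$travel_s, 0)
  expect_gt(simulate_timing(impt)$travel_s, 0)
})

test_that("spots are distributed to phases by modular timing arithmetic", {
  sch <- structure(list(spots = data.frame(spot = 1:6,
                                           time_s = c(0, 0.1, 0.3, 1.1, 3.9, 4.0))),
                   class = "timing_schedule")
  P <- 10; T_ <- 4
  # oracle: per-spot modular arithmetic
  for (s0 in c(0, 3, 9)) {
    a <- distribute_spots_to_phases(sch, T_, P, s0)
    oracle <- (floor(((c(0, 0.1, 0.3, 1.1, 3.9, 4.0) %% T_) / T_) * P) + s0) %% P
    for (p in 0:(P - 1)) expect_equal(a[[p + 1]], which(oracle == p),
                                      ignore_attr = TRUE)
  }
  # all spots within one dwell starting at phase k land in phase k
  sch2 <- structure(list(spots = data.frame(spot = 1:3,
                                            time_s = c(0, 0.1, 0.3))),
                    class = "timing_schedule")
  a2 <- distribute_spots_to_phases(sch2, T_, P, 5)
  expect_equal(a2[[6]], 1:3)
  expect_true(all(lengths(a2[-6]) == 0))
  # every spot assigned exactly once
  a3 <- distribute_spots_to_phases(sch, T_, P, 7)
  expect_equal(sort(unlist(a3)), 1:6)
  expect_error(distribute_spots_to_phases(sch, 0, P, 0), "period")
})

test_that("start-phase sweep gives one distinct scenario per phase", {
  plan <- coarse_impt_plan(optimized = FALSE)
  sch <- simulate_timing(plan)
  P <- 10
  assigns <- lapply(0:(P - 1), function(s)
    distribute_spots_to_phases(sch, 4, P, s))
  expect_length(unique(lapply(assigns, function(a) vapply(a, length, 1L))), P)
  expect_length(assigns, 10)
})

test_that("partial doses sum to the static dose when motion is absent", {
  ph <- static_phantom()
  plan <- static_impt_plan()
  sch <- simulate_timing(plan)
  P <- length(ph$phases$phases)
  pts <- mask_points(ph$structures$grid, roi_mask(ph$structures, "CTV"))
  a <- distribute_spots_to_phases(sch, ph$phases$period, P, 0)
  acc <- accumulate_4ddd(plan, ph$phases, a, points = pts)
  static <- compute_dose(plan, ph$phases$midp, points = pts)
  # identity DVFs: accumulated dose equals the static dose to numerical noise
  expect_equal(acc$accumulated, static, tolerance = 1e-12)
  expect_lt(max(abs(Reduce(`+`, acc$partial) - static)) / max(static), 1e-9)
})

test_that("all spots in one phase reduce to the warped single-phase dose", {
  ph <- coarse_phantom()
  plan <- coarse_impt_plan(optimized = FALSE)
  P <- length(ph$phases$phases)
  pts <- mask_points(ph$structures$grid, roi_mask(ph$structures, "CTV"))
  a <- c(list(seq_len(nrow(plan$spots))), rep(list(integer(0)), P - 1))
  acc <- accumulate_4ddd(plan, ph$phases, a, points = pts)
  oracle <- compute_dose(plan, phase_density(ph$phases, 1),
                         points = phase_points(ph$phases, 1, pts))
  expect_equal(acc$accumulated, oracle, tolerance = 1e-12)
})

test_that("two-phase rigid motion matches the shift-and-sum oracle", {
  ph <- coarse_phantom()
  plan <- coarse_impt_plan(optimized = FALSE)
  P <- length(ph$phases$phases)
  # split spots between phases 2 and 4; oracle sums the two phase doses
  # evaluated at the deformed point positions via independent spot_dose calls
  n <- nrow(plan$spots)
  idx1 <- seq_len(floor(n / 2)); idx2 <- setdiff(seq_len(n), idx1)
  a <- rep(list(integer(0)), P); a[[2]] <- idx1; a[[4]] <- idx2
  pts <- mask_points(ph$structures$grid, roi_mask(ph$structures, "CTV"))
  acc <- accumulate_4ddd(plan, ph$phases, a, points = pts)
  oracle <- 0
  for (ph_i in c(2, 4)) {
    idx <- if (ph_i == 2) idx1 else idx2
    dens <- phase_density(ph$phases, ph_i)
    ppts <- phase_points(ph$phases, ph_i, pts)
    for (i in idx)
      oracle <- oracle + spot_dose(plan$spots[i, ], dens,
                                   machine = plan$machine,
                                   isocenter = plan$isocenter, points = ppts)
  }
  expect_equal(acc$accumulated, oracle, tolerance = 1e-9)
})

test_that("shifting the start phase by P changes nothing", {
  plan <- coarse_impt_plan(optimized = FALSE)
  sch <- simulate_timing(plan)
  a1 <- distribute_spots_to_phases(sch, 4, 10, 3)
  a2 <- distribute_spots_to_phases(sch, 4, 10, (3 + 10) %% 10)
  expect_identical(a1, a2)
})

test_that("zero-amplitude phantoms have exactly zero DVH-band widths", {
  ph <- static_phantom()
  plan <- static_impt_plan()
  res <- interplay_bands(plan, ph$phases, ph$structures)
  expect_equal(nrow(res$values), length(ph$phases$phases))  # 10 scenarios
  expect_true(all(res$bands$width == 0))
})

test_that("bands are nonnegative and computed from the per-scenario extremes", {
  ph <- coarse_phantom()
  plan <- coarse_impt_plan()
  res <- interplay_bands(plan, ph$phases, ph$structures,
                         start_phases = c(0, 2))
  expect_equal(nrow(res$values), 2)
  for (m in c("D98%", "D1%")) {
    expect_equal(res$bands$width[res$bands$metric == m],
                 abs(diff(res$values[[m]])))
    expect_gte(res$bands$width[res$bands$metric == m], 0)
  }
})
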