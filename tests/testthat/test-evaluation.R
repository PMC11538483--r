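test_that("DVH metrics on constructed samples match counting oracles", {
  # uniform 60 Gy
  u <- dvh_curve(rep(60, 200), 0.1)
  expect_equal(dvh_metric(u, "D98%"), 60)
  expect_equal(dvh_metric(u, "D1%"), 60)
  expect_equal(dvh_metric(u, "Dmean"), 60)
  expect_equal(dvh_metric(u, "V30Gy"), 100)

  # 100 voxels, half 40 Gy, half 20 Gy
  h <- dvh_curve(c(rep(40, 50), rep(20, 50)), 0.5)
  expect_equal(dvh_metric(h, "V30Gy"), 50)
  expect_equal(dvh_metric(h, "Dmean"), 30)
  # D25cc = dose to hottest 25 cc = within the 40 Gy half
  expect_equal(dvh_metric(h, "D20cc"), 40)
  expect_error(dvh_metric(h, "D60cc"), "exceeds")

  # endpoint identities on a random sample
  set.seed(5)
  d <- runif(300, 10, 70)
  crv <- dvh_curve(d, 0.2)
  expect_equal(dvh_metric(crv, "D100%"), min(d))
  expect_equal(dvh_metric(crv, "D0%"), max(d))
  expect_equal(dvh_metric(crv, "Dmean"),
               dvh_metric(dvh_curve(rev(d), 0.2), "Dmean"))
  expect_error(dvh_metric(crv, "Q5"), "unknown")
})

test_that("cumulative DVH is nonincreasing and starts at 100%", {
  set.seed(6)
  crv <- dvh_curve(rgamma(200, 4, 0.1), 0.3)
  doses <- seq(0, 100, by = 5)
  v <- dvh_volume_at(crv, doses)
  expect_equal(v[1], 100)
  expect_true(all(diff(v) <= 0))
})

test_that("HI, CI and integral dose behave on an ideal and a toy plan", {
  n <- c(20, 20, 20)
  g <- voxel_volume(array(0, n), 4)
  p <- grid_points(g)
  ctv <- array(sqrt(rowSums(p^2)) <= 12, n)
  body <- array(sqrt(rowSums(p^2)) <= 36, n)
  st <- structure_set(list(CTV = ctv, Body = body), g)

  # ideal: exactly the prescription on the CTV, zero elsewhere
  ideal <- voxel_volume(array(ifelse(ctv, 60, 0), n), 4)
  m <- conformity_homogeneity_id(ideal, st, 60)
  expect_equal(m$CI, 1)
  expect_equal(m$HI, 0)
  expect_equal(m$ID_gycc, 60 * sum(ctv) * voxel_cc(g))

  # doubling dose doubles ID
  dbl <- voxel_volume(2 * ideal$values, 4)
  expect_equal(conformity_homogeneity_id(dbl, st, 60)$ID_gycc, 2 * m$ID_gycc)

  # toy overlap: prescription isodose covers CTV plus a shell
  piv <- array(sqrt(rowSums(p^2)) <= 16, n)
  toy <- voxel_volume(array(ifelse(piv, 60, 0), n), 4)
  mt <- conformity_homogeneity_id(toy, st, 60)
  tv <- sum(ctv); pv <- sum(piv); ov <- sum(ctv & piv)
  expect_equal(mt$CI, ov^2 / (tv * pv))          # hand-computed Paddick
  expect_lt(mt$CI, 1)
  mr <- conformity_homogeneity_id(toy, st, 60, ci = "rtog")
  expect_equal(mr$CI, pv / tv)
  expect_error(conformity_homogeneity_id(toy, st, 0), "prescription")
})

test_that("NTCP is a logistic in the mean dose with required covariates", {
  m <- ntcp_model("x", "MHD", intercept = -2, slope_per_gy = 0.1)
  # S = 0 at 20 Gy
  expect_equal(ntcp(m, 20), 0.5)
  expect_gt(ntcp(m, 20.1), 0.5)
  # monotone for positive slope
  expect_gt(ntcp(m, 20), ntcp(m, 10))
  # direct formula oracle with covariates
  mc <- ntcp_model("x", "MLD", -4, 0.12,
                   covariates = list(age = 0.02, comorbidity = 0.8))
  got <- ntcp(mc, 15, list(age = 70, comorbidity = 1))
  want <- 1 / (1 + exp(-(-4 + 0.12 * 15 + 0.02 * 70 + 0.8 * 1)))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(ntcp(mc, 15, list(age = 70)), "comorbidity")
  # bounded in (0, 1)
  for (d in c(-50, 0, 50, 120)) {
    v <- ntcp(m, d)
    expect_gt(v, 0); expect_lt(v, 1)
  }
  # default model set is mean-dose driven
  dm <- default_ntcp_models()
  expect_setequal(vapply(dm, function(x) x$metric, ""),
                  c("MHD", "MLD", "MED"))
})

test_that("paired Wilcoxon comparison flags significance at 0.05", {
  set.seed(8)
  a <- data.frame(case = 1:14, mhd = rnorm(14, 10, 2))
  b <- a; b$mhd <- a$mhd + rnorm(14, 1.5, 0.5)   # clear shift
  res <- compare_plans(a, b)
  expect_equal(res$metric, "mhd")
  expect_true(res$significant)
  expect_gt(res$median_diff, 0)

  # barely-overlapping shift: non-significant when p exceeds 0.05
  set.seed(10)
  b2 <- a; b2$mhd <- a$mhd + rnorm(14, 0, 1)
  res2 <- compare_plans(a, b2)
  expect_equal(res2$significant, res2$p_value <= 0.05)

  # identical samples: degenerate, p = 1
  expect_warning(res3 <- compare_plans(a, a), "degenerate|zero")
  expect_equal(res3$p_value, 1)
  expect_false(res3$significant)
})

test_that("signed-rank p matches exact enumeration at n = 14", {
  set.seed(12)
  x <- rnorm(14); y <- x + abs(rnorm(14, 0.8, 0.3))  # all differences positive
  d <- y - x
  stopifnot(all(d > 0))
  # exact two-sided distribution by enumerating all 2^14 sign patterns
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 14))
  Ws <- as.matrix(signs) %*% r
  p_le <- mean(Ws <= W); p_ge <- mean(Ws >= W)
  oracle <- min(1, 2 * min(p_le, p_ge))
  expect_equal(wilcoxon_signed_rank(y, x), oracle, tolerance = 1e-12)
  # all-positive differences give the minimal attainable p
  expect_equal(oracle, 2 / 2^14, tolerance = 1e-12)
})

test_that("median difference is the median of paired differences", {
  a <- data.frame(case = 1:5, m = c(1, 2, 3, 4, 100))
  b <- data.frame(case = 1:5, m = c(2, 4, 5, 5, 90))
  res <- suppressWarnings(compare_plans(a, b))
  expect_equal(res$median_diff, stats::median(b$m - a$m))
})
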