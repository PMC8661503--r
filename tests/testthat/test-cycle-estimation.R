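test_that("noise-free points on a line are fitted exactly", {
  times <- c(2, 4, 8, 16)
  curve <- curve_from_points(times, 0.025 * times + 0.4)
  fit <- fit_labeling_curve(curve)
  expect_equal(fit$m, 0.025, tolerance = 1e-12)
  expect_equal(fit$b, 0.4, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 4L)
})

test_that("OLS coefficients agree with a normal-equations brute-force oracle", {
  times <- c(2, 4, 8, 16, 24)
  fracs <- 0.02 * times + 0.35 + c(0.013, -0.008, 0.021, -0.017, 0.004)
  curve <- curve_from_points(times, fracs)
  fit <- fit_labeling_curve(curve)
  # closed-form least squares computed from scratch
  X <- cbind(1, times)
  beta <- unname(solve(t(X) %*% X, t(X) %*% fracs))
  expect_equal(fit$b, beta[1, 1], tolerance = 1e-10)
  expect_equal(fit$m, beta[2, 1], tolerance = 1e-10)
})

test_that("inversion of slope and intercept reproduces the printed formulas", {
  f1 <- fit_labeling_curve(curve_from_points(c(2, 4, 8, 16),
                                             0.025 * c(2, 4, 8, 16) + 0.4))
  e1 <- estimate_cycle_params(f1, gf = 1)
  expect_equal(e1$tc_hat, 40, tolerance = 1e-9)
  expect_equal(e1$ts_hat, 16, tolerance = 1e-9)

  f2 <- fit_labeling_curve(curve_from_points(c(2, 4, 8, 16),
                                             0.02 * c(2, 4, 8, 16) + 0.33))
  e2 <- estimate_cycle_params(f2, gf = 0.8)
  expect_equal(e2$tc_hat, 40, tolerance = 1e-9)
  expect_equal(e2$ts_hat, 16.5, tolerance = 1e-9)
})

test_that("exact inversion holds over a (tc, ts, gf) grid when all times are below the plateau", {
  for (tc in c(30, 40, 50)) for (ts in c(8, 12, 16)) for (gf in c(0.7, 1)) {
    times <- c(2, 4, 8, 12)  # all < min(tc - ts) = 14
    curve <- noise_free_curve(tc, ts, gf, times)
    est <- estimate_cycle_params(fit_labeling_curve(curve), gf = gf)
    expect_lt(abs(est$tc_hat - tc) / tc, 1e-9)
    expect_lt(abs(est$ts_hat - ts) / ts, 1e-9)
  }
})

test_that("including the plateau point biases the slope down and plateau exclusion removes it", {
  tc <- 40; ts <- 20; gf <- 0.9   # plateau from t = 20 on
  times <- c(2, 4, 8, 16, 24)
  curve <- noise_free_curve(tc, ts, gf, times)
  est_all <- estimate_cycle_params(fit_labeling_curve(curve, policy = "all"),
                                   gf = gf)
  expect_gt(est_all$tc_hat, tc * 1.01)   # downward slope bias inflates tc
  fit_px <- fit_labeling_curve(curve, policy = "plateau_exclude", gf = gf)
  expect_false(24 %in% fit_px$times_used)
  est_px <- estimate_cycle_params(fit_px, gf = gf)
  expect_lt(abs(est_px$tc_hat - tc) / tc, 1e-9)
  expect_lt(abs(est_px$ts_hat - ts) / ts, 1e-9)
})

test_that("fit errors and flags follow the contracts", {
  expect_error(fit_labeling_curve(curve_from_points(4, 0.5)),
               "at least 2 distinct exposure times")
  z <- curve_from_points(c(2, 8), c(0, 0))
  expect_true("degenerate_fit_all_zero" %in% fit_labeling_curve(z)$flags)
  down <- fit_labeling_curve(curve_from_points(c(2, 4, 8), c(0.5, 0.4, 0.2)))
  expect_error(estimate_cycle_params(down, gf = 1), "non-positive")
  up <- fit_labeling_curve(curve_from_points(c(2, 4, 8), c(0.1, 0.2, 0.3)))
  expect_error(estimate_cycle_params(up, gf = 0), "\\(0, 1\\]")
  expect_error(fit_labeling_curve(curve_from_points(c(2, 4), c(0.1, 0.2)),
                                  policy = "plateau_exclude"), "requires")
  # ts > tc flag whenever the intercept exceeds the growth fraction
  f <- fit_labeling_curve(curve_from_points(c(2, 4, 8), c(0.60, 0.61, 0.63)))
  expect_true("ts_exceeds_tc" %in% estimate_cycle_params(f, gf = 0.5)$flags)
})

test_that("growth-fraction estimation supports supplied, ki67 and plateau routes", {
  expect_equal(estimate_growth_fraction(method = "supplied", gf = 1), 1)
  expect_equal(estimate_growth_fraction(method = "ki67", ki67_fraction = 0.85),
               0.85)
  sat <- curve_from_points(c(8, 12, 20, 24), c(0.5, 0.65, 0.8, 0.8))
  expect_equal(estimate_growth_fraction(sat, method = "plateau"), 0.8)
  rising <- curve_from_points(c(2, 4, 8), c(0.2, 0.3, 0.5))
  expect_error(estimate_growth_fraction(rising, method = "plateau"),
               "no saturated time points")
  # simulated: gf = 0.85, saturation from t = tc - ts = 18 h
  p <- cycle_population_params(tc = 30, ts = 12, gf = 0.85)
  spec <- mixture_spec(p, n_cells_per_field = 2000, n_fields = 6,
                       n_replicates = 2, seed = 31)
  curve <- simulate_cumulative_labeling(spec, times = c(2, 4, 8, 16, 20, 24))
  gf_hat <- estimate_growth_fraction(curve, method = "plateau")
  n_sat <- sum(curve$n_total[curve$time >= 20])
  expect_lt(abs(gf_hat - 0.85), 3 * sqrt(0.85 * 0.15 / n_sat))
})

test_that("estimates are invariant under relabeling of field and replicate ids", {
  p <- cycle_population_params(tc = 40, ts = 16, gf = 0.9)
  curve <- simulate_cumulative_labeling(mixture_spec(p, seed = 5))
  relab <- curve
  relab$field <- match(relab$field, c(3, 1, 6, 2, 5, 4))      # permute fields
  relab$replicate <- 3 - relab$replicate                      # swap replicates
  for (pol in c("all", "plateau_exclude")) {
    e1 <- estimate_cycle_params(fit_labeling_curve(curve, pol, gf = 0.9), 0.9)
    e2 <- estimate_cycle_params(fit_labeling_curve(relab, pol, gf = 0.9), 0.9)
    expect_equal(e1$tc_hat, e2$tc_hat)
    expect_equal(e1$ts_hat, e2$ts_hat)
    expect_equal(sort(unname(e1$tc_reps)), sort(unname(e2$tc_reps)))
  }
})

test_that("control curves are steeper than TGFb-inhibited curves in expectation", {
  kin <- mge_kinetics_table()
  dmso <- kin[kin$condition == "DMSO" & kin$subpop == "NKX2.1+", ]
  ly <- kin[kin$condition == "LY" & kin$subpop == "NKX2.1+", ]
  slopes <- vapply(1:20, function(i) {
    f <- function(k, seed) {
      p <- cycle_population_params(tc = k$tc, ts = k$ts, gf = 0.9)
      curve <- simulate_cumulative_labeling(
        mixture_spec(p, seed = seed))
      fit_labeling_curve(curve, "plateau_exclude", gf = 0.9)$m
    }
    c(f(dmso, 1000 + i), f(ly, 2000 + i))
  }, numeric(2))
  expect_gt(mean(slopes[1, ]), mean(slopes[2, ]))
})

test_that("condition comparison returns zero difference for identical replicates and detects separated means", {
  a <- manual_estimate(c(40, 41, 39))
  cmp0 <- compare_conditions(a, a, labels = c("x", "y"))
  expect_equal(cmp0$tc_diff, 0)
  expect_equal(cmp0$tc$p_value, 1)

  b1 <- manual_estimate(c(40, 40.01, 39.99))
  b2 <- manual_estimate(c(46, 46.01, 45.99))
  cmp <- compare_conditions(b1, b2, labels = c("ctrl", "trt"))
  expect_lt(cmp$tc$p_value, 0.01)
  expect_equal(cmp$tc_diff, -6, tolerance = 1e-6)
  expect_error(compare_conditions(manual_estimate(40), b2), ">= 2 replicate")
})

test_that("recovery study reports near-unbiased tc with calibrated interval coverage", {
  # six replicate-level fits (two experiments of three technical replicates)
  st <- kinetics_recovery_study(tc = 40, ts = 16, gf = 0.9,
                                n_repetitions = 100, n_fields = 2,
                                n_replicates = 6, seed = 99)
  expect_lt(abs(mean(st$tc_hat) - 40) / 40, 0.05)
  covered <- abs(st$tc_hat - 40) <= 2 * st$tc_sem
  expect_gte(mean(covered[!is.na(st$tc_sem)]), 0.8)
})
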