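test_that("analytic labeled fraction matches closed form and brute-force enumeration", {
  p <- cycle_population_params(tc = 40, ts = 16, gf = 1)
  expect_equal(analytic_labeled_fraction(p, 0), 0.4)  # intercept gf*ts/tc

  p0 <- cycle_population_params(tc = 40, ts = 16, gf = 0)
  expect_equal(analytic_labeled_fraction(p0, c(0, 5, 100)), c(0, 0, 0))

  p8 <- cycle_population_params(tc = 40, ts = 16, gf = 0.8)
  expect_equal(analytic_labeled_fraction(p8, 8), 0.48)

  # independent brute force: enumerate uniformly placed cycle positions and
  # ask whether each traverses S-phase within the exposure window
  tc <- 40; ts <- 16; tg2m <- 2; t <- 8
  a <- (seq_len(4e5) - 0.5) * tc / 4e5
  s0 <- tc - ts - tg2m
  next_s <- (s0 - a) %% tc
  labeled <- (a >= s0 & a < s0 + ts) | next_s <= t
  expect_equal(0.8 * mean(labeled), 0.48, tolerance = 1e-4)

  # plateau at gf for t >= tc - ts
  expect_equal(analytic_labeled_fraction(p8, c(24, 30, 1000)), rep(0.8, 3))
  expect_error(analytic_labeled_fraction(p8, -1), "must be >= 0")
})

test_that("parameter validation rejects inconsistent kinetics", {
  expect_error(cycle_population_params(tc = 0, ts = 1), "'tc'")
  expect_error(cycle_population_params(tc = 10, ts = 11), "'ts'")
  expect_error(cycle_population_params(tc = 10, ts = 5, gf = 1.2), "'gf'")
  expect_error(cycle_population_params(tc = 10, ts = 5, quit_prob = -0.1),
               "'quit_prob'")
  # G2/M shrinks when the cycle leaves no room for the default 2 h
  expect_equal(cycle_population_params(tc = 10, ts = 9)$tg2m, 1)
  expect_equal(cycle_population_params(tc = 10, ts = 10)$tg2m, 0)
  expect_error(mixture_spec(list(cycle_population_params(30, 10)),
                            proportions = c(0.5, 0.5)), "one mixing proportion")
  expect_error(mixture_spec(list(cycle_population_params(30, 10),
                                 cycle_population_params(30, 12, label = "b")),
                            proportions = c(0.6, 0.6)), "sum to 1")
})

test_that("simulated labeled fractions converge to the analytic oracle", {
  sets <- list(c(tc = 40, ts = 16, gf = 0.8, t = 8),
               c(tc = 30, ts = 12, gf = 1.0, t = 4),
               c(tc = 50, ts = 10, gf = 0.6, t = 16))
  for (s in sets) {
    p <- cycle_population_params(tc = s["tc"], ts = s["ts"], gf = s["gf"])
    spec <- mixture_spec(p, n_cells_per_field = 4000, n_fields = 6,
                         n_replicates = 2, seed = 42)
    curve <- simulate_cumulative_labeling(spec, times = s["t"])
    n <- sum(curve$n_total)
    frac <- sum(curve$n_labeled) / n
    truth <- analytic_labeled_fraction(p, s["t"])
    se <- sqrt(truth * (1 - truth) / n)
    expect_lt(abs(frac - truth), 3 * se)
  }
})

test_that("labeled fraction is 1 everywhere when S-phase spans the whole cycle", {
  p <- cycle_population_params(tc = 20, ts = 20, gf = 1)
  curve <- simulate_cumulative_labeling(mixture_spec(p, seed = 9),
                                        times = c(1, 5))
  expect_true(all(curve$n_labeled == curve$n_total))
})

test_that("labeled fraction is non-decreasing in exposure time within a run and plateaus at gf", {
  p <- cycle_population_params(tc = 40, ts = 16, gf = 0.8)
  spec <- mixture_spec(p, n_cells_per_field = 3000, n_fields = 3,
                       n_replicates = 2, seed = 11)
  times <- c(2, 4, 8, 16, 24, 30, 48)
  curve <- simulate_cumulative_labeling(spec, times = times)
  key <- interaction(curve$replicate, curve$field)
  for (k in levels(key)) {
    d <- curve[key == k, ]
    d <- d[order(d$time), ]
    expect_true(all(diff(d$n_labeled) >= 0))
    expect_equal(d$n_total, rep(d$n_total[1], nrow(d)))  # common cohort
  }
  # for t >= tc - ts = 24 every cycling cell is labeled: fraction sticks at
  # the realized cycling fraction of the cohort (Monte-Carlo gf)
  late <- curve[curve$time >= 24, ]
  per_time <- tapply(late$n_labeled, late$time, sum)
  expect_true(all(per_time == per_time[[1]]))
  frac <- per_time[[1]] / sum(curve$n_total[curve$time == 24])
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 18000))
})

test_that("generators are byte-identical under a fixed seed and respect the mixture structure", {
  pops <- list(cycle_population_params(40, 16, gf = 0.9, label = "marker_pos"),
               cycle_population_params(35, 14, gf = 0.7, label = "marker_neg"))
  spec <- mixture_spec(pops, proportions = c(0.8, 0.2), seed = 123)
  c1 <- simulate_cumulative_labeling(spec, times = c(2, 8))
  c2 <- simulate_cumulative_labeling(spec, times = c(2, 8))
  expect_identical(c1, c2)
  c3 <- simulate_cumulative_labeling(spec, times = c(2, 8), seed = 124)
  expect_false(identical(c1, c3))
  expect_setequal(unique(c1$subpop), c("marker_pos", "marker_neg"))
  # mixing proportions respected in expectation
  tot <- tapply(c1$n_total[c1$time == 2], c1$subpop[c1$time == 2], sum)
  expect_lt(abs(tot[["marker_pos"]] / sum(tot) - 0.8), 0.05)

  tab1 <- simulate_pulse_chase(spec, pulse = 2, chase = 10)
  tab2 <- simulate_pulse_chase(spec, pulse = 2, chase = 10)
  expect_identical(tab1, tab2)

  ev1 <- simulate_flow_sample(trajectory_params(), 40, 500, seed = 7)
  ev2 <- simulate_flow_sample(trajectory_params(), 40, 500, seed = 7)
  expect_identical(ev1, ev2)

  # seeds are mandatory for simulation
  expect_error(simulate_cumulative_labeling(mixture_spec(pops[[1]]),
                                            times = 2), "seed")
  expect_error(simulate_cumulative_labeling(spec, times = numeric(0)),
               "positive hours")
  expect_error(simulate_pulse_chase(spec, pulse = 0, chase = 1), "'pulse'")
})

test_that("the exponential-growth age mode depletes late-cycle positions as expected", {
  p <- cycle_population_params(tc = 40, ts = 16, gf = 1)
  mk <- function(mode) mixture_spec(p, n_cells_per_field = 20000, n_fields = 1,
                                    n_replicates = 1, seed = 61,
                                    age_distribution = mode)
  short <- 0.01  # exposure short enough to read out the in-S-phase fraction
  frac <- vapply(c("uniform", "exp_growth"), function(m) {
    d <- simulate_cumulative_labeling(mk(m), times = short)
    sum(d$n_labeled) / sum(d$n_total)
  }, numeric(1))
  # S-phase sits late in the cycle where an expanding population has fewer
  # cells, so the instantaneous labeled fraction drops below ts/tc
  truth_exp <- 2 * (2^(-(40 - 16 - 2) / 40) - 2^(-(40 - 2) / 40))
  expect_lt(abs(frac[["uniform"]] - 16 / 40), 3 * sqrt(0.4 * 0.6 / 20000))
  expect_lt(abs(frac[["exp_growth"]] - truth_exp),
            3 * sqrt(truth_exp * (1 - truth_exp) / 20000))
  expect_lt(frac[["exp_growth"]], frac[["uniform"]])
  # still saturates at the growth fraction
  sat <- simulate_cumulative_labeling(mk("exp_growth"), times = 40)
  expect_equal(sum(sat$n_labeled), sum(sat$n_total))
})

test_that("trajectory model hits its calibration anchors and orders conditions", {
  ctrl <- trajectory_params()
  ly <- trajectory_params(condition_scale = 0.3)
  # zero hazard -> no positives ever
  expect_equal(trajectory_prevalence(trajectory_params(hazard = 0), c(25, 60)),
               c(0, 0))
  # reduced hazard lies below control from day 30 onward
  days <- seq(30, 60, by = 5)
  expect_true(all(trajectory_prevalence(ly, days) <
                    trajectory_prevalence(ctrl, days)))
  # forced-exit mode: a reduced-hazard condition converges toward control
  ctrl_cci <- trajectory_params(forced_exit_day = 35)
  ly_cci <- trajectory_params(condition_scale = 0.3, forced_exit_day = 35)
  gap <- function(d) abs(trajectory_prevalence(ctrl_cci, d) -
                           trajectory_prevalence(ly_cci, d))
  expect_lt(gap(60), gap(40))
  expect_lt(gap(60), 0.01)
})
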