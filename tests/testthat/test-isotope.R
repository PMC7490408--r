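test_that("delta <-> ratio conversions match hand arithmetic", {
  expect_equal(delta_from_ratio(0.01118, 0.01118), 0)
  expect_equal(delta_from_ratio(0.02236, 0.01118), 1000)
  # (0.0123/0.01118 - 1) * 1000, computed by hand
  expect_equal(delta_from_ratio(0.0123, 0.01118), 100.178891, tolerance = 1e-8)
  expect_equal(ratio_from_delta(0, 0.01118), 0.01118)
  expect_equal(ratio_from_delta(1000, 0.01118), 0.02236)
  expect_error(delta_from_ratio(-0.01, 0.01118), "positive")
  expect_error(ratio_from_delta(-1000, 0.01118), "-1000")
})

test_that("delta/ratio round trip is exact to 1e-12 relative", {
  set.seed(41)
  d <- runif(1000, -999, 5000)
  back <- delta_from_ratio(ratio_from_delta(d, iso_ref[["N"]]), iso_ref[["N"]])
  expect_equal(back, d, tolerance = 1e-12)
  r <- ratio_from_atom_fraction(atom_fraction(ratio_from_delta(d)))
  expect_equal(r, ratio_from_delta(d), tolerance = 1e-12)
})

test_that("atom fraction is correct, bounded and strictly monotone", {
  expect_equal(atom_fraction(0.01118), 0.01118 / 1.01118, tolerance = 1e-12)
  expect_equal(atom_fraction(0.01118), 0.0110564, tolerance = 1e-5)
  expect_equal(atom_fraction(1.0), 0.5)
  expect_lt(atom_fraction(1e-9), 1e-8)
  r <- sort(runif(200, 1e-4, 10))
  f <- atom_fraction(r)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  # monotone in delta as well
  d <- seq(-500, 3000, by = 10)
  expect_true(all(diff(atom_fraction(ratio_from_delta(d))) > 0))
  expect_error(atom_fraction(0), "positive")
})

test_that("excess atom fraction subtracts the control baseline", {
  expect_equal(excess_atom_fraction(0.0120, 0.0111), 0.0009)
  expect_equal(excess_atom_fraction(0.013, 0.013), 0)
  expect_equal(excess_atom_fraction(0.010, 0.012), -0.002)  # noise retained
  expect_equal(excess_atom_fraction(0.010, 0.012, clamp = TRUE), 0)
})

test_that("bulk uptake rate normalises by label strength and time", {
  # food with excess label atom fraction exactly 0.979
  f0 <- atom_fraction(iso_ref[["C"]])
  food <- food_source("test", atom_frac_13c = f0 + 0.979)
  # sample whose tissue excess is exactly 5e-4
  d_ctl <- -20
  f_ctl <- atom_fraction(ratio_from_delta(d_ctl))
  d_smp <- delta_from_ratio(ratio_from_atom_fraction(f_ctl + 5e-4))
  r <- bulk_uptake_rate(d_smp, d_ctl, food, "C", time_h = 3)
  expect_equal(r$excess, 5e-4, tolerance = 1e-12)
  expect_equal(r$rate, 1000 * 5e-4 / 0.979 / 3, tolerance = 1e-9)
  expect_equal(r$rate, 0.1702417, tolerance = 1e-6)
  # control-equal sample: zero rate
  expect_equal(bulk_uptake_rate(d_ctl, d_ctl, food, "C", 3)$rate, 0)
  # linear in excess, inverse in time and label strength
  d2 <- delta_from_ratio(ratio_from_atom_fraction(f_ctl + 1e-3))
  expect_equal(bulk_uptake_rate(d2, d_ctl, food, "C", 3)$rate, 2 * r$rate,
               tolerance = 1e-9)
  expect_equal(bulk_uptake_rate(d_smp, d_ctl, food, "C", 6)$rate, r$rate / 2,
               tolerance = 1e-12)
  expect_error(bulk_uptake_rate(d_smp, d_ctl, food, "C", 0), "time")
  expect_error(bulk_uptake_rate(d_smp, d_ctl, food, "N", 3), "label")
})

test_that("rate estimator recovers a known rate under Gaussian delta noise", {
  set.seed(99)
  rho <- 0.8                       # umol mmol-1 h-1
  food <- food_source("lab", 0.98)
  x <- food_excess(food, "C")
  t_h <- 3
  e_true <- rho * x * t_h / 1000
  f_ctl <- atom_fraction(ratio_from_delta(-20))
  d_true <- delta_from_ratio(ratio_from_atom_fraction(f_ctl + e_true))
  n <- 1000
  d_obs <- d_true + rnorm(n, 0, 10)
  est <- bulk_uptake_rate(d_obs, -20, food, "C", t_h)$rate
  se <- sd(est) / sqrt(n)
  expect_lt(abs(mean(est) - rho), 3 * se)
})

test_that("control baselines and the bulk table pool controls per species", {
  cfg <- sip_config("HMA", delta_noise_sd = 0)
  d <- simulate_tracer_experiment(cfg, seed = 5)
  base <- control_baseline(d$bulk)
  expect_equal(base$delta13C_ctrl, -20, tolerance = 1e-9)
  expect_equal(base$delta15N_ctrl, 8, tolerance = 1e-9)
  tab <- bulk_uptake_table(d$bulk, d$foods)
  # glucose is 13C-only: no N rows
  expect_false(any(tab$treatment == "glucose" & tab$element == "N"))
  # noiseless rates equal the generator's true rates at every time point
  agg <- aggregate(rate ~ treatment + element, tab, function(r) max(abs(r - mean(r))))
  expect_true(all(agg$rate < 1e-9))
  m <- merge(aggregate(rate ~ treatment + element, tab, mean),
             d$truth$rates, by = c("treatment", "element"))
  expect_equal(m$rate.x, m$rate.y, tolerance = 1e-9)
})
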