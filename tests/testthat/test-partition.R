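test_that("per-cell content converts filter amounts to pg per cell", {
  expect_equal(per_cell_content(8, 1e8, "C"), 0.96)
  expect_equal(per_cell_content(0, 1e7, "N"), 0)
  expect_equal(per_cell_content(8, 1e8, "C"), per_cell_content(16, 2e8, "C"))
  expect_equal(per_cell_content(7, 1e8, "N"), 7 * 14 * 1e6 / 1e8)
  expect_error(per_cell_content(1, 0, "C"), "positive")
})

test_that("biomass fractions are biomass-weighted and sum to 100", {
  b <- biomass_fractions(1e6, 1e8, 100, 0.25)
  expect_equal(b$pct_microbe, 20)
  expect_equal(b$pct_host + b$pct_microbe, 100)
  expect_equal(biomass_fractions(10, 1000, 100, 1)$pct_microbe, 50)
  # species profiles: HMA microbes ~25% of C biomass, LMA well under 0.5%
  hma <- sip_config("HMA"); lma <- sip_config("LMA")
  expect_equal(biomass_fractions(hma$n_host, hma$n_microbe,
                                 hma$c_host, hma$c_microbe)$pct_microbe,
               25, tolerance = 0.01)
  expect_lt(biomass_fractions(lma$n_host, lma$n_microbe,
                              lma$c_host, lma$c_microbe)$pct_microbe, 0.5)
})

test_that("purity unmixing inverts forward mixing", {
  # perfect purity: identity
  M1 <- mixing_matrix(1, 1, 60, 0.25)
  expect_equal(unname(M1), diag(2))
  expect_equal(unmix_fraction_enrichment(0.001, 0.004, M1),
               c(host = 0.001, microbe = 0.004))
  # stated impurity case: solution of the 2x2 system (direct solve oracle)
  M <- mixing_matrix(0.85, 0.99, 60, 0.25)
  e_meas <- c(0.001, 0.004)
  oracle <- solve(M) %*% e_meas
  got <- unmix_fraction_enrichment(e_meas[1], e_meas[2], M)
  expect_equal(unname(got), as.vector(oracle), tolerance = 1e-12)
  # remixing reproduces the measurements
  expect_equal(as.vector(M %*% got), e_meas, tolerance = 1e-12)
})

test_that("unmix-mix identity holds over random purities and contents", {
  set.seed(7)
  for (i in 1:50) {
    ph <- runif(1, 0.6, 1); pm <- runif(1, 0.6, 1)
    ch <- runif(1, 10, 100); cm <- runif(1, 0.05, 2)
    M <- mixing_matrix(ph, pm, ch, cm)
    expect_equal(rowSums(M), c(host_fraction = 1, microbe_fraction = 1))
    e_true <- runif(2, 0, 0.01)
    e_meas <- as.vector(M %*% e_true)
    expect_equal(unname(unmix_fraction_enrichment(e_meas[1], e_meas[2], M)),
                 e_true, tolerance = 1e-10)
  }
})

test_that("partition shares are biomass x enrichment weighted and sum to 100", {
  p <- partition_uptake(0.002, 0.002, 75, 25)
  expect_equal(p$pct_microbe, 25)
  expect_equal(p$pct_host + p$pct_microbe, 100, tolerance = 1e-9)
  expect_equal(partition_uptake(0.002, 0, 75, 25)$pct_microbe, 0)
  expect_equal(partition_uptake(0, 0.002, 75, 25)$pct_host, 0)
  # negative enrichment clamps for the shares, survives in diagnostics
  p2 <- partition_uptake(0.002, -0.001, 75, 25)
  expect_equal(p2$pct_microbe, 0)
  expect_equal(p2$diagnostics$e_microbe, -0.001)
  # both non-positive: flagged, not a crash
  p3 <- partition_uptake(-0.001, 0, 75, 25)
  expect_equal(p3$status, "no_uptake")
  expect_true(is.na(p3$pct_host))
  # monotone in microbe biomass at fixed specific enrichments
  shares <- sapply(c(5, 15, 25, 50), function(bm)
    partition_uptake(0.001, 0.004, 100 - bm, bm)$pct_microbe)
  expect_true(all(diff(shares) > 0))
})

test_that("particulate food is attributed 100% to host cells", {
  p <- particulate_partition("bacteria", 75, 25, "C")
  expect_equal(p$pct_host, 100)
  expect_equal(p$pct_microbe, 0)
  expect_equal(p$pct_host + p$pct_microbe, 100)
  expect_error(particulate_partition("algal_DOM"), "particulate")
})

test_that("fraction route recovers true shares on synthetic data", {
  cfg <- sip_config("HMA")
  truth <- 100 * cfg$share_c[["algal_DOM"]]
  ests <- vapply(1:40, function(i) {
    d <- simulate_tracer_experiment(cfg, seed = 1000 + i)
    fx <- d$fractions[d$fractions$element == "C", ]
    g <- fx[fx$treatment == "algal_DOM", ]
    wide <- data.frame(
      delta_host = g$delta_permil[g$fraction == "host_fraction"],
      delta_microbe = g$delta_permil[g$fraction == "microbe_fraction"])
    d_ctl <- mean(fx$delta_permil[fx$treatment == "control"])
    fraction_partition(wide, d_ctl, "C",
                       census = list(n_host = cfg$n_host,
                                     n_microbe = cfg$n_microbe),
                       contents = list(c_host = cfg$c_host,
                                       c_microbe = cfg$c_microbe),
                       n_boot = 0)$pct_microbe
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 3 * se + 0.5)
  # LMA defaults put the microbe DOM share below 5%
  lma <- sip_config("LMA")
  d <- simulate_tracer_experiment(lma, seed = 77)
  fx <- d$fractions[d$fractions$element == "C", ]
  g <- fx[fx$treatment == "algal_DOM", ]
  wide <- data.frame(
    delta_host = g$delta_permil[g$fraction == "host_fraction"],
    delta_microbe = g$delta_permil[g$fraction == "microbe_fraction"])
  d_ctl <- mean(fx$delta_permil[fx$treatment == "control"])
  est <- fraction_partition(wide, d_ctl, "C",
                            census = list(n_host = lma$n_host,
                                          n_microbe = lma$n_microbe),
                            contents = list(c_host = lma$c_host,
                                            c_microbe = lma$c_microbe),
                            n_boot = 0)$pct_microbe
  expect_lt(est, 5)
})
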