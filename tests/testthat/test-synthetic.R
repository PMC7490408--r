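test_that("configs validate fields and hold the documented biomass anchors", {
  expect_error(sip_config("HMA", not_a_field = 1), "unknown config fields")
  hma <- sip_config("HMA")
  lma <- sip_config("LMA")
  expect_equal(hma$purity_microbe, 0.99)
  expect_equal(hma$purity_host, 0.85)
  # implied microbe biomass anchors: ~25% (HMA) and <0.5% (LMA)
  bh <- biomass_fractions(hma$n_host, hma$n_microbe, hma$c_host,
                          hma$c_microbe)
  bl <- biomass_fractions(lma$n_host, lma$n_microbe, lma$c_host,
                          lma$c_microbe)
  expect_equal(bh$pct_microbe, 25, tolerance = 0.1)
  expect_lt(bl$pct_microbe, 0.5)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sip_config("HMA")
  expect_identical(simulate_tracer_experiment(cfg, seed = 9),
                   simulate_tracer_experiment(cfg, seed = 9))
  expect_identical(simulate_inex(cfg, seed = 9), simulate_inex(cfg, seed = 9))
  sc <- small_scene_cfg()
  expect_identical(simulate_nanosims_stack(sc, seed = 9),
                   simulate_nanosims_stack(sc, seed = 9))
  # a different seed changes the data
  expect_false(identical(simulate_inex(cfg, seed = 9),
                         simulate_inex(cfg, seed = 10)))
})

test_that("noiseless tracer generation + pipeline is the identity on truth", {
  cfg <- noiseless_cfg("HMA")
  d <- simulate_tracer_experiment(cfg, seed = 13)
  rep <- run_full_analysis(d, seed = 1, n_boot = 0, verbose = FALSE)
  pr <- rep$partition[rep$partition$method == "fraction", ]
  for (el in c("C", "N")) {
    tr_shares <- d$truth[[el]]$share
    for (tr in names(tr_shares)) {
      got <- pr$pct_microbe[pr$element == el & pr$treatment == tr]
      expect_equal(got, 100 * tr_shares[[tr]], tolerance = 1e-9)
    }
  }
  # biomass recovered exactly at zero count/filter noise
  expect_equal(pr$pct_host + pr$pct_microbe, rep(100, nrow(pr)),
               tolerance = 1e-9)
})

test_that("null NanoSIMS scenes carry no enrichment signal", {
  cfg <- small_scene_cfg(drift = 0)
  sim <- simulate_nanosims_stack(cfg, seed = 61, is_control = TRUE)
  sm <- accumulate_planes(sim$stack)
  cal <- make_cal(r_c = sim$truth$r_c_ctrl, r_n = sim$truth$r_n_ctrl)
  dd <- roi_deltas(sm, sim$rois, cal)
  n25 <- sum(dd$mass25); n24 <- sum(dd$mass24)
  d_hat <- (n25 / n24 / cal$r_c - 1) * 1000
  se <- 1000 * sqrt(1 / n25 + 1 / n24)
  expect_lt(abs(d_hat), 3 * se)
  expect_true(all(sim$truth$delta_c == 0))
})

test_that("scene placement fails loudly when cells cannot fit", {
  cfg <- small_scene_cfg(drift = 0, size = 48, n_bacteria = 300,
                         n_choanocyte = 2, max_tries = 50)
  expect_error(simulate_nanosims_stack(cfg, seed = 8), "density too high")
})

test_that("tracer dataset CSV round trip preserves the tables", {
  cfg <- sip_config("LMA")
  d <- simulate_tracer_experiment(cfg, seed = 17)
  dir <- file.path(tempdir(), "trds")
  write_tracer_dataset(d, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_tracer_dataset(dir, d$foods)
  expect_equal(back$bulk$delta13C_permil, d$bulk$delta13C_permil,
               tolerance = 1e-12)
  expect_equal(nrow(back$fractions), nrow(d$fractions))
  expect_equal(back$counts$n_microbe, d$counts$n_microbe, tolerance = 1e-9)
})
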