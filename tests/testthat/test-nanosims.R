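test_that("alignment returns zero shifts for drift-free stacks", {
  cfg <- small_scene_cfg(drift = 0)
  sim <- simulate_nanosims_stack(cfg, seed = 201)
  al <- align_planes(sim$stack)
  expect_true(all(al$shifts == 0L))
  expect_equal(dim(al$stack$counts), dim(sim$stack$counts))
})

test_that("alignment recovers injected drift and cropping only removes", {
  cfg <- small_scene_cfg(drift = 3)
  sim <- simulate_nanosims_stack(cfg, seed = 202)
  expect_true(any(sim$truth$shifts != 0L))
  al <- align_planes(sim$stack)
  expect_identical(al$shifts, sim$truth$shifts)
  for (ch in 1:4)
    expect_lte(sum(al$stack$counts[, , ch, ]), sum(sim$stack$counts[, , ch, ]))
  # a stack drifted beyond the tolerated fraction fails loudly
  expect_error(align_planes(sim$stack, max_shift_frac = 0.01), "alignment")
})

test_that("plane accumulation conserves counts", {
  one <- matrix(3L, 16, 16)
  arr <- array(0L, c(16, 16, 4, 10))
  for (p in 1:10) for (ch in 1:4) arr[, , ch, p] <- one
  st <- nsims_stack(arr)
  sm <- accumulate_planes(st)
  expect_true(all(sm$mass24 == 30L))
  expect_equal(sum(sm$mass26), sum(st$counts[, , 3, ]))
  # Poisson planes: mean of the sum ~ planes x rate
  set.seed(11)
  lam <- 7
  arr2 <- array(rpois(16 * 16 * 4 * 10, lam), c(16, 16, 4, 10))
  sm2 <- accumulate_planes(nsims_stack(arr2))
  expect_lt(abs(mean(sm2$mass24) - 10 * lam),
            3 * sqrt(10 * lam / (16 * 16)))
})

test_that("ratio maps divide channels and mask starved pixels", {
  den <- matrix(1000L, 8, 8)
  num <- matrix(as.integer(0.0112 * 1000), 8, 8)
  den[1, 1] <- 0L
  den[2, 2] <- 19L
  sm <- make_summed(den, num, den, num)
  rm <- ratio_maps(sm, min_counts = 20)
  expect_true(is.na(rm$r_c[1, 1]))
  expect_true(is.na(rm$r_c[2, 2]))
  expect_equal(rm$r_c[3, 3], 11 / 1000)
  expect_true(all(rm$r_c[!is.na(rm$r_c)] == 11 / 1000))
})

test_that("ROI deltas are ratio-of-sums against the control ratio", {
  r0 <- 11 / 500
  cal <- make_cal(r_c = r0)
  den <- matrix(500L, 10, 10)
  num <- matrix(11L, 10, 10)        # exactly the control ratio
  num[, 6:10] <- 22L                # doubled minor isotope
  lab <- matrix(0L, 10, 10)
  lab[, 1:5] <- 1L
  lab[, 6:10] <- 2L
  rois <- roi_set(lab, data.frame(roi_id = 1:2,
                                  cell_type = c("choanocyte", "choanocyte")),
                  pixel_um = NA)
  dd <- roi_deltas(make_summed(den, num, den, num), rois, cal)
  expect_equal(dd$delta13C[1], 0, tolerance = 1e-6)
  expect_equal(dd$delta13C[2], 1000, tolerance = 1e-6)
  # union of two disjoint ROIs lies between the two deltas
  lab_u <- matrix(1L, 10, 10)
  rois_u <- roi_set(lab_u, data.frame(roi_id = 1, cell_type = "choanocyte"),
                    pixel_um = NA)
  du <- roi_deltas(make_summed(den, num, den, num), rois_u, cal)
  expect_gt(du$delta13C, min(dd$delta13C))
  expect_lt(du$delta13C, max(dd$delta13C))
  # under-count ROI excluded with a reason
  den2 <- matrix(0L, 10, 10)
  dd2 <- roi_deltas(make_summed(den2, num, den2, num), rois, cal)
  expect_true(all(is.na(dd2$delta13C)))
  expect_true(all(grepl("low_C_counts", dd2$exclude_reason)))
})

test_that("painted compartment deltas are recovered within Poisson error", {
  cfg <- small_scene_cfg(drift = 0)
  for (d_true in c(0, 500, 1000)) {
    sim <- simulate_nanosims_stack(cfg, seed = 300 + d_true,
                                   paint = list(delta_c = c(
                                     bacteria = d_true, choanocyte = d_true,
                                     mesohyl_other = d_true)))
    sm <- accumulate_planes(sim$stack)
    cal <- make_cal(r_c = sim$truth$r_c_ctrl, r_n = sim$truth$r_n_ctrl)
    dd <- roi_deltas(sm, sim$rois, cal)
    # pooled delta per cell type, with its Poisson-propagated SE
    for (ty in unique(dd$cell_type)) {
      g <- dd[dd$cell_type == ty, ]
      n25 <- sum(g$mass25); n24 <- sum(g$mass24)
      d_hat <- (n25 / n24 / cal$r_c - 1) * 1000
      se <- (1000 + d_hat) * sqrt(1 / n25 + 1 / n24)
      expect_lt(abs(d_hat - d_true), 3 * se)
    }
  }
})

test_that("the 2-SD rule classifies against per-type control stats", {
  stats <- data.frame(cell_type = rep(c("bacteria", "choanocyte"), each = 2),
                      element = c("C", "N", "C", "N"),
                      mean = c(0, 0, 10, 5), sd = c(20, 30, 5, 8),
                      n = 50)
  cal <- make_cal(stats = stats)
  dd <- data.frame(roi_id = 1:4,
                   cell_type = c("bacteria", "bacteria", "choanocyte",
                                 "choanocyte"),
                   delta13C = c(0 + 2.5 * 20, 0 + 1.9 * 20,
                                10 + 2.5 * 5, 10 + 1.9 * 5),
                   delta15N = c(100, -10, 5 + 2.01 * 8, NA))
  out <- classify_enriched(dd, cal)
  expect_equal(out$enriched_c, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$enriched_n, c(TRUE, FALSE, TRUE, NA))
  dd$cell_type[1] <- "mesohyl_other"
  expect_error(classify_enriched(dd, cal), "control statistics")
})

test_that("false-positive rate of the 2-SD rule is the one-sided normal tail", {
  set.seed(12)
  mu <- 3; sig <- 40
  # control stats estimated from a large control ROI sample
  ctrl <- rnorm(2000, mu, sig)
  stats <- data.frame(cell_type = "bacteria", element = "C",
                      mean = mean(ctrl), sd = sd(ctrl), n = length(ctrl))
  cal <- make_cal(stats = stats)
  nulls <- data.frame(roi_id = seq_len(2000), cell_type = "bacteria",
                      delta13C = rnorm(2000, mu, sig),
                      delta15N = NA_real_)
  out <- classify_enriched(nulls, cal)
  fpr <- mean(out$enriched_c)
  p0 <- pnorm(2, lower.tail = FALSE)   # 0.02275
  expect_lt(abs(fpr - p0), 1.96 * sqrt(p0 * (1 - p0) / 2000))
})

test_that("hotspot extraction finds injected blocks and nothing else", {
  cfg <- small_scene_cfg(drift = 0)
  ctl <- simulate_nanosims_stack(cfg, seed = 401, is_control = TRUE)
  smc <- accumulate_planes(ctl$stack)
  cal <- control_calibration(smc, ctl$rois)
  # control choanocytes: no hotspots
  hs0 <- extract_hotspots(smc, ctl$rois, cal, "C")
  expect_equal(nrow(hs0$table), 0)
  # injected 6x6 block at 2000 permil inside an enriched choanocyte
  sim <- simulate_nanosims_stack(cfg, seed = 402,
                                 hotspot = list(delta = 2000, size = 6, n = 1))
  sm <- accumulate_planes(sim$stack)
  hs <- extract_hotspots(sm, sim$rois, cal, "C")
  expect_equal(nrow(hs$table), 1)
  covered <- sum(hs$labels > 0 & sim$truth$hotspot_mask) /
    sum(sim$truth$hotspot_mask)
  expect_gte(covered, 0.8)
  # hotspot pixels are contained in the parent choanocyte
  parent <- hs$table$parent_roi[1]
  expect_true(all(sim$rois$labels[hs$labels > 0] == parent))
  expect_equal(sim$rois$table$cell_type[sim$rois$table$roi_id == parent],
               "choanocyte")
})

test_that("enrichment summaries count proportions per type", {
  dd <- data.frame(roi_id = 1:10, cell_type = "bacteria",
                   delta13C = c(rep(500, 8), 0, 0),
                   delta15N = 0,
                   enriched_c = c(rep(TRUE, 8), FALSE, FALSE),
                   enriched_n = FALSE)
  s <- suppressWarnings(enrichment_summary(dd))
  expect_equal(s$prop_enriched[s$element == "C"], 0.8)
  expect_equal(s$n[s$element == "C"], 10)
  expect_warning(enrichment_summary(dd), "only 10 ROIs")
})

test_that("NanoSIMS partition mirrors the biomass-weighted rule", {
  cal <- make_cal()
  mk <- function(db, dc) data.frame(
    roi_id = 1:4, cell_type = c("bacteria", "bacteria", "choanocyte",
                                "choanocyte"),
    delta13C = c(db, db, dc, dc), delta15N = NA_real_)
  # equal specific enrichment: share equals biomass share
  p <- nanosims_partition(mk(300, 300), cal, 75, 25, "C")
  expect_equal(p$pct_microbe, 25, tolerance = 1e-9)
  # zero bacterial excess: zero microbe share
  p0 <- nanosims_partition(mk(0, 300), cal, 75, 25, "C")
  expect_equal(p0$pct_microbe, 0)
  # empty compartment: no estimate, not an error
  dd <- mk(300, 300)[3:4, ]
  pe <- nanosims_partition(dd, cal, 75, 25, "C")
  expect_equal(pe$status, "no_estimate")
})

test_that("stack and ROI TIFF round trips preserve integer data", {
  cfg <- small_scene_cfg(drift = 0, size = 64, n_bacteria = 5,
                         n_choanocyte = 1)
  sim <- simulate_nanosims_stack(cfg, seed = 77)
  pre <- file.path(tempdir(), "stk")
  write_stack_tiff(sim$stack, pre)
  st2 <- read_stack_tiff(pre)
  expect_identical(sim$stack$counts, st2$counts)
  expect_equal(st2$raster_um, sim$stack$raster_um)
  pre2 <- file.path(tempdir(), "roi")
  write_roi_tiff(sim$rois, pre2)
  r2 <- read_roi_tiff(pre2)
  expect_identical(sim$rois$labels, r2$labels)
  expect_equal(sim$rois$table$cell_type, r2$table$cell_type)
})
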