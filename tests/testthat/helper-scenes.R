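# shared fixtures: small NanoSIMS scenes and hand-built containers

small_scene_cfg <- function(species = "HMA", drift = 3, ...) {
  base <- sip_config(species)$scene
  sc <- modifyList(base, list(size = 128, planes = 6, n_bacteria = 20,
                              n_choanocyte = 2, n_mesohyl = 0,
                              drift_max = drift))
  dots <- list(...)
  if (length(dots)) sc <- modifyList(sc, dots)
  sip_config(species, scene = sc)
}

# align + accumulate + crop the ROI mask to the common window
process_scene <- function(sim) {
  al <- align_planes(sim$stack)
  sm <- accumulate_planes(al$stack)
  w <- al$window
  lab <- sim$rois$labels[seq(w$rows[1], w$rows[2]),
                         seq(w$cols[1], w$cols[2])]
  list(summed = sm, rois = roi_set(lab, sim$rois$table, pixel_um = NA),
       shifts = al$shifts)
}

make_summed <- function(m24, m25, m26, m27) {
  storage.mode(m24) <- storage.mode(m25) <- "integer"
  storage.mode(m26) <- storage.mode(m27) <- "integer"
  structure(list(mass24 = m24, mass25 = m25, mass26 = m26, mass27 = m27,
                 pixel_um = 30 / 256, species = NA, treatment = NA,
                 is_control = FALSE),
            class = "nsims_summed")
}

make_cal <- function(r_c = 0.0224, r_n = 0.00368, stats = NULL,
                     pixel_stats = NULL) {
  structure(list(r_c = r_c, r_n = r_n, stats = stats,
                 pixel_stats = pixel_stats, pool_types = FALSE),
            class = "nsims_calibration")
}

# zero-noise HMA configuration: the pipeline must become the identity
noiseless_cfg <- function(species = "HMA") {
  sip_config(species, delta_noise_sd = 0, count_cv = 0, filter_cv = 0)
}
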