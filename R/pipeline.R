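#' Run the full host/symbiont partitioning analysis
#'
#' Orchestrates every stage on whatever input classes are present in
#' `data`: bulk-tissue uptake rates, fraction-route partitioning with
#' purity correction and bootstrap CIs, NanoSIMS-route partitioning from
#' ion-image scenes, in situ diet summaries, and the headline integration
#' (symbiont share of the total heterotrophic diet). Missing input
#' classes skip their stage (and dependent stages) with a logged message.
#'
#' @param data list with any of:
#'   * `bulk`, `foods`: bulk tracer table and food-source list
#'     (see [bulk_uptake_table()]);
#'   * `fractions`, `counts`, `filters`: cell-separation tables as
#'     produced by [simulate_tracer_experiment()];
#'   * `nanosims`: list with `scenes` and `controls`, each a list of
#'     `list(stack =, rois =)` entries;
#'   * `inex`: in situ records for [diet_summary()].
#' @param seed integer seed governing every stochastic step (bootstraps).
#' @param n_boot bootstrap resamples for partition and diet CIs.
#' @param dom_source treatment whose microbe share feeds the diet
#'   integration (default `"algal_DOM"`, the source closest to the
#'   natural DOM pool).
#' @param correct_purity,clamp passed to the fraction route.
#' @param exclude_nonpumping passed to [diet_summary()].
#' @param pool_time pool time points when computing uptake rates
#'   (default `TRUE`).
#' @param verbose print stage log messages (default `TRUE`).
#' @return Object of class `sip_report`: `uptake`, `partition` (both
#'   routes), `roi_summary`, `diet`, `headline` (per species: `f_doc`,
#'   `s_dom`, `symbiont_total_share` with CIs) and `config_hash`.
#' @export
run_full_analysis <- function(data, seed = 1L, n_boot = 2000,
                              dom_source = "algal_DOM",
                              correct_purity = TRUE, clamp = FALSE,
                              exclude_nonpumping = TRUE, pool_time = TRUE,
                              verbose = TRUE) {
  log <- function(...) if (verbose) message("[spongeSIP] ", ...)
  set.seed(seed)
  out <- list(seed = seed)
  out$config_hash <- config_hash(list(data = names(data), seed = seed,
                                      n_boot = n_boot,
                                      dom_source = dom_source,
                                      correct_purity = correct_purity,
                                      clamp = clamp))

  ## ---- bulk uptake rates ----
  if (!is.null(data$bulk) && !is.null(data$foods)) {
    out$uptake <- bulk_uptake_table(data$bulk, data$foods,
                                    by_time = !pool_time, clamp = clamp)
    log("bulk uptake rates: ", nrow(out$uptake), " sample x element rows")
  } else log("bulk stage skipped (no bulk table or food sources)")

  ## ---- compartment biomass from censuses and filters ----
  biomass <- NULL
  if (!is.null(data$counts) && !is.null(data$filters)) {
    pre <- data$counts[data$counts$source == "pre_separation", ]
    census <- list(n_host = mean(pre$n_host), n_microbe = mean(pre$n_microbe))
    pcc <- function(frac, el) {
      f <- data$filters[data$filters$fraction == frac, ]
      amount <- if (el == "C") f$C_umol else f$N_umol
      mean(per_cell_content(amount, f$n_cells_filtered, el))
    }
    biomass <- list(census = census)
    for (el in c("C", "N")) {
      contents <- list(c_host = pcc("host_fraction", el),
                       c_microbe = pcc("microbe_fraction", el))
      biomass[[el]] <- c(list(contents = contents),
                         biomass_fractions(census$n_host, census$n_microbe,
                                           contents$c_host, contents$c_microbe))
    }
    log(sprintf("biomass: microbe holds %.2f%% of C, %.2f%% of N",
                biomass$C$pct_microbe, biomass$N$pct_microbe))
  } else log("biomass stage skipped (no censuses or filters)")

  ## ---- fraction-route partition ----
  if (!is.null(data$fractions) && !is.null(biomass)) {
    fx <- data$fractions
    rows <- list()
    for (el in c("C", "N")) {
      fe <- fx[fx$element == el, ]
      ctl <- fe[fe$treatment == "control", ]
      if (nrow(ctl) == 0) stop("fraction table has no control rows")
      d_ctl <- mean(ctl$delta_permil)
      for (tr in setdiff(unique(fe$treatment), "control")) {
        if (el == "N" && !is.null(data$foods[[tr]]) &&
            is.na(data$foods[[tr]]$atom_frac_15n)) next  # unlabelled element
        g <- fe[fe$treatment == tr, ]
        if (tr == "bacteria") {
          p <- particulate_partition("bacteria",
                                     biomass[[el]]$biomass_host,
                                     biomass[[el]]$biomass_microbe, el)
          p$ci_low <- p$ci_high <- NA_real_
        } else {
          wide <- merge(
            g[g$fraction == "host_fraction",
              c("replicate", "delta_permil")],
            g[g$fraction == "microbe_fraction",
              c("replicate", "delta_permil")],
            by = "replicate", suffixes = c("_host", "_microbe"))
          names(wide)[2:3] <- c("delta_host", "delta_microbe")
          ph <- unique(g$purity[g$fraction == "host_fraction"])[1]
          pm <- unique(g$purity[g$fraction == "microbe_fraction"])[1]
          p <- fraction_partition(
            wide, d_ctl, el,
            census = biomass$census, contents = biomass[[el]]$contents,
            purity_host = ph, purity_microbe = pm,
            correct_purity = correct_purity, n_boot = n_boot)
        }
        rows[[paste(el, tr)]] <- data.frame(
          species = fx$species[1], treatment = tr, element = el,
          method = "fraction", pct_host = p$pct_host,
          pct_microbe = p$pct_microbe,
          ci_low = p$ci_low, ci_high = p$ci_high)
      }
    }
    out$partition <- do.call(rbind, rows)
    rownames(out$partition) <- NULL
    log("fraction-route partition: ", nrow(out$partition), " rows")
  } else log("fraction partition skipped (needs fractions + biomass)")

  ## ---- NanoSIMS route ----
  if (!is.null(data$nanosims) && !is.null(biomass)) {
    ns <- data$nanosims
    process <- function(entry) {
      al <- align_planes(entry$stack)
      sm <- accumulate_planes(al$stack)
      rois <- entry$rois
      # alignment cropping: keep the ROI mask in the common window
      w <- al$window
      rois$labels <- rois$labels[seq(w$rows[1], w$rows[2]),
                                 seq(w$cols[1], w$cols[2])]
      list(summed = sm, rois = roi_set(rois$labels, rois$table,
                                       pixel_um = NA))
    }
    ctl <- lapply(ns$controls, process)
    cal <- control_calibration(lapply(ctl, `[[`, "summed"),
                               lapply(ctl, `[[`, "rois"))
    scn <- lapply(ns$scenes, process)
    deltas <- do.call(rbind, lapply(seq_along(scn), function(i) {
      d <- roi_deltas(scn[[i]]$summed, scn[[i]]$rois, cal)
      d$treatment <- ns$scenes[[i]]$stack$treatment
      d$scene <- i
      d
    }))
    deltas <- classify_enriched(deltas, cal)
    out$roi_summary <- enrichment_summary(deltas, min_n = 1)
    out$calibration <- cal
    out$roi_deltas <- deltas
    rows <- list()
    for (tr in unique(deltas$treatment)) {
      for (el in c("C", "N")) {
        p <- nanosims_partition(deltas[deltas$treatment == tr, ], cal,
                                biomass[[el]]$biomass_host,
                                biomass[[el]]$biomass_microbe, el)
        rows[[paste(tr, el)]] <- data.frame(
          species = ns$scenes[[1]]$stack$species, treatment = tr,
          element = el, method = "nanosims",
          pct_host = p$pct_host, pct_microbe = p$pct_microbe,
          ci_low = NA_real_, ci_high = NA_real_)
      }
    }
    out$partition <- rbind(out$partition, do.call(rbind, rows))
    rownames(out$partition) <- NULL
    log("NanoSIMS route: ", length(scn), " scenes, ",
        nrow(deltas), " ROIs")
  } else if (!is.null(data$nanosims)) {
    log("NanoSIMS partition skipped (needs biomass for weighting)")
  } else log("NanoSIMS stage skipped (no scenes)")

  ## ---- in situ diet and headline ----
  if (!is.null(data$inex)) {
    s_dom <- NULL
    if (!is.null(out$partition)) {
      pr <- out$partition
      pick <- pr$treatment == dom_source & pr$element == "C" &
        pr$method == "fraction"
      if (any(pick)) {
        s_dom <- setNames(pr$pct_microbe[pick] / 100, pr$species[pick])
        log(sprintf("symbiont DOM-C share (%s): %.1f%%",
                    dom_source, 100 * s_dom[1]))
      }
    }
    out$diet <- diet_summary(data$inex, s_dom = s_dom, n_boot = n_boot,
                             exclude_nonpumping = exclude_nonpumping)
    if (!is.null(s_dom)) {
      out$headline <- out$diet$summary[
        , intersect(c("species", "f_doc", "f_doc_ci_low", "f_doc_ci_high",
                      "s_dom", "symbiont_total_share",
                      "share_ci_low", "share_ci_high"),
                    names(out$diet$summary))]
      log("headline: symbiont total-diet share computed")
    } else log("headline skipped (no DOM partition available)")
  } else log("in situ stage skipped (no InEx records)")

  class(out) <- "sip_report"
  out
}

#' @export
print.sip_report <- function(x, digits = 3, ...) {
  cat("spongeSIP analysis report (seed ", x$seed, ", config ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  if (!is.null(x$uptake)) {
    agg <- aggregate(rate ~ species + treatment + element, x$uptake, mean)
    cat("\nMean bulk uptake rates (umol mmol-1 h-1):\n")
    print(format(agg, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$partition)) {
    cat("\nHost/symbiont partition (% of assimilation):\n")
    print(format(x$partition, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$headline)) {
    cat("\nSymbiont share of total heterotrophic C:\n")
    print(format(x$headline, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

## stable hash of an R object (md5 of its serialization)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
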