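#' Per-cell elemental content from a filtered cell fraction
#'
#' Elemental analysis of a filter holding a known number of separated
#' cells gives the mean content per cell. Input is umol of element on the
#' filter; output is pg per cell (umol x molar mass -> ug, x 1e6 -> pg).
#'
#' @param amount_umol umol of C or N measured on the filter, >= 0.
#' @param n_cells number of cells filtered, > 0.
#' @param element `"C"` (molar mass 12) or `"N"` (14).
#' @return pg of element per cell.
#' @examples
#' per_cell_content(8, 1e8, "C")  # 0.96 pg C per cell
#' @export
per_cell_content <- function(amount_umol, n_cells, element = c("C", "N")) {
  element <- match.arg(element)
  if (any(n_cells <= 0)) stop("number of cells filtered must be positive")
  if (any(amount_umol < 0)) stop("element amount cannot be negative")
  mm <- c(C = 12, N = 14)[[element]]
  amount_umol * mm * 1e6 / n_cells
}

#' Host and microbe biomass fractions
#'
#' Percent of total cellular element biomass in each compartment, from a
#' pre-separation cell census and mean per-cell contents.
#'
#' @param n_host,n_microbe cell counts per unit tissue (pre-separation).
#' @param c_host,c_microbe per-cell element content, pg per cell.
#' @return List with `pct_host`, `pct_microbe` (summing to 100),
#'   `biomass_host`, `biomass_microbe` (pg per unit tissue).
#' @examples
#' biomass_fractions(1e6, 1e8, 100, 0.25)  # microbes hold 20% of biomass
#' @export
biomass_fractions <- function(n_host, n_microbe, c_host, c_microbe) {
  stopifnot(n_host >= 0, n_microbe >= 0, c_host > 0, c_microbe > 0)
  bh <- n_host * c_host
  bm <- n_microbe * c_microbe
  if (bh + bm <= 0) stop("total biomass is zero")
  list(pct_host = 100 * bh / (bh + bm),
       pct_microbe = 100 * bm / (bh + bm),
       biomass_host = bh, biomass_microbe = bm)
}

#' Biomass-weighted purity mixing matrix
#'
#' Cell-separation purities are reported as fractions of cells of the
#' intended type. Isotope measurements of a fraction, however, average
#' over element biomass, so count purities are converted to biomass
#' weights using per-cell contents. Row 1 is the host fraction, row 2 the
#' microbial fraction; columns are the (host, microbe) compartments.
#'
#' @param purity_host,purity_microbe cell-count purity of the host and
#'   microbial fractions, in (0, 1].
#' @param c_host,c_microbe per-cell element content, pg per cell.
#' @return 2x2 mixing matrix with rows summing to 1.
#' @export
mixing_matrix <- function(purity_host, purity_microbe, c_host, c_microbe) {
  stopifnot(purity_host > 0, purity_host <= 1,
            purity_microbe > 0, purity_microbe <= 1,
            c_host > 0, c_microbe > 0)
  w_hh <- purity_host * c_host /
    (purity_host * c_host + (1 - purity_host) * c_microbe)
  w_mm <- purity_microbe * c_microbe /
    (purity_microbe * c_microbe + (1 - purity_microbe) * c_host)
  matrix(c(w_hh, 1 - w_mm, 1 - w_hh, w_mm), nrow = 2,
         dimnames = list(c("host_fraction", "microbe_fraction"),
                         c("host", "microbe")))
}

#' Unmix measured fraction enrichments into compartment enrichments
#'
#' Separated cell fractions are impure, so the enrichment measured on a
#' fraction is a biomass-weighted mixture of the true host and microbe
#' compartment enrichments. Solving the 2x2 linear system M E = E_meas
#' recovers the compartment values; with perfect purities the
#' measurements pass through unchanged.
#'
#' @param e_meas_host,e_meas_microbe measured excess atom fraction of the
#'   host and microbial cell fraction.
#' @param M mixing matrix from [mixing_matrix()].
#' @return Named numeric vector `c(host = , microbe = )` of unmixed
#'   excess atom fractions (possibly negative; clamping is left to the
#'   caller).
#' @export
unmix_fraction_enrichment <- function(e_meas_host, e_meas_microbe, M) {
  stopifnot(is.matrix(M), all(dim(M) == 2))
  if (kappa(M, exact = TRUE) > 1e8)
    stop("degenerate fraction composition: mixing matrix is near-singular")
  e <- solve(M, c(e_meas_host, e_meas_microbe))
  c(host = unname(e[1]), microbe = unname(e[2]))
}

#' Partition assimilation between host and symbiont compartments
#'
#' The share of total element assimilation attributable to each
#' compartment is the product of compartment biomass and compartment
#' specific enrichment (excess atom fraction), normalised to 100%:
#' \deqn{pct_{microbe} = 100 \, B_m E_m / (B_m E_m + B_h E_h).}
#' Negative enrichments (noise) are clamped to zero for the shares; the
#' unclamped values are kept in the diagnostics.
#'
#' @param e_host,e_microbe compartment excess atom fractions.
#' @param biomass_host,biomass_microbe compartment element biomass (any
#'   common unit, e.g. pg per unit tissue or mmol).
#' @param element `"C"` or `"N"` (metadata only).
#' @return Object of class `partition_result`: `pct_host`,
#'   `pct_microbe`, `biomass_pct_microbe`, `status` (`"ok"` or
#'   `"no_uptake"` when both enrichments are <= 0, in which case the
#'   percentages are `NA`), and `diagnostics` with the unclamped inputs.
#' @examples
#' partition_uptake(0.001, 0.001, 75, 25)  # equal specific enrichment
#' @export
partition_uptake <- function(e_host, e_microbe, biomass_host, biomass_microbe,
                             element = "C") {
  stopifnot(biomass_host > 0, biomass_microbe > 0)
  eh <- max(e_host, 0)
  em <- max(e_microbe, 0)
  tot <- biomass_host * eh + biomass_microbe * em
  if (tot <= 0) {
    res <- list(element = element, pct_host = NA_real_, pct_microbe = NA_real_,
                status = "no_uptake")
  } else {
    pm <- 100 * biomass_microbe * em / tot
    res <- list(element = element, pct_host = 100 - pm, pct_microbe = pm,
                status = "ok")
  }
  res$biomass_pct_microbe <-
    100 * biomass_microbe / (biomass_host + biomass_microbe)
  res$diagnostics <- list(e_host = e_host, e_microbe = e_microbe,
                          biomass_host = biomass_host,
                          biomass_microbe = biomass_microbe)
  class(res) <- "partition_result"
  res
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Host/symbiont assimilation partition (", x$element, ")\n", sep = "")
  if (x$status == "no_uptake") {
    cat("  no detectable uptake in either compartment\n")
  } else {
    cat(sprintf("  host:    %6.2f %%\n  microbe: %6.2f %%\n",
                x$pct_host, x$pct_microbe))
  }
  cat(sprintf("  microbe biomass share: %.2f %%\n", x$biomass_pct_microbe))
  invisible(x)
}

#' Partition for a particulate (POM) food source
#'
#' Sponges capture particulate food by host-cell phagocytosis, so the
#' particulate treatment is attributed entirely to host cells; symbionts
#' receive a fixed 0% share. Dissolved treatments must never be routed
#' here.
#'
#' @param treatment treatment label; must be a particulate source
#'   (`"bacteria"`).
#' @inheritParams partition_uptake
#' @return A `partition_result` with `pct_host = 100`.
#' @export
particulate_partition <- function(treatment = "bacteria",
                                  biomass_host = 1, biomass_microbe = 1,
                                  element = "C") {
  if (!treatment %in% "bacteria")
    stop("particulate partition applies only to particulate (POM) treatments")
  res <- list(element = element, pct_host = 100, pct_microbe = 0,
              status = "ok",
              biomass_pct_microbe =
                100 * biomass_microbe / (biomass_host + biomass_microbe),
              diagnostics = list(rule = "POM assimilated by host cells only"))
  class(res) <- "partition_result"
  res
}

#' Fraction-route partition with purity correction and bootstrap CI
#'
#' Full fraction-based partitioning for one species x treatment x
#' element: converts replicate fraction delta measurements to excess atom
#' fractions, unmixes them through the purity matrix (optional), averages
#' replicates, and partitions by compartment biomass. Uncertainty comes
#' from a nonparametric bootstrap over replicate measurement pairs.
#'
#' @param fractions data.frame with one row per replicate and columns
#'   `delta_host`, `delta_microbe` (per-mil values of the host and
#'   microbial cell fraction) for the element of interest.
#' @param delta_control per-mil control baseline for the fractions.
#' @param element `"C"` or `"N"`.
#' @param census list/row with `n_host`, `n_microbe` (pre-separation).
#' @param contents list/row with per-cell contents `c_host`, `c_microbe`
#'   (pg per cell for this element).
#' @param purity_host,purity_microbe cell-count purities; defaults match
#'   typical separations (>85% host, >99% microbial fraction).
#' @param correct_purity logical, apply the unmixing correction
#'   (default `TRUE`); the uncorrected result is always reported in
#'   `$uncorrected`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed optional integer seed for the bootstrap.
#' @return A `partition_result` with extra fields `ci_low`, `ci_high`
#'   (95% percentile bootstrap CI on `pct_microbe`), `uncorrected`
#'   (microbe share without purity correction) and `n_replicates`.
#' @export
fraction_partition <- function(fractions, delta_control, element = c("C", "N"),
                               census, contents,
                               purity_host = 0.85, purity_microbe = 0.99,
                               correct_purity = TRUE,
                               n_boot = 2000, seed = NULL) {
  element <- match.arg(element)
  stopifnot(is.data.frame(fractions),
            all(c("delta_host", "delta_microbe") %in% names(fractions)),
            nrow(fractions) >= 1)
  r_ref <- iso_ref[[element]]
  bio <- biomass_fractions(census$n_host, census$n_microbe,
                           contents$c_host, contents$c_microbe)
  M <- mixing_matrix(purity_host, purity_microbe,
                     contents$c_host, contents$c_microbe)

  share_of <- function(rows, correct) {
    eh_meas <- mean(excess_from_delta(rows$delta_host, delta_control, r_ref))
    em_meas <- mean(excess_from_delta(rows$delta_microbe, delta_control, r_ref))
    e <- if (correct) unmix_fraction_enrichment(eh_meas, em_meas, M)
         else c(host = eh_meas, microbe = em_meas)
    partition_uptake(e[["host"]], e[["microbe"]],
                     bio$biomass_host, bio$biomass_microbe, element)
  }

  res <- share_of(fractions, correct_purity)
  res$uncorrected <- share_of(fractions, FALSE)$pct_microbe
  res$n_replicates <- nrow(fractions)

  if (n_boot > 0 && nrow(fractions) > 1) {
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(fractions), replace = TRUE)
      share_of(fractions[idx, , drop = FALSE], correct_purity)$pct_microbe
    }, numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
    res$ci_low <- ci[1]
    res$ci_high <- ci[2]
  } else {
    res$ci_low <- res$ci_high <- NA_real_
  }
  res
}
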