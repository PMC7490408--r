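#' International reference isotope ratios
#'
#' Reference ratios used to convert between delta notation and absolute
#' isotope ratios: Vienna Pee Dee Belemnite for carbon (13C/12C) and
#' atmospheric N2 for nitrogen (15N/14N).
#'
#' @format A named numeric vector with elements `C` (0.01118) and
#'   `N` (0.00368).
#' @export
iso_ref <- c(C = 0.01118, N = 0.00368)

#' Convert an isotope ratio to delta notation
#'
#' Delta notation expresses the minor/major isotope ratio of a sample as a
#' per-mil deviation from a reference ratio:
#' \deqn{\delta = (R_{sample}/R_{ref} - 1) \times 1000.}
#'
#' @param r_sample numeric, isotope ratio(s) of the sample (e.g. 13C/12C).
#'   Must be positive.
#' @param r_ref numeric, reference isotope ratio. Defaults to the VPDB
#'   carbon ratio; see [iso_ref].
#' @return Numeric vector of delta values in per mil.
#' @seealso [ratio_from_delta()], [atom_fraction()]
#' @examples
#' delta_from_ratio(0.02236, iso_ref["C"])  # 1000 permil
#' @export
delta_from_ratio <- function(r_sample, r_ref = iso_ref[["C"]]) {
  if (any(!is.finite(r_sample)) || any(r_sample <= 0))
    stop("isotope ratios must be positive and finite")
  if (any(!is.finite(r_ref)) || any(r_ref <= 0))
    stop("reference ratio must be positive and finite")
  (r_sample / r_ref - 1) * 1000
}

#' Convert a delta value to an isotope ratio
#'
#' Algebraic inverse of [delta_from_ratio()].
#'
#' @param delta numeric, per-mil delta value(s); must exceed -1000.
#' @param r_ref numeric, reference isotope ratio.
#' @return Numeric vector of isotope ratios.
#' @export
ratio_from_delta <- function(delta, r_ref = iso_ref[["C"]]) {
  if (any(!is.finite(delta)) || any(delta <= -1000))
    stop("delta values must be finite and > -1000 permil")
  if (any(!is.finite(r_ref)) || any(r_ref <= 0))
    stop("reference ratio must be positive and finite")
  r_ref * (1 + delta / 1000)
}

#' Atom fraction of the minor isotope
#'
#' Converts a minor/major isotope ratio R to the minor-isotope atom
#' fraction F = R / (1 + R), the quantity that is conserved under mixing
#' and used for tracer bookkeeping.
#'
#' @param r numeric, isotope ratio(s); must be positive.
#' @return Atom fractions in (0, 1).
#' @export
atom_fraction <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("isotope ratios must be positive and finite")
  r / (1 + r)
}

#' Ratio from atom fraction
#'
#' Inverse of [atom_fraction()]: R = F / (1 - F).
#'
#' @param f numeric atom fraction(s) in (0, 1).
#' @return Isotope ratios.
#' @export
ratio_from_atom_fraction <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("atom fractions must lie in (0, 1)")
  f / (1 - f)
}

#' Excess atom fraction over a control baseline
#'
#' The tracer signal: sample atom fraction minus the control (natural
#' abundance) atom fraction. Negative values can arise from measurement
#' noise and are retained; use `clamp = TRUE` to truncate at zero.
#'
#' @param f_sample,f_control atom fractions in (0, 1).
#' @param clamp logical; truncate negative excess at 0 (default `FALSE`,
#'   which keeps means unbiased).
#' @return Excess atom fraction (may be negative unless clamped).
#' @export
excess_atom_fraction <- function(f_sample, f_control, clamp = FALSE) {
  stopifnot(all(f_sample > 0 & f_sample < 1), all(f_control > 0 & f_control < 1))
  e <- f_sample - f_control
  if (clamp) e <- pmax(e, 0)
  e
}

#' Delta value to excess atom fraction
#'
#' Convenience composition: converts a measured delta value and a control
#' baseline delta into the excess atom fraction of the tracer.
#'
#' @param delta,delta_control per-mil delta values.
#' @param r_ref reference isotope ratio for the element.
#' @inheritParams excess_atom_fraction
#' @return Excess atom fraction.
#' @export
excess_from_delta <- function(delta, delta_control, r_ref = iso_ref[["C"]],
                              clamp = FALSE) {
  excess_atom_fraction(atom_fraction(ratio_from_delta(delta, r_ref)),
                       atom_fraction(ratio_from_delta(delta_control, r_ref)),
                       clamp = clamp)
}

#' Describe a labelled food source
#'
#' A food source is characterised, per element, by the atom fraction of
#' the heavy label and the natural-abundance baseline; the difference is
#' the labelling strength used to normalise uptake rates.
#'
#' @param name character, e.g. "glucose", "amino_acids", "algal_DOM",
#'   "bacteria".
#' @param atom_frac_13c,atom_frac_15n label atom fractions in \[0, 1\].
#'   `atom_frac_15n = NA` marks a source labelled in carbon only.
#' @param natural_frac_13c,natural_frac_15n natural-abundance atom
#'   fractions; defaults derive from [iso_ref].
#' @param conc_added concentration added to the incubation, umol C per L
#'   (default 80, matching addition at about ambient DOC levels).
#' @return A list of class `food_source`.
#' @export
food_source <- function(name,
                        atom_frac_13c,
                        atom_frac_15n = NA_real_,
                        natural_frac_13c = atom_fraction(iso_ref[["C"]]),
                        natural_frac_15n = atom_fraction(iso_ref[["N"]]),
                        conc_added = 80) {
  stopifnot(is.character(name), length(name) == 1L,
            atom_frac_13c >= 0, atom_frac_13c <= 1,
            conc_added > 0)
  if (atom_frac_13c < natural_frac_13c)
    stop("label atom fraction below natural abundance for 13C")
  if (!is.na(atom_frac_15n) && atom_frac_15n < natural_frac_15n)
    stop("label atom fraction below natural abundance for 15N")
  structure(list(name = name,
                 atom_frac_13c = atom_frac_13c,
                 atom_frac_15n = atom_frac_15n,
                 natural_frac_13c = natural_frac_13c,
                 natural_frac_15n = natural_frac_15n,
                 conc_added = conc_added),
            class = "food_source")
}

#' Labelling strength of a food source
#'
#' Label minus natural atom fraction for the requested element.
#'
#' @param food a [food_source()].
#' @param element `"C"` or `"N"`.
#' @return Excess atom fraction of the food; errors if the source is
#'   unlabelled in that element.
#' @export
food_excess <- function(food, element = c("C", "N")) {
  element <- match.arg(element)
  x <- if (element == "C") food$atom_frac_13c - food$natural_frac_13c
       else food$atom_frac_15n - food$natural_frac_15n
  if (is.na(x) || x <= 0)
    stop("food source '", food$name, "' carries no ", element, " label")
  x
}

#' Bulk-tissue tracer uptake rate
#'
#' Converts the isotopic enrichment of bulk tissue relative to unlabelled
#' controls into an element assimilation rate. The excess atom fraction of
#' the tissue is normalised by the labelling strength of the food source
#' and by incubation time:
#' \deqn{\rho = 1000 \cdot E_{sample} / (x_{food} \cdot t)}
#' in umol element assimilated per mmol element tissue per hour (the
#' factor 1000 converts the mmol tissue basis).
#'
#' @param delta numeric, per-mil delta value(s) of the tissue sample(s).
#' @param delta_control per-mil control baseline (typically the mean of
#'   unlabelled controls of the same species).
#' @param food a [food_source()].
#' @param element `"C"` or `"N"`.
#' @param time_h incubation time in hours, > 0.
#' @param clamp logical, truncate negative rates at zero (off by default
#'   so treatment means stay unbiased at low enrichment).
#' @return data.frame with columns `excess` (tissue excess atom fraction)
#'   and `rate` (umol mmol-1 h-1).
#' @examples
#' f <- food_source("amino_acids", atom_frac_13c = 0.98, atom_frac_15n = 0.98)
#' bulk_uptake_rate(50, -20, f, "C", time_h = 3)
#' @export
bulk_uptake_rate <- function(delta, delta_control, food,
                             element = c("C", "N"), time_h,
                             clamp = FALSE) {
  element <- match.arg(element)
  stopifnot(inherits(food, "food_source"))
  if (any(!is.finite(time_h)) || any(time_h <= 0))
    stop("incubation time must be positive")
  x_food <- food_excess(food, element)
  r_ref <- iso_ref[[element]]
  e <- excess_from_delta(delta, delta_control, r_ref, clamp = clamp)
  data.frame(excess = e, rate = 1000 * e / (x_food * time_h))
}

#' Control baseline delta values
#'
#' Mean delta of control samples, grouped by species (and optionally by
#' time point). Used as the natural-abundance baseline for excess
#' enrichment.
#'
#' @param samples data.frame of bulk measurements with columns `species`,
#'   `treatment`, `time_h`, `delta13C_permil`, `delta15N_permil`,
#'   `is_control`.
#' @param by_time logical; if `TRUE` baselines are computed per species x
#'   time point instead of pooling all controls per species.
#' @return data.frame with columns `species` (, `time_h`),
#'   `delta13C_ctrl`, `delta15N_ctrl`, `n_ctrl`.
#' @export
control_baseline <- function(samples, by_time = FALSE) {
  stopifnot(is.data.frame(samples),
            all(c("species", "delta13C_permil", "delta15N_permil",
                  "is_control") %in% names(samples)))
  ctl <- samples[as.logical(samples$is_control), , drop = FALSE]
  if (nrow(ctl) == 0L) stop("no control samples present")
  keys <- if (by_time) list(species = ctl$species, time_h = ctl$time_h)
          else list(species = ctl$species)
  agg <- aggregate(ctl[c("delta13C_permil", "delta15N_permil")], keys, mean)
  n <- aggregate(list(n_ctrl = ctl$delta13C_permil), keys, length)
  out <- merge(agg, n)
  names(out)[names(out) == "delta13C_permil"] <- "delta13C_ctrl"
  names(out)[names(out) == "delta15N_permil"] <- "delta15N_ctrl"
  out
}

#' Uptake rates for a bulk tracer experiment table
#'
#' Applies [bulk_uptake_rate()] to every non-control row of a bulk
#' measurement table, using per-species control baselines, for both
#' elements where the food source carries a label.
#'
#' @param samples data.frame as in [control_baseline()], plus columns
#'   `C_umol_per_mg`/`N_umol_per_mg` (carried through) and `replicate`.
#' @param foods named list of [food_source()] objects keyed by treatment.
#' @param by_time passed to [control_baseline()].
#' @param clamp passed to [bulk_uptake_rate()].
#' @return Long-format data.frame: species, treatment, time_h, replicate,
#'   element, excess, rate.
#' @export
bulk_uptake_table <- function(samples, foods, by_time = FALSE, clamp = FALSE) {
  base <- control_baseline(samples, by_time = by_time)
  trt <- samples[!as.logical(samples$is_control), , drop = FALSE]
  trt <- merge(trt, base, by = intersect(names(base), names(trt))[
    intersect(names(base), names(trt)) %in% c("species", "time_h")])
  out <- list()
  for (el in c("C", "N")) {
    dcol <- if (el == "C") "delta13C_permil" else "delta15N_permil"
    ccol <- if (el == "C") "delta13C_ctrl" else "delta15N_ctrl"
    for (tr in unique(trt$treatment)) {
      food <- foods[[tr]]
      if (is.null(food)) stop("no food source defined for treatment '", tr, "'")
      labelled <- if (el == "C") TRUE else !is.na(food$atom_frac_15n)
      if (!labelled) next
      rows <- trt[trt$treatment == tr, , drop = FALSE]
      res <- bulk_uptake_rate(rows[[dcol]], rows[[ccol]], food, el,
                              rows$time_h, clamp = clamp)
      out[[paste(el, tr)]] <- data.frame(
        species = rows$species, treatment = tr, time_h = rows$time_h,
        replicate = rows$replicate, element = el,
        excess = res$excess, rate = res$rate)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
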