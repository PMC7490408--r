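#' Net removal of an organic-carbon pool
#'
#' Concentration difference between the water inhaled and exhaled by a
#' sponge; positive values mean removal, negative values (release
#' events) are retained.
#'
#' @param c_in,c_ex concentrations, umol C per L.
#' @return Net removal, umol C per L.
#' @export
net_removal <- function(c_in, c_ex) {
  stopifnot(all(c_in >= 0), all(c_ex >= 0))
  c_in - c_ex
}

#' Volume-specific carbon flux
#'
#' Removal concentration times pumping rate, with the litre-to-millilitre
#' conversion: flux = deltaC / 1000 x P.
#'
#' @param delta_c net removal, umol C per L.
#' @param pumping volume-specific pumping rate, mL per min per cm3
#'   sponge; must be positive.
#' @return Flux in umol C per min per cm3 sponge.
#' @examples
#' c_flux(12, 0.05)  # 6e-4
#' @export
c_flux <- function(delta_c, pumping) {
  if (any(pumping <= 0)) stop("pumping rate must be positive")
  delta_c / 1000 * pumping
}

#' Total organic carbon flux
#'
#' @param c_doc,c_poc DOC and POC fluxes, umol C per min per cm3.
#' @return Their sum.
#' @export
toc_flux <- function(c_doc, c_poc) c_doc + c_poc

#' Dietary fractions of DOC and POC
#'
#' @param c_doc,c_poc fluxes with `c_doc + c_poc > 0`.
#' @return List with `f_doc` and `f_poc` summing to 1.
#' @export
diet_fractions <- function(c_doc, c_poc) {
  toc <- c_doc + c_poc
  if (any(toc <= 0)) stop("undefined diet: total organic carbon flux is zero")
  list(f_doc = c_doc / toc, f_poc = c_poc / toc)
}

#' Symbiont share of the total heterotrophic diet
#'
#' Combines the dietary DOC fraction with the symbiont share of
#' dissolved-C assimilation. Particulate carbon is captured by host-cell
#' phagocytosis, so the symbiont POM share is zero and the total share
#' reduces to `f_doc * s_dom`.
#'
#' @param f_doc dietary fraction of DOC in \[0, 1\].
#' @param s_dom symbiont share of DOC assimilation in \[0, 1\] (for the
#'   DOM source most representative of the in situ pool).
#' @param f_poc dietary fraction of POC; defaults to `1 - f_doc`.
#' @return Symbiont share of total heterotrophic C, as a fraction.
#' @examples
#' symbiont_diet_share(0.924, 0.65)  # ~0.60
#' @export
symbiont_diet_share <- function(f_doc, s_dom, f_poc = 1 - f_doc) {
  stopifnot(all(f_doc >= 0 & f_doc <= 1), all(s_dom >= 0 & s_dom <= 1),
            all(f_poc >= 0 & f_poc <= 1))
  if (any(abs(f_doc + f_poc - 1) > 1e-9))
    stop("f_doc and f_poc must sum to 1")
  f_doc * s_dom
}

#' Summarise in situ diet records
#'
#' Computes per-record DOC/POC/TOC fluxes and dietary fractions for a
#' table of inhaled-exhaled concentration pairs, with nonparametric
#' bootstrap confidence intervals over individual sponges. Both the mean
#' of per-record fractions and the fraction of mean fluxes are reported;
#' they differ whenever flux varies between individuals.
#'
#' @param records data.frame with columns `species`, `doc_in`, `doc_ex`,
#'   `poc_in`, `poc_ex`, `pumping_ml_min_cm3` and optionally `pumping_ok`
#'   (logical; see `exclude_nonpumping`).
#' @param s_dom optional named vector of symbiont DOC-assimilation shares
#'   per species, used to add the total-diet symbiont share.
#' @param n_boot bootstrap resamples (default 9999).
#' @param seed optional integer seed.
#' @param exclude_nonpumping drop records whose `pumping_ok` is `FALSE`
#'   (individuals that ceased pumping; default `TRUE`).
#' @param conf confidence level for the percentile intervals.
#' @return Object of class `diet_summary`: `records` (with per-record
#'   fluxes) and `summary`, one row per species with mean fluxes,
#'   `f_doc` (fraction of mean fluxes), `f_doc_mean_of_records`,
#'   bootstrap CIs, and (when `s_dom` is supplied)
#'   `symbiont_total_share` with its CI.
#' @export
diet_summary <- function(records, s_dom = NULL, n_boot = 9999, seed = NULL,
                         exclude_nonpumping = TRUE, conf = 0.95) {
  need <- c("species", "doc_in", "doc_ex", "poc_in", "poc_ex",
            "pumping_ml_min_cm3")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (exclude_nonpumping && "pumping_ok" %in% names(records))
    records <- records[as.logical(records$pumping_ok), , drop = FALSE]
  records$c_doc <- c_flux(net_removal(records$doc_in, records$doc_ex),
                          records$pumping_ml_min_cm3)
  records$c_poc <- c_flux(net_removal(records$poc_in, records$poc_ex),
                          records$pumping_ml_min_cm3)
  records$c_toc <- toc_flux(records$c_doc, records$c_poc)
  records$f_doc <- ifelse(records$c_toc > 0,
                          records$c_doc / records$c_toc, NA_real_)
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - conf) / 2

  one_species <- function(g, sp) {
    fd <- function(rows) mean(rows$c_doc) / mean(rows$c_toc)
    est <- data.frame(species = sp, n = nrow(g),
                      c_doc = mean(g$c_doc), c_poc = mean(g$c_poc),
                      c_toc = mean(g$c_toc),
                      f_doc = fd(g),
                      f_doc_mean_of_records = mean(g$f_doc, na.rm = TRUE))
    if (n_boot > 0 && nrow(g) > 1) {
      bf <- vapply(seq_len(n_boot), function(i)
        fd(g[sample.int(nrow(g), replace = TRUE), , drop = FALSE]),
        numeric(1))
      ci <- unname(quantile(bf, c(alpha, 1 - alpha), na.rm = TRUE))
      est$f_doc_ci_low <- ci[1]
      est$f_doc_ci_high <- ci[2]
    } else {
      est$f_doc_ci_low <- est$f_doc_ci_high <- NA_real_
      bf <- NULL
    }
    if (!is.null(s_dom) && sp %in% names(s_dom)) {
      est$s_dom <- s_dom[[sp]]
      est$symbiont_total_share <- symbiont_diet_share(est$f_doc, est$s_dom)
      if (!is.null(bf)) {
        bs <- symbiont_diet_share(bf, est$s_dom)
        ci <- unname(quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE))
        est$share_ci_low <- ci[1]
        est$share_ci_high <- ci[2]
      } else {
        est$share_ci_low <- est$share_ci_high <- NA_real_
      }
    }
    est
  }
  spl <- split(records, records$species)
  summ <- do.call(rbind, Map(one_species, spl, names(spl)))
  rownames(summ) <- NULL
  structure(list(records = records, summary = summ, conf = conf,
                 n_boot = n_boot),
            class = "diet_summary")
}

#' @export
print.diet_summary <- function(x, digits = 3, ...) {
  cat("In situ diet summary (fluxes in umol C min-1 cm-3)\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
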