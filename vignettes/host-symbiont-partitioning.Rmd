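---
title: "Partitioning sponge DOM assimilation between host cells and microbial symbionts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning sponge DOM assimilation between host cells and microbial symbionts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongeSIP)
```

spongeSIP quantifies which compartment of a sponge holobiont — the
animal host's cells or its microbial symbionts — assimilates dissolved
and particulate organic matter, by combining four measurement channels:
bulk-tissue stable-isotope tracing, isotope analysis of separated cell
fractions, NanoSIMS ion imaging of single cells, and in situ
inhaled–exhaled (InEx) flux sampling. This vignette explains the model
behind each stage, the parameters that matter, the choices we made where
the methodology is genuinely open, and what the synthetic-data
generators can and cannot tell you about real data.

## 1. Isotope algebra and bulk uptake rates

All tracer bookkeeping runs through three reversible conversions:

* δ notation: $\delta = (R_{sample}/R_{ref} - 1)\times 1000$ (per mil),
  with $R_{ref}$ = 0.01118 for carbon (VPDB) and 0.00368 for nitrogen
  (air);
* isotope ratio to atom fraction: $F = R/(1+R)$ — the quantity that is
  conserved under mixing, hence the correct currency for tracer math;
* excess atom fraction: $E = F_{sample} - F_{control}$, the tracer
  signal above the natural-abundance baseline.

The bulk uptake rate normalises the tissue excess by the labelling
strength of the food and by incubation time:

$$\rho = \frac{1000 \, E_{sample}}{x_{food}\, t}
\quad \left[\mu mol\; element\; (mmol\; element\; tissue)^{-1} h^{-1}\right],$$

with $x_{food}$ the *excess* (label minus natural) atom fraction of the
food source. Normalising by the excess rather than the total label
fraction is a deliberate choice — it makes $\rho$ exactly zero for an
unlabelled food and linear in the tracer signal; the formula lives in
one function (`bulk_uptake_rate()`) so an alternative normalisation can
be swapped without touching anything else.

Two further conventions:

* **Negative excess values are retained** by default. Clamping at zero
  would bias treatment means upward precisely where enrichment is weak
  (glucose); a `clamp` flag exists for reporting.
* **The control baseline** is the mean of all unlabelled controls of the
  same species. `control_baseline(by_time = TRUE)` switches to
  per-time-point baselines when instrument drift between sessions is a
  concern.

## 2. Fraction-route partitioning

Host and microbial cells are separated by centrifugation; typical count
purities are >85% for the host fraction and >99% for the microbial
fraction. Because isotope measurements average over *biomass* rather
than cell counts, count purities are first converted to element-biomass
weights using per-cell contents, giving a 2×2 mixing matrix $M$ whose
rows are the biomass composition of each measured fraction. Measured
fraction enrichments are then unmixed by solving $M E = E_{meas}$
(`unmix_fraction_enrichment()`), which is the exact inverse of the
forward contamination process. With perfect purities $M$ is the
identity; a condition number above $10^8$ raises a
degenerate-composition error rather than returning noise-amplified
estimates.

Whether the original fraction measurements should be purity-corrected at
all is ambiguous in practice, so the correction is **on by default and
the uncorrected share is always reported** alongside
(`fraction_partition()$uncorrected`).

Compartment shares combine specific enrichment with biomass:

$$pct_{microbe} = 100\,\frac{B_m E_m}{B_m E_m + B_h E_h},$$

where $B$ is element biomass (census × per-cell content). Negative
unmixed enrichments are clamped to zero *for the share only* and kept
unclamped in the diagnostics. If both compartments are non-positive the
result carries the status `"no_uptake"` instead of a number.
Particulate food is attributed 100% to host cells
(`particulate_partition()`): sponges capture particles by choanocyte
phagocytosis, and dissolved treatments are never routed through this
rule.

Uncertainty on shares comes from a nonparametric bootstrap over
replicate fraction-measurement pairs (default 2000 resamples, seeded).
Resampling replicates — not residuals — keeps the interval honest with
only a handful of replicates, at the cost of some CI undercoverage when
n is very small.

## 3. NanoSIMS route

Stacks are 256 × 256 px rasters of a 30 × 30 µm field (0.117 µm pixels),
10 repeated planes, four ion channels (¹²C₂⁻, ¹³C¹²C⁻, ¹²C¹⁴N⁻,
¹²C¹⁵N⁻). The processing chain is:

1. **Drift correction** (`align_planes()`): each plane's ¹²C¹⁴N channel
   (the highest-count channel) is cross-correlated against plane 1 by
   FFT and shifted by the *integer* peak offset; the same shift applies
   to all four channels and the stack is cropped to the common window.
   Sub-pixel registration is deliberately excluded — it would
   interpolate counts and break Poisson statistics. An estimated shift
   beyond 25% of the frame is treated as an alignment failure.
2. **Accumulation** (`accumulate_planes()`): pixelwise integer sum;
   counts are conserved over the common region.
3. **Ratio maps** (`ratio_maps()`): per-pixel channel ratios, masked
   where the denominator holds fewer than 20 accumulated counts
   (`min_counts`) — below that, shot noise dominates the ratio.
4. **ROI quantification** (`roi_deltas()`): the ROI ratio is the
   **ratio of summed counts**, not the mean of per-pixel ratios. The
   per-pixel-mean estimator is biased upward at low counts
   (Jensen's inequality applied to 1/denominator); the ratio of sums is
   the maximum-likelihood estimator under Poisson counting. δ values are
   referenced to the *measured control ratios* (`control_calibration()`)
   rather than international standards, because the instrument's
   relative accuracy far exceeds its absolute accuracy.
5. **Enrichment calls** (`classify_enriched()`): an ROI is enriched when
   its δ exceeds the mean of control ROIs *of the same cell type* by
   more than 2 control SDs (one-sided). Per-type control statistics are
   the default; `pool_types = TRUE` pools them, for the case where
   control ROIs are scarce. Under a Gaussian null this rule has a
   one-sided false-positive rate of about 2.3%, which the test suite
   verifies by Monte Carlo.
6. **Hotspots** (`extract_hotspots()`): sub-cellular enrichment spots
   inside choanocytes are segmented from the smoothed (3×3 mean)
   per-pixel δ map at a threshold of the **pixel-level** control mean
   plus k = 5 pixel-level control SDs, grouped by 8-connectivity, and
   kept at ≥10 px. Pixel-level statistics matter here: per-pixel δ noise
   is dominated by counting statistics and is an order of magnitude
   wider than ROI-level control SDs, so an ROI-level threshold would
   flag entire mildly-enriched cells. All three criteria (k, minimum
   area, smoothing window) are package conventions, exposed as
   parameters, since no community standard exists.

The NanoSIMS partition (`nanosims_partition()`) averages the excess atom
fraction of each compartment's ROIs and applies the same
biomass-weighted share formula as the fraction route, making the two
routes directly comparable on shared truth. Note that the carbon ratio
measured on molecular ions (¹³C¹²C⁻/¹²C₂⁻) is proportional to, but not
numerically equal to, the atomic ¹³C/¹²C ratio; δ values and partition
shares are invariant to that proportionality, so no molecular-to-atomic
conversion is applied.

No dead-time or quasi-simultaneous-arrival correction is applied; the
channel pipeline has an obvious single place to add one if detector
conditions require it.

## 4. In situ diet integration

Fluxes are $C_{flux} = \Delta C_{in-ex}/1000 \times P_{sponge}$
(µmol C min⁻¹ cm⁻³; the 1000 converts litres to millilitres), TOC is
the sum of DOC and POC fluxes, and the dietary DOC fraction is
$f_{DOC} = C_{DOC}/C_{TOC}$. Negative removals (release events) are
retained in means; individuals that stopped pumping can be excluded
with a row flag. Both the fraction of mean fluxes and the mean of
per-record fractions are reported, because they differ whenever flux
varies between individuals; the fraction of means is the headline value
(it weights individuals by the carbon they actually processed).

The headline integration is deliberately simple:

$$share_{symbiont} = f_{DOC} \times s_{DOM} + f_{POC} \times 0,$$

with $s_{DOM}$ the symbiont share of dissolved-C assimilation for the
DOM source most representative of the natural pool (algal DOM by
default). The share is monotone in both inputs and bounded by
$s_{DOM}$. Uncertainty comes from a bootstrap over individual sponges
(default 9999 resamples, seeded).

## 5. Permutation ANOVA

`perm_anova()` partitions the squared Euclidean distance matrix into
among- and within-group sums of squares (the Gower identity) and
permutes group labels; on univariate data the pseudo-F is
algebraically identical to the classical one-way F, which the test
suite asserts to 1e-9 against `lm()`/`anova()`. The p-value uses the
+1 convention — the observed ordering counts as one permutation — so
$p \ge 1/(n_{perm}+1)$ and p = 0 is impossible. Pairwise post hoc
p-values are uncorrected by default, matching the convention of the
commercial permutation-ANOVA software this mirrors; a Holm flag is
available. Two-factor crossed designs use Type III partial sums of
squares with sum-to-zero contrasts and Freedman–Lane permutation of
reduced-model residuals (`perm_anova2()`); heavily unbalanced or nested
designs are out of scope.

## 6. What the generators simulate — and what they do not

The generators exist so that every stage has a testable ground truth.
Their defaults describe the two study archetypes:

* **HMA profile**: 10⁶ host cells and 8×10⁷ microbial cells per mg dry
  tissue at 60 vs 0.25 pg C per cell, putting 25% of cellular carbon in
  the symbionts; true symbiont shares of dissolved-C assimilation of
  0.87 (glucose), 0.72 (amino acids) and 0.65 (algal DOM).
* **LMA profile**: 10⁶ microbial cells per mg, i.e. ≈0.4% of carbon
  biomass, with symbiont DOM shares of a few percent at most (0.01 for
  algal DOM).

Per-cell contents and food label strengths are plausible synthetic
values — chosen once, anchored to the biomass dichotomy above, and not
tuned afterwards. Measurement noise is Gaussian on the δ scale (SD
10 ‰), ion counts are independent Poisson draws per pixel/channel/plane,
cell counts and filter loads carry lognormal noise (CV 10% and 5%), and
pumping rates are lognormal — the simplest models consistent with each
measurement's physics. Drift is an integer cumulative random walk
(±3 px) applied as a circular shift, so injected shifts are exactly
recoverable and counts are conserved.

A generated dataset is therefore *idealised* in ways real data are not:
cells are non-overlapping circles with sharp boundaries and uniform
composition; ROIs are exactly the true cell masks (no drawing error);
fraction purities are known rather than estimated; the δ noise is
homoscedastic; there is no instrument drift within a plane, no QSA or
dead-time loss, and no biological translocation between compartments.
Passing the recovery tests shows the estimators are correct *given the
model*; it does not validate ROI drawing, separation protocols or
detector corrections on real samples.

Two structural identities make the generators useful as oracles: with
all noise set to zero the full pipeline reproduces every ground-truth
share to numerical precision (the generator forward-mixes true
enrichments through the same purity matrix the pipeline inverts), and
with a fixed seed every generator is byte-reproducible.

## 7. Numerical choices and degenerate inputs

* δ↔ratio round trips hold to 1e-12 relative; inputs at or below
  −1000 ‰ or non-positive ratios raise domain errors.
* Near-singular purity matrices (condition number > 1e8) error out.
* ROIs (or pixels) whose denominator counts fall below `min_counts`
  are excluded with a reason code (`"low_C_counts"`/`"low_N_counts"`),
  never silently reported.
* Zero total enrichment yields a flagged no-uptake/no-estimate status
  rather than 0/0.
* Ties in the permutation null are counted in favour of the null
  (`>=` with a 1e-12 guard), keeping the test conservative.
* All percent outputs satisfy host + microbe = 100 to 1e-9 by
  construction.

The test suite exercises these at deliberately modest problem sizes —
500 replicate tracer datasets and two dozen full-size NanoSIMS scenes
for parameter recovery, 1000 null simulations for the type-I error of
the permutation test, 2000 Monte-Carlo ROIs for the false-positive rate
of the enrichment rule — sizes at which the binomial and standard-error
tolerances in the tests are meaningful without being wasteful.

## 8. Known limitations

* The uptake-rate normalisation (excess vs total food atom fraction) is
  a documented convention; published values computed with a different
  normalisation will differ by a constant factor per food source.
* The NanoSIMS partition weights compartments by a biomass estimate
  that comes from the cell-separation channel; an error there moves
  both routes in the same direction, so route agreement is a
  consistency check, not full independence.
* Bootstrap CIs over ≤4 replicates undercover; they are reported as
  percentile intervals, not exact coverage statements.
* Symbiont-to-host translocation is not modelled: the partition reads
  *where tracer sits at sampling time*, which understates host benefit
  if symbiont-assimilated carbon is later transferred.
* The two-factor permutation scheme assumes exchangeable residuals
  under the reduced model; heavily unbalanced designs should be
  analysed elsewhere.
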