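# spongeSIP

Partitioning host and symbiont contributions to sponge organic-matter
assimilation from stable-isotope tracers, cell separation, NanoSIMS
imaging and in situ feeding measurements.

## The scientific problem

Marine sponges process enormous quantities of dissolved organic matter
(DOM), yet they are holobionts: a filter-feeding animal host plus a
dense microbial symbiont community. Who actually eats the DOM — the
host's choanocyte (filter) cells or the symbionts living in the mesohyl?
The question matters because high-microbial-abundance (HMA) and
low-microbial-abundance (LMA) sponges host microbial communities that
differ by orders of magnitude, and the answer determines how carbon
moves through benthic ecosystems.

spongeSIP implements the quantitative chain that answers it:

1. **Isotope tracer algebra.** Samples enriched with ¹³C/¹⁵N-labelled
   food are expressed in δ notation,
   δ = (R_sample/R_ref − 1) × 1000 (R_ref = 0.01118 for VPDB carbon,
   0.00368 for atmospheric N₂), converted to atom fractions
   F = R/(1+R), and turned into bulk uptake rates
   ρ = 1000·E/(x_food·t), where E is the tissue excess atom fraction
   over unlabelled controls and x_food the label strength of the food.
2. **Cell-fraction partitioning.** Centrifugation separates host and
   microbial cell fractions (count purities ~85% and ~99%). Measured
   fraction enrichments are unmixed through a biomass-weighted 2×2
   purity matrix, then combined with compartment biomass B (cell census
   × per-cell C or N content) to give the symbiont share of
   assimilation: pct_microbe = 100·B_m·E_m / (B_m·E_m + B_h·E_h).
   Particulate food (bacteria) is attributed 100% to host phagocytosis.
3. **NanoSIMS single-cell route.** Four-channel ion-count rasters
   (¹²C₂⁻, ¹³C¹²C⁻, ¹²C¹⁴N⁻, ¹²C¹⁵N⁻; 30 × 30 µm, 256 × 256 px,
   10 planes) are drift-corrected by integer cross-correlation,
   accumulated, and converted to ratio maps. ROI δ values use the
   ratio of summed counts referenced to measured control ratios; an ROI
   is "enriched" when its δ exceeds the control mean by >2 control SDs,
   and sub-cellular hotspots are segmented inside choanocytes. The same
   biomass weighting yields an independent partition estimate.
4. **Diet integration.** In situ inhaled/exhaled (InEx) concentration
   pairs give fluxes C_flux = ΔC_in−ex × P_sponge; the DOC dietary
   fraction f_DOC times the symbiont DOM share s_DOM gives the symbiont
   share of the *total* heterotrophic diet (POM counts fully toward the
   host).
5. **Statistics.** Univariate permutation ANOVA (Euclidean distance,
   9999 permutations) with pairwise post hoc tests, plus seeded
   synthetic-data generators with known ground truth for every input
   class.

## Worked example

Simulate an HMA-type sponge experiment with a known truth (symbionts
hold 25% of cellular biomass and perform 65% of algal-DOM carbon
assimilation), then run the pipeline:

```r
library(spongeSIP)

cfg    <- sip_config("HMA")
dat    <- simulate_tracer_experiment(cfg, seed = 42)
inex   <- simulate_inex(cfg, seed = 43)
report <- run_full_analysis(c(dat, list(inex = inex$records)),
                            seed = 1, n_boot = 1000)
report
```

```
spongeSIP analysis report (seed 1, config 220b464c)

Mean bulk uptake rates (umol mmol-1 h-1):
 species   treatment element  rate
     HMA   algal_DOM       C 1.363
     HMA amino_acids       C 0.904
     HMA    bacteria       C 0.259
     HMA     glucose       C 0.174
     ...

Host/symbiont partition (% of assimilation):
 species   treatment element   method pct_host pct_microbe ci_low ci_high
     HMA     glucose       C fraction     19.2        80.8   66.7    92.9
     HMA amino_acids       C fraction     29.8        70.2   68.3    72.4
     HMA   algal_DOM       C fraction     34.8        65.2   61.9    67.4
     HMA    bacteria       C fraction    100.0         0.0     NA      NA
     ...

Symbiont share of total heterotrophic C:
 species f_doc f_doc_ci_low f_doc_ci_high s_dom symbiont_total_share
     HMA 0.923        0.919         0.928 0.652                0.602
```

Reading the output: the sponge removed DOC at rates giving a dietary
DOC fraction f_DOC ≈ 0.92; the fraction route estimated that symbionts
performed ≈65% of algal-DOM carbon assimilation (the generator's truth);
multiplying the two gives the headline — symbionts account for ≈60% of
the sponge's total heterotrophic carbon. NanoSIMS scenes, when supplied
via `data$nanosims`, add an independent `method = "nanosims"` estimate
of the same shares.

## Package layout

- `R/isotope.R` — δ/ratio/atom-fraction algebra, food sources, bulk
  uptake rates
- `R/partition.R` — per-cell contents, biomass fractions, purity
  unmixing, partition shares, bootstrap CIs
- `R/nanosims.R` — stacks, ROI sets, drift correction, accumulation,
  ratio maps, calibration, enrichment calls, hotspots
- `R/insitu.R` — InEx fluxes, diet fractions, symbiont diet share
- `R/permanova.R` — univariate and two-factor permutation ANOVA
- `R/simulate.R` — seeded generators with ground truth
- `R/pipeline.R` — `run_full_analysis()` orchestration
- `vignettes/host-symbiont-partitioning.Rmd` — methods and design notes
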