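# rangeOverlap

Kernel home-range overlap analysis for territorial social carnivores.

Neighbouring packs of territorial carnivores — African wild dogs are the
motivating case — overlap their ranges to wildly different degrees. Two
plausible drivers are kinship (kin-clustered populations may tolerate
related neighbours deep inside their territories) and relative pack size
(larger groups may push onto smaller ones). This package implements the
complete analysis chain needed to test those drivers from GPS collar
data, plus a simulator with closed-form ground truth for validating
every estimator.

## What it computes

For each pack, a fixed-kernel utilisation distribution (UD) from
twice-daily GPS fixes using the reference bandwidth
`h_i = s_i · n^(-1/6)` per axis, and its 50/75/95% probability-mass
isopleths on a raster grid. For each neighbour pair (dyad), at each
level:

* **directional overlap** — intersection area as a percentage of each
  focal pack's kernel, `100 · A(K_a ∩ K_b) / A(K_focal)`, two values per
  dyad;
* **exclusive-kernel utilisation intensity** — percent of fixes in the
  50% core, the 75%−50% and the 95%−75% annuli, divided by each
  compartment's area (%/km²);
* **overlap-zone occupancy** — the fraction of a pack's fixes inside the
  95% ∩ 95% zone.

Group comparisons are rank-based (Mann-Whitney U with exact enumeration
for small samples, tie-corrected Kruskal-Wallis H, Nemenyi-type pairwise
comparisons on mean ranks). Drivers of overlap are assessed with
random-intercept linear mixed models fitted by profiled maximum
likelihood, ranked by `AICc = −2ℓ + 2k + 2k(k+1)/(N−k−1)`, and
summarised by Akaike-weight model averaging over the cumulative-weight
top set (full averaging, unconditional SEs, relative importance).

The synthetic module simulates each pack as a stationary isotropic
Ornstein-Uhlenbeck process, whose circular-normal stationary law gives
closed-form isopleth radii `R_p = σ·sqrt(−2·ln(1−p))` and circle-lens
overlap oracles against which the whole pipeline is tested.

## Worked example

```r
library(rangeOverlap)

study <- makeFixtures("paper_like", seed = 1)   # 21 packs, 20 dyads
res   <- runPipeline(pipelineConfig(study = study, outDir = "results"))

ov95 <- subset(res$overlap, level == 0.95)
summarizeValues(ov95$pct_of_focal[ov95$relatedness == "related"])
#>    n     mean   median       sd      min      max
#> 1 24 31.21376 25.62973 17.96761 6.119012 79.00807
summarizeValues(ov95$pct_of_focal[ov95$relatedness == "unrelated"])
#>    n     mean    median      sd min      max
#> 1 16 2.149147 0.2988455 4.49364   0 14.98973

res$stats$tests$overlap_95
#> Mann-Whitney Rank Sum Test
#> U = 377.0; T = 143.0; P = 3.36e-07

res$stats$tests$intensity
#> Kruskal-Wallis ANOVA on ranks
#> H = 53.7, df = 2, P = 2.23e-12

res$models$averaged
#> Model-averaged effects (full averaging over 3 models, cumulative weight > 0.95)
#>                            parameter estimate     se ci_lower ci_upper      p importance
#> 1                        (Intercept)   0.7771 5.5731 -10.1462  11.7004 0.8891     1.0000
#> 2                 relatednessrelated  28.0823 6.0185  16.2860  39.8786 0.0000     1.0000
#> 3                    pack_size_ratio   1.1329 3.5226  -5.7714   8.0373 0.7477     0.3668
#> 4 pack_size_ratio:relatednessrelated   0.8549 3.7351  -6.4659   8.1756 0.8190     0.1036
```

Reading this output: related neighbours share on average ~31% of their
95% kernels in this synthetic world while unrelated neighbours share
~2%, the rank test finds that difference decisive, utilisation intensity
differs strongly across the three kernel compartments (core used most
intensively per km²), and the model-averaged relatedness effect
(+28 percentage points) dominates the pack-size-ratio effect, whose
interval straddles zero. The `results/` directory receives the long
overlap/occupancy/intensity tables, the rank-test report, model and
averaged-effect tables, a prediction surface for the
ratio × relatedness interaction, per-pack UD rasters (ESRI ASCII),
isopleth and overlap-zone GeoJSON, and a JSON run manifest.

A thin CLI wrapper lives at `inst/scripts/overlap-pipeline.R`
(`fixtures`, `run`, `simulate` verbs).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full analysis from scratch on the paper-shaped synthetic
study (generating the study with the given seed, running every pipeline
stage, and logging the headline comparisons and model ranking) and
writes the acceptance JSON to `--out`.

## Vignette

`vignettes/territory-overlap-methods.Rmd` documents the model and every
design decision: the kernel protocol and its smoothing bias, the
directional-overlap and intensity conventions, the exact/asymptotic
rank-test switch, the profiled-likelihood mixed-model machinery and the
AICc parameter-count convention, and what the synthetic world does and
does not emulate.
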