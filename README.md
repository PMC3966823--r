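# neonicr

Neonicotinoid seed treatments dominate insect pest control on the northern
Great Plains: most canola, and much of the wheat, barley, oat and pulse
area, is sown from seed coated with clothianidin, thiamethoxam or
imidacloprid. The prairie pothole region that grows these crops is also
dense with small depressional wetlands that collect runoff and snowmelt
from the surrounding fields. `neonicr` is an R toolkit for the two
questions this raises:

1. **How much active ingredient goes where?** A *use atlas* converts a
   gridded crop-classification map plus a treatment registry into
   per-hectare application-rate surfaces, quarter-section (65-ha) parcel
   aggregates, rate-category breakdowns, and totals of treated area (ha)
   and active-ingredient mass (kg).
2. **What ends up in the wetlands?** A *residue pipeline* turns censored
   (below limit-of-quantification) per-compound concentration measurements
   into recovery-corrected totals, detection frequencies and crop-by-season
   summary tables, and a Gaussian linear mixed model tests crop × season
   effects on log total concentration, with Wald chi-square interaction
   contrasts under Dunn–Šidák family-wise correction.

The statistical core, in the field's standard notation: the application
rate is `rate (g AI/ha) = seed loading (g AI/kg) × seeding rate (kg/ha)`,
applied per pixel as the expected value `rate × treated fraction`; the
residue model is

```
log(total + δ) = season * crop + baseline + previous crop
                 + (season intercepts | quarter section)
                 + (season intercepts | wetland in quarter section) + ε
```

with δ = half the smallest LOQ, summer and grassland as reference levels,
AIC selection between random-effect structures, and per-test level
`1 − (1 − α)^(1/k)` for a family of k contrasts. A synthetic-data module
generates block-structured crop landscapes and censored wetland panels with
known ground truth, so the whole pipeline is testable without any
confidential input; the bundled registry (`inst/extdata/synthetic_registry.csv`)
uses published label rates but **synthetic** treated fractions, since the
real treated-percentage data are confidential.

Intended users: environmental chemists and ecotoxicologists summarising
wetland monitoring panels, and exposure modellers who need reproducible
seed-treatment use surfaces from land-cover products.

## Worked example

```r
library(neonicr)

# --- use atlas on a simulated 80 x 80 landscape (100-m pixels, 6400 ha) ---
grid     <- gen_landscape(landscape_config(n_row = 80, n_col = 80, seed = 42))
registry <- read_registry(system.file("extdata", "synthetic_registry.csv",
                                      package = "neonicr"))
rasters  <- lapply(unique(registry$ai),
                   function(a) build_use_raster(grid, registry, a))
total    <- merge_use_rasters(rasters)
summarize_use(total, total_cropland_ha = 6400)
#> <use_summary> total (year 2012)
#>   treated area: 2266 ha (35% of 6400 ha cropland)
#>   AI mass:      67.34 kg
#>         name lower upper area_ha pct_within
#>          Low  0.00  1.25     0.0   0.000000
#>   Low-Medium  1.25  4.00   153.6   6.779661
#>       Medium  4.00 10.50   921.6  40.677966
#>  Medium-High 10.50 26.00  1190.4  52.542373
#>         High 26.00 70.00     0.0   0.000000
```

2266 of 6400 ha (35%) carry treated seed, delivering 67.3 kg of active
ingredient, mostly at 4–26 g AI/ha — the Medium and Medium-High bins.

```r
# --- residue panel: 50 quarter sections x 3 wetlands x 4 seasons ---------
sim <- gen_residue_panel(panel_config(seed = 42))
detection_frequency(sim$panel, "summer2012")
#> $numerator
#> [1] 92
#> $denominator
#> [1] 150
#> $percent
#> [1] 61

spec <- lmm_spec(re_structure = "nested")
fit  <- fit_lmm(build_model_data(sim$panel, spec), spec)
subset(as.data.frame(fit$coefficients), term %in% c("cropbarley", "cropcanola"))
#>         term estimate    se   df    t        p
#> 4 cropbarley     2.87 0.405 82.1 7.08 4.55e-10
#> 5 cropcanola     2.36 0.392 90.8 6.02 3.65e-08

head(as.data.frame(interaction_contrasts(fit)[
  interaction_contrasts(fit)$crop == "canola", ]), 3)
#>     crop   season_a   season_b estimate chisq df  p_value alpha_adjusted significant
#> 1 canola summer2012   fall2012     2.16  38.5  1 5.38e-10        0.00285        TRUE
#> 2 canola summer2012 spring2013    -3.12 112.4  1 2.90e-26        0.00285        TRUE
#> 3 canola   fall2012 spring2013    -5.29 230.1  1 5.80e-52        0.00285        TRUE
```

61% of sampled wetlands have at least one detection in the growing season.
On the log scale, wetlands in barley and canola sit about 2.4–2.9 units
above grassland (both significant), and the canola contrasts show the
summer→fall decline and the strong snowmelt rebound the generator builds
in; each contrast is tested at the Šidák-adjusted level 0.00285 (family of
18).

A command-line wrapper exposes the same stages
(`exec/neonicr simulate | map-use | summarize-residues | fit-model`); every
run writes its outputs plus a `manifest.json` recording inputs, parameters,
seed and version, and identical configuration + seed reproduces every
output byte for byte.

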