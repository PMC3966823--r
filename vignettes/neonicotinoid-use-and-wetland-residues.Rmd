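---
title: "Mapping seed-treatment use and analysing censored wetland residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping seed-treatment use and analysing censored wetland residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neonicr)
```

`neonicr` couples two analyses that together describe neonicotinoid exposure
of prairie pothole wetlands: a deterministic *use atlas* that converts a
gridded crop map and a treatment registry into per-hectare application-rate
surfaces, and a *residue pipeline plus mixed model* that turns censored,
repeated wetland concentration measurements into detection frequencies,
summary tables and crop-by-season inference. Because the original inputs of
such studies (proprietary crop rasters, confidential treated-percentage
data, raw field measurements) are generally unavailable, the package also
ships a synthetic-data module that generates both kinds of input with known
ground truth; every stage of the pipeline is tested against it.

## The use atlas

The atlas rests on a simple identity. A crop sown with treated seed at seed
loading $\ell$ (g active ingredient per kg seed) and seeding rate $r$ (kg
seed per ha) receives an application rate

$$ a = \ell \, r \quad \text{(g AI/ha).} $$

Where product labels permit several loadings, the registry stores a single
resolved rate per (crop, AI) — by convention the median of the recommended
rates, resolved before entry. Typical resolved rates for thiamethoxam are
13 g/ha on barley, 21 g/ha on canola and 26 g/ha on beans; across all
crop–AI combinations rates span roughly 12–70 g/ha.

Only a fraction $f \in [0,1]$ of each crop's area is actually sown with
treated seed. `build_use_raster()` therefore assigns each pixel of crop $c$
the *expected* rate $a_{c} f_{c}$ and carries $f_c$ alongside in a treated
fraction surface. This is a deterministic expected-value treatment: we do
not randomly label individual pixels as treated, because reproducibility
matters more here than realism of the spatial pattern, and all reported
aggregates (areas, masses) are identical in expectation either way.
Consequences:

* treated area is the fraction-weighted pixel area
  $\sum_{\text{rate}>0} f \cdot A_{\text{px}}$, with
  $A_{\text{px}} = \text{resolution}^2/10^4$ ha;
* AI mass is $\sum \text{(expected rate)} \cdot A_{\text{px}} / 1000$ kg,
  i.e. the resolved label rate applied to the fraction-weighted area;
* when per-AI rasters are merged (`merge_use_rasters()`), rates add and the
  merged treated fraction is the per-pixel **maximum** of the component
  fractions — a pixel counts as treated once any AI treats it. Treated
  fractions of different AIs on the same crop overlap in reality in unknown
  ways; the maximum is the most conservative choice that never counts the
  same hectare twice.

Field crops in this land-survey system are planted at the quarter-section
scale (65 ha), so `aggregate_quarter_sections()` tiles the raster into
axis-aligned square blocks whose pixel count best approximates the target
area (8 × 8 pixels = 64 ha at 100-m resolution; 27 × 27 ≈ 65.6 ha at 30 m).
Edge blocks are truncated and keep their true, smaller area. No tiling rule
is canonical; axis-aligned blocks keep the operation exact, fast and
order-independent.

Rate categories follow the conventional five bins (g AI/ha): Low (0, 1.25],
Low-Medium (1.25, 4], Medium (4, 10.5], Medium-High (10.5, 26] and High
(26, 70]. Published category tables print shared boundaries ("1.25–4",
"4–10.5") without stating which side is closed; we fix the convention as
half-open **upper-inclusive** intervals, so a boundary rate of 4 g/ha falls
in Low-Medium. A rate of exactly 0 is untreated and belongs to no bin; a
rate above 70 g/ha is an error rather than a silent clamp, because it
signals a registry mistake. All internal computation is unrounded;
reporting helpers round percentages half-up to integers
(`treated_percent(10.993e6, 25e6)` is 44).

Grids travel as ESRI ASCII rasters — a plain-text, single-band format with
an explicit `NODATA_value` tag — and the registry and category tables as
CSV. Non-cropland (nodata) pixels carry rate 0 and fraction 0 everywhere
and never enter a denominator: the total-cropland denominator is always
supplied explicitly (it comes from crop-reporting statistics, not from the
raster).

## The residue pipeline

Measurements arrive in long format, one row per (wetland, season, matrix,
AI), with the measured concentration, the limit of quantification (LOQ) and
the assay's mean recovery fraction. Water concentrations are ng/L and
sediment µg/kg wet weight; both matrices use identical logic and are never
converted into one another.

Processing order is: censor, then correct. A value is censored ("not
detected") when it is strictly below its LOQ — a value exactly at the LOQ
counts as a detection; no convention is universal here, and the
boundary-inclusive rule is fixed and tested. Detected values are divided by
the recovery fraction (78.9 measured at recovery 0.789 becomes 100).
Censored values contribute **zero** to sums and arithmetic means. Published
per-crop tables of this kind do not quite pin down the averaging
convention (per-AI means do not exactly sum to the printed totals), so the
zero-substitution mean is the default and a `detects_only` mode is provided
for sensitivity analysis; neither is claimed to reproduce any published
table exactly.

Because the four neonicotinoids bind the same insect receptor and act
additively, the *total neonicotinoid concentration* of a sample is the sum
of its detected AI concentrations. Detection frequency is computed at two
levels with different denominators: a wetland counts when any AI is
detected in that season, and a quarter section counts when any of its
sampled wetlands does. Wetlands that were dry or flooded in a season are
simply absent from that season's panel and hence from its denominator,
which is why the denominator varies across seasons. Percentages round
half-up to integers (49/136 → 36%, 37/49 → 76%).

Two LOQ sets circulate for these assays: the set used in summary tables
(acetamiprid 0.25, clothianidin 0.6, imidacloprid 0.55, thiamethoxam 0.9
ng/L) and the analytical method's stated limits, exactly double each value.
The most plausible reading is a detection-limit versus quantification-limit
distinction. The lower, table set is the default (`loq_defaults()`), the
method set is one argument away, and nothing downstream assumes either.

## The mixed model

Inference about crop and season effects uses a Gaussian linear mixed model
on the log scale:

$$ \log(T_{ijk} + \delta) = \mu + \text{season}_j + \text{crop}_i +
   (\text{season} \times \text{crop})_{ij} + \gamma\, b_{k} +
   \text{crop}^{\,\text{prev}}_i + u_{q(k)j} + w_{kj} +
   \varepsilon_{ijk}, $$

where $T$ is the total concentration of wetland $k$ in season $j$, $b_k$ is
the wetland's pre-seeding (baseline) log concentration, and $u$ and $w$ are
random intercepts for quarter section and for wetland nested within quarter
section. The baseline season's rows become the covariate and leave the
response. Reference levels are the growing season (summer) and grassland.

Choices that needed fixing:

* **Zeros before the log.** Non-detect totals are 0; the offset is
  $\delta = \tfrac{1}{2}\min(\text{LOQ}) = 0.125$ ng/L by default — half
  the smallest quantifiable value, the usual substitution for censored
  observations. $\delta$ is configurable and all estimates should be read
  as conditional on it.
* **Random-effect structure.** The default (`"season_specific"`) estimates
  an independent intercept variance per season for each grouping level —
  six variance components for three modelled seasons — implemented as
  per-season indicator random terms `(0 + 1[season=s] | group)`. Wetland
  variance in these systems is strongly season-dependent (drawdown,
  snowmelt pulses), which a single shared variance would average away. The
  single-variance nesting (`"nested"`) and an optional random time slope
  per wetland are one configuration switch away, and `select_random_effects()`
  chooses among candidate structures by AIC.
* **ML for selection, REML for the final fit.** AICs are only comparable
  when every candidate is fitted by maximum likelihood on identical data,
  so selection refits candidates with ML and the winner is then refitted by
  REML. AIC ties (within 1e-6) break toward fewer parameters.
* **Estimability is an error, not a footnote.** A rank-deficient fixed
  design (for example, an empty crop-by-season cell, or a previous-crop
  covariate identical to the current crop) raises an error naming the
  aliased terms rather than silently dropping them.
* **Convergence.** The fit is flagged, never silently accepted: after a
  convergence failure the optimizer restarts up to three times from
  jittered parameters (all randomness under the caller's seed), and the
  `converged` flag travels with the result. A *singular* fit (a variance
  estimated at exactly zero) is legitimate and reported separately.
  Coefficient t statistics use Satterthwaite degrees of freedom.

Post-hoc questions — "did concentrations drop between summer and fall *for
this crop*?" — are interaction contrasts: differences of model cell means
within a crop across a season pair, with covariates held fixed so they
cancel. Each contrast is a 1-df Wald chi-square computed from the
fixed-effect vector and its covariance. The family-wise level α is
converted to a per-test level by the Dunn–Šidák rule
$\alpha' = 1-(1-\alpha)^{1/k}$, which always lies between the Bonferroni
level $\alpha/k$ and $\alpha$. The published family size for such analyses
is rarely stated; here $k$ is the number of contrasts actually tested in
the run (by default, every season pair within every crop that has data in
both cells).

The drawdown sanity check — whether wetlands that later dried differed from
those that stayed wet — is a Mann–Whitney U comparison. $U_a$ is the number
of (a, b) pairs with $a > b$ plus half the ties, so $U_a + U_b = n_a n_b$.
The two-sided p-value is exact when there are no ties and the smaller group
has at most 8 observations, and otherwise uses the normal approximation
with tie and continuity corrections.

## What the synthetic generator does and does not emulate

`gen_landscape()` plants one crop per quarter-section block, matching the
land-survey reality that fields are planted at that scale; sub-parcel
mixing is deliberately not simulated. `gen_residue_panel()` draws, for each
sample,

$$ \log T = m_{\text{crop},\text{season}} + u_{\text{qs}} + w_{\text{wetland}}
   + \varepsilon, $$

all Gaussian — a lognormal concentration model, consistent with residuals
being approximately normal after log transformation in this kind of data.
The back-transformed total is split across the four AIs by fixed mixing
weights (clothianidin-dominant by default, matching which compounds
dominate field detections — a configuration choice, not a truth claim),
multiplied by each AI's recovery fraction to mimic assay loss, and left for
the pipeline to censor at each AI's LOQ. Fall samples are dropped with the
drawdown probability; the ground truth (crop assignments, random effects,
true log totals) is returned beside the panel.

Defaults mirror the sampling design this package targets: 50 quarter
sections × 3 wetlands × 4 seasons; crop shares canola-dominant (0.37) with
an 0.11 grassland reference stratum; fall drawdown probability 0.4 (about
80 of 136 wetlands samplable after harvest); variance components
$\sigma_{\text{qs}} = 1.0$, $\sigma_{\text{wetland}} = 1.1$,
$\sigma_{\text{resid}} = 0.8$ on the log scale, the magnitude reported for
such panels. The default cell-mean matrix is calibrated analytically so
that the probability of a sample clearing its most sensitive censoring
threshold reproduces the characteristic seasonal detection cycle (low
pre-seeding, peak in the growing season, collapse after harvest, strong
snowmelt rebound); with these defaults a generated panel shows roughly
35/73/25/92% seasonal wetland-level detection. Pre-seeding cell means are
indexed by the *previous* year's crop, since no current-year seed is in the
ground yet.

The generator does **not** emulate: spatial correlation between
neighbouring quarter sections, runoff or transport dynamics, temporal decay
within a season, measurement error beyond lognormal residuals and assay
recovery, or wetland permanence classes. Passing tests on synthetic panels
therefore demonstrate that the estimators recover the generating model —
not that real wetland data satisfy that model.

## Simulation studies shipped with the tests

The package's acceptance suite runs three simulation studies, sized to make
their Monte-Carlo error small relative to the property being checked:

* **Parameter recovery** — 200 panels at the default design; truth places
  barley 2.0 log units above grassland, with all means high enough
  (grassland growing-season mean 3.5 log ng/L) that censoring is negligible
  and the check isolates estimator behaviour from censoring distortion.
  The mean estimate must sit within 10% of truth and the Satterthwaite 95%
  Wald intervals must cover truth at a rate consistent with nominal
  (accepted band 0.90–0.99, about ±3 Monte-Carlo standard errors).
* **Family-wise error** — 500 panels under a global null (every cell mean
  3.5); the Šidák-corrected contrast family must reject in at most
  $\alpha$ plus binomial Monte-Carlo error of the replicates, and the raw
  contrast p-values must be near-uniform (Kolmogorov distance < 0.1).
* **Oracle equivalence** — raster build/merge/summarise agree with a
  per-pixel enumeration oracle to machine precision on random grids up to
  20 × 20, and the U statistic agrees with an exhaustive pair-count oracle
  over 1000 random instances with group sizes up to 8.

These simulations fit the single-variance nested structure, which matches
the generator's constant-variance truth; the season-specific default
remains the recommended structure for real panels, where the variance
heterogeneity it models is the point. Replicates whose random crop
assignment produces an empty crop-by-season cell (possible for the rarest
crop at 5% of 50 quarter sections) fail estimability by design and are
excluded from the tallies; the suites require at least 90% usable
replicates.

## Known limitations

* The atlas is an expected-value exposure model: it says nothing about
  which particular fields were treated, and its accuracy is bounded by the
  registry's resolved rates and treated fractions.
* Acetamiprid is deliberately absent from the atlas examples (its use
  pattern — foliar plus seed treatment on horticultural crops — does not
  fit the seed-loading identity), though nothing prevents adding registry
  rows for it.
* The mixed model requires every modelled crop-by-season cell to contain
  data; heavily unbalanced panels may need crops pooled or seasons dropped
  before fitting.
* The δ offset makes log-scale estimates conditional on a censoring
  convention; conclusions that hinge on wetlands near the LOQ should be
  checked under both LOQ sets and both mean modes.
* No spatial autocorrelation, no Bayesian variant, and no attempt to
  reproduce any published coefficient table — the raw study data behind
  such tables are not available, and the package's claims are about its
  own computations.
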