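---
title: "Validating a capillary electrophoresis assay: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a capillary electrophoresis assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cevalidate)
```

## The problem

Quantitative CE assays for drug substances are validated against
ICH-style criteria: system suitability, linearity, limits of detection and
quantitation, precision, accuracy (spike recovery), selectivity and
robustness. cevalidate implements that entire computation as a tested
pipeline, anchored to a validated ertapenem sodium assay run in 10 mM
phosphate electrolyte at pH 7 with 15 kV separation voltage and an analyte
migration time near 3.2 min. Because the raw instrument traces of such
studies are rarely deposited, the package pairs the statistics with a
simulator whose ground truth is exactly the published response law, so
every stage can be verified end to end.

## The signal model

An electropherogram is modelled as

$$ y(t) = h\,e^{-(t-t_m)^2 / 2\sigma_p^2} + b_0 + b_1 t + \varepsilon(t), \qquad
\varepsilon(t) \sim \mathcal N(0, \sigma_b^2), $$

a single Gaussian analyte peak on a linear-drift baseline with i.i.d.
detector noise. A single symmetric Gaussian is the simplest shape
consistent with the reported symmetric peak and with the half-height plate
number formula used downstream; asymmetric (EMG) peaks, overlapping peaks
and spectral dimensions are out of scope.

The quantitation variable in CE is the **corrected area**
$A_\mathrm{corr} = A_\mathrm{raw}/t_m$, which removes the analyte-velocity
dependence of the detector residence time. The simulator therefore imposes
its response law on the corrected area: a run at concentration $C$ draws

$$ A_\mathrm{corr} = S\,C + b + \mathcal N(0, \sigma_A), \qquad
t_m = \mu_t + \mathcal N(0, \sigma_t), $$

and renders a Gaussian whose raw area is $A_\mathrm{corr}\cdot t_m$. With
all noise terms at zero, peak integration followed by the calibration fit
returns the configured slope and intercept to better than six significant
figures — the pipeline's round-trip identity.

### Default parameters and why

| parameter | default | unit | rationale |
|---|---|---|---|
| calibration levels | 70…120 by 10 | µg/mL | the assay's validated range |
| replicates | 3 | — | triplicate study design (N = 18, total df 17) |
| response slope / intercept | 2281.7 / −24495 | area per µg/mL, area | the assay's calibration line |
| `noise_sd` | 1000 | corrected-area units | same order as the residual SD implied by the reference ANOVA (√2744346.59 ≈ 1657); gives R² ≈ 0.999, matching the study |
| `migration_time` | 3.2 | min | the analyte's migration time |
| `migration_jitter_sd` | 0.02 | min | the replicate migration-time SD of the reference system-suitability runs |
| `peak_sigma` | 0.031 | min | reproduces plate numbers near 10,900 via N = 5.54 (t/w½)² |
| `sampling_rate` | 600 | points/min | ≈ 44 points across the half-height width, ample for quadrature and width interpolation |
| `run_length` | 5 | min | covers the peak ± 6σ with margin |
| `baseline_drift_slope` | 0.1 | mAU/min | mild drift, as in routine runs |
| `baseline_noise_sd` | 0.05 | mAU | small relative to peak height; sets the blank-detection noise floor |

All sub-seeds are derived deterministically from the master seed with a
Lehmer-style integer mix, so studies are reproducible run by run and
identical `(config, seed)` pairs give bitwise-identical traces.

### What the generator does and does not emulate

It emulates the *statistical* structure the validation mathematics
consumes: a linear corrected-area response with homoscedastic noise,
migration-time jitter, baseline drift and noise, replicate study layouts,
content shifts under robustness factor changes, and analyte loss under
degradation (peak scaling by $1-f$ with no interfering product peaks,
since the reference stress study found none co-migrating). It does **not**
emulate electrophoretic physics — mobility from charge and size, Joule
heating, electroosmotic-flow drift, peak tailing mechanisms, or
degradation kinetics. Passing tests therefore demonstrate that the
*computations* are correct and statistically calibrated under the stated
model, not that the model captures every behaviour of a real instrument;
heteroscedastic response noise or drifting migration times between days,
for instance, are outside it.

### Speciation

`speciation_fractions()` implements the sequential macro-dissociation
model: $m$ ascending pKa values give $m+1$ protonation states with

$$ f_k(\mathrm{pH}) \propto 10^{\sum_{i \le k} (\mathrm{pH} - \mathrm{p}K_{a,i})}, $$

normalised per pH (computed with a log-scale shift for numerical
stability). For ertapenem's two printed macroscopic constants (3.22,
9.03), the singly deprotonated form carries > 99% of the population at
pH 7 — the rationale for the phosphate electrolyte. The published
microspecies diagram for this molecule distinguishes seven microstates
from micro-constants that are not public; a two-constant macro-model is
the faithful reconstruction from the available values, and it cannot
resolve those microstates.

## Peak metrology

Baseline: a linear fit through the lowest-quartile signal points (almost
surely off-peak), then a refit on all points lying less than 5 MAD above
that first line. The first pass is robust to the peak; the second removes
the downward bias of fitting only the noise's lower tail, so subtracted
residuals have median ≈ 0. Both passes are deterministic.

Detection: local maxima of the baseline-subtracted signal above
`min_height` (default: 10 × the MAD of the off-peak noise, floored at
1 mAU so a noiseless blank is still a blank). A run with no qualifying
maximum returns an empty table with a warning rather than an error —
blanks are an expected input class.

Integration window: from the apex outward to the first baseline crossing,
capped at ±6σ̂ where σ̂ = w½/2.3548. The cap matters in the noiseless
limit, where a Gaussian never crosses zero: stopping instead at a fixed
fraction of peak height (e.g. 0.1%) would clip ≈ 0.02% of the area and
silently cost the round-trip identity its six significant figures, while
±6σ leaves a relative tail below 10⁻⁸.

Apex refinement: a quadratic through the three log-signal points around
the sampled maximum, exact for a Gaussian. Without it the apex is
quantised to the sampling grid and the corrected area inherits a ~2·10⁻⁴
relative error at the default rate.

Quantities: trapezoidal raw area; corrected area $A/t_m$; plate number
$N = 5.54\,(t_m/w_{1/2})^2$ (the pharmacopoeial half-height formula);
asymmetry factor = trailing/leading half-width at 10% height, so fronting
peaks (broad leading edge, as this assay shows) give values below 1.

## Validation statistics

**Linearity.** OLS over all replicate points, and the five-row
lack-of-fit partition: SS_between over level means (df k−1), SS_regression
= slope²·Sxx over all N points (df 1), deviation of linearity =
SS_between − SS_regression (df k−2), residue (pure error) = SS_total −
SS_between (df N−k). Between, regression and deviation are each tested
against the residue mean square at α = 0.05. Computing the regression SS
on all points (not level means) is what yields the df 1 / df k−2
structure of the reference table. Unequal replicate counts are rejected on
this path by design (the plain fit and R² remain available).
`assemble_anova()` builds the same table from published SS/df when raw
data are unavailable.

**LOD/LOQ.** 3σ/S and 10σ/S. The guideline phrase "standard deviation of
the response" is ambiguous; the default σ is the residual SD of the
calibration fit, with intercept-SD and blank-SD selectable via
`sigma_source`. The published pair for the reference assay (0.77, 2.32)
has ratio 3.01 rather than 10/3 and cannot be reproduced by any single σ;
the package guarantees the 10/3 identity instead.

**Precision.** Sample (n−1) SDs everywhere; repeatability is the RSD of
seven same-day determinations; intermediate precision is the RSD of the
day-mean contents. Reported statistics render at 2 dp; internal values are
full precision.

**Content and recovery.** $C_s = A_s C_{rs} / A_{rs}$ against an external
reference standard, $C_s\% = 100\,C_s/C_t$; spike recovery
$R\% = 100(C_f - C_u)/C_a$ at spike levels of 10, 30 and 50 µg/mL over a
70 µg/mL base (the 80/100/120% design).

## Robustness

The screen uses a fixed 15-run, 7-factor three-level matrix (2n+1 runs):
each factor is at +1 in four runs, −1 in four, and nominal in seven, with
run 8 entirely nominal. The matrix embeds nominal levels and is not a
standard orthogonal Plackett–Burman construction, so it is stored as a
literal design; user-supplied designs must satisfy the same 4/4/7 column
balance.

For factor $i$ and side $s$, the deviation is
$D_i^s = |\bar y_{i=s} - \bar y_{i=0}|$. The nominal reference is the mean
over all seven runs with that factor at 0 — not the single all-nominal
run — because it uses all available data and is consistent with the
two-mean presentation of such studies. Each side's seven deviations pool
into $S = \sqrt{(2/7)\sum D^2}$, and a factor change is insignificant when
$D < \sqrt 2\,S$ (strict; the all-zero case $D =$ criterion $= 0$ is
defined to pass). The criterion constant is $\sqrt 2$: applied to the
reference study's printed deviations it reproduces the published criteria
(1.31 upper side; 0.806 lower side, which the source prints truncated as
0.80).

Because $\sqrt 2 S$ is a screening bound, not a calibrated test, each
factor–side comparison has roughly a 5% false-alarm rate under a truly
robust (null) method at the default noise; across 14 comparisons a
simulated null study is flagged somewhere in roughly half of seeds. The
Monte-Carlo property test bounds the per-test rate below 20%; users of
`run_full_validation()` on null configurations should expect the overall
verdict to vary by seed exactly as a real screen would.

## Pipeline reproducibility

`run_full_validation()` executes simulate → peaks → statistics →
robustness with stage-separated sub-seed streams. Study sizes follow the
reference design: 18 calibration runs, 10 system-suitability runs,
triplicate content, 7 repeatability determinations, 3 days × triplicate
for intermediate precision, 3 spike levels × 3, and 15 robustness runs.
Reports carry a config hash, the seed and a schema version; identical
config and seed reproduce the report exactly (timestamps aside), and the
JSON serialisation round-trips all numeric fields losslessly.

## Known limitations

* Single-peak quantitation only: no deconvolution of overlapping peaks,
  no EMG fitting, no diode-array dimension.
* The linear-drift baseline is global; wandering baselines would need a
  windowed estimator.
* The lack-of-fit ANOVA requires a balanced design.
* Weighted regression and outlier tests (Grubbs, Dixon, Mandel) are
  intentionally absent.
* The speciation model is macroscopic; microspecies resolution would
  require micro-constants that are not available.
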