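---
title: "Modelling aggregate inorganic arsenic exposure after a volcanic eruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aggregate inorganic arsenic exposure after a volcanic eruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arsrisk)
```

## The problem

Explosive eruptions mobilise geogenic arsenic into groundwater, lake water
and agricultural soil. In lakeside farming and fishing communities this
creates several simultaneous exposure routes to inorganic arsenic (iAs) —
the toxicologically dominant species — through drinking water, lake-derived
fish and clams, and crops grown on ash-affected soil. `arsrisk` implements a
probabilistic (Monte Carlo) aggregate exposure and risk assessment for this
setting, parameterised for the population of Batangas province after the
2020 Taal eruption: environmental measurements in, per-individual doses and
risk metrics out, with a global sensitivity analysis to say which inputs
drive the answer.

## Model structure

For each simulated individual $j$ the aggregate daily dose is

$$E_{j} = \sum_{i \in \text{media}} \frac{C_{ij} \cdot IR_{ij}}{BW_j}
\quad [\mu g / kg \cdot day],$$

where $C_{ij}$ is the iAs concentration in medium $i$ (µg/g for foods,
µg/L for water), $IR_{ij}$ the individual's daily intake of that medium
(g/day or L/day) and $BW_j$ the individual's own body weight (kg). One
Monte Carlo iteration is one individual; a run is 10,000 of them.

Concentrations are reconstructed from environmental measurements:

* **Fish**: lake-water total As × bioaccumulation factor
  (uniform 10.3–22 L/kg) × a dry-season multiplier (truncated normal,
  mean 6.71, SD 4.50 on [2.21, 13.66]) for individuals exposed in the dry
  season × the aquatic inorganic fraction (uniform 0.117–0.142).
* **Clams**: dry-weight total As (truncated normal, mean 5.67 mg/kg, SD 3,
  truncated to [0, mean + 3 SD]) × the same aquatic fraction draw used for
  fish.
* **Crops** (rice, corn, vegetables, root crops): soil total As
  (uniform 1.92–7.91 mg/kg) × a crop-specific soil-to-crop transfer factor
  × a fixed terrestrial inorganic fraction — 0.5 in the lower-bound (LB)
  scenario, 0.9 in the upper-bound (UB) scenario. One soil draw is shared
  by the four crops within an iteration: a simulated household farms one
  soil environment. The two scenarios are the only difference between runs,
  so under a common seed UB crop concentrations are exactly 1.8 × LB.
* **Drinking water**: total well-water As used directly as iAs (speciation
  of drinking water was measured as essentially inorganic), at a fixed
  intake of 1.791 L/day.

Risk metrics are the standard linear ones: the hazard quotient
$HQ = E/RfD$ with $RfD = 0.06$ µg/kg-day, and the excess lifetime cancer
risk $ECR = E \times CSF$ with $CSF = 0.032$ (µg/kg-day)$^{-1}$, so
$ECR/HQ \equiv RfD \cdot CSF = 0.00192$ row-wise. ECR is reported as
computed even where the linear extrapolation exceeds 1; such values flag
the breakdown of the low-dose approximation, not a literal probability,
and are deliberately not capped.

## Calibration of the drinking-water distribution

The well-water dataset behind the model is summarised only by its range,
0.000735–0.11 mg/L over 72 samples. Trace-element concentrations in
groundwater are canonically right-skewed, so the package models water As as
lognormal and calibrates it to the printed range with
`calibrate_lognormal_from_range()`: the geometric mean is the geometric
midpoint $\sqrt{lo \cdot hi}$ and `sigma_log` is chosen so that a stated
central interval has the range as its endpoints.

The choice of that interval's coverage matters. Reading the range as a
central 95% interval treats the extremes of 72 samples as the 2.5% and
97.5% quantiles, which systematically overstates the spread (the expected
plotting position of a sample extreme among 72 is much further out) and
inflates the arithmetic mean to ≈ 0.020 mg/L, pushing the drinking-water
pathway share to ≈ 20% of the LB total dose. The default configuration
instead uses the Hazen plotting positions of the sample extremes,
$0.5/n$ and $1 - 0.5/n$, i.e. coverage $1 - 1/n = 1 - 1/72 \approx 0.986$
(`hazen_coverage(72)`). This gives `sigma_log` ≈ 1.018, an arithmetic mean
of ≈ 0.0151 mg/L and a water share of ≈ 15% — consistent with the
scenario-invariant water contribution the model is meant to reproduce.
`calibrate_lognormal_from_range()` itself defaults to 0.95 for generic use;
the sample-size-aware coverage is a property of the shipped default
configuration, not of the function.

## Season, independence and randomness

* **Season**: each individual is assigned to the rainy or dry season with
  probability 0.5 (`season_split`). The seasonal multiplier applies to fish
  only. An equal mixture reproduces the observed fish contribution share;
  the split is exposed as an argument for populations with different
  exposure seasonality.
* **Independence**: intakes, body weight and concentrations are mutually
  independent — no intake–body-weight correlation is imposed, because no
  correlation structure is available to estimate one. Intake distributions
  are truncated normals bounded at 0 and mean + 3 SD; with SD ≫ mean
  (national survey dispersions), truncation makes them half-normal-like,
  and their truncated means sit well above the nominal means. This is a
  property of the published parameterisation, preserved deliberately.
* **Randomness**: one master seed per run; every sampled variable draws
  from its own child stream (`child_seed()`, a string hash of the variable
  name folded with the master seed). Consequences: bit-identical runs for a
  given seed; LB and UB runs share all draws; adding a variable does not
  perturb the others' draws. Truncated normals are sampled by inverse CDF,
  which is exact and respects bounds by construction.

## Sensitivity analysis

`sensitivity_analysis()` computes standardized regression coefficients
(SRC: OLS on standardized inputs and response) and partial rank correlation
coefficients (PRCC: correlation of rank-residuals controlling for all other
inputs) over the 18 sampled primitives: 4 environmental concentrations, the
bioaccumulation factor, the dry-season multiplier, the aquatic inorganic
fraction, 4 transfer factors, 6 food intakes and body weight. PRCC
p-values use $t = r\sqrt{df/(1-r^2)}$ with $df = n - 2 - k$, $k = 17$
controlled covariates. The binary season flag is excluded from the design
matrix (it is not a continuous input; its multiplier is included) — a
documented caveat, since the flag itself carries seasonal variance.

One mapping caveat deserves emphasis. Tornado plots in this literature
often label a driver "iAs concentration in rice". In this model that
quantity is not a primitive: it is soil As × transfer factor × fixed
fraction. The decomposition splits its influence between `soil_As` (shared
across all four crops, and therefore highly ranked on its own) and
`TF_rice`. Under the UB scenario `TF_rice` ranks 5th by |PRCC| but 6th by
|SRC|, with `soil_As` 2nd by both — the two columns jointly carry what a
coarser parameterisation would attribute to a single rice-concentration
variable. Rankings of composite labels are therefore not directly
comparable across parameterisations.

## The pregnancy subgroup

A pregnant subgroup can be flagged (`pregnant_fraction`) and given intake
multipliers (`apply_subgroup_modifiers()`); its anthropometrics come from
the female distributions. No default modifier profile is asserted: reduced
seafood intake in pregnancy is plausible but unquantified for this
population, so the mechanism is configurable and any default should be
treated as exploratory, not as an estimate.

## Synthetic field tables

`generate_field_tables()` produces synthetic raw measurement tables (72
well-water values from the same calibrated lognormal restricted to the
observed range; soil, lake and clam values uniform within their measured
ranges) and `fit_inputs_from_tables()` closes the loop back to model
inputs. These fixtures reproduce the ranges, skewness and sample sizes of
the real monitoring data but none of its spatial structure (danger-zone
distance, well type), so tests built on them validate the calibration
machinery, not the field campaign.

## Numerical choices and problem sizes

* Exceedance fractions use strict inequality (HQ > 1, not ≥).
* Tornado ties are broken alphabetically; all 18 inputs are always
  reported regardless of significance.
* Contribution percentages are ratios of pathway means to the total mean
  (not means of per-individual ratios), matching the pie-chart convention.
* Degenerate inputs fail loudly: zero-width truncation intervals,
  non-positive lognormal ranges, rank-deficient sensitivity designs (the
  offending columns are named), media missing from field tables.
* The test suite exercises the full model at 10,000 iterations (the study
  scale) for distributional checks and 200–5,000 iterations for structural
  ones; sampler-moment checks use $10^5$–$10^6$ draws against quadrature
  oracles. A full dual-scenario run with sensitivity takes a few seconds on
  one CPU.

## Limitations

The model inherits the limitations of its inputs: transfer and
bioaccumulation factors from other geochemical settings; total-As (not
speciated) measurements for soil, water and clams; national rather than
lakeshore dietary patterns; no age stratification; dry-weight clam
concentrations applied to fresh-weight intake (conservative); no dermal or
inhalation pathways; and a daily-dose convention without lifetime
averaging. Passing tests demonstrate fidelity to the stated
parameterisation, not to unmeasured features of the real exposed
population.
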