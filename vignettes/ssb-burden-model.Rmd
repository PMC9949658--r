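---
title: "A comparative risk assessment model for the burden of sugar-sweetened beverage consumption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A comparative risk assessment model for the burden of sugar-sweetened beverage consumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbcra)
```

## The question the model answers

How many deaths, disease events, disability-adjusted life years (DALYs)
and direct medical dollars in a population can be attributed to
sugar-sweetened beverage (SSB) consumption?  `ssbcra` answers this with a
comparative risk assessment: the burden observed under current consumption
is compared with a counterfactual population that is identical except that
SSB intake is zero.  The packaged inputs describe Argentina in 2020
(roughly 30.2 million adults averaging about one 240 ml serving per day,
and 12.9 million children averaging about one and a half), but every input
is a CSV table and the engine is country-agnostic.

## Causal structure

Exposure acts through two pathways, kept strictly disjoint to avoid double
counting:

* **Direct pathway** — per-serving relative risks act on type-2 diabetes
  (RR 1.37 per serving/day, one value assumed to act identically on
  incident cases, prevalent cases and deaths) and on cardiovascular
  conditions (RR 1.08, 95% CI 1.04–1.13 for incidence/prevalence; RR 1.08,
  95% CI 1.02–1.14 for mortality).  These RRs are not adjusted for BMI.
* **BMI-mediated pathway** — each serving/day shifts attained BMI
  (+0.10 kg/m² below a baseline BMI of 25, +0.23 kg/m² at or above it;
  children +0.57/1.7 ≈ +0.335 kg/m² per serving/day).  Downstream
  conditions (cancers, osteoarthritis, low back pain, asthma, dementias,
  chronic kidney disease, gallbladder disease) respond to BMI through
  log-linear RRs per kg/m² above a reference BMI.  Diabetes and
  cardiovascular disease are excluded from this pathway *by validation*,
  because they already carry the direct RRs.

Children contribute only overweight/obesity cases and their annual costs;
their long-term disease risks are deliberately not extrapolated.

## The attributable fraction

For a stratum with exposure distribution $X$ (servings/day) and a
per-serving relative risk $\theta$, the dose-specific risk is
$RR(x) = \theta^{x}$ and the population attributable fraction against the
zero-consumption counterfactual is

$$\mathrm{PAF} = 1 - \frac{1}{\mathbb{E}\!\left[RR(X)\right]}.$$

The mean-RR reading deserves a note: a literal sum of individual relative
risks in the denominator would exceed one person and drive the fraction
toward 1 regardless of the exposure, contradicting PAF semantics, so the
engine uses the standard continuous-exposure form above.  When only a
stratum mean is available — the packaged-table case — the exposure is a
point mass at the mean; full sample-based distributions go through the same
code path.  A linear dose-response ($1 + (\theta-1)x$) is available behind
the `dose_response` switch for sensitivity analysis.

For the BMI-mediated pathway the same comparison runs over the BMI
distribution before and after the counterfactual shift:
$\mathrm{PAF} = 1 - \mathbb{E}[RR(B_{cf})] / \mathbb{E}[RR(B_{base})]$
with $RR(b) = \rho^{\max(0,\,b - b_0)}$, flat below the reference BMI
$b_0$ (default 22.5 kg/m², the midpoint of the conventional
theoretical-minimum-risk window).

Attribution is then linear: attributable events, deaths, YLDs, YLLs and
costs are the PAF times the corresponding all-cause totals, with
case-driven quantities (events, YLDs, costs) using the events PAF and
death-driven quantities (deaths, YLLs) the mortality PAF.

## Reconstructing a BMI distribution from published summaries

Published inputs give only a mean BMI and category prevalences (WHO adult
cutoffs 25/30/35/40 kg/m²).  `fit_bmi_distribution()` rebuilds an
individual-level point set in three steps:

1. a log-normal shape (positive support, right skew, like empirical BMI)
   is anchored so its mass at or above 25 equals the total
   overweight-plus-obesity prevalence;
2. its spread is solved (one-dimensional root find) so that the
   *post-stratified* mean — category masses re-weighted to the published
   cells, within-category shapes from the log-normal, support clamped to
   10.1–79.9 kg/m² — matches the published mean;
3. points are placed at quantile midpoints within each category, so
   category masses are exact by construction and the point set is
   deterministic; any residual mean error (discretization, or profiles at
   the edge of the log-normal family — two of the packaged strata need
   this) is absorbed by shifting points within categories in proportion to
   their headroom, which provably preserves the category masses.

Child strata have no published absolute cutoffs or mean BMI, so the
packaged child means are synthetic placeholders and the child
overweight/obesity thresholds are defined as baseline quantiles matching
the published prevalences under a fixed-shape log-normal (`sdlog = 0.12`).
This makes the child calculation a statement about *mass moved across the
baseline thresholds*, which is exactly what the counterfactual needs, and
nothing more.

The counterfactual shift selects each individual's coefficient once from
the baseline BMI (no re-evaluation when the shift crosses 25, since no
iteration rule is published) and floors shifted BMI at 13 kg/m², never
raising a point above its baseline.

## Burden accounting

Rates are consumed per 100,000 as published; counts are rate × population
/ 10⁵.  YLD = prevalent cases × disability weight; YLL = deaths × residual
life expectancy at the stratum midpoint age (open-ended bands close at
85), interpolated from an abridged life table — the packaged one is a
synthetic stand-in, shipped as `life_table_synthetic.csv`.  DALYs = YLD +
YLL with no age-weighting and no discounting.  Whether a condition's
"events" are incident or prevalent counts is configuration
(`events_basis`): prevalent for diabetes, musculoskeletal conditions and
overweight/obesity; incident elsewhere.  Costs are incident cases ×
first-year cost + prevalent cases × annual cost; the packaged cost tables
are already in USD (flagged by `cost_unit`), and local-currency inputs are
divided by the exchange rate (48.14 ARS/USD in the packaged economics
table) at reporting time.

## Uncertainty propagation

`run_mc()` repeats the whole deterministic chain (1000 iterations by
default) drawing, per iteration:

* one value per relative risk, shared across strata — the RR is a global
  parameter — normal with sd = (CI upper − CI lower)/3.92, floored at
  10⁻⁶ (a log-normal alternative sits behind `rr_sampling`);
* stratum consumption means, independent normal draws truncated at 0;
* optionally the BMI-shift coefficients (`sample_bmi_deltas`, default off,
  since it is not clear the published intervals sampled them).

Negative attributable fractions from sub-unity RR draws are *retained*
inside the simulation so percentile intervals are not biased upward; only
deterministic point estimates cap at zero (with a warning).  Intervals are
percentile 2.5/97.5, and both-sex and all-condition cells are summed
within each iteration before taking percentiles, so interval bounds
respect the correlation between cells.  A fixed seed makes runs bitwise
reproducible.

## What the synthetic generator does and does not emulate

`generate_population()` emits internally consistent inputs for arbitrary
stratum layouts: Gamma-distributed consumption means (non-negative,
right-skewed), BMI profiles derived from a log-normal consistent with the
drawn mean (so the fit always has an exact solution), and epidemiology,
costs and RRs perturbed ±20% around the packaged values.
`generate_known_truth()` inverts the model: given a target PAF $p$ it sets
$\theta = 1/(1-p)$ at one serving/day, so every attributable quantity has
a closed form; with observation noise requested, the inputs carry a noisy
draw of the true mean and RR while the expected burden is computed from
the truth, which is what makes interval-coverage testing meaningful.

The generator does not emulate survey microdata, household structure,
socioeconomic gradients, or correlated measurement error between strata —
so passing tests certify the engine's arithmetic and calibration under the
stated sampling laws, not the field accuracy of any particular national
estimate.

## Numerical choices and problem sizes

* BMI point sets: 2000 points per stratum by default (tests use 1000–2000);
  category masses are exact, means match to root-finder tolerance (~10⁻¹⁰).
* Monte Carlo: 1000 iterations for the headline run; the calibration study
  uses 200 replicates × 200 iterations, which keeps the full validation
  suite under a minute while leaving binomial noise on coverage around
  ±1.5 percentage points (the pass threshold of 93% sits three standard
  errors below the observed ~95%).
* Root finding brackets σ ∈ [0.02, 0.8]; degenerate profiles (all mass on
  one side of 25) fall back to a fixed shape with a location solve.
* Ties and floors: RR draws floored at 10⁻⁶, consumption at 0, shifted BMI
  at 13 kg/m²; exposure weights renormalized when they do not sum to 1
  within 10⁻⁹.

## Known limitations

* The packaged per-disease rates are national aggregates; the published
  headline estimates were built from single-year, sex-specific rates that
  exist only in supplementary material, so the end-to-end deterministic
  run on packaged tables is indicative rather than a reproduction.  The
  reporting stage therefore also consumes the published per-condition,
  per-sex burden table directly, where aggregation identities can be
  checked exactly.
* Several published summary cells are internally inconsistent at the ±1
  level (and the grand-total cost row by ~0.8%); recomputed sums are
  reported in all outputs.
* BMI-mediated RRs and the diabetes RR confidence interval are synthetic
  placeholders pending country-specific values; they are clearly flagged
  in the schema documentation.
* No caloric-compensation or substitution behaviour, no lag structure, no
  productivity costs, no discounting.
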