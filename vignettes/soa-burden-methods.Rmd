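---
title: "Methods: from modeled aromatic SOA to monetized mortality burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from modeled aromatic SOA to monetized mortality burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soaburden)
```

## The problem

Single-ring aromatic hydrocarbons in gasoline exhaust oxidize to secondary
organic aerosol (SOA), a component of PM2.5. Chemical-transport models
underpredict this component — ambient tracer-based measurements run roughly
twice the modeled values nationally, with strong regional differences — so a
health impact assessment built directly on model output would understate the
burden. `soaburden` chains four corrections and transformations: bias-correct
the field against monitors, keep only the gasoline-attributable share,
convert concentration to attributable mortality, and monetize.

## The bias-correction model

For monitor pair $i$ in region $r$ (observed tracer-based aromatic SOA
$y_{ri}$ in µgC/m³ against co-located modeled values $x_{ri}$):

$$y_{ri} = \beta_0 + (\beta_1 + u_r)\,x_{ri} + \varepsilon_{ri},
\qquad u_r \sim N(0, \sigma_u^2),\quad
\varepsilon_{ri} \sim N(0, \sigma_e^2).$$

Random intercepts are constrained to zero: the reference fit reports region
intercept effects of exactly 0, and the physically meaningful bias is
multiplicative (a model that predicts zero SOA where none exists should not
acquire a region-specific offset). Three regions are used — Northeast and
Midwest merged (`MidwestEast`), `South`, `West` — because SOA yields depend
on NOx regime and temperature, which differ along exactly this split.

**Estimation.** REML, profiling the restricted likelihood over the variance
ratio $\lambda = \sigma_u^2/\sigma_e^2$. Because the random-effects design is
block-diagonal with one rank-one block per region
($V_r = I + \lambda x_r x_r^\top$), Sherman–Morrison gives every needed
quantity in closed form and each profile evaluation is $O(n)$. A bounded
scalar optimizer searches $\log\lambda \in [-30, 30]$ with tolerance
$10^{-8}$; the boundary $\lambda = 0$ is evaluated explicitly and kept if it
is at least as good, which floors the variance components at zero. This
3-group, 2-fixed-effect problem needs no general-purpose mixed-model
machinery, and the scalar profile is deterministic and auditable; the test
suite cross-checks the fit against both `lme4` and a dense-grid
profile-likelihood oracle (agreement to at least 5–6 digits and 3
significant figures respectively).

Input rows are canonicalized (sorted by site, then month) before fitting, so
results are permutation-invariant. A single-region input degenerates to
pooled OLS with a warning; constant model values within a region are a
singular design and an error.

**Composition and application.** Each region's adjustment equation is
$\text{conc}_{\text{adj}} = \beta_0 + (\beta_1 + \hat u_r)\,\text{conc}$,
clamped at zero. Negative composed slopes are allowed but flagged — with
three regions the BLUPs are weakly shrunken and a pathological campaign can
produce one; clamping output at zero keeps concentrations physical. The
reference coefficients (`reference_bias_fit()`) compose to slopes
3.016 / 1.627 / 1.04 with intercept 0.01875 µg/m³.

## Source attribution

The packaged national inventory of single-ring aromatic VOC (tons/yr) gives
gasoline 2,491,313 of a 3,608,762 total — a 69.0% share, computed from the
inventory at run time rather than hard-coded, so users can swap inventories.
Uniform mode scales every unit by this fraction. The urban/rural sensitivity
mode instead scales only rural units by it and urban units by
`urban_fraction` (default 1), reflecting the possibility that urban aromatic
emissions are essentially all gasoline-derived. Shares carry full precision
internally; "69%" appears only after report rounding.

## Health impact

Attributable cases per unit follow the log-linear health impact function

$$\text{cases} = y_0\,(1 - e^{-\beta\,\Delta C})\,\text{Pop},$$

with $y_0$ the baseline all-cause mortality rate (per person-year),
$\Delta C$ the unit's full gasoline-attributable concentration
(rollback-to-zero counterfactual) and $\beta$ the concentration-response
coefficient per µg/m³. At the relevant exposure scale
($\Delta C \le 0.6$, $\beta \le 0.015$) this is within
$\beta\Delta C/2 < 0.5\%$ of the linear form, so the choice of functional
form cannot materially change results; `expm1()` is used so the bound holds
numerically even at tiny $\beta\Delta C$. Cases are bounded by baseline
deaths by construction.

Four packaged coefficients span the literature: 0.015 and 0.006 (two major
cohort studies, the latter twice with different uncertainty widths) and
0.011 (an expert-elicitation consensus distribution). $\beta$ uncertainty is
normal truncated at zero. The elicitation's 5th/95th bounds (0.003, 0.020)
are as published; for the cohort CRFs the bounds are back-solved from the
published 5th/95th percentile spreads of the impact estimates, which is
exact to the extent the case-to-$\beta$ mapping is linear (here, to
$<0.2\%$). `propagate_uncertainty()` draws $\beta$ by inverse-CDF truncation
(no rejection, hence bit-reproducible under a fixed seed and exactly
`n_draws` uniforms consumed), recomputes national cases per draw, and
reports empirical type-7 quantiles. Only CRF uncertainty is propagated —
field and population are held fixed — matching standard practice of
reporting C-R-function-only percentile bounds.

## Valuation

Dollars are cases × the value of mortality risk, $7.4M in 2006 USD, with no
inflation or income-growth adjustment (single-year framing). Stored values
are unrounded; report formatters round billions to one decimal, millions and
cases to integers. State reports rank by descending central cases with
alphabetical tie-break.

## The synthetic world

The generators emulate the study conditions, with ground truth recorded for
recovery testing:

- **Field**: abstract "county-like" units allocated round-robin across the
  lower 48 states + DC; log-normal concentrations per region. Default
  regional means (0.060 / 0.045 / 0.025 µg/m³, sd 0.03) put the national
  mean of statewide averages near 0.045 µg/m³ — the unadjusted model scale.
  A statewide mode targets the published per-state means (0.03–0.23 µg/m³)
  and rescales each state's draw so its sample mean hits the target
  *exactly*: boundary states sit at the ends of the published range, so an
  uncalibrated sample mean would breach it with probability ≈ 1/2 regardless
  of sample size; exact calibration is the only reading under which
  "statewide means lie in the published range" is a checkable property.
- **Monitors**: sites sampled evenly per region; observations from the
  truth's linear bias model plus Gaussian noise truncated at zero. The
  default noise sd is 33% of the regional mean observation, the approximate
  error of tracer-based aromatic-SOA estimates; recovery tests use sd 0.02
  µgC/m³. Observed and modeled values are treated in the same unit: the
  µgC (organic carbon) vs µg (organic mass) conversion is not published, so
  `model_scale` exposes it explicitly (default 1) instead of fixing it
  silently.
- **Inventory**: the published source-category tonnages as code defaults,
  overridable per source or replaceable outright.
- **Population**: log-normal populations (mean 60,000, CV 1 — county-scale),
  constant baseline mortality rate 0.008/person-year by default (no age
  stratification; the reference analysis's age structure is unpublished, so
  synthetic rates are deliberately simple and configurable), urban flags at
  a configured proportion (default 0.3).

Not emulated: atmospheric chemistry/transport, monthly time structure beyond
a label, spatial autocorrelation, and any true spatial variation in the
gasoline share. Passing recovery tests therefore demonstrates that the
estimation machinery is correct under the stated noise model — not that the
bias model is correctly specified for real monitor networks, where
measurement error in $x$, seasonal confounding and spatially correlated
residuals all exist.

## Numerical and design choices

- REML profile tolerance $10^{-8}$ on $\log\lambda$; variance floor at 0;
  $O(n)$ Sherman–Morrison evaluations.
- Serialized fits print doubles with 17 significant digits so write→read
  round-trips exactly.
- Ties in source ranking break by label; state-report ties alphabetically.
- All generators take explicit seeds; the pipeline derives per-stage seeds
  as small offsets from one master seed, and `run_pipeline()` output
  directories are byte-identical under a fixed config + seed (the manifest
  records seed, parameters and row counts, never timestamps).
- Test and example problem sizes — 98–600 units, 30–300 monitors, 200
  replicates for recovery, $10^4$–$10^5$ Monte-Carlo draws — were chosen as
  the smallest sizes at which the statistical assertions have comfortable
  power; the full suite runs in well under a minute.

## Limitations

Morbidity endpoints, life-table accounting, population projection and
cessation lag are out of scope. The headline published mortality counts
depend on proprietary gridded fields and census-tract baseline data that are
not reproducible at desk scale; what the package reproduces exactly is the
published worked-example arithmetic (inventory shares, composed slopes,
monetization, reference comparison), and what it verifies statistically is
the machinery (REML recovery, HIF bounds, uncertainty propagation) on
synthetic data of known truth.
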