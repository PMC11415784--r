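---
title: "Methods: extreme temperature-attributable mortality, from exposure to projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extreme temperature-attributable mortality, from exposure to projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model, its assumptions, the tunable parameters, the synthetic-data
generator, and the numerical and design choices made where the design was
genuinely open.

## The exposure definition

An *extreme heat day* for county $c$ is a day whose daily mean temperature
(conventionally the mean of the daily minimum and maximum) strictly exceeds
the 97.5th percentile of that county's baseline-period daily means; an
*extreme cold day* falls strictly below the 2.5th percentile. The baseline
is a fixed historical window (1979–2000 in the full-scale setting), so the
thresholds are absolute Celsius cutoffs frozen for all later periods,
including projections. Two conventions had to be pinned down:

* **Percentile estimator.** Percentiles use linear interpolation between
  order statistics (`quantile()` type 7, the most common default).
  Threshold values shift by a few hundredths of a degree across
  conventions; since downstream counts use strict inequalities the choice
  is documented and tested against a hand-written sort-and-interpolate
  oracle, not left implicit.
* **Ties.** A day exactly at a threshold is *not* extreme ("over" / "under"
  read strictly). A day can never be both hot and cold because the
  thresholds must satisfy cold < hot; a constant temperature series, for
  which the two percentiles coincide, is rejected as degenerate.

The sensitivity pair (99, 1) and a heat-index variant are first-class
options. The heat index is the US National Weather Service regression
(Fahrenheit-native, converted internally), with its low-temperature
simple-formula fallback and the published low- and high-humidity
adjustments. For the heat-index exposure the same symmetric percentile
logic is applied on the apparent-temperature scale, with thresholds
recomputed from the same baseline years — the natural reading where the
convention is otherwise unstated.

Projected exposure is processed per climate model (GCM): extreme days are
counted in each GCM's daily series against the frozen thresholds, collapsed
to mean counts per county and calendar month across the projection years
(a 30-year mean at full scale, shorter in the synthetic default), and only
then averaged — unweighted — across GCMs. Excess-death projection runs per
GCM and averages *deaths*, not exposure, so the ensemble mean of the
nonlinear excess formula is computed correctly.

## Rate stabilisation

Small-county monthly rates are noisy. Before fitting, rates can be shrunk
by Marshall's (1991) *local* empirical Bayes estimator on a county
adjacency graph: with neighborhood $J(i) = N(i)\cup\{i\}$,

$$m_i = \frac{\sum_J y_j}{\sum_J n_j},\qquad
  s^2_i = \frac{\sum_J n_j (r_j - m_i)^2}{\sum_J n_j},\qquad
  w_i = \frac{(s^2_i - m_i/\bar n_i)_+}{(s^2_i - m_i/\bar n_i)_+ + m_i/n_i},$$

and $\hat r_i = m_i + w_i (r_i - m_i)$. The method is named but its formula
is not printed in the methodological literature this package follows, so
three choices are recorded here: the estimator is *local* (not global), the
neighborhood *includes* the county itself, and a negative prior-variance
estimate is truncated to zero (full shrinkage to the local mean). Isolated
counties fall back to the same estimator on the pooled set of all counties.
Smoothing granularity is equally unstated upstream; the default smooths
*period-aggregate* county rates (one shrinkage factor per county, applied
multiplicatively to its monthly rates), with a monthly mode and an off
switch (`smooth_mortality(enabled = FALSE)`) for sensitivity runs. The
estimator is verified to machine precision against a hand-computed
three-county fixture.

## The mortality model

The association is estimated by Poisson pseudo-maximum likelihood:

$$\mathbb{E}[y_{cmt}] = \exp\!\big(\alpha_c + \gamma_m + \delta_t +
  \beta_h H_{ct} + \beta_c C_{ct} + \textstyle\sum_k f_k(x_{k,ct})\big)$$

Only the Poisson *score equations* are used, so the outcome need not be an
integer and no Poisson variance assumption is made; overdispersion is
handled by sandwich standard errors. Two outcome modes share the same score
equations (and are tested to return identical coefficients):

* **rate mode (default)** — outcome is the monthly (age-adjusted) rate per
  100,000 with analytic weights equal to population;
* **count mode** — outcome is the death count with offset
  $\log(\text{pop}/10^5)$.

Fixed effects for county, calendar month, and year are *absorbed*:
at each IRLS step the working response and regressors are residualised by
alternating weighted within-group demeaning to tolerance $10^{-10}$, then
weighted least squares is solved on the demeaned system; IRLS stops when
the relative deviance change falls below $10^{-9}$. Fitting is
deterministic. Fixed-effect groups whose outcome is identically zero are
perfectly separated; they are dropped and logged. The absorbed component is
afterwards decomposed back into additive county/month/year effects by
weighted backfitting (exact at convergence, since the component lies in the
span of the fixed-effect sets); this supports out-of-period prediction.

Covariates enter as restricted cubic splines: $k$ knots at conventional
percentile positions (5/35/65/95 for the default $k=4$) give $k-1$ design
columns including the linear term, cubic between knots and linear beyond
the terminal knots. The covariate list is fully configurable — the
full-scale analysis's covariate identities live outside the main
methodological text, so nothing is hard-coded.

Inference uses the heteroskedasticity-robust sandwich
$\hat V = \frac{n}{n-k} A^{-1} B A^{-1}$ with $A = \tilde X' W \tilde X$,
$B = \tilde X' \mathrm{diag}\big(w^2(y-\hat\mu)^2\big) \tilde X$, and $k$
counting explicit plus absorbed parameters. Cluster-robust errors (by
county) are available but off by default, matching the
heteroskedasticity-robust description of the estimator this design
follows. Wald tests are two-sided with no multiplicity adjustment.

**BIC and specification choice.** The linear-in-days exposure
specification is compared with a restricted-cubic-spline-of-exposure
variant by BIC $= -2\log PL + k\ln n$, with $k$ counting explicit
parameters only and ties broken toward fewer parameters. One numerical
subtlety: in rate mode the population-weighted pseudo-likelihood is scaled
by the rate denominator, which would make likelihood differences
meaninglessly large; the pseudo-likelihood is therefore evaluated on the
count-equivalent scale (weights folded back into deaths), making BIC
invariant to the rate-versus-count parameterisation.

## Attribution

Excess deaths are a counterfactual difference: expected deaths at observed
exposure minus expected deaths with the extreme-day counts set to zero,
everything else (fixed effects, covariates) held at observed values:

$$E_h = \sum_{ct} \hat\mu_{ct}\big(1 - e^{-\hat\beta_h H_{ct}}\big),$$

analogously for cold, with heat and cold zeroed one at a time from the same
joint fit so that heat + cold = combined holds exactly. Totals are divided
by the number of study years (mean annual figures); per-million rates
divide by the at-risk population.

The confidence-interval machinery for excess deaths is not specified in
the source methodology; the package defaults to the standard **delta
method** on $(\hat\beta_h,\hat\beta_c)$ with the robust covariance, with a
seed-controlled parametric simulation alternative (10,000 draws from
$N(\hat\beta,\hat V)$). Both treat the absorbed fixed effects as fixed at
their estimates — coefficient uncertainty only, the standard practice for
attributable-burden intervals. Strata (age groups, sexes, regions, metro
status) are fitted separately; aggregates across independently fitted
strata add point estimates and variances. Region-restricted fits mean
regional totals need not sum to the national figure, as in any
subgroup-refit design.

## Projection

Mid-century projection substitutes projected extreme-day counts (per GCM)
and projected population into the excess formula while freezing the
regression coefficients, fixed effects, and covariate contributions at
their current-period estimates — covariate drift and adaptation are
explicitly out of scope. Population scenarios pair with emissions
pathways (SSP2 with RCP4.5, SSP5 with RCP8.5); unknown pairings are
errors. Because projected exposure is indexed by calendar month, the year
fixed effect must be summarised: the default uses the *mean* of
current-period year effects (equivalently, the exposure-free log-rate is
averaged across current years per county-month), with a last-year option.
When projected exposure carries an explicit year column, the per-year path
is used instead — this makes the identity scenario (projected exposure and
population equal to current) reproduce current-period estimates to
floating-point accuracy, a property the tests assert.

Projection intervals reflect coefficient uncertainty only; climate-model
spread is reported separately as the per-GCM minimum and maximum. Percent
change versus the current period uses the delta method on the ratio, with
the gradients of both estimates taken with respect to the *same*
coefficient vector. A non-positive current-period point estimate (possible
in small or null synthetic studies) leaves the relative change undefined
and is reported as `NA` rather than an error mid-pipeline; the direct
`percent_change()` call retains the hard error on non-positive input.
When lagged exposure terms are in the model, the lag of a climatological
calendar-month mean is taken as the previous calendar month's mean (cyclic
at the year boundary).

## The synthetic generator

`simulate_study()` produces a complete toy study with known truth:

* **Temperatures.** Each county follows
  $T(c,d) = a_c + A_c \sin(2\pi\,\mathrm{doy}/365 - \pi/2 + \phi_c)$ plus
  AR(1) noise with persistence $\rho = 0.7$ and innovation scale 3 °C —
  persistence makes threshold exceedances cluster into synthetic heat
  waves and cold snaps. County means draw from 8–18 °C and amplitudes from
  10–14 °C. Each GCM adds one constant shift drawn from
  $N(2.0, 0.5^2)$ °C (intermediate pathway) or $N(3.0, 0.5^2)$ °C (high
  pathway) — realistic mid-century magnitudes, chosen once. Constant
  shifts (not time-varying trends) are a documented simplification:
  sufficient to exercise the ensemble machinery, not a climate emulation.
* **Deaths.** $y_{cts} \sim \mathrm{Pois}\big(\mathrm{pop}/10^5\cdot
  \text{base}_s\cdot e^{\alpha_c+\gamma_m+\delta_t+\beta_h H+\beta_c C}\big)$
  per age stratum $s$, with winter-peaked month effects and planted
  per-day effects at published magnitudes: heat 0.09% (older) / 0.17%
  (younger), cold 0.26% / 0.27%. Baseline rates are 350 (older) and 30
  (younger) deaths per 100,000 per month — realistic US all-cause
  magnitudes. Strata share exposure but have distinct coefficients,
  mirroring separate per-stratum fits.
* **Scale.** 100 counties on a 10×10 grid (rook adjacency), 5 baseline +
  5 current + 5 projection years, 20 GCMs. County adult populations draw
  uniformly from 0.5–5 million so the 100 synthetic counties partition a
  national-scale adult population (~275 million): the toy panel then
  carries statistical information comparable to a full national county
  panel and recovery tests run at realistic precision. Scenario population
  growth factors (older +19% / younger −13.2% intermediate; +35% / −1.5%
  high) match published national projections by age group.
* **Truth object.** Expected counts $\mu_{ct}$ at the true parameters are
  stored, and the closed form
  $\sum\mu(1-e^{-\beta_h H - \beta_c C})$ is exposed via `truth_excess()`;
  the attribution path evaluated at the true coefficients must match it to
  $10^{-10}$ relative — a test, not an assumption.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: spatial correlation of temperature across
counties, realistic US climatology or demographic pyramids, within-county
exposure heterogeneity, harvesting/displacement dynamics, or adaptation.
One consequence worth noting: with published effect sizes the synthetic
current-period burden is more cold-dominated than the real-world mix, so
the *combined* synthetic trajectory under warming is flatter than the
published one even while the heat and cold components move in the expected
directions.

## Test problem sizes

The suite runs oracle equivalence on ten random panels of at most 5
counties × 24 months; Monte-Carlo recovery and null calibration each use
50 replicates of the default 100-county, 60-month study (per-stratum
fits); structural tests use a 16-county, 2-year configuration with 3 GCMs.
These sizes were chosen so the whole suite exercises every path at
meaningful precision while remaining quick to run routinely.

## Known limitations

* Delta-method intervals ignore fixed-effect and smoothing-stage
  uncertainty.
* Projection intervals exclude climate-ensemble spread by design (the
  per-GCM range is reported alongside).
* The BIC uses the pseudo-likelihood; it is a pragmatic specification
  ranking, not a posterior model probability.
* Grid-to-county aggregation is a centroid-mean hook; raster handling is
  out of scope, as are choropleth rendering and end-of-century horizons.
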