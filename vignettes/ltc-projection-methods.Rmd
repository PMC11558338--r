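---
title: "Methods: illness-death model projection of long-term care demand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: illness-death model projection of long-term care demand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcproj)
```

## The model

`ltcproj` treats need for long-term care (LTC) as an irreversible chronic
condition in a three-state illness-death model: *no need for care* →
*need for care* → *dead*, with death also possible directly from the
first state. Four age- and calendar-time-dependent quantities describe the
system: the prevalence $p(t,a)$ of the care-dependent state, the incidence
rate $i(t,a)$ of becoming care-dependent (per person-year), and the
mortality rates $m_0(t,a)$ and $m_1(t,a)$ of people without and with need
for care. Only the *all-cause* mortality $m = (1-p)\,m_0 + p\,m_1$ is
observable in routine statistics, so the model is parameterized by $m$
together with the mortality rate ratio $R = m_1/m_0$. The prevalence obeys

$$\left(\partial_t + \partial_a\right) p
  = (1-p)\left[\,i - m\,\frac{p\,(R-1)}{1 + p\,(R-1)}\right].$$

Remission (recovery from care-dependency) is assumed to be zero; it is
rarer than termination of care by death, and its omission makes any
incidence derived by inverting the equation a lower bound.

Key assumptions, each of which a user can relax only by supplying
different inputs:

* $R$ is constant over age, calendar time and sex (no German data exist to
  support anything richer); the package accepts any positive value and the
  standard scenarios use 1.17 and 3.2, the bounds reported in the
  literature.
* Incidence and mortality surfaces are deterministic inputs; the package
  propagates no parameter uncertainty.
* The model covers ages 60–100. Ages below 60 contribute no LTC cases;
  published care rates below 60 are near zero.

## Integration along characteristics

Along a cohort's characteristic $a = a_0 + (t - t_0)$ the transport
equation becomes an ODE in the cohort's elapsed time, integrated by
classical fourth-order Runge–Kutta (`solve_cohort()`). The surface solver
(`project_prevalence_surface()`) sweeps all cohorts in lockstep: the 41
cohorts alive at the baseline year start from the baseline age profile,
and the cohorts reaching age 60 in later years enter at the lower age
boundary.

Numerical choices, with defaults and rationale:

* **Grid.** Integer (year, age) nodes, 2021–2050 × 60–100 by default
  (`age_time_grid()`). Rate surfaces are evaluated off-node by bilinear
  interpolation — the simplest rule that is exact for the tabulated nodes,
  keeps rates non-negative, and avoids the overshoot a higher-order
  interpolant could produce at the steep old-age end of a mortality
  surface.
* **Step size.** 10 RK4 substeps per one-year node interval (step
  0.1 y). Against the closed-form solution available for $R=1$ and
  constant incidence, this leaves a maximum error of order $10^{-12}$ over
  40 years; the test suite also verifies the expected fourth-order
  behaviour (error ratio ≈ 16 when the step is halved).
* **Clamping.** Prevalence is clamped to $[0,1]$ after every node step.
  Values escaping the unit interval by more than $10^{-6}$ raise an error
  instead of being silently clipped — an excursion that large indicates
  invalid inputs, not round-off. Inside RK stages the state is guarded
  into $[0,1]$ before the right-hand side is evaluated, because
  intermediate stage values may overshoot transiently.
* **Entry boundary.** Cohorts reaching age 60 after the baseline year are
  assigned the baseline profile's value at age 60 (constant entry
  prevalence), configurable via `entry_prevalence`. With no data on
  sub-60 incidence this is the least-structured choice, and at age-60
  prevalences of about 1–2 % the induced uncertainty is small relative to
  the old-age dynamics that dominate head counts.
* **Open age group.** Published baseline tables end at "90+"; by default
  the open-group value is replicated through age 100
  (`extend_open_group()`), with linear extrapolation (capped at 1) as an
  alternative. Replication is conservative; the difference matters little
  for counts because population numbers above 95 are small.

## The inverse problem

`derive_incidence()` rearranges the transport equation to estimate
incidence from a prevalence surface, all-cause mortality and $R$:

$$i = \frac{(\partial_t + \partial_a)\,p}{1-p}
      + m\,\frac{p\,(R-1)}{1 + p\,(R-1)}.$$

The directional derivative is estimated by the centred diagonal difference
$[p(t{+}1,a{+}1) - p(t{-}1,a{-}1)]/2$ at interior nodes and one-sided
differences along the grid edges; the two corner nodes with no diagonal
neighbour get derivative 0. Prevalence is clamped to $1 - 10^{-9}$ before
the division, and a surface containing exactly saturated nodes ($p = 1$)
is rejected. Negative derived rates — possible from differencing noise,
and expected in principle because zero remission makes the derived
incidence a lower bound — are floored at zero with a warning; the count of
floored nodes is attached as an attribute.

Accuracy has a structural floor worth understanding. The centred
difference carries an $O(h^2)$ truncation error at one-year node spacing,
and the node-sampled inverse problem is genuinely under-determined: a
two-node diagonal cannot pin down the within-cell shape of the rate, and
the prevalence surface is only $C^1$ along characteristics when rates are
bilinearly interpolated. In the round-trip exercises the tests perform,
the generating incidence is recovered at interior nodes to about $10^{-4}$
(absolute, per person-year), while re-projecting the *derived* incidence
reproduces the prevalence surface only to about $10^{-3}$ at the
edge-affected nodes — the one-sided edge estimates carry $O(h)$ errors
that the integration then accumulates. A residual-driven refinement was
evaluated during development and rejected: it polishes the re-projection
residual but only by pushing the recovered incidence *away* from the true
rates into the problem's null directions, which is the wrong trade for an
estimator whose point is the rates themselves.

## Scenario engine

`default_scenarios()` encodes the eight standard combinations: population
variant 1 or 2, $R \in \{3.2, 1.17\}$, and an annual incidence increase of
0 % or 2 %. Design decisions:

* The 2 % trend acts multiplicatively on the baseline age profile,
  $i(t,a) = i_0(a)\,(1.02)^{t-t_0}$, so the final projection year uses
  exponent 29 for a 2021 baseline (the first affected year is 2022). The
  exponent convention is configurable by shifting `t0`.
* Sexes are projected fully independently — separate baselines, incidence
  and mortality, no interaction.
* All-cause mortality is variant-specific (the population variants embody
  different life-expectancy assumptions), so a scenario's variant selects
  both its population counts and its mortality surface.
* All scenarios of a run share a single incidence input. Under a shared
  incidence, prevalence is monotonically non-increasing in $R$ (stronger
  excess mortality removes prevalent cases faster), and this ordering is
  asserted node-wise in the tests. Published projections that pair each
  $R$ with its own $R$-specific derived incidence set can show the
  opposite ordering of head counts; the engine accepts such paired inputs
  by simply running separate configurations.

Head counts are prevalence × projected population
(`counts_from_prevalence()`), and `make_report()` formats one row per
scenario: counts in millions rounded to one decimal, percent changes
computed on the *unrounded* counts and rounded half-up to integer percent
(`round_half_up()`, since base R's banker's rounding would disagree with
the conventions of published tables at exact halves). The care ratio —
recipients in formal care per professional caregiver — defaults to a 36 %
formal-care share and 1.6 million caregivers, both overridable.

## The synthetic-data generator

`gen_full_fixture()` produces a complete, internally consistent input
bundle shaped like the official German sources, so that every pipeline
stage (including file I/O and the CLI) can be exercised without any
download:

* **Baseline prevalence**: logistic in age per sex,
  $p(a) = p_{\max}\,\mathrm{logit}^{-1}(s\,(a - a_{50}))$, defaults
  $p_{\max} = 0.75/0.85$, midpoint 86/84, slope 0.16 (male/female) —
  about 1 % at age 60 rising towards a plateau near the open age group,
  women above men at high ages, matching the shape of published care-rate
  tables.
* **Mortality**: Gompertz with secular improvement,
  $m(t,a) = e^{b_0 + b_1 a - g\,(t-2021)}$, defaults $b_0 = -10.7/-11.3$,
  $b_1 = 0.1$, and improvement $g = 0.5\,\%$ (variant 1) or $1\,\%$
  (variant 2) per year — variant 2 is the higher-life-expectancy variant.
* **Incidence**: exponential in age, $i_0(a) = e^{c_0 + c_1 a}$, a few
  per mille at 60 rising to roughly 0.1–0.3 at the oldest ages.
* **Population**: cohort-consistent counts. The baseline column survives
  a cohort-size curve through the baseline mortality schedule; later
  years follow $N(t{+}1,a{+}1) = N(t,a)\,e^{-m(t,a)}$ exactly, with fresh
  entry cohorts at age 60. Cohort sizes carry a Gaussian baby-boom bulge
  (+30 % centred on cohorts reaching 60 around 2026) and a small long-run
  drift, so projected demand grows over the horizon as it does in the
  real population. Entry sizes (~0.6 million per sex and year) put the
  synthetic 60+ population near 33 million with about 6 million
  care-dependent people at baseline — an 18 % prevalence share of the 60+
  population, comparable to German magnitudes.

The only randomness is a small lognormal jitter (σ = 1 %) on baseline and
entry-cohort counts, driven entirely by the configured seed; identical
seeds give byte-identical bundles. The generator is mechanistic rather
than statistical by design: round-trip and ordering tests require inputs
that satisfy the same consistency relations real demographic tables
approximately do, or they would fail for reasons unrelated to the code
under test.

What the fixture does *not* emulate — and hence what passing tests do not
show: real FSO magnitudes and their irregular cohort structure (war
cohorts), migration in and out of the 60+ population, the 2017 care-grade
reclassification and other administrative breaks in the prevalence
series, and any calibration to published projected counts. Reproducing
published absolute numbers requires the real prevalence, mortality and
population tables; the package's correctness claims are about the solver,
the inversion and the engine's structural behaviour, which the synthetic
conditions test fully.

## Verification strategy and problem sizes

The test suite checks the solver against three independent oracles: the
closed form $p(\tau) = 1 - (1-p_0)e^{-i\tau}$ for $R = 1$ and constant
incidence (40-year horizon, tolerance $10^{-8}$); `deSolve`'s classical
RK4 on the same cohort ODE; and a vectorized forward-Euler integration of
the full surface. For the surface comparison the Euler oracle is run at
steps $h = 1/512$ and $1/1024$ years and Richardson-extrapolated
($2E_{h/2} - E_h$): a single first-order Euler pass at $h = 1/512$ has an
intrinsic truncation error of order $10^{-5}$ at these rate magnitudes,
larger than the quantity being measured, and the extrapolation removes
the oracle's leading error term while remaining independent of the RK4
code path. Unit tests run on reduced grids (15 years × 21 ages) to stay
fast; the acceptance-style tests use the full default grid
(30 years × 41 ages, both sexes, all eight scenarios).

## Known limitations

* No uncertainty quantification; scenarios bracket, they do not weight.
* The inverse estimator's accuracy floor (above) means derived incidence
  should be treated as having ~$10^{-4}$ absolute resolution at interior
  nodes, worse along grid edges.
* Irreversibility (zero remission) is built into the model structure.
* Sub-60 dynamics and regional (municipal) disaggregation are out of
  scope.
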