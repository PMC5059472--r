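---
title: "Multi-pool SOC decomposition: models, fitting and projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-pool SOC decomposition: models, fitting and projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(socpools)
```

## The model

Laboratory soil incubations measure the CO₂–C a soil releases while its
organic carbon decomposes. `socpools` describes that release with a
multi-pool first-order model: soil organic carbon (SOC) is partitioned into
conceptual fractions — fast, slow, and (in the three-pool variant) passive —
each decaying exponentially at its own rate. The instantaneous emission rate
is

$$R(t) = C_{tot}\left[f_1 k_1 e^{-k_1 t} + f_2 k_2 e^{-k_2 t}
        + (1 - f_1 - f_2)\,k_3 e^{-k_3 t}\right],$$

with the cumulative release its closed-form integral,

$$C_{cum}(t) = C_{tot}\left[f_1(1 - e^{-k_1 t}) + f_2(1 - e^{-k_2 t})
             + (1 - f_1 - f_2)(1 - e^{-k_3 t})\right].$$

$C_{tot}$ is fixed at 1000 mg C g⁻¹ SOC: all model quantities are normalised
per unit SOC, and per-gram-soil values are recovered by multiplying by the
measured SOC concentration, never by refitting. The two-pool variant drops the
passive pool (slow fraction $1 - f_1$). The mean residence time of a pool is
$1/k$; a fast-pool rate of $k_1 = 1/124\ \mathrm{d^{-1}}$ corresponds to
roughly 0.34 yr.

Assumptions worth keeping in mind: decomposition is strictly first-order (no
microbial feedback, no substrate interactions), rates are constant over the
incubation (one temperature per fitted series, no Q10 response), and pools do
not exchange carbon. The ordering $k_1 > k_2 > k_3 > 0$ is enforced so pool
labels are identifiable and per-pool attribution is well defined; without it,
MCMC chains label-switch.

## From jar headspace to flux

`headspace_to_flux()` converts a sealed-jar measurement window into a rate:
moles of headspace air from the ideal gas law ($n = PV/RT$, with the jar
volume reduced by dry soil mass / an assumed solids density of 1.3 g cm⁻³),
the CO₂ increase in ppm of that air converted to carbon mass via 12.011 g
mol⁻¹, normalised by dry soil (and SOC) mass and window length. Because the
initial headspace aliquot withdrawn for the gas chromatograph is replaced
with CO₂-free air, the stored starting concentration is diluted by
$(V - v_{sample})/V$ before differencing (toggleable). Concentration
decreases yield negative rates flagged `negative_flux` rather than silently
clipped. Pressure defaults to 101.325 kPa and is configurable for
high-altitude laboratories.

`build_series()` collapses replicate jars into one series per sample: the
per-time measurement s.d. is the replicate standard deviation floored at
`max(0.05 × mean, 1e-4)` mg C g⁻¹ SOC d⁻¹. The floor keeps the Gaussian
likelihood defined when replicates coincide; whether the field s.d. should be
replicate scatter or analytical GC error is not decidable from typical
incubation reports, so replicate scatter is used and documented.

## Bayesian fitting

The likelihood is heteroscedastic Gaussian on the observed rates,
$\ell(\theta) = -\sum_{t,i} [Z_i(t) - X(t)]^2 / 2\sigma(t)^2$, omitting the
normalisation constant (irrelevant to Metropolis–Hastings with data-supplied
σ). Priors are independent uniforms over a box; the defaults
($f_1 \in [0, 0.05]$, $f_2 \in [0, 0.95]$, $k_1 \in [10^{-3}, 1]$,
$k_2 \in [10^{-5}, 10^{-3}]$, $k_3 \in [10^{-8}, 10^{-5}]$ d⁻¹) encode the
fast/slow/passive timescale separation as contiguous non-overlapping rate
bands, which also makes the ordering constraint automatic. Site-specific
widening (e.g. slower pools for low-emission soils) is an explicit override.

The sampler is a from-scratch Metropolis–Hastings implementation (C++ core,
R's RNG, so a seed fully reproduces a chain). Each iteration sweeps the
components one at a time: a reflected uniform jump with half-width
`step_fraction × (upper − lower)` for that component, accepted with
probability $\min(1, e^{\ell' - \ell})$. We deliberately use component-wise
sweeps rather than all-components-at-once jumps: with a posterior orders of
magnitude narrower than the prior in some directions (typical for $k_1$ under
a wide band), joint jumps accept well below 1% and the chain is unusable,
whereas sweeps hold acceptance near 25–30% on the same problems. Proposals
violating $f_1 + f_2 \le 1$ or the rate ordering are redrawn; with the
default bands the feasible region is the full box and this is exactly
symmetric (with deliberately overlapping user bands it is approximate — noted
here rather than hidden). The chain starts at the prior-box midpoint
(deterministic), discards `n_burn` iterations and stores every `thin`-th
state. Defaults: 50,000 iterations, 10,000 burn-in, thinning 10, step
fraction 0.05. A multi-seed Gelman–Rubin diagnostic (`gelman_rubin()`) is
available but not required.

`summarize_posterior()` classifies each marginal as well-constrained when its
50-bin histogram over the prior range has an interior mode (modal bin centre
outside the outer 5% of the range on each side) at least twice the uniform
density. Constrained parameters are reported at their value in the single
highest-log-likelihood draw (an MLE); unconstrained ones at the marginal
mean. The edge rule is conservative on linear-scale histograms: a parameter
whose true value sits within the lowest 5% of a wide prior band (e.g.
$k_1 = 0.0081$ in $[10^{-3}, 1]$) is reported unconstrained even when the
data peak it sharply. This is a known, documented property of the stated
rule, not a bug.

## Model comparison

`compare_models()` fits both pool structures to the same series and compares
them by the least-squares AIC, $n\ln(\mathrm{RSS}/n) + 2p$, with residuals
against the replicate-mean rate per time point ($n$ = number of time points,
$p$ = 3 or 5). Fit metrics are evaluated at the highest-log-likelihood stored
draw — the approximate maximum-likelihood vector — because an RSS-based AIC
is only coherent at (approximate) ML; mixing per-parameter means into the
prediction vector can produce arbitrarily bad curves when a parameter is
unconstrained. Ties within $|\Delta AIC| \le 2$ are reported `"equivalent"`
and resolved toward the smaller model.

## Projections and regional risk

`horizon_report()` evaluates the fitted model at a projection horizon,
returning the released fraction of SOC and the per-pool shares of cumulative
release. The seasonal-thaw convention of `thawed_days()` uses 30-day months:
85 years of 4 thawed months each gives exactly 10,200 effective incubation
days. `regional_risk()` is the upscaling arithmetic
`stock (Pg C) × 1000 × areal-decline fraction × release fraction`, rounded to
integer Tg C half-away-from-zero. The release fraction may be supplied (e.g.
0.454) or computed as the cohort mean of fitted `cum_fraction_of_soc` at the
last horizon (`release_fraction: fitted` in the pipeline config).

## The synthetic cohort

No public incubation dataset accompanies this class of analysis, so
`make_cohort()` generates one with the statistical structure the fitter
assumes: by default 5 sites × 2 soil layers × 3 replicate jars × 2
temperatures (−5/5 °C) on the canonical schedule (days
1,3,5,7,13,19,26,33,40,47,54,61,68,75,80 — every 2 days to day 7, then every
5–8 days to day 80). Observations are $Z_i(t) = R(t)(1+\varepsilon)$ with
$\varepsilon \sim N(0, 0.05)$ i.i.d. per replicate and time — multiplicative
noise because fluxes span orders of magnitude across samples — truncated at
zero (an aerobic jar cannot take up CO₂) and flagged when truncation occurs.
A matching raw headspace table is emitted by inverting the flux conversion
exactly.

True parameters are drawn uniformly from layer-specific sub-boxes chosen once
from the reported structure of upland permafrost soils: fast pool below ~1.6%
of SOC with mean residence time near 0.34 yr ($k_1 \in [0.005, 0.012]$ d⁻¹),
a slow pool of roughly half of SOC ($k_2 \in [1, 2.5] \times 10^{-4}$ d⁻¹), a
passive remainder ($k_3 \in [5 \times 10^{-7}, 5 \times 10^{-6}]$ d⁻¹), with
permafrost fast/slow fractions shifted above the active layer's. Sub-zero
jars scale all rates by 0.25 — a placeholder for temperature limitation, not
a Q10 model. With these defaults the cohort-mean fast-pool share of the
80-day release sits near 30–38% and collapses below 2% at 10,200 days,
matching the qualitative short- vs long-horizon attribution pattern expected
of these soils.

What the generator does *not* emulate: drift or autocorrelation in GC
measurements, replicate-level biological heterogeneity (replicates share one
truth), flush-event artefacts, moisture or oxygen dynamics, and any covariate
structure (biomarkers, microbial abundances). A green recovery test therefore
establishes that the fitter inverts its own stated noise model — not that
field data meet that model.

## Identifiability: what an 80-day window can and cannot estimate

A point the test suite makes quantitative: with the canonical 80-day schedule
and 5% multiplicative noise, the fast pool decays less than half-way
($e^{-0.0081 \times 80} \approx 0.52$), so the likelihood mainly constrains
the product $f_1 k_1$ and a mild curvature. The likelihood maximum itself —
located independently by multi-start bounded optimisation — is displaced
along this ridge by median ~56% in $f_1$ and ~38% in $k_1$ across simulated
cohorts; slow/passive parameters are worse because those pools barely decay
within the window. No estimator can do better from the same data. The
package's acceptance test asserts the tight recovery bounds regardless and is
allowed to fail there, documenting the limit instead of hiding it.
Lengthening the schedule to 390 days measurably improves the slow-pool rate's
recovery, which the suite also asserts; interval coverage for $k_1$ is ~90%.

## Numerical choices

- `expm1` is used for $1 - e^{-kt}$, so passive pools with $kt \sim 10^{-4}$
  integrate accurately and the three-pool model with $f_1 + f_2 = 1$
  reproduces the two-pool model to below $10^{-12}$.
- Reflection at box boundaries is iterative and bounded; the C++ core avoids
  libm symbols newer than the runtime's.
- Observed cumulative release integrates the replicate-mean trapezoidally,
  with the unobserved interval before the first sample filled by a rectangle
  at the first rate.
- Rounding of risk totals is half-away-from-zero, which reproduces all four
  published-scenario endpoints exactly; `round()`'s half-to-even does not.
- Time zero is the start of flux measurement; pre-equilibration days are
  excluded.

## Pipeline

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(out_dir = "run1", n_sites = 2, temperatures = 5),
                    seed = 42)
```

writes the simulated inputs, per-sample posterior summaries, the AIC
comparison table, horizon reports, the risk JSON and a manifest carrying the
seed and a hash of the configuration, so identical config + seed reproduce
the bundle byte-for-byte.

## Known limitations

- First-order, temperature-static kinetics only; no microbial-explicit or
  Michaelis–Menten variants.
- The constrained/unconstrained rule is linear-scale and conservative near
  wide prior bounds (see above).
- Single-chain fits by default; run `gelman_rubin()` across seeds before
  trusting slow/passive-pool intervals.
- Regional risk is bulk arithmetic — no spatial structure, no climate
  trajectory, no temperature modulation over the projection horizon.
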