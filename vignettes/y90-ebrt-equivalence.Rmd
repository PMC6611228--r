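---
title: "Methods: Y-90 / EBRT radiobiological equivalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-90 / EBRT radiobiological equivalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirteq)
```

## The problem

Selective internal radiation therapy delivers Y-90 beta-particle dose
to liver tumours over several days as the source decays
(T<sub>phys</sub> = 64.1 h). Clinical dose prescriptions, however, lean
on radiosensitivity parameters measured under acute external-beam
exposure. The two regimes differ in a specific, modellable way:
sublethal damage created early in a protracted exposure is repaired
before later damage can interact with it, which suppresses the
quadratic ("two-track") term of the linear-quadratic survival model
while leaving the linear term to reflect the intrinsic per-track
effectiveness of the radiation. `sirteq` implements the chain of models
that quantifies this — dosimetry of the in vitro exposure, mixed-model
LQ fitting of clonogenic counts, the Lea–Catcheside protraction factor,
and BED/EQD conversion — so that a Y-90 absorbed dose can be expressed
as the equivalent fractionated EBRT dose for a cell line of known
radiosensitivity.

## Dosimetry of the monolayer exposure

Cells in the stack geometry receive dose at rate
$\dot D(t) = A_0 e^{-\lambda t} S(t)$, where $S(t)$ is the S-value of
the 15 µm cell monolayer (absorbed dose per unit activity,
cGy MBq⁻¹ d⁻¹). Medium evaporation over a 6 d exposure (up to a third
of the volume) thins the absorbing layer, so $S$ drifts upward;
`sirteq` follows the convention of interpolating linearly between a
start value $S_i$ and an end value $S_f$, giving the closed form

$$D(T) = \frac{A_0}{\lambda}\left[\frac{S_f-S_i}{\lambda T}
  \bigl(1-(1+\lambda T)e^{-\lambda T}\bigr)
  + S_i\bigl(1-e^{-\lambda T}\bigr)\right].$$

Setting $S_f = S_i$ recovers the unmodified constant-S MIRD cumulated
activity formula exactly. The packaged per-position S-values already
embed the measured non-uniformity of each source formulation (free
chloride versus chelated DOTATATE), which is why the two formulations
have different position profiles. End-of-exposure S-values are not
tabulated anywhere, so `dish_dose_table()` parameterises them as
`evaporation_factor` × S_initial, default 1.2 — a middle-of-the-road
reading of "up to a third of the medium lost", and configurable.

Numerical choices: all internal arithmetic is in hours, MBq and Gy
(S-values are converted at the boundary, 1 cGy d⁻¹ = 0.01/24 Gy h⁻¹);
the factor $(1-(1+x)e^{-x})/x$ is evaluated by its series
$x/2 - x^2/3 + x^3/8$ for $x < 10^{-6}$ to avoid cancellation at short
exposures; $T = 0$ returns zero dose rather than an error; the decay
constant is always derived from the half-life, never stored separately.

One property worth knowing: with the *endpoints* $S_i, S_f$ held fixed,
$D(T)$ is **not** globally monotone in $T$. Lengthening the exposure
stretches the S ramp, so the early high-activity part of the exposure
sees values closer to $S_i$; past a few half-lives this outweighs the
extra tail dose (e.g. 37.5 Gy at 400 h versus 36.8 Gy at 2000 h for
$A_0 = 20$ MBq, $S$ 47.3→56.8). Monotonicity holds for constant $S$.
Physically the evaporation ramp is tied to a fixed 6 d window, so this
regime is outside normal use, but the tests assert monotonicity only
where it is true.

## The survival model and its fit

Each well contributes a surviving fraction
$SF = (\text{colonies}/\text{plated})/PE$, with the plating efficiency
$PE$ estimated from the 0 Gy control wells *of the same biological
repeat* — so control SF averages 1 by construction. The model is

$$-\ln SF_{ij} = \alpha D_{ij} + \beta D_{ij}^2 + b_i + \varepsilon_{ij},
\qquad b_i \sim N(0, \sigma_b^2),\ \varepsilon_{ij} \sim N(0, \sigma_e^2),$$

with no fixed intercept (the population curve satisfies $SF(0)=1$
exactly) and one random intercept per biological repeat. Estimation is
restricted maximum likelihood with the variance ratio
$r = \sigma_b^2/\sigma_e^2$ profiled out: for given $r$ the GLS
estimates and the restricted criterion are closed-form, and $r$ is
located by bounded scalar search on a log scale. A flat or
boundary-preferring profile resolves to $\sigma_b = 0$, which makes the
fit deterministic and reproducible; the test suite verifies the whole
fit (coefficients, covariance, both variance components) against
`nlme::lme` on stochastic data. Design choices, and why:

- **β is not constrained non-negative.** Protracted exposures produce β
  estimates statistically indistinguishable from zero, and confidence
  intervals that cross zero are themselves informative. An explicit
  `alpha_only = TRUE` refit (quadratic column dropped, β ≡ 0) is the
  supported way to impose the simpler model.
- **Zero-colony wells are excluded** from the log-domain fit (no
  continuity correction) and reported in the fit object; a continuity
  correction would bias α upward at high doses where counts are small.
- **A single replicate set degrades to fixed-effects least squares**
  with a warning: one group cannot identify $\sigma_b$.
- **Intervals are normal-approximation** (±1.96 SE). With three
  biological repeats a t-based interval has no well-defined denominator
  degrees of freedom for the variance-component case; the simulation
  study below measures what the normal approximation actually delivers.

The α/β ratio carries a first-order delta-method standard error,
$SE^2 = \mathrm{var}(\alpha)/\beta^2 - 2\alpha\,\mathrm{cov}(\alpha,\beta)/\beta^3
+ \alpha^2 \mathrm{var}(\beta)/\beta^4$. Against a $10^5$-draw
bivariate-normal Monte Carlo propagation this agrees within 5% for
CV(β) up to about 12% at any correlation; beyond that the first-order
SE increasingly underestimates the exact ratio SD (the ratio
distribution picks up skewness of order CV²), reaching ≈14% shortfall
at CV(β) = 18%. Fits at the assay design used here produce CV(β) of
4–7%, comfortably inside the envelope. `alpha_beta_ratio()` refuses
alpha-only fits rather than returning an undefined ratio.

## Protraction and equivalence

For a mono-exponentially decaying dose rate the Lea–Catcheside factor
has the closed form implemented in `g_factor()`; writing
$f(s) = (1-e^{-sT})/s$, it is a difference quotient of $f$ between
$s = 2\lambda$ and $s = \lambda+\mu$ (repair rate
$\mu = \ln 2/T_{rep}$), scaled by $2\lambda^2/(1-e^{-\lambda T})^2$.
Two numerical points: the apparent singularity at $\mu = \lambda$ is
removable and handled by a second-order Taylor branch switched on at
$|\mu-\lambda| < 10^{-5}\cdot 2\lambda$ (continuity across the switch is
tested at $\mu = \lambda(1 \pm 10^{-6})$); and the closed form is
validated against double numerical quadrature of the defining integral
to $10^{-8}$ relative over a randomised $(T_{rep}, T)$ grid, since no
printed reference value exists for the finite-exposure factor at
arbitrary arguments. Limits: $G \to 1$ as $T \to 0$ (acute) or
$T_{rep} \to \infty$ (no repair), and $G \to G_\infty =
T_{rep}/(T_{rep}+T_{phys})$ as $T \to \infty$.

`solve_trep()` inverts $G_T$ for the repair half-time by bisection-safe
root finding on the bracket $[10^{-4}, 10^{4}]$ h ($G_T$ is strictly
increasing in $T_{rep}$, so the root is unique), to $10^{-10}$ on $G$.
The equivalence chain then assumes the intrinsic quadratic sensitivity
is shared between modalities and only suppressed by protraction
($\beta_{Y90} = G_6\,\beta_{EBRT}$), while the linear terms are related
by $RBE_{max} = \alpha_{Y90}/\alpha_{EBRT}$. Under those premises,

$$BED_{Y90} = D\left(RBE_{max} + \frac{G_\infty D}{(\alpha/\beta)_{EBRT}}\right),
\qquad EQD_d = \frac{BED_{Y90}}{1 + d/(\alpha/\beta)_{EBRT}}.$$

EQD values for doses above 32 Gy — the ceiling of the underlying
clonogenic measurements — are flagged `extrapolated` by `eqd_curve()`.
The published summary pairs the 10 Gy-fraction equivalents
{17.6, 19.3} Gy with the two cell lines in the opposite order from what
direct evaluation of the EQD formula gives; `equivalence_reference()`
follows the direct evaluation (DLD-1 19.3, HT-29 17.6), and order-free
comparisons (min/max over lines) are used where the assignment matters.

## What the simulator emulates — and what it does not

`simulate_clonogenic()` generates the data-generating process the
fitter assumes, no more: expected colonies
$N \cdot PE \cdot e^{-(\alpha D + \beta D^2 + b_i)}$, Poisson counts,
triplicate wells × three biological repeats, acute doses 0–10 Gy or a
protracted ladder built by `simulate_y90_experiment()` from the stack
dosimetry (3 activities × 4 positions ≈ 0.7–31 Gy). Defaults chosen
once from the stated experimental ranges: 4000 cells plated per well
(from 3000–5000), plating efficiency 0.6, $\sigma_b = 0.1$ on the
$-\ln SF$ scale (a ~10% between-repeat variation, typical of clonogenic
repeats; no value is stated). Expectations exceeding the number of
plated cells are clipped with a warning — that specification is
unphysical, not an edge case to silently accept.

Two deliberate simplifications. First, colony counts are Poisson with
no overdispersion beyond the replicate intercept; real assays can be
overdispersed (counting error, colony merging at high density), so
passing recovery tests here demonstrates correctness of the estimation
machinery, not robustness to misspecified noise. Second, because
plating efficiency is estimated from the same repeat's controls, the
normalisation cancels most of $b_i$ from the normalised response; the
replicate intercept in fitted data then mainly reflects shared
control-count noise. This mirrors how real assays are normalised, and
it means $\sigma_b$ recovered from simulated data will sit well below
the generating value — a property of the normalisation, not a bug. The
≥50-cell colony threshold is absorbed into plating efficiency; no
cell-cycle, bystander or oxygen effects; α is dose-rate-independent by
assumption.

## Problem sizes and verification

The test suite (≈13 s) checks, among others: the dose closed form
against adaptive quadrature (1000 randomised exposures, $10^{-8}$
relative); the G closed form against double quadrature (200 randomised
points, $10^{-8}$); recovery of α at the assay design over 200
simulated experiments (95% Wald coverage required to land in
[0.90, 0.98], mean bias under 3%); the delta-method SE against
$10^5$-draw Monte Carlo (within 5% in the envelope above); and the full
equivalence chain against the published modelling values (within 1%,
repair half-times at their printed two-decimal precision). End-to-end
repair-half-time recovery (simulate acute + protracted → fit both →
invert G) uses 25 paired experiments and requires the median recovered
$T_{rep}$ within 25% of truth — the β ratio of two noisy fits is the
least stable quantity in the chain, and that tolerance reflects it.

## Known limitations

- No repopulation term in BED and no LET-dependence of β; the
  equivalence premise $\beta_{Y90} = G\,\beta_{EBRT}$ is exactly the
  assumption a very short recovered $T_{rep}$ (minutes, as for HT-29)
  should make one question.
- The fitter assumes homoscedastic Gaussian noise on $-\ln SF$; counts
  at the highest doses are small enough that this is approximate, which
  is visible as Wald coverage sitting slightly below nominal.
- Fits are per cell line × modality; no hierarchical sharing across
  modalities.
- Table-level uncertainty propagation (CIs on $T_{rep}$, $G_\infty$,
  EQD) is not reproduced: the published interval method for those
  derived quantities is unstated, and point estimates are the
  comparison target.
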