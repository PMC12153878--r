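---
title: "Energy and nitrogen metabolism in a 2x2 crossover chamber trial: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy and nitrogen metabolism in a 2x2 crossover chamber trial: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruminbal)
```

## What the package computes, and for whom

A respiration-chamber feeding trial measures, for each cow-period, three
strands of data: gas-concentration traces from the chamber, daily intake
and milk records, and quantitative excreta collections. `ruminbal` turns
these into the standard whole-animal energy and nitrogen quantities —
substrate oxidation, heat production, energy balance, apparent
digestibility, N partition, use efficiencies — and runs the crossover
mixed-model inference on top. Because the raw animal data behind trials of
this kind are rarely deposited, the package ships a synthetic-trial
generator whose every latent quantity is stored, so the full pipeline can
be validated against known truth.

## Chamber model and its assumptions

The chamber is treated as a single well-mixed compartment:
$V\,dC/dt = Q\,C_{in} + E(t) - Q\,C_{out}$, with $E < 0$ for O₂
(consumption). The simulator solves this exactly on each sampling step
(emission held at its midpoint value), and the inversion integrates
$Q\,(C_{out}-C_{in})$ with the trapezoid rule on the native 6-min grid,
prorating partial boundary intervals, then divides by the recovery rate.
Consequences of the model:

- Only the time constant $V/Q$ depends on the chamber volume. The volume
  is not part of the study record, so it is configurable with a default of
  50 m³ (typical walk-in cattle chamber); at the stated 30 m³/h airflow
  the time constant is ~1.7 h, so a trace started at inlet conditions is
  within 5% of steady state after ~5 h and effectively at steady state
  inside the default 12-h settle-in.
- The recovery rate is applied to the concentration *excess*
  $C_{out}-C_{in}$, not to the absolute outlet fraction. A recovery rate
  is the measured fraction of a known gas release recovered by the system;
  scaling the absolute O₂ fraction (~0.21) by 0.997 would inject a
  spurious signal ~30× larger than the animal's own. Integration divides
  by the same factor, so simulate→integrate round-trips exactly.
- Gas volumes are assumed already reduced to one consistent reference
  (STP, dry). No temperature/pressure/Haldane correction is applied; an
  overall multiplicative correction can be folded into the recovery
  argument if a dataset needs one.
- Missing samples: gaps ≤ 30 min are bridged by the trapezoid (linear
  interpolation); longer gaps flag the day invalid rather than guessing.
  Negative integrated volumes are flagged, never silently zeroed.

## Calorimetry conventions

The stoichiometric layer is deliberately literal: CO₂_ferm = 1.7·CH₄;
mCO₂ = CO₂ − CO₂_ferm; mRQ = mCO₂/O₂; the Frayn oxidation forms use mCO₂
while the Brouwer heat production uses **total** CO₂. Mixed conventions
for the CO₂ term exist in the literature; this package implements the pair
exactly as used in the motivating trial and documents the asymmetry rather
than "fixing" it. Negative FOX (net lipogenesis) or COX values are
returned with a flag, not clamped: they are physiologically meaningful.

Urinary N inside FOX/COX/HP is the balance-stage value — the spot urine N
concentration (sampled at the end of the barn phase, day 14) multiplied by
the mean daily urine mass of the collection window (days 15–18) — held
constant across the 48-h gas window. This mirrors the source protocol,
where concentration and volume are measured on different days; the
generator makes the pairing exact by construction.

## The energy-balance factor

The source equation for energy balance prints
EB = MEI − HP − ECM·0.00314 MJ/kg. Taken literally the milk term of a
30-kg/d cow is ~0.09 MJ/d, and EB for the anchor marginal means comes out
at **+61 MJ/d** — for a cow in established lactation eating ~200 MJ/d and
producing ~141 MJ/d of heat, an impossibility, and the same table prints
EB ≈ −33 MJ/d. One kg of energy-corrected milk carries ~3.14 MJ, so the
printed value is read as a kJ/MJ unit slip. The default factor is 3.14
MJ/kg; the literal 0.00314 remains selectable, and both the balance
function and the pipeline report flag it prominently when in force. The
acceptance suite demonstrates both arms.

Relatedly, the urine table of the source prints an "N, wt%" around 12–14%,
which cannot be percent of fresh urine mass given the printed excretion
(~93–116 g/d) over ~11 kg/d of urine (~0.8%). The pipeline never uses the
wt% form: urine N is carried as g/kg fresh urine throughout.

## The synthetic trial: a stated world

The generator realizes exactly the design and effect structure the
inference stage assumes: 12 cows entering in 3 blocks of 4, each block
split 2/2 across the two treatment sequences, 21-d periods, 14-d washout,
and for every response
$y = \text{baseline} + \text{treatment} + \text{period} + \text{block} +
\text{cow} + \varepsilon$.

Defaults are anchored to the chamber-period marginal means of the
motivating hemp-vs-soy trial: DMI 17.4 kg/d (control) with +0.2 kg/d
treatment effect, milk 29.7 kg/d, fat 4.23%, protein 3.59%, lactose
4.99%, body weight 639 kg (−20 kg under treatment, matching the mBW
127→124 contrast), CH₄ 522 L/d (−11 under treatment), digestibility
truths 0.675/0.689/0.671 (DM/OM/energy) and CP degradability 0.652 for
control versus 0.657/0.674/0.651/0.641 under treatment, urine 11.1 vs
11.5 kg/d. O₂ and CO₂ baselines (6838 and 7110 L/d) are back-solved from
the anchor heat production (HP/mBW ≈ 1138 kJ/kg^0.75) and mRQ ≈ 0.91 via
the Brouwer identity, so the simulated gas exchange lands on the printed
scale by construction.

Choices the study does not pin down, fixed once here:

- **N retention**: not printed. The anchor N ledger implies ≈ +20 g/d
  under treatment and ≈ −7 g/d for control (intake − feces − milk −
  urine); those values are the defaults. Negative retention is ordinary
  body-protein mobilization and is consistent with the negative energy
  balances. The generated ledger closes exactly: urinary N is derived as
  the residual, and an infeasible ledger (negative implied urinary N) is
  rejected with a diagnostic rather than silently truncated.
- **Digestibility variation**: one shared cow-period deviation
  (SD 0.01) shifts all four digestibility truths together. Digestive
  efficiency co-varies across fractions in real animals, and the shared
  draw guarantees the fecal DM/OM/ash mass balance stays feasible, which
  independent draws do not.
- **Within-day emission**: an optional 24-h sinusoid (default relative
  amplitude 0.1) stands in for feeding-driven diurnal variation. It is a
  stand-in, not a claim about the study, which reports no within-day
  profile.
- **Sensor noise**: i.i.d. Gaussian on the outlet fraction, default SD
  1% of each gas's steady-state excess. Negative concentrations after
  noise are clipped at zero and counted.
- **Emission variance**: cow-level SDs (200/200/40 L/d for O₂/CO₂/CH₄)
  plus cow-period residuals (120/120/25 L/d) chosen so the simulated
  group-mean standard errors land near the anchor tables' printed SEs.
- **Fecal DM fraction** is fixed at 0.15 (typical cattle feces); only the
  product fresh mass × DM fraction enters any downstream quantity.

Reproducibility: one master seed; each cow draws from its own derived
sub-stream, so regenerating any subset of cows is bit-identical.

**What a green synthetic test establishes** — that the algebra, unit
conventions, integration, exclusion rules and model machinery are
mutually consistent and recover a known truth. **What it does not** — that
real chambers are well-mixed, that real sensor error is Gaussian and
independent, that digestibilities or emissions are Gaussian across cows,
or that the anchor trial's biology is re-derivable: the published
marginal means are used only as scale anchors, never as targets.

## Statistical stage: decisions

- **Model**: `y ~ group + period + sequence + block + (1|cow)` by REML
  (lme4), sum-to-zero contrasts, plus `time` and `group:time` for
  repeated measures.
- **Fallback ladder**, applied in order and recorded in `path`:
  Shapiro–Wilk on residuals at α = 0.05 → log2 transform → re-check →
  gamma GLMM (log link; the link is a choice, the source states only the
  family) → singular mixed fit → fixed-effects `lm`. Heteroscedasticity
  (Breusch–Pagan type) is flagged but never triggers a fallback.
  Residuals from numerically exact fits (SD < 1e−8) are treated as
  normal; otherwise machine noise would send perfect models down the
  ladder.
- **Degrees of freedom**: Satterthwaite, computed from the closed-form
  REML likelihood in (τ², σ²) with finite-difference gradient and
  Hessian; multi-df terms use the eigen-decomposition combination rule.
  lmerTest is the reference construction but is not a dependency; the
  package's own REML pieces are tested against lme4's log-likelihood,
  fixed effects and vcov.
- **EMMs**: fixed-effect design averaged over the full factorial
  reference grid with equal weights (the classical estimated marginal
  mean); back-transformed with delta-method SEs when the ladder
  transformed the response.
- **Tukey–Kramer**: studentized-range adjustment with each contrast's own
  SE and df; for two groups it reduces to the unadjusted t-test, which
  the tests assert against a numeric integration oracle.
- **Robust z screen**: z = (x − median)/(1.4826·MAD), threshold 3.5 (not
  part of the study record; configurable), flags only — removal is an
  explicit analyst action. When the raw MAD is zero the scores are
  degenerate: points at the median score NaN and are never flagged,
  points off the median are infinitely many MADs out and are flagged,
  with a warning either way. This keeps both desiderata — a constant
  vector yields no flags, while a vector constant but for one gross
  outlier still flags it.
- **Intake exclusion**: cow-periods with mean DMI/mBW < 0.1 kg/kg^0.75
  are excluded and logged; the boundary itself is retained (strict
  "less than").
- **TOST sample size**: log-scale within-subject SD
  $\sigma_w = \sqrt{\log(1+CV^2)}$, SE of the treatment contrast
  $\sigma_w\sqrt{2/n}$ on $n-2$ df. Power is exact — the joint rejection
  region integrated over the χ² distribution of the variance estimate —
  rather than the common two-noncentral-t lower bound, so the returned
  (even, balanced-sequence) n is the true smallest design, which the
  acceptance suite verifies by Monte Carlo at n and n−2.
- **t-test sample size**: smallest per-group n whose noncentral-t power
  meets the target; d = 1.0 at α = 0.05, power 0.8 gives the classical
  17/group.

## Known limitations

- Single-compartment chamber only: no calibration drift, cross-talk
  between chambers, or open-circuit/SF₆ methods.
- The gamma-GLMM arm uses lme4's Laplace approximation; with 12 cows its
  Wald chi-square p-values are asymptotic and rougher than the LMM arm's
  Satterthwaite t/F tests. In the simulated Gaussian world it is entered
  rarely (the acceptance suite bounds spurious entry below 5%).
- ME density is an input (as in feed tables), not estimated from feed
  chemistry; no NEL estimation, body-condition modelling, behaviour
  processing or milk fatty-acid profiles.
- The anchor-based internal-consistency check recombines published
  marginal means through nonlinear formulas; means do not commute through
  nonlinearities, so it is a sign-and-order-of-magnitude check by design,
  never a numeric reproduction.
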