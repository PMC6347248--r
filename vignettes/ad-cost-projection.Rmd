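---
title: "Methods: a four-state Markov cohort model of Alzheimer's disease costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-state Markov cohort model of Alzheimer's disease costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcohort)
```

## The disease core

Progression is a time-homogeneous Markov chain over Mild, Moderate, Severe
and an absorbing Death state, stepped yearly. The transient block $Q$ and
the death column jointly form a row-stochastic law: each row of
`cbind(q, death)` sums to one, checked to $10^{-12}$ at construction. The
chain is deliberately age-independent — stage alone determines one-year
death risk (5.5%, 21.5%, 48.0%) and movement. That is a known limitation
of this model class (old patients progress like young ones), and it has a
structural consequence for the demography the model can be coupled to,
discussed below.

Everything the package derives from the chain flows through the
fundamental matrix $N = (I - Q)^{-1}$, computed by a dense LU solve
(`solve()`), which the test suite cross-checks against a truncated Neumann
series $\sum_k Q^k$ and against Monte-Carlo walkers. Two functionals
matter:

* **Sojourns from Mild entry** — row 1 of $N$: expected total years spent
  in each stage by an incident patient (all incidence enters at Mild).
  "Total" includes returns after improvement; it is *not* the consecutive
  stay $1/(1-p_{stay})$. We adopted the total-years-from-Mild metric
  because it is the only functional under which all five published
  scenario matrices deliver their advertised +1 or +2 years (the suite
  verifies each rounds exactly to its integer).
* **Limit stage mix** — row 1 of $N$ normalised to sum one: the long-run
  stage composition of a patient population sustained by a steady stream
  of Mild entrants. It seeds the initial split of prevalent patients and
  prices the steady-state per-patient cost. We chose this closed form over
  an empirical end-of-simulation snapshot: it is deterministic, cheap, and
  coincides with the snapshot in the stationary limit.

### Scenario laws and the prolongation solver

The five drug scenarios are stored verbatim as published rows. Entries the
scenario text does not name stay at baseline; the residual that closes a
row to one goes to the death probability for the Moderate scenarios
(giving 0.210 and 0.186) and to the stay probability for the Severe
scenario (0.772) — the only allocations consistent with unit row sums.

`solve_prolongation()` reconstructs such laws from a sojourn target: scale
both worsening probabilities out of the stage by a common $\alpha \in
(0,1]$, hold that stage's death fixed, absorb the freed mass into stay,
and bisect (`uniroot`, converged to $10^{-9}$ years) on the Mild-entry
sojourn. This policy reproduces all three published mild+1 numbers (81.4%,
12.1%, 1.0%). Severe has no onward worsening, so there the solver lowers
the death probability with stay absorbing the mass — mirroring how the
published severe scenario was built. Two honest non-results are frozen
into tests rather than hidden: the $\Delta = 2$ solution for Mild is
0.8418, which does not round to the published 84.4% (that matrix yields
+2.086 years; its exact derivation is unstated, so we carry it verbatim),
and with Moderate death held fixed the attainable prolongation tops out
near +1.4 years, which is presumably why the published moderate+2 row also
lowers the death entry.

The three MCI scenarios keep the baseline law and act purely as incidence
multipliers (0.9, 0.7, 0.5) from the drug year — MCI persons live inside
the healthy pool, matching its mortality, and are not a simulated
compartment.

## Prevalence, calibration, and the yearly step

Prevalence follows $r(x) = 0.0142\,e^{0.1161 x}$. The curve's argument is
interpreted as $x = \text{age} - 60$ with onset age 60 and cap 0.95, all
configurable. With $x$ equal to calendar age the expression exceeds one at
age 60, so some offset is required; 60 gives 1.42% at 60 and about 26% at
85, in line with AD epidemiology. The cap is needed because the raw
exponential passes one near age 97.

The engine's yearly update, in fixed order: (1) patient deaths by stage;
(2) stage transitions among survivors, using the survival-conditioned law
$q_{ij}/(1-d_i)$ so that the transition rows and death probabilities
jointly form the one-year law; (3) deaths of the healthy; (4) ageing by
one year (closed top age — survivors of age 100 remain there; the entry
age refills from the projection, all healthy); (5) new Mild entrants drawn
from the healthy pool. Counts are continuous expected values, not sampled
agents.

Calibration runs this update once under the reference law. Each year and
age, entrants are set so post-update patients equal
$r(a) \times$ projected population — floored at zero when surviving
patients already exceed the target and truncated by the available healthy
pool, with both events logged as diagnostics. Healthy mortality is derived
in the same pass as (cohort deaths − model patient deaths)/healthy,
clipped to $[0,1]$ with clipping logged. Both tables are frozen; every
scenario consumes them verbatim (the runner enforces the single shared
calibration). Calibration and simulation share one code path and the same
arithmetic, so re-simulating the reference is bit-identical to the
calibration run — a fixed-point property the suite asserts with
`identical()`. The post-update matching convention is one consistent
reading of "incidence found on the first run"; matching pre-transition
would shift rates slightly but not the scenario comparisons, which all
share whatever convention calibration used.

## The synthetic demography

The generator emulates an EU-28-like baseline projection: 5.08×10⁸
persons in 2015, a Gaussian large-cohort bump centred at modal age 45
(sd 12) whose height is solved by `uniroot` so that 19% of the base-year
population is 65+, closed cohorts (zero net migration — the healthy
mortality derivation is then well posed), entry cohorts shrinking 0.2% per
year, and Gompertz–Makeham healthy mortality
$\mu(a) = 2\times10^{-4} + 7.7\times10^{-5} e^{0.075 a}$,
$q(a) = 1 - e^{-\mu(a)}$. The population ages and slowly declines over the
horizon. The generator is fully deterministic given its configuration;
the only optional randomness is a seeded lognormal perturbation of the
mortality curve (off by default).

One design point deserves emphasis. Because patient mortality is
age-independent (limit-mix weighted, about 13.6% per year), a demography
whose very-old-age total mortality is far above that value is *internally
inconsistent* with the disease model wherever prevalence is high: at
capped ages the patient stock would outlive its own prevalence target
(entrant floors bind) and implied healthy mortality would go negative.
The preset therefore (a) keeps the healthy law moderate at the top ages
(about 12–13% at 100, lighter than real centenarian mortality) and (b) by
default generates cohort deaths *jointly* with the disease process
(`disease_consistent = TRUE`): healthy persons die under the
Gompertz–Makeham law, prevalent patients die under the chain, and cohort
deaths are the sum. The projection is then exactly the demography the
model itself would produce, calibration runs with zero clamping events,
and the reference round-trip reproduces the prevalence curve to machine
precision. `disease_consistent = FALSE` gives a plain one-law projection
for demographic tests.

What the generator does **not** emulate: migration flows, realistic
extreme-old-age mortality, country heterogeneity, cohort-specific
mortality improvement, and the (unnamed) vintage of any official
projection. Consequently the package's absolute euro totals are not
comparable to published absolute tables — scenario *ratios and signs* are
the meaningful outputs on synthetic demography, and the tests assert
exactly those (nested MCI savings, Severe-stage savings under Mild
prolongation, overall cost increases by 2080). Passing tests demonstrate
the mechanics and the in-chain quantities, not a forecast for Europe.

## Costs

Stage costs are carried as monthly euros per patient in three classes and
annualised ×12 (23,112 / 40,118.40 / 55,401.60 per stage-year). The
monthly reading is a design decision: it reproduces the published
per-patient annual averages (≈ €28–33k) to within 1%, whereas yearly or
weekly readings are off by an order of magnitude. Prices are constant —
no discounting or inflation. Comparison reports store full-precision
deltas and percentages; only formatting and CSV writers round (billions
to one decimal, percentages to two).

## Stochastic oracles

Two independent stochastic implementations guard the deterministic code.
`mc_stage_walk()` simulates individual patients through the chain
(vectorised over walkers) and agrees with the fundamental matrix within
three standard errors at 10⁶ walkers. `micro_oracle()` replays the full
yearly update on a small projection with every death, transition and
onset sampled (binomial/multinomial) in the same order and with the same
probabilities as the engine. Every sampling step is linear in the state,
so the deterministic engine propagates the oracle's exact expectation;
the suite compares the engine with the mean of 20 oracle replicates
within three standard errors plus a small allowance (half a person per
age cell) for the integerised initial state.

## Numerical choices and degenerate inputs

* Bisection tolerances: $10^{-9}$ years on sojourn targets; machine-level
  `uniroot` tolerances internally.
* Row-sum validation at $10^{-12}$; fundamental-matrix residual
  $N(I-Q)=I$ checked at $10^{-9}$.
* Zero-count cohorts get mortality 0 (reported via an attribute); cohort
  mortality clipped to $[0,1]$; negative generated counts are an error.
* Unreachable prolongations are rejected with the attainable maximum
  rather than returning the closest law.
* The Eurostat reader strips observation flags, folds `Y_GE100`-style
  open groups into the closed top age, errors on malformed cells with
  their row and column, and names any missing required year or age.
* Problem sizes in the shipped tests: the full preset (101 ages × 66
  years) for calibration and pattern checks, a 20-age × 10-year,
  10⁵-person projection for oracle comparisons, 10⁶ walkers for the
  sojourn oracle — together a few seconds of runtime.

## Known limitations

Stage transitions and stage mortality do not depend on age or sex; MCI is
not an explicit compartment; costs are constant-price and EU-aggregate;
incidence calibration assumes the prevalence curve applies unchanged over
the whole horizon; and the synthetic demography, while internally
consistent, is a stand-in — feed `read_eurostat_tsv()` with a real
extract for applied work, and expect calibration diagnostics (entrant
floors, mortality clipping) to report where that demography conflicts
with the age-independent chain.
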