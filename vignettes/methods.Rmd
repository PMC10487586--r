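---
title: "Methods: a Markov cohort model of pharmacist adherence support in HIV care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of pharmacist adherence support in HIV care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmcea)
```

## The model

HIV progression is represented as a four-state Markov cohort model over
the WHO clinical stages: **A** (asymptomatic, CD4 > 500 cells/mm³),
**B** (symptomatic, CD4 200–500), **C** (AIDS-defining, CD4 < 200) and
**D** (death). Death is absorbing; every transition matrix row is
checked to be a probability vector, and the D row must be exactly
(0, 0, 0, 1). The cohort advances in 2-month cycles — the follow-up
interval of the adherence trial the inputs come from — for a one-year
horizon of six cycles. Two strategies are compared from a
healthcare-payer perspective: usual care, and usual care plus
pharmacist-led education and counselling, costed at 290 USD per alive
participant per cycle (one session every two months, derived from
Pakistani pharmacist salaries). Neither costs nor effects are
discounted in the base case; the engine supports per-cycle discounting
for scenario work.

Per-cycle accounting values occupancy at cycle start (t = 0, …, 5) with
no half-cycle correction: the source analysis does not state its
convention, and cycle-start valuation is the simplest choice whose
feasibility envelope contains the published totals; the calibration
step absorbs the residual freedom this leaves.

### The effectiveness unit

Over one year the published arm totals are 4.05 and 2.93 "QALYs". A
calendar QALY cannot exceed the best stage utility, 0.83, in a single
year — so those totals are only reachable as an *unscaled per-cycle
utility sum*, whose six-cycle maximum is 6 × 0.83 = 4.98. The package
therefore defaults to `qaly_convention = "per_cycle_sum"` and calls the
unit "QALY-units"; the textbook-correct calendar weighting (each cycle's
utility × 2/12) is available as `"calendar_weighted"`. This is a
testable distinction, not a matter of taste: the feasibility test
asserts 2.93 ≤ 4.98 under the default and 2.93 > 0.83 under the
alternative.

### Inputs

| Input | Base | Plausible range | Distribution (PSA) |
|---|---|---|---|
| Utility, stage A | 0.83 | 0.67–0.99 | beta |
| Utility, stage B | 0.34 | 0.27–0.40 | beta |
| Utility, stage C | 0.03 | 0.024–0.036 | beta |
| Cost/cycle, stage A | 22 USD | ±20% | gamma |
| Cost/cycle, stage B | 104 USD | ±20% | gamma |
| Cost/cycle, stage C | 134 USD | ±20% | gamma |
| Intervention cost/cycle | 290 USD | 232–348 | gamma |

All currency is 2023 USD internally; PKR output uses the flat rate
270 PKR/USD. (The source's own PKR figures are not flat-rate
consistent — e.g. 1383 USD × 270 = 373,410 PKR against a printed
372,406 — so USD is canonical and PKR is derived output only.)

The per-cycle background death probability is not published for
Pakistan; it enters as a configurable override, default 0.005 per
2-month cycle from every alive state, a deliberately small assumption
consistent with treated-cohort mortality on ART. The override rescales
each alive row's alive-state entries to sum to 0.995, preserving their
proportions.

## Calibration

The transition matrices the original trial implied were never printed;
only the arm-level totals were. `calibrate_arm()` therefore solves an
inverse problem: find a valid transition matrix (and initial stage
split) whose model outputs hit the targets. Alive rows and the initial
split are parameterised by softmax transforms of unconstrained logits,
so every candidate is row-stochastic by construction and any
off-the-shelf optimiser applies; the objective is the equal-weighted sum
of squared *relative* errors on (QALY-units, cost), balancing scales
that differ by three orders of magnitude. Each arm is optimised from 10
seeded random starts (BFGS, then a Nelder–Mead polish; cap 2000
iterations per start), declaring convergence when both relative errors
are within 1% of target.

Two honesty points. First, the problem is under-determined: many
matrices reproduce two scalar targets. The package claims — and the
tests assert — *output-space* agreement only, never that the calibrated
matrix equals the trial's. Second, feasibility is checked before
optimisation and infeasible targets raise an error rather than being
clamped: the intervention target (4.05, 1979 USD) is feasible because
4.05 ≤ 4.98 and the stage-cost residual 1979 − 6 × 290 = 239 USD lies in
[0, 6 × 134]. The trial's qualitative finding that more than half of
intervention participants improved stage can be imposed as an optional
constraint via a pinned initial split; it is off by default because its
exact operationalisation in the trial is unclear.

Calibrated this way, the model's downstream results line up closely
with the published analysis wherever comparison is possible: the
deterministic ICER is 1383.9 USD/QALY-unit, the tornado is led by the
intervention cost and the stage-A utility, and the threshold-crossing
solves land near the published 341.9 USD and 0.71 (the analysis scripts
print the exact values computed at run time).

## Sensitivity analyses

**One-way:** each parameter moves to its low and high bound with all
else at base; entries are ordered by descending ICER spread (ties
alphabetical). Utilities and the intervention cost use ±20% of base
(0.83 × 1.2 ≈ 0.996 is still a valid utility, but values are clipped at
1 for safety); stage costs use their published plausible ranges, which
are also ±20%. Endpoints where the comparison degenerates into
dominance are recorded as labels, not numbers. The willingness-to-pay
crossing value of a parameter is solved by bisection — the ICER is cheap
and piecewise-smooth, so robustness beats derivative methods — to 1e-6
on the parameter, then re-evaluated; the solve is accepted only if the
re-evaluated ICER is within 0.5 USD/QALY-unit of the threshold.

**Probabilistic:** 1000 iterations; every utility is drawn from a beta
and every cost from a gamma distribution, independently (no correlation
structure is published). The published analysis gives no shape
parameters, so both families are moment-matched from (base, range) with
the plausible range read as a 95% interval, sd = (high − low)/3.92 —
the standard convention, isolated in `fit_beta()` / `fit_gamma()` so it
can be swapped. The stage-C utility (0.03, range 0.024–0.036) fits a
valid beta; draws are clipped to [0, 1] defensively. Transition
probabilities stay at their calibrated point values by default, since
the published analysis does not state whether they were sampled; an
optional mode redraws each alive row from a Dirichlet(counts + 1)
posterior fed by the synthetic trial's transition counts. All
randomness flows from one integer seed, and the same seed reproduces a
PSA bit for bit.

Because the calibrated matrices are not the (unavailable) trial
matrices, the published PSA percentages (68% of iterations below the
threshold; 52%/68%/90% acceptability at 1383/1658/2898 USD) are not
reproducible point-for-point. The suite instead checks the properties
that must hold: degenerate ranges collapse to the deterministic result;
the acceptability curve is monotone when every sampled incremental
effect is positive; and the curve evaluated *at* the deterministic ICER
lies in [0.35, 0.65] — the near-median crossing that symmetric input
uncertainty implies, and the package's analogue of the published 52% at
1383 USD/QALY.

## The synthetic trial generator

`simulate_trajectories()` emulates the structure of the source RCT —
two arms of 33 participants, stage observed every two months, loss to
follow-up — with per-subject categorical draws from the arm's matrix and
an initial-split draw. Defaults observe six cycles (the real trial
observed a single 8-week transition, which cannot identify a six-cycle
process; the longer window is an artifact choice for estimator checks)
and censor 5% per cycle independently of state, a non-informative
stand-in for the trial's ~34% overall attrition; a state-dependent
dropout hook would be the first extension for realism. Death is
recorded as an observed absorbing transition. `estimate_matrix()` is
the row-wise maximum-likelihood counter, forcing the death row
absorbing and flagging (never imputing) alive rows with zero exposure.

What the generator deliberately does *not* emulate: interval censoring
within the two-month window, continuous CD4 dynamics, state-dependent
dropout, and measurement error in staging. Passing tests therefore show
the estimator and pipeline are correct for the stated generative
process, not that the model fits any real cohort.

## Numerical choices

- Row-stochasticity and occupancy conservation tolerance: 1e-9;
  engine-versus-oracle agreement: 1e-10.
- Bisection tolerance 1e-6 on the parameter; crossing acceptance band
  0.5 USD/QALY-unit on the re-evaluated ICER.
- Moment-fit means verified to 1e-6 (by numerical integration for the
  beta in tests).
- Tie-break in the tornado: alphabetical; undefined spreads sort last.
- Degenerate ICER sign patterns map to labels (`equal_effect`,
  dominance) — division by zero cannot occur.

Problem sizes in the shipped tests and scripts — 100 random models for
the oracle check, 10,000–100,000 synthetic subjects for consistency
checks, 1000 PSA iterations — were chosen as the smallest sizes at
which the Monte-Carlo bounds involved are sharp.

## Known limitations

Transition matrices are time-homogeneous; the horizon is one year by
design (the source avoided extrapolating a 2-month trial further);
calibration recovers *a* consistent matrix, not *the* matrix, so any
quantity that depends on dynamics beyond the calibrated targets (e.g.
the exact PSA percentages) inherits that non-identifiability; and the
cost model charges the intervention per alive participant per cycle,
which is the reading consistent with the published totals but not the
only conceivable one.
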