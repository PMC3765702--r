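---
title: "Model and methods: anticoagulation cost-utility microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: anticoagulation cost-utility microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`afcua` is an individual-sampling Markov model of anticoagulation in
newly diagnosed atrial fibrillation. Each virtual patient is followed in
daily cycles from treatment start to death or five years (1,825 days),
under one of three arms: standard warfarin dosing (`sdw`),
pharmacogenetic-guided warfarin dosing (`gtw`), and dabigatran 150 mg
twice daily (`dab150`).

The daily loop is:

1. **INR state** (warfarin arms). The day's INR category — below (<2),
   within (2–3) or above (>3) the therapeutic range — is drawn i.i.d.
   from the arm- and year-specific occupancy probabilities. Under `sdw`,
   TTR is 64% with 54% of out-of-range time below range. Under `gtw`,
   the year-1 TTR is uplifted by 7.3% *relatively* (0.64 × 1.073 =
   0.687); from year 2 both warfarin arms use the `sdw` proportions
   (everyone is assumed at a stable maintenance dose after one year).
2. **At most one major event.** A major-bleed Bernoulli test runs first;
   a major-thromboembolism test runs only if no bleed occurred. Daily
   probabilities derive from annual in-range risks (bleeding 1.4%, TE
   2.4%) by `p_daily = 1 − (1 − p_annual)^(1/365)`, with relative risks
   composed on the hazard scale: `p = 1 − exp(−rr · λ)`. This keeps
   probabilities valid for any `rr ≥ 0` and makes `rr = 1` an exact
   identity.
3. **Resolution.** Bleeds split into intracranial (ICH) vs extracranial
   (all gastrointestinal); ICH outcomes are no deficit 8% / mild 16% /
   severe 34% / death-in-first-month 42%; GI bleeds are fatal with
   probability 2%. Thromboembolisms split across stroke / MI / PE / DVT;
   stroke kills 8.3% in month 1 and 5.6% in each of months 2–3, and
   survivors draw a sequela; MI, PE, DVT are fatal with probabilities 7%,
   12%, 6%. Fatal events draw a uniformly distributed death day inside
   their stated window; the event cost is still charged and utility
   accrues until death.
4. **Treatment status.** ICH stops anticoagulation permanently; a GI
   bleed stops it for 30 days. Off treatment, the drug-related bleed
   hazard is zero and the TE hazard equals the warfarin below-range
   (subtherapeutic) hazard — no separate untreated-AF risk is published.
5. **Accrual.** Daily drug cost; INR-monitoring cost as monthly cost / 30
   (SD-W $8.06, GT-W $5.00 in year 1; $4.03 thereafter; none for
   dabigatran); day-0 one-time items (genotyping $615 for `gtw`, a $27.90
   LMWH bridging course for warfarin arms); one-time event costs on event
   days; post-event monthly costs for mild ($1,855) or severe ($6,259)
   sequelae. Utility is the minimum across active states. Both channels
   are discounted by `(1 + 0.03)^(−day/365)`; the daily QALY increment is
   `utility/365 × discount`.

### Dabigatran hazards

The trial-derived dabigatran relative risks (bleeding 0.93; stroke 0.66,
MI 1.38, PE 1.61, DVT 1.0) reference the warfarin arm's whole INR
experience, i.e. the time-weighted average hazard. We implement this as a
*counterfactual INR state*: the dabigatran arm draws a daily state from
the `sdw` occupancy using the same shared uniform, and multiplies that
state's hazard by its relative risks. The time average equals
`rr × weighted-average hazard` exactly, and — unlike multiplying the
average directly — setting all dabigatran RRs to 1 reproduces the `sdw`
arm's event days stream-for-stream, which is the package's central
common-random-numbers identity test.

### Utility durations

The source gives utility scores per health state but no durations. We
apply: the event-state utility for 30 days from the day after the event
(MI 0.84, PE 0.76, DVT 0.84, extracranial bleed 0.80, no-deficit events
0.95); mild/severe stroke/ICH sequela utilities (0.75 / 0.39 stroke,
0.75 / 0.51 ICH) from the event onward, permanently, together with the
monthly post-event cost starting 30 days after the event. An individual
with several active states carries the minimum utility and the cost of
the worst sequela. Fatal cases keep their severe-state utility until the
death day.

## Randomness and the common-random-numbers design

All randomness comes from a counter-based generator: each uniform is a
64-bit hash (splitmix64 chain) of (master seed, replicate, individual,
purpose, day, index), mapped to (0, 1) with 53 bits. Consequences:

* regeneration is bit-identical regardless of execution order;
* each of the 1,000 replicate populations is shared by all three arms;
* event-occurrence uniforms (INR state, bleed test, TE test) and
  resolution uniforms (subtype, outcome, death day) are shared across
  arms, so between-arm deltas isolate the intervention. This is what
  makes the one-way scenarios' very small QALY differences (order 0.01)
  resolvable at feasible cohort sizes.

We deliberately share resolution uniforms across arms (rather than
keying them by arm): keying would decouple the arms after their first
event even under identical parameters, destroying the unit-RR identity
above, while sharing is well-defined under different subtype splits
(inverse transform with different cutpoints) and strictly reduces
variance.

INR states are i.i.d. across days — the source specifies only time
fractions, not autocorrelation; real INR series are autocorrelated, so
within-patient event clustering is understated. Documented limitation.

## Parameters

Every model input lives in one registry (`default_parameter_set()`),
serialized losslessly to JSON (`inst/extdata/params_table1.json`). The
probabilistic-sensitivity layer (`psa_registry()`) interprets each
published sensitivity range as a central 95% interval and fits
two-parameter families under an exact mean constraint: beta for
probabilities and utilities (concentration optimized by least squares on
the 2.5%/97.5% quantiles), gamma for costs (shape optimized, scale =
mean/shape), log-normal for relative risks (`sigma` from the closed-form
symmetric-CI rule, `mu = log(mean) − sigma²/2`). Event-type splits,
outcome trees and globals are never sampled. Draws are independent
across parameters; no correlation structure is published.

Three printed-table inconsistencies are resolved by defaults, each with a
flag restoring the literal reading:

* **Relative-risk labels** (`literal_rr_labels`): the table prints
  bleeding RR 4.7 for *below*-range and TE RR 3.5 for *above*-range
  INR. Clinically, INR > 3 causes bleeding and INR < 2 causes
  thromboembolism, so the default assigns bleeding 4.7 to above-range
  and TE 3.5 to below-range (0.9 to above).
* **ICH utilities** (`literal_ich_utilities`): printed as no deficit
  0.51 / severe 0.95, inverted relative to the stroke block; the default
  uses no deficit 0.95 / mild 0.75 / severe 0.51.
* **TTR uplift** (`additive_ttr_uplift`): "7.3%" is applied relatively
  (0.64 × 1.073) because the published threshold statement equates a 20%
  uplift with TTR 76.8% = 64% × 1.2; the flag switches to +7.3 points.

Other normalizations: the dabigatran bleed split (12.6% + 90.4% = 103%)
is renormalized to sum to one; stroke outcomes (sum 111.3%) keep the
printed total death probability of 19.5% and renormalize survivor
sequelae over (40.2, 42.5, 9.1); the DVT relative risk for dabigatran,
absent from the source, is 1; all intracranial bleeds are modelled as ICH
(the subdural unit cost is carried but has no published probability
mass).

## The deterministic oracle

`cohort_expectation_oracle()` validates simulated means without
sampling. Expected event counts are exact to all orders of recurrence: a
compact occupancy chain over treatment status (on / off-temporary
countdown / off-permanent / dying countdown / dead) propagated daily.
Expected cost and QALY use a first-event expansion — exact through the
first major event and its full expected continuation (cessation, utility
windows, sequela costs, death-day distributions) — neglecting only the
cost/utility perturbation of later events, whose probability at the
90-day validation horizon is ~1e-4 per person, an order of magnitude
below the 3-standard-error Monte-Carlo comparison band at n = 200,000.
The acceptance suite compares simulation and oracle per arm at exactly
that scale.

## Economic analysis

Ratios are computed at full precision and reported rounded half away
from zero to the nearest dollar, matching the published integers. The
dominance frontier sorts by cost, removes strictly dominated strategies
(ties share the frontier), iteratively removes extended-dominated ones
(ICUR vs the previous frontier strategy exceeding the next one's), and
reports pairwise ICURs along the frontier — this reproduces the
published convention in which a scenario's dabigatran ICUR is quoted
against whichever strategy is its frontier comparator. Acceptability
curves are pairwise against `sdw` (matching the published figure):
at each willingness-to-pay λ, the fraction of PSA draws with
`λ·ΔQALY − Δcost ≥ 0`, plus the fraction of strictly dominant draws.
The TTR threshold search bisects the `gtw` year-1 TTR on [baseline,
0.95] with shared streams across steps (tolerance 0.005 by default) and
signals "no threshold" if the ICUR never crosses.

## What the synthetic world does and does not establish

The generator reproduces the stated virtual population — age
Normal(64, 8) truncated to [18, 100], no prior stroke, event dynamics
exactly as parameterized — at the stated scales (10,000 × 1,000
replicates for the base case, 5,000 × 1,000 for PSA; the test suite runs
reduced scales and says so). Green tests establish internal correctness:
closed-form agreement in the zero-risk world, oracle agreement at 90
days, event-tree frequencies, CRN identities, dominance arithmetic
against the published tables. They do not establish that the published
*absolute* per-patient costs, QALYs or event rates are reproduced; those
depend on mechanics the source does not specify (background mortality,
utility durations, second-event handling, PSA shapes), and the published
rates are not mutually consistent (below).

## Known limitations

* **The dabigatran TE direction cannot be reproduced from the published
  inputs.** The split-weighted dabigatran multiplier is
  0.525×0.66 + 0.125×1.38 + 0.30×1.61 + 0.05×1 = **1.052**: applied to
  the warfarin reference hazard, total dabigatran thromboembolism is
  ~5% *higher* than warfarin's, while the published table prints it 14%
  lower (1.813 vs 2.12 per 100 person-years) — and that printed warfarin
  rate is itself below the in-range annual risk of 2.4%, impossible
  under non-negative relative risks. Consequently two qualitative
  acceptance checks fail by design: dabigatran does not show fewer TE
  events than SD-W, and its acceptability at $50,000/QALY is ~0.80
  rather than ≈1 (the QALY gain is capped near 0.06 instead of the
  published 0.2529). The bleeding side of the same construction does
  match the published ratio (2.872/3.21 ≈ 0.93).
* No background (non-event) mortality: the five-year horizon limits the
  distortion, but absolute QALY totals are higher than they would be
  with life-table mortality. A config hook exists
  (`flags$background_mortality`), off by default, and no life table is
  bundled.
* No minor events, no adherence modelling, no INR autocorrelation or
  dose-titration dynamics (all outside the published model), single
  payer perspective, no covariate effects (the input table has no
  age-dependent rates; age is recorded but inert).
* Off-treatment thromboembolic risk is approximated by the warfarin
  below-range hazard; months are 30-day blocks, years 365-day blocks.
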