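---
title: "A three-state Markov model for first-line therapy in advanced renal-cell carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov model for first-line therapy in advanced renal-cell carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalcea)
```

## The decision problem

First-line avelumab plus axitinib prolongs progression-free survival (PFS)
relative to sunitinib in advanced renal-cell carcinoma, at a much higher
acquisition cost.  `renalcea` implements a cohort-level decision model that
asks whether the health gained is worth the money spent from a US payer
perspective: both strategies are simulated over ten years, their discounted
costs and quality-adjusted life-years (QALYs) accumulated, and the
comparison summarised as an incremental cost-effectiveness ratio (ICER)
judged against a willingness-to-pay (WTP) threshold of $150,000 per QALY.

## Model structure

The model is a three-state Markov cohort: progression-free survival (PFS),
progressed disease (PD), and death, with death absorbing and reachable
from both alive states.  The entire cohort starts in PFS at age 61.  One
cycle is 6 weeks (42 days); the horizon is 87 cycles, the smallest whole
number of cycles covering ten years.

State-transition probabilities derive from Weibull survival models
$S(t) = \exp(-\lambda t^{\gamma})$ fitted to the trial's PFS and OS
Kaplan-Meier curves.  The per-cycle discrete hazard entering cycle $t$ is

$$p(t) = 1 - \exp\left[\lambda (t-1)^{\gamma} - \lambda t^{\gamma}\right],$$

which satisfies $\prod_{k \le T}\bigl(1 - p(k)\bigr) = S(T)$ exactly; the
test suite verifies this identity to $10^{-10}$ over the full horizon.

Two curves must be combined into one transition matrix, and the
combination is a genuine modelling choice:

* **Death from either alive state** uses the OS hazard, floored by
  life-table background mortality: $p_{\text{death}}(t) =
  \max\{p_{OS}(t),\, q_{\text{bg}}(t)\}$.  The maximum (rather than a sum)
  avoids double counting, because the fitted OS curve already contains
  all-cause deaths observed during trial follow-up.  Age advances
  continuously as $61 + 42t/365.25$ and is floored for table lookup.
* **PFS to PD** is the PFS exit hazard net of death,
  $\max\{0,\, p_{PFS}(t) - p_{\text{death}}(t)\}$.  This keeps the
  simulated death column exactly equal to the fitted OS curve whenever
  the OS hazard dominates background mortality (a property the tests
  check to $10^{-10}$ with background mortality disabled).

Half-cycle correction is applied as a trapezoid: the effective occupancy
of cycle $k$ is the mean of the state vector at its start and end, used
identically for costs and health outcomes.  Costs and QALYs are then
discounted at 3% per year via $(1.03)^{-42k/365.25}$.

### The time-unit question

The Weibull scale/shape pairs are taken from the published input table.
Evaluating them with $t$ in 6-week cycles reproduces the published
absolute QALY totals closely, and that is the unit this package adopts.
It is worth recording that the same parameters evaluated with $t$ in
months reproduce the trial's median PFS (about 13.8 and 8.4 months) and
the source's statement that over 90% of the cohort is dead at year ten —
but then under-predict the published QALY totals by roughly 20%.  The
published quantities are not all consistent with a single time unit; the
cycle-unit reading was chosen because the QALY and cost totals, not the
medians, are the quantities this package sets out to reproduce.  The
choice is isolated in `weibull_params()`/`transition_prob()`, so a
month-based analysis only requires rescaling the parameters.

## Costing

All prices are 2019 US dollars, used exactly as published.

* **First-line therapy** accrues only while in PFS (treat-to-progression,
  as in the trial): avelumab 10 mg/kg IV every 2 weeks at an assumed 70 kg
  (700 mg, i.e. 70 priced 10-mg units, three administrations per cycle,
  each with a $302.27 administration fee), axitinib 5 mg orally twice
  daily, and in the comparator arm sunitinib 50 mg/day for the first 4 of
  every 6 weeks.  Drug cost is linear in milligrams; no vial wastage.
* **Adverse events**: grade 3+ events with incidence of at least 5% in
  either arm are charged as one incidence-weighted lump sum at cycle 1.
  The published costs are per event without timing information, so a
  one-off charge at entry is the simplest defensible reading; anaemia,
  priced per month, is charged for one month.  The sensitivity ranges
  cover the uncertainty this introduces.
* **Progressed disease**: patients receive subsequent therapy
  (cabozantinib after the combination; cabozantinib, sunitinib or
  nivolumab after sunitinib) or supportive care at $1,256 per cycle,
  treated here as a per-cycle figure (the source states no period; the
  $1,022-1,489 sensitivity range covers it).  Subsequent therapy persists
  for the whole of PD occupancy — no second progression is modelled.

### The subsequent-therapy reading

The published shares (30.4%; 10.8%/8.9%/41.4%) are described as the most
common subsequent treatments, alongside uptake figures of 20.8% and 39.2%
of each arm receiving any subsequent therapy.  Read literally — shares
within the treated subset — the progressed-state cost is small and the
reproduced arm totals fall 19% and 43% short of the published ones.
Applied instead as branch probabilities of the progressed state (the
natural encoding in a cohort-model package, with the residual on
supportive care), the totals land within 6% and 12%.  Because model
validation against the published totals so clearly favours it, the second
reading is the default in `rcc_base_config()`; the uptake figures are
retained in the configuration and `apply_subsequent_uptake()` switches to
the literal reading in one call.  Note the two published statements cannot
both be literal: a 41.4% share of the whole arm would exceed the 39.2% of
the arm said to receive any subsequent therapy.

## Sensitivity analysis

`model_parameters()` enumerates the sampled quantities following the
input table's distribution column: prices and costs are gamma, utilities
and adverse-event probabilities beta; Weibull survival parameters are
*not* sampled (the table assigns them no distribution), which is a known
limitation — structural survival uncertainty is not propagated.

* Ranges: published low/high where available, otherwise ±20% of base.
* Gamma moments: mean at base, SD $=(\text{high}-\text{low})/(2\times1.96)$,
  reading ranges as approximate 95% intervals.
* Beta moments: mean at base, SD $=0.2\times$ base (no utility ranges are
  published); if the moments are infeasible the SD is shrunk with a
  warning.
* The PD utility (0.66 in both arms — the same health state) is one
  shared parameter.  Sampling it independently per arm would manufacture
  spurious incremental-QALY variance from a quantity that is identical by
  construction.
* PFS utilities differ by arm (0.82 vs 0.73, reflecting treatment
  experience) and are sampled per arm.
* Sampled utilities may cross (a drawn PD utility can exceed a drawn PFS
  utility); no ordering constraint is imposed on draws.

The one-way analysis re-runs the full two-arm model at each parameter's
range ends and sorts by ICER spread; the health-state utilities dominate
the tornado, consistent with the source's qualitative finding.  The PSA
derives one substream seed per draw from the master seed, so results are
bitwise reproducible and enlarging `n` never reshuffles earlier draws.
Ties at zero net monetary benefit count against the comparator.

## Synthetic data

Nothing is downloaded.  Two generators stand in for external inputs:

* `simulate_km()` draws Weibull event times by inverse-CDF sampling with
  uniform censoring whose upper bound is calibrated by bisection to the
  requested expected censor fraction, then applies the product-limit
  estimator.  It emulates the *shape* of trial Kaplan-Meier data — random
  censoring, step estimates — but not administrative censoring patterns,
  informative dropout, or digitisation error from published figures, so
  parameter-recovery results (median relative error under 10% for
  $\lambda$ and 5% for $\gamma$ at $n = 2000$ over 20 seeds) bound only
  statistical, not structural, error.
* `fixture_life_table()` is a deliberately synthetic Gompertz-style
  schedule, $q(a) = \min\{1, 0.0005\,e^{0.09(a-30)}\}$ for ages 40-110
  with the last age absorbing.  It yields $q(61) \approx 0.008$, a
  plausible all-cause figure for a 61-year-old, and matters little here:
  the OS hazards exceed it from the first cycle in both arms.  A real
  national table can be supplied as a two-column CSV.

## Numerical choices

* Curve fitting is ordinary least squares on the complementary-log-log
  linearisation $\log(-\log S) = \log\lambda + \gamma\log t$ —
  deterministic, exact on noiseless input (identity to $10^{-6}$), with
  points at $S \in \{0, 1\}$ dropped (their transform is undefined).
  Maximum-likelihood fitting on the individual data is used only as an
  independent cross-check in the tests.
* Candidate-family selection uses $R^2$ on the survival scale, computed
  on the same point set for all four families (Weibull, log-logistic,
  log-normal, logistic) so the statistic is comparable; a family whose
  linearisation yields inadmissible parameters scores $-\infty$.
* Degenerate inputs: zero-QALY differences produce dominance labels, not
  division errors; degenerate sensitivity ranges return the base value
  exactly; an all-zero price configuration runs and labels the comparator
  dominant.

## Problem sizes

The bundled analyses run at the sizes used throughout the documentation
and checks: an 87-cycle horizon per arm, 1,000 Monte-Carlo draws per PSA
seed (averaged over three seeds for the headline probability), 20
replicate cohorts of 2,000 subjects for parameter recovery, and 5,000
subjects for the product-limit convergence check.

## Known limitations

* The published results table is not fully internally consistent with the
  published inputs.  With the defaults, the combination arm's QALYs and
  cost and the base-case ICER reproduce within 3-7%, the sunitinib arm's
  QALYs within 5%, but its cost remains about 12% below the published
  figure, and the incremental cost and QALY are correspondingly off
  (about +10% and +18%).  The published price-reduction ICERs ($86,929
  and $137,605) imply a discounted PFS duration in the combination arm of
  roughly 15 discounted cycles, which no reading of the inputs examined
  here produces together with the published QALY totals (the cycle-unit
  trace gives about 18, the month-unit trace about 13.5); this package
  reports its own computed scenario ICERs rather than tuning toward the
  published ones.
* Survival-parameter uncertainty is excluded from the PSA (see above).
* No microsimulation, tunnel states, time-varying utilities, dose
  reductions, vial wastage, or societal costs; the PD-L1-positive
  subgroup requires the trial's hazard ratio, which is not bundled and
  must be supplied by the user.
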