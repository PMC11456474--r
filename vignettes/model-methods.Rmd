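---
title: "Model structure, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceavte)
```

## What the model represents

The package implements a monthly-cycle Markov cohort model of primary
anticoagulant thromboprophylaxis in patients with active cancer. The
population at risk is cancer patients without prior venous thromboembolism
(VTE); the strategies compared are prophylactic-dose direct oral
anticoagulants (DOACs, pooled or apixaban/rivaroxaban individually),
low-molecular-weight heparins (LMWHs), and no prophylaxis. The cohort starts
free of complications. Each month a patient can:

* suffer a **first or recurrent VTE**, split into pulmonary embolism (PE) or
  deep-vein thrombosis (DVT) by the strategy's PE share; any VTE triggers a
  3-month course of therapeutic-dose anticoagulation before returning to
  prophylactic dosing;
* suffer a **bleeding event**, split into clinically relevant non-major
  bleeding (CRNMB) versus major bleeding (MB), and MB further into
  gastrointestinal bleeding (GIB) versus intracranial haemorrhage (ICH).
  CRNMB and GIB are *transient*: they levy a one-time cost (and, for MB, a
  one-time utility loss) but do not change state. ICH is a state; on entry
  65.7% of patients permanently discontinue anticoagulation, so ICH carries
  on-treatment and off-treatment branches with their own bleeding and death
  rates;
* **progress**: treated DVT can develop post-thrombotic syndrome (PTS) on a
  year-indexed schedule, treated PE can develop chronic thromboembolic
  pulmonary hypertension (CTEPH) in its first two years; CTEPH mortality is
  highest in the first 90 days and declines over four periods;
* **die**, either from the background cancer mortality (in the
  complication-free state) or at the state-specific death rate of the
  condition occupied.

## Tunnel states and the transition matrix

All time-varying hazards depend on *time since entering a condition*, not on
calendar time, so they are encoded as monthly tunnel states: DVT, PE and
CTEPH each expand into months 1–24 plus a "late" tail in which every
schedule has become constant (PTS incidence at its year-3+ value, CTEPH
incidence zero, CTEPH mortality at its year-3 value). Months 1–3 of the
DVT/PE tunnels are flagged as the therapeutic-dose window. With death, the
two ICH branches, PTS and the complication-free state this gives 80 states.

Because tunnels absorb all time-dependence, the one-cycle matrix is
identical at every cycle; `matrix_at(cycle)` exists for interface
compatibility. Within a cycle the competing events are *mutually exclusive
branch masses* in the style of a decision-tree chance node, not independent
hazards: monthly probabilities of VTE, bleeding and death are laid side by
side and an error is raised if they exceed 1 — the builder never silently
renormalises. Row sums are asserted to 1e-12 in the test suite across all
strategies.

Annual or period probabilities `p` over `m` months convert to monthly
probabilities as `1 − (1−p)^(1/m)` (constant-rate assumption). The CTEPH
mortality periods (days 1–90, days 91–365, year 2, year 3+) convert with
period lengths 3, 9, 12 and 12 months and map to tunnel months 1–3, 4–12,
13–24 and the late tail.

## Parameters

Every input is a named `parameter` with a point estimate, 95% bounds, an SD,
a distribution family and the period it describes; the packaged base set
(`base_case_parameters()`, shipped as `inst/extdata/parameters.yaml`) is the
complete input table of the base analysis. Strategy-specific values live in
override blocks with a fallback chain (subgroup drugs and price variants
inherit from their pooled strategy, everything else from the shared table),
so the resolved per-strategy table can be exported with `as.data.frame()`
and audited row by row.

Key tunables, with defaults and rationale:

* **Cycle length** 1 month, **horizon** 36/60/120 cycles (3/5/10 years):
  monthly cycles resolve the 3-month therapeutic window and the 90-day CTEPH
  mortality period.
* **Discount rate** 5%/year on both costs and QALYs, applied as
  `(1+r)^(−t/12)` per cycle; the national pharmacoeconomic guideline value.
* **Willingness to pay** $37,125.240/QALY (three times per-capita GDP),
  stored as a parameter, never hard-coded.
* **`self_pay_ratio`** (default 1.0) multiplies all drug costs
  (prophylactic and therapeutic). It represents the patient's self-payment
  share under Chinese Medicare. The default deliberately models *full* list
  price: the actual reimbursement share is plan- and region-specific and no
  single published value exists, so any reimbursement scenario must set it
  explicitly in the config. Because drug cost is by far the largest cost
  component of the active strategies, conclusions at the willingness-to-pay
  threshold are highly sensitive to this single input — at full list price
  LMWHs are strictly dominated and DOAC prophylaxis sits above the
  threshold, while reimbursement ratios around one third place DOACs below
  it. The one-way sensitivity analysis exposes it like any other parameter.
* **Utilities** are per-year-alive state weights (complication-free cancer
  0.650, DVT 0.610, PE 0.620, ICH 0.330, PTS 0.500, CTEPH 0.630, death 0),
  accrued as `u/12` per occupied cycle. The input table also carries
  "permanent disutility" rows for the same conditions; subtracting them from
  the baseline does *not* reproduce the explicit state utilities
  (0.650 − 0.190 = 0.460 ≠ 0.610 for DVT), so both cannot be applied at
  once. The engine uses the explicit state utilities; the permanent
  disutility rows are retained as sensitivity handles only. One-time
  decrements are charged on event *flows*: 0.270 per major bleed and 0.013
  per CRNMB.
* **Costs** (2023 USD, converted at ¥1 = $0.144): one-cycle prophylactic
  drug prices, 3-month therapeutic prices (spread evenly over the three
  window cycles), one-time event costs (DVT 693, PE 1,121, ICH 4,378.347,
  GIB 1,876.013, CRNMB 8.250) charged on the transition flow into the event,
  and annual management costs for post-ICH care, PTS and CTEPH divided by 12
  per occupied cycle. Prophylaxis is lifelong, so every living on-treatment
  state outside the therapeutic window accrues the prophylactic price;
  off-treatment ICH accrues no drug cost.

## Design choices where the structure was genuinely open

* **Mortality composition** (`mortality_mode`): state-specific death rates
  (e.g. 0.402/year in PE) come from cohort studies of cancer patients in
  that condition, so by default they are treated as that state's *total*
  mortality rather than added on top of the background cancer rate.
  `"additive"` combines the two hazards for exploration. Note the corollary
  that low-mortality chronic states (PTS at 0.033/year) then carry less
  mortality than the complication-free state; this is what the source
  estimates imply and is surfaced here rather than patched.
* **Recurrent VTE** re-enters the acute PE/DVT tunnels using the same PE
  share as first VTE (no separate recurrent split exists), restarting the
  therapeutic window and its costs. Recurrence out of the ICH states also
  re-enters those tunnels — clinically, a new thrombotic event restarts
  anticoagulation even in patients who had discontinued after ICH.
* **Off-treatment ICH** patients carry no-prophylaxis (placebo) bleeding and
  VTE composition, since they are effectively unprotected.
* **No-prophylaxis therapeutic pricing**: patients without prophylaxis who
  develop VTE still receive 3 months of therapeutic anticoagulation; it is
  priced at the pooled-DOAC treatment cost (first-line therapy in current
  guidelines). This is an explicit override in the config, not a hidden
  constant.
* **No half-cycle correction** by default (payoffs accrue on
  start-of-cycle occupancy, matching common cohort-software defaults); a
  `half_cycle` flag enables the standard correction, which moves 5-year
  totals by well under 2%.
* **PSA distributions**: beta by method of moments for probabilities,
  proportions, utilities and disutilities; log-normal for costs with the
  printed value as the *median* and the printed SD as the log-scale
  standard deviation — the only reading that reproduces the asymmetric 95%
  bounds of the cost rows via `median·exp(±1.96σ)`. Draws are independent
  (no correlation structure is published); sampled branch masses that would
  exceed 1 at a chance node are renormalised and the draw counted. Ties in
  net monetary benefit go to the cheaper strategy so acceptability curves
  are deterministic.
* **Indexing**: cycles and tunnel months are 0-based internally in the trace
  (row 1 is the starting occupancy) and reported 1-based in state names
  (`dvt_m1` is the first month after the event).

## The synthetic trial generator

`generate_trial_arms()` emulates the evidence base behind the
no-prophylaxis event rates: per study a logit-normal random effect with
variance τ² shifts the baseline rate, control events are binomial at the
shifted rate and treated events binomial at the shifted rate times a
relative risk (clamped at 1 and counted). Defaults in the test-suite
recovery checks use a 0.194 baseline (the pooled no-prophylaxis first-VTE
rate), relative risks near the implied DOAC effect (~0.54), 6–12 studies of
500–10,000 patients per arm and τ² of 0–0.05 — moderate heterogeneity of
the kind seen across prophylaxis trials. What it does *not* emulate:
multi-arm trials sharing a control group, differential follow-up,
time-to-event censoring, or publication bias; passing the recovery tests
therefore shows the pooling arithmetic is right, not that real-world
evidence synthesis is unbiased. At strong heterogeneity (τ² ≈ 0.3) the
DerSimonian–Laird estimator acquires a small downward bias because the
logit-scale weights correlate with the random effects; the unbiasedness
check is run at τ² = 0.05 where this vanishes into Monte Carlo error.

## Numerical conventions

Bisection in `threshold_search()` stops when the comparison's ICER is
within $0.01 of the willingness to pay or the bracket is narrower than
1e-6, and refuses brackets without a sign change. Row-stochasticity is
asserted (1e-12), never repaired. Mass conservation in the trace is checked
to 1e-10 over 120 cycles. Reported tables round to 3 decimals; all internal
arithmetic is full precision. Every stochastic entry point (`run_psa()`,
`generate_trial_arms()`, `perturb_parameters()`) requires an explicit seed
and is bit-reproducible under it. Test problem sizes — 10,000 PSA draws at
the 5-year horizon, 500 replicates for the τ²-recovery check, 120-cycle
property sweeps — were chosen as the smallest sizes at which the Monte
Carlo error bands in those tests are meaningful.

## Known limitations

* The model has no age structure and no cancer-type stratification; the
  background mortality is a single annual rate.
* Event probabilities extracted from trials with ≤1.5 years of follow-up
  are extrapolated to 5–10 years under the constant-rate assumption.
* Anticoagulant discontinuation is modelled only after ICH; adherence,
  dose adjustment and drug–drug interactions are out of scope.
* The evidence-synthesis module pools single proportions and applies
  relative risks; it is a verification path, not a full network
  meta-analysis (no consistency equations or ranking probabilities).
* Reproduction of externally published totals for this comparison hinges on
  the unpublished drug-reimbursement share discussed above; the package
  reports full-list-price results by default and treats reimbursement as an
  explicit scenario input.
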