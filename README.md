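# ceavte

A Markov cohort cost-effectiveness model for **primary thromboprophylaxis of
cancer-associated venous thromboembolism (VTE)** from a Chinese payer
perspective, comparing direct oral anticoagulants (DOACs: apixaban,
rivaroxaban), low-molecular-weight heparins (LMWHs) and no prophylaxis.

It is written for health economists and clinical pharmacists who want a
transparent, fully scripted and testable re-implementation of this class of
decision model: every input is a named, validated parameter in a plain YAML
file; every stage — evidence pooling, transition-matrix construction, cohort
propagation, incremental analysis, deterministic and probabilistic
sensitivity analysis — is an exported, unit-tested function.

## The model

Patients with active cancer start free of complications and move monthly
between health states

```
no complication → {DVT, PE} → {PTS, CTEPH} → death
               → ICH (on / off anticoagulation)
```

with transient bleeding tolls (clinically relevant non-major bleeding and
gastrointestinal major bleeding) that cost money and quality of life without
changing state. Time-dependence — the 3-month therapeutic anticoagulation
window after any VTE, the year-indexed incidence of post-thrombotic syndrome
(PTS) and chronic thromboembolic pulmonary hypertension (CTEPH), and the
period-indexed CTEPH case fatality — is encoded in monthly *tunnel states*,
so the one-cycle transition matrix `P` is row-stochastic and cycle-invariant.

Per strategy *s* the cohort trace is `x_{t+1} = x_t P_s`, and discounted
totals accrue as

```
Cost_s  = Σ_t (1+r)^(-t/12) [ x_t c  +  x_t E τ ]
QALY_s  = Σ_t (1+r)^(-t/12) [ x_t u/12  −  x_t E δ ]
```

with `c` per-cycle state costs (drug, chronic-state management), `u` annual
state utilities, `E` the per-cycle event-probability matrix, `τ` one-time
event costs and `δ` one-time disutilities (major bleeding, CRNMB), and
`r = 0.05` the annual discount rate. Strategies are compared by incremental
cost-effectiveness ratios (ICER = ΔCost/ΔQALY), dominance and extended
dominance along the efficiency frontier, and net monetary benefit
(NMB = QALY·λ − Cost) at the willingness-to-pay threshold
λ = $37,125.240/QALY (3× per-capita GDP).

Annual (or period) probabilities are converted to monthly ones by
`1 − (1−p)^(1/m)`. No-prophylaxis event rates can be regenerated from
trial-arm counts by DerSimonian–Laird random-effects pooling on the logit
scale (`pool_proportions()`), and comparative rates derived with relative
risks (`apply_rr()`).

## Worked example

```r
library(ceavte)
fit <- cea_markov(strategies = c("placebo", "doac", "lmwh"), horizon_months = 60)
print(fit)
#> Markov cohort cost-effectiveness model: 3 strategies, 60 monthly cycles, 5% discount
#>  strategy      cost  qaly
#>   placebo  1403.118 1.763
#>      doac  6600.240 1.834
#>      lmwh 13055.121 1.830
summary(fit)
#> Cost-effectiveness summary (60 cycles, WTP $37125.240/QALY)
#>  strategy      cost  qaly dominated ext_dominated icer_frontier icer_vs_placebo
#>   placebo  1403.118 1.763     FALSE         FALSE            NA              NA
#>      doac  6600.240 1.834     FALSE         FALSE      73236.81        73236.81
#>      lmwh 13055.121 1.830      TRUE         FALSE            NA       174485.49
#> Net monetary benefit at WTP:
#>  strategy      nmb
#>   placebo 64065.19
#>      doac 61502.60
#>      lmwh 54892.38
```

Read this as: over five years, no prophylaxis costs $1,403 and yields 1.763
QALYs; DOAC prophylaxis adds 0.071 QALYs for $5,197 more (ICER
$73,237/QALY at full, unreimbursed drug prices — above the threshold);
LMWHs cost more than DOACs while yielding slightly fewer QALYs and are
strictly dominated. Drug reimbursement is governed by the `self_pay_ratio`
parameter (default 1 = the patient pays list price); reimbursement scenarios
set it explicitly in the config and move the ICERs roughly in proportion to
the drug-cost share. See the methods vignette
(`vignettes/model-methods.Rmd`) for why this parameter dominates the
conclusions.

Probabilistic sensitivity analysis and acceptability curves:

```r
psa   <- simulate(fit, nsim = 10000, seed = 1)          # seeded PSA
curve <- ceac(psa$draws, wtp_grid = seq(0, 80000, 2000))
plot(curve)
```

Evidence pooling from arm-level counts:

```r
pool_proportions(data.frame(study_id = 1:3, events = c(10, 30, 20), total = 100))
#> pooled proportion 0.1913 (95% CI 0.1033-0.3270), tau2 = 0.3324, k = 3
```

A thin command-line wrapper covers the same stages
(`base-case`, `scenarios`, `dsa`, `psa`, `ceac`, `pool`):

```sh
Rscript inst/scripts/ceavte-cli.R base-case --horizon 60 --out results/
Rscript inst/scripts/ceavte-cli.R psa --n 10000 --seed 7 --out results/
```

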