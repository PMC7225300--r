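# renalcea

A Markov cohort cost-effectiveness model of first-line **avelumab plus
axitinib versus sunitinib** in advanced renal-cell carcinoma, from a US
payer perspective.

Immune-checkpoint combinations extend progression-free survival in
advanced RCC but cost far more than tyrosine-kinase-inhibitor
monotherapy.  For health-economic analysts and methods-minded clinicians,
this package rebuilds the full decision analysis as tested, reusable
code: a three-state cohort engine, transparent costing from dosing
schedules and unit prices, and deterministic and probabilistic
sensitivity machinery — with every input auditable in a single YAML
configuration.

## The model

Three health states — progression-free (PFS), progressed disease (PD),
death — simulated in 6-week cycles over 10 years (87 cycles) from age 61.
Survival is extrapolated with Weibull models $S(t)=\exp(-\lambda
t^\gamma)$ fitted to Kaplan–Meier curves; the per-cycle transition
probability entering cycle $t$ is

$$p(t) = 1-\exp\bigl[\lambda(t-1)^{\gamma}-\lambda t^{\gamma}\bigr],$$

with death from either alive state taking
$\max\{p_{OS}(t),\,q_{\text{background}}(t)\}$ and PFS→PD the PFS exit
hazard net of death.  Costs (first-line regimen while in PFS,
subsequent-therapy / supportive-care mix in PD, a one-off
incidence-weighted adverse-event charge) and utility-weighted person-time
are accumulated with trapezoid half-cycle correction and 3% annual
discounting, and summarised as

$$\mathrm{ICER} = \frac{\Delta C}{\Delta Q}, \qquad
  \mathrm{NMB} = \lambda_{\mathrm{WTP}}\,\Delta Q - \Delta C,$$

against a willingness-to-pay of \$150,000 per QALY.  One-way sensitivity
analysis produces a tornado table; the probabilistic analysis samples
costs from gamma and utilities/probabilities from beta distributions over
1,000 seeded Monte-Carlo draws and yields cost-effectiveness
acceptability curves.  The methods vignette
(`vignettes/cost-effectiveness-model.Rmd`) documents every modelling
choice and limitation.

## Worked example

```r
library(renalcea)

res <- run_base_case(rcc_base_config())
res
#> <cea_comparison> avelumab + axitinib vs sunitinib
#>   incremental cost  $236,845
#>   incremental QALYs 0.447
#>   ICER              $529,441 per QALY
#>   NMB at $150,000/QALY: $-169,743
```

The combination buys 0.447 extra discounted QALYs for an extra $236,845 —
about $529,000 per QALY, far above the $150,000 threshold (hence the
negative net monetary benefit).  `tidy()` gives the strategy-level table:

```r
tidy(res)[, c("arm", "total_cost", "total_qalys", "incremental_cost",
              "incremental_qalys", "icer")]
#> # A tibble: 2 × 6
#>   arm          total_cost total_qalys incremental_cost incremental_qalys    icer
#> 1 sunitinib       592243.        3.14              NA             NA         NA
#> 2 avelumab + …    829088.        3.58          236845.             0.447 529441.
```

Price scenarios, the tornado, and the probabilistic analysis:

```r
run_price_scenario(rcc_base_config(), "avelumab", 0.30)$icer
#> [1] 42645.45   # avelumab at 30% of list price

head(one_way_dsa(rcc_base_config()), 2)[, c("name", "spread")]
#> # A tibble: 2 × 2
#>   name                     spread
#> 1 utility_pfs_combination 1943142.
#> 2 utility_pfs_sunitinib    605944.

psa <- run_psa(rcc_base_config(), n = 1000, seed = 1)
glance(psa)$prob_cost_effective
#> [1] 0.018
```

The state utilities dominate the tornado, and at $150,000/QALY the
combination is cost-effective in only ~2% of draws.  `autoplot(psa)`,
`plot_ceac(ceac(psa))`, `plot_tornado()` and `plot_trace()` draw the
standard figures.

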