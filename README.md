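# seqcea

Markov cohort cost-utility modelling for sequential rheumatoid-arthritis
treatment.

`seqcea` is for health economists and HTA analysts who need a tested,
scriptable implementation of the classic RA treatment-sequence
cost-utility model: a cohort enters on a first-line TNF-inhibitor
strategy (certolizumab pegol, adalimumab, etanercept or infliximab, with
or without background methotrexate), is classified at 3 or 6 months into
ACR response categories, and on discontinuation cascades through a
conventional-DMARD sequence (sulfasalazine → leflunomide → gold →
hydroxychloroquine → azathioprine → cyclosporine → penicillamine) to
palliation. The package computes discounted lifetime costs and QALYs per
strategy, incremental cost-effectiveness ratios with dominance
classification, one-way sensitivity scenarios, and a probabilistic
sensitivity analysis with cost-effectiveness acceptability curves.

## The model

- **States.** Entry (pre-response) → first-line response states
  (ACR20/ACR50/ACR70) → per follow-up drug an assessment state and a
  continuing state → palliation → death (absorbing). Non-responders at
  the first assessment move straight to the first follow-up line;
  follow-up non-responders move on after one cycle; discontinuation
  follows a constant hazard calibrated to a 37-month median duration on
  TNF inhibitors, `p = 1 − 0.5^(cycle/median)`.
- **Disability and utility.** The cohort's HAQ-DI is tracked per state.
  Response categories improve HAQ (defaults ΔHAQ = 0 / −0.32 / −0.55 /
  −0.80 for none/ACR20/ACR50/ACR70); utility follows through the linear
  mapping ΔEQ-5D = −0.2102·ΔHAQ from the baseline utility of 0.38, with
  80 % of the first-cycle gain front-loaded by week 4, a small
  continuation gain over the following year, full rebound on
  discontinuation, and HAQ drift on conventional therapy and palliation.
- **Mortality.** A synthetic Gompertz–Makeham life table supplies
  age/sex-specific annual death probabilities; the hazard is multiplied
  by `1.330^HAQ` (the relative risk of death per HAQ-DI unit) and
  converted to cycle probabilities.
- **Costs.** Drug acquisition per dosing regimen with per-unit wastage
  (whole vials/syringes dispensed; per-mg costing available as a
  scenario), weight-based infliximab dosing at a fixed 81.4 kg or under
  a weight distribution, €232.80 per IV infusion, a shared monitoring
  schedule, and annual HAQ-band resource costs. Costs inflate at 3 %/year
  from the 2009 cost year and everything is discounted at 3.5 %/year.

Inputs that the published analyses this model family is built on cite
but never print (life table, follow-up DMARD efficacy and durations,
HAQ-band costs, response-category HAQ changes) are supplied by a
documented synthetic defaults registry; every value in the configuration
carries a `"paper"` or `"default"` provenance flag.

## Worked example

```r
library(seqcea)

cfg <- default_parameter_set()
strategies <- c("CZP+MTX", "ADA+MTX q2w", "ADA+MTX weekly",
                "ETA+MTX", "IFX3+MTX", "IFX5+MTX")

res <- evaluate_strategies(cfg, strategies)
res
#> # A tibble: 6 × 3
#>   strategy          cost qalys
#>   <chr>            <dbl> <dbl>
#> 1 CZP+MTX        151061.  5.23
#> 2 ADA+MTX q2w    146536.  5.05
#> 3 ADA+MTX weekly 189388.  5.05
#> 4 ETA+MTX        146466.  5.20
#> 5 IFX3+MTX       140265.  4.87
#> 6 IFX5+MTX       160449.  4.87

incremental_table(res, "CZP+MTX")
#> # A tibble: 5 × 6
#>   reference comparator     delta_cost delta_qaly    icer dominance
#>   <chr>     <chr>               <dbl>      <dbl>   <dbl> <chr>
#> 1 CZP+MTX   ADA+MTX q2w         4525.     0.185   24520. icer_defined
#> 2 CZP+MTX   ADA+MTX weekly    -38327.     0.185      NA  reference_dominant
#> 3 CZP+MTX   ETA+MTX             4595.     0.0314 146228. icer_defined
#> 4 CZP+MTX   IFX3+MTX           10796.     0.357   30236. icer_defined
#> 5 CZP+MTX   IFX5+MTX           -9388.     0.357      NA  reference_dominant
```

Read this as: under the default inputs, certolizumab pegol + MTX gains
0.19 QALYs over either adalimumab schedule; it *dominates* (cheaper and
more effective than) weekly adalimumab and 5 mg/kg infliximab, and buys
its QALY advantage over 2-weekly adalimumab at about €24,500/QALY —
under a €30,000/QALY willingness-to-pay threshold, a cost-effective
trade. Absolute costs and QALYs depend on the defaulted (unpublished)
inputs; the incremental structure is the robust output.

Probabilistic sensitivity analysis and acceptability curves:

```r
psa <- run_psa(cfg, strategies, n_draws = 200, seed = 42)
glance(psa)
#> # A tibble: 5 × 6
#>   comparator     n_draws mean_delta_cost mean_delta_qaly prob_ce_at_wtp
#> 1 ADA+MTX q2w        200           4342.          0.185           0.895
#> 2 ADA+MTX weekly     200         -38383.          0.187           1
#> 3 ETA+MTX            200           4541.          0.0233          0
#> 4 IFX3+MTX           200          10050.          0.356           0.64
#> 5 IFX5+MTX           200          -6671.          0.357           0.98

autoplot(psa)          # cost-effectiveness planes
autoplot(ceac(psa))    # acceptability curves
```

One-way sensitivity scenarios are registered by name
(`owsa_scenarios()`): time horizon, discount rates, inflation, 3-month
response assessment, baseline HAQ, rebound fraction, per-mg costing,
HAQ-DI utility pathway, no HAQ-mortality association, IV administration
cost ±20 %:

```r
run_owsa(cfg, c("horizon_5y", "rebound_50"), strategies)
```

Configurations are plain YAML (`write_model_config()` /
`load_model_config()`); the shipped base case is at
`inst/extdata/default_config.yaml`.

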