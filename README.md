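# flightnoise

Decision-analytic cost-effectiveness modelling of aircraft noise exposure.

Automated flight-path optimisation can route departures — and their noise —
over densely populated neighbourhoods. This package weighs the two sides of
one such routing decision for a noise-affected community: keeping a noisy
departure route in *limited* use (residents stay unexposed, but society pays
recurring flight-delay costs) versus flying it *year-round* (delays largely
avoided, but residents face chronic >60 dB DNL noise, which raises their risk
of cardiovascular disease, RR 1.14, and generalized anxiety disorder,
RR 1.79). It is aimed at health economists and environmental-health
researchers who want a transparent, scriptable alternative to spreadsheet or
proprietary decision-tree implementations of this class of model.

## The model in brief

A three-state annual-cycle Markov cohort (*no prior CVD*, *prior CVD*,
*death*) runs from age 41 to age 110 for each policy arm. Each cycle applies
age-banded CVD incidence (multiplied by 1.965 for a prior history and by the
noise RR in the exposed arm), memoryless anxiety episodes, and death from
background mortality combined with a per-event CVD case fatality. Rewards
are event-based costs (CVD $36,066; anxiety $3,127 per event year), a
$1,754/person-year flight-delay cost in the limited arm
($1,516 operating + $238 productivity, from the delay-cost equations
`C = DELAY × SPEED × CASM × SEAT × FLIGHT` and
`P = DELAY × WAGE × SEAT × FLIGHT`), and utilities 1.0 / 0.844 with
event decrements 0.283 (CVD) and 0.16 (anxiety), everything discounted at 3%.
The headline result is the incremental cost-effectiveness ratio
`ICER = ΔC/ΔQ` of limited vs. year-round use, with probabilistic (10,000-draw
PSA, CEAC) and one-way (tornado) sensitivity analyses around it.

All inputs ship with the package: published point estimates with fitted
sampling distributions (beta/gamma by moment matching, log-normal from 95%
CIs), and a clearly-labelled synthetic Gompertz life table (life expectancy
39.5 years at age 41) standing in for the unpublished mortality inputs, so
results using it track the published analysis structurally rather than
exactly (see the methods vignette's limitations section).

## Worked example

```r
library(flightnoise)

params <- cea_parameters()        # base-case parameter set
lt     <- gompertz_life_table()   # synthetic life table (bundled fixture)

run_cea(params, lt)
#> <cea_result>
#>   limited vs year_round
#>   limited      cost $74,643, QALYs 20.02
#>   year_round   cost $50,729, QALYs 19.25
#>   incremental: $23,914, 0.765 QALYs (tradeoff)
#>   ICER: $31,244/QALY
```

Limiting the noisy route costs society more (the delay costs exceed the
health-care savings) but buys 0.77 quality-adjusted life years per exposed
person, at $31,244 per QALY — well under the conventional $50,000/QALY
willingness-to-pay threshold.

Uncertainty, via 10,000 Monte Carlo draws from the parameter distributions:

```r
psa <- run_psa(params, lt, n_draws = 10000, seed = 42)
psa_summary(psa)
#>   n_draws p_cost_saving p_icer_below_threshold ceac_at_0 ceac_at_50k ceac_at_100k
#> 1   10000        0.0375                 0.8301    0.0375       0.654       0.8676
autoplot(psa)       # cost-effectiveness plane
plot_ceac(psa)      # acceptability curve
```

So limiting the route is outright cost-saving in 3.8% of draws and
cost-effective at a $100,000/QALY threshold in 87% of them. The strongest
single lever is the anxiety–noise association:

```r
tornado_analysis(params, lt, default_owsa_ranges()[c(1, 2, 5), ])
#>        parameter  low high  icer_min  icer_max
#> 1   rr_anx_noise 1.00 3.06  1820.508 287455.05
#> 2 p_anxiety_base 0.08 0.28 15002.261  75228.23
#> 3   rr_cvd_noise 1.00 1.18 28910.498  41577.92
```

With no anxiety effect at all (RR = 1) the ICER climbs to ≈$287k/QALY; at the
upper bound of its CI (3.06) limiting the route nearly pays for itself.

The flight-delay cost equations are exposed directly:

```r
scs <- default_delay_scenarios(hourly_wage_usd = 10.33)
incremental_delay_costs(scs$limited, scs$year_round)
#>           arm flights_per_year operating_cost productivity_loss operating_cost_pp
#> 1     limited            14892      129503684          20627793            1545.3
#> 2  year_round              876        4217329            671751              50.3
#> 3 incremental            14016      125286355          19956042            1494.9
```

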