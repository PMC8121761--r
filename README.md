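# fvchain

A system-dynamics simulator of a smallholder fruit-and-vegetable (F&V)
aggregation value chain, built for horizon-scanning the producer-versus-
consumer trade-offs that emerge when such schemes are upgraded.

## The problem

Village-level aggregation schemes pool smallholders' F&V each morning
and transport it to market on the farmers' behalf. They cut farmers'
transport costs and open up distant urban markets — and precisely for
that reason they tend to reinforce urban-centric produce flows, leaving
small retail-oriented rural markets under-supplied. Upgrades intended to
fix this (recruiting more members, subsidising transport to the small
market, market-based cold storage, demand-boosting campaigns) interact
through price, trust and market-choice feedbacks, and routinely produce
unintended consequences. `fvchain` asks: under which plausible futures
do *three* outcomes improve simultaneously —

1. cumulative F&V purchases per retail customer in the small market
   ("access"),
2. cumulative profit per member farmer ("profit"), and
3. the scheme's return on investment (transport fees collected
   post-subsidy, relative to aggregator compensation of 0.1 Rs/kg sold)?

## The model

A stock-and-flow model at half-day resolution (2,922 half-days,
2017-10-01 to 2021-09-30). Scheme membership follows Bass diffusion
gated by trust and relative utility,

  dL/dt = (p/1000 · N + q · L/M · N) · τ · u  −  δ · L · (1 − τ),

coupled to seasonal production with profit reinvestment, a bounded
market-preference stock weighted towards guaranteed sales, softmax
trader choice, reference-anchored price formation
p = p_ref · clamp((demand/volume)^η, 0.5, 1.5), trader entry/exit,
FIFO perishable inventory (2-day ambient vs 21-day cold shelf life), and
constant-elasticity retail demand with weekly smoothing. A Monte-Carlo
engine samples four upgrade magnitudes uniformly, pairs every scenario
run with a common-random-number baseline, classifies the outcome deltas
into six trade-off categories, and extracts "core" members per category.
A two-stage sensitivity module perturbs parameters multiplicatively
(V = V₀·ε, ε ∈ [0.75, 1.25]), scores runs against LOESS constraint
corridors, and screens influential parameters with Kolmogorov–Smirnov
tests. All non-public inputs are synthesised by a fixture module.

See `vignettes/value-chain-model.Rmd` for the full model description,
parameter rationale and limitations.

## Worked example

```r
library(fvchain)
cfg    <- default_config()
inputs <- make_fixture_inputs(cfg, seed = 1)

# do-nothing baseline
baseline <- run_simulation(cfg, scenario = NULL, run_seed = 1, inputs = inputs)
baseline
#> <fvchain_run> seed 1
#>   cumulative Market-B purchases: 106.27 kg/customer
#>   cumulative member profit:      39387 Rs/farmer
#>   mean scheme ROI:               6.88
#>   final members: 4719 of 12087 farmers; trust 0.85; pref A 77%

# one upgrade future: moderate extension plus strong demand growth
sc <- list(extension_rate = 0.06, subsidy_B = 10,
           cs_active_raw = 0, cs_level = 0, demand_growth = 9)
upgrade <- run_simulation(cfg, sc, run_seed = 1, inputs = inputs)
classify_tradeoff(upgrade$outcomes, baseline$outcomes)
#> [1] "access_profit_wins"
```

The baseline reproduces the deployed scheme's character: membership
grows organically from 90 to a few thousand farmers, ~95% of aggregated
supply flows to the large urban market, and the scheme collects roughly
seven rupees in transport fees per rupee of aggregator compensation.
The upgrade future shown combines moderate recruitment with strong
demand growth: both small-market purchases (+10.2 kg/customer) and
member profits (+1,108 Rs/farmer) beat the baseline, but the scheme's
ROI slips just below it (-0.03) under the transport subsidy — an
"access & profit wins" trade-off, one ROI hair short of a win-win-win.

Ensembles and classification:

```r
ens <- run_ensemble(ensemble_spec(n_runs = 100, phase = 1, master_seed = 42))
table(ens$category)
conditional_probability_profile(ens$demand_growth, ens$category, n_bins = 5)
```

A thin command-line front end wraps the same functions:

```sh
exec/fvchain ensemble --phase 1 --n-runs 100 --seed 42 --out runs/
exec/fvchain fixtures --seed 1 --out fixtures/
```

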