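---
title: "A half-day stock-and-flow model of a horticultural aggregation value chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A half-day stock-and-flow model of a horticultural aggregation value chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system being modelled

`fvchain` simulates a smallholder fruit-and-vegetable (F&V) value chain in
which a village-level aggregation scheme pools members' produce each
morning and trucks it to market on their behalf. Two markets compete for
that produce: a large urban wholesale market ("Market A") with deep
capacity, out-of-state distance traders and high commissions, and a small
retail-oriented local market ("Market B") with a limited customer base,
lower charges and weaker purchasing power. The model's purpose is not
point prediction but horizon scanning: simulating thousands of plausible
upgrade futures and classifying each by whether it improves (i) F&V
purchases per retail customer in the small market, (ii) cumulative profit
per member farmer, and (iii) the financial sustainability of the
aggregation scheme itself — the three-way "win-win-win" question.

The simulator integrates all stocks by explicit forward differences at
the system's native half-day resolution (morning and afternoon market
sessions) from 2017-10-01 to 2021-09-30 — 2,922 half-days. Upgrade
scenarios switch on at 2018-10-01 and run for the remaining three years.
F&V is treated as a single homogeneous commodity.

## Model structure

**Membership (Bass diffusion with trust and utility).** A fixed farmer
population of 12,087 splits into scheme members (initially 90) and
independent farmers. Adoption flows follow the innovation-diffusion form

$$a_t = \Big(\tfrac{p}{1000} N_t + q \tfrac{L_t}{M} N_t\Big)\,
  \tau_t\, u_t,$$

where $L$ and $N$ are the member and non-member stocks, $M = 12{,}087$,
$p$ is the extension (innovation) rate in recruits per 1,000 non-members
per half-day, and $q$ the word-of-mouth (imitation) coefficient. Two
multiplicative gates extend the classical model: a trust stock
$\tau \in [0,1]$ that drifts up or down with the monthly trends of member
profits and guaranteed sales, and a relative utility index $u$ built from
the member-to-independent ratios of trailing weekly profit and
guaranteed-sales fraction, each ratio clamped to $[0,2]$ and equal to 1
at parity. Dis-adoption removes members at a rate proportional to
$1-\tau$. With $\tau \equiv u \equiv 1$ and no dis-adoption the
trajectory reduces to the closed-form Bass curve, which the test suite
verifies to within 1% relative Euler error at unit half-day steps.

**Production and marketing schedule.** Farmers market once every 5 days
in Rabi (Oct–Feb), 7 in Zaid (Mar–May) and 8 in Kharif (Jun–Sep).
Aggregation happens only in the morning, so the member marketing
fraction is $1/\text{interval}$ on mornings; independent farmers spread
$1/(2\,\text{interval})$ over both sessions. Marketable production per
half-day is
`farmers x marketing_fraction x land x fv_fraction x yield x multiplier`,
less household consumption (raised 10% per unit fraction of female-headed
households), gifts, and pre-farmgate losses. The F&V land share follows a
monthly cycle from ~80% (peak Rabi) to ~50% (Kharif), scaled by a
saturating response in (0.8, 1.2) to the F&V-to-staple price ratio.
Cumulative profits are reinvested at each season start: land is bought
with 20% of cumulative profit whenever that spend exceeds the price of a
tenth of a katha (Rs 7,600), and 10% of cumulative profit buys yield
gains at 1% per Rs 20,000, capped at 1.5% per year.

**Market choice.** Each morning a participation share of members (a
logistic in the weekly profit and guaranteed-sales differences between
the member and independent channels, bounded in [0.2, 1]) opts into
aggregation; non-aggregated member produce is marketed through the
independent channel, with its revenue still accruing to the member
population. Aggregated supply splits between the markets by a preference
stock in [0, 100] (% to Market A) that adjusts toward whichever market
offered better trailing *morning* guaranteed sales and per-kg marketing
profit — mornings only, because members never observe afternoon
conditions. Guaranteed sales carry more weight than price (0.6 vs 0.4),
reflecting farmers' emphasis on marketing certainty. Independent
farmers use a constant split (85% to A) jittered by up to ±10% per
half-day.

**Traders and prices.** Market A hosts morning-only distance traders
(2,000 kg/trader/half-day), all-day wholesalers (600 kg/trader/half-day)
and retailers whose capacity is customer demand; Market B has only
wholesalers and retailers. Within a market, supply is shared by a
softmax over each cohort's trailing guaranteed-sales fraction and
expected price; supply turned away by a full cohort spills to others
with remaining capacity before counting as unsold. Offered prices anchor
on the distance traders' expected price — a weekly seasonal reference
series — scaled by $(\text{remaining demand}/\text{volume faced})^\eta$
and clamped to $[0.5, 1.5]$ times the anchor; low-grade produce (a
uniform 60–100% high-grade draw per half-day) earns half price. Trader
cohorts enter in proportion to trailing 30-day profits and exit under
losses; initial counts anchor peak-Rabi capacities near 100,000 (A) and
20,000 (B) kg/day. Unsold stock ages in half-day cohorts and spoils
after two days, or 21 days within a trader's cold-storage share
(allocated in proportion to supply shares, rented at 0.15
Rs/kg/half-day).

**Retail demand.** Customer purchases follow constant-elasticity demand
around a reference price (elasticities −0.6 urban, −0.9 rural), smoothed
with a 14-half-day time constant (consumers adjust about weekly). The
customer populations are fixed, so retailer entry splits the same
customers rather than conjuring new ones. The scenario's external demand
growth (0–10 %/yr, compounded per half-day) is interpreted as
market-wide F&V demand growth: it scales wholesale and export downstream
demand directly and retail demand through its reference level. With a
retail-only reading the growth scenario has almost no price leverage and
cannot offset supply-driven price declines, which is inconsistent with
its role as the enabling-environment upgrade.

**Outcomes and classification.** Over the scenario window each run
accumulates Market-B purchases per customer, member profit per farmer,
and the scheme's return on investment — transport fees collected from
members (post-subsidy) divided by aggregator compensation at 0.1 Rs per
kg sold, averaged over half-days with sales. Each scenario run is paired
with a do-nothing baseline sharing the same random streams (common
random numbers), so outcome deltas isolate the scenario effect. Strict
sign wins (ties count as losses) map the eight octants onto six
categories: win-win-win; access & profit wins; access wins; profit wins;
others (only ROI wins); lose-lose-lose. "Core" members of each category
lie further from the baseline than the category mean plus one standard
deviation, with distances measured on deltas scaled by their
ensemble-wide standard deviations because the three dimensions carry
different units (set `normalize = FALSE` for raw-unit distances).

## Scenario engine

Four upgrade magnitudes are drawn uniformly and independently:
extension rate 0–0.274 recruits/1,000 non-members/half-day; Market-B
transport subsidy 0–100%; cold storage (an activation draw thresholded
at 0.5 and an investment level 0–3, worth 25,000 kg/half-day in A and
5,000 in B per level unit); and demand growth 0–10 %/yr. The refined
second-phase ranges (extension 0.035–0.086, subsidy 0–50, storage
0–0.62, growth 7.5–10) bracket the space where three-way wins
concentrate. Child seeds derive deterministically from the master seed,
so ensembles are bit-reproducible.

```{r}
library(fvchain)
ens <- run_ensemble(ensemble_spec(n_runs = 100, phase = 1, master_seed = 42))
table(ens$category)
conditional_probability_profile(ens$cs_level, ens$category, n_bins = 5)
```

## Sensitivity and calibration machinery

Parameters are perturbed multiplicatively, $V = V_0\,\varepsilon$ with
$\varepsilon \sim U[0.75, 1.25]$ (one at a time), or jointly within
±5/±10/±25% for the moderately sensitive ("yellow") and most sensitive
("red") tiers. Each perturbed run is scored by the fraction of its daily
aggregated Market-A sales falling inside a constraint corridor over the
evaluation window (2018-03-01 to 2018-08-25, 178 days): at least 95%
in-corridor is insensitive, 90–95% yellow, below 90% red. A two-sample
Kolmogorov–Smirnov test between the multipliers of behaviour-giving
(≥95% coverage) and non-giving runs flags influential parameters.

The corridor is the pointwise band
$\hat f(t) \pm 1.96\sqrt{\mathrm{se}(\hat f)^2 + \hat\sigma^2}$ of a
LOESS fit (span 0.3, degree 1) to the observed series, with
$\hat\sigma$ the residual standard error. Including $\hat\sigma$ makes
it a prediction-style band: a replicate series statistically
indistinguishable from the observations keeps about 95% of its points
inside, which is the property the coverage score needs; a band built
from the mean's standard error alone would shrink with sample size and
reject faithful runs. A noiseless series collapses the band onto the
fitted line.

Because the original scheme's dashboard and the regional wholesale price
records are proprietary, the fixture module synthesises all non-public
inputs: a 52-week seasonal price template (sinusoid with mean-one
lognormal weekly noise) tiled over the horizon, a staple-price series,
truncated-normal household cost draws, and pseudo-observed calibration
series built by overlaying 5% multiplicative noise on baseline model
output. Corridors fitted to pseudo-observations therefore test the
machinery and the model's self-consistency, not agreement with the real
deployment — with real dashboard exports the same functions apply
unchanged.

## Parameterisation

Constants printed in the source field study are locked in
`default_config()` and covered by tests: the population (12,087; 90
initial members), marketing intervals (5/7/8 days), transport cost
ranges (0.50–0.85, 0.80–1.10, 1.00–1.50 Rs/kg; first-year subsidies up
to 50%), investment rules (20%/10% of cumulative profit, Rs 76,000 per
katha, 1% yield per Rs 20,000, 1.5%/yr cap), trader capacities
(2,000/600 kg per half-day), market capacity anchors (100,000 and 20,000
kg/day), quality range (60–100% high grade), half-price low-grade rule,
shelf lives (2 vs 21 days), storage rent (0.15 Rs/kg/half-day), and the
scheme compensation rate (0.1 Rs/kg).

Everything else is a calibration constant of this package, chosen once
for a plausible baseline and documented in-line in `default_config()`:
slow organic membership growth (90 → a few thousand over four years);
interior, responsive market preference with ~95% of aggregated supply
urban-bound on average; peak-Rabi farm supply slightly exceeding market
capacity (Bihar's notorious seasonal gluts), so guaranteed sales and
prices genuinely fluctuate; farmer profits positive but modest, so the
land-investment threshold binds only occasionally. Two structural
choices deserve emphasis: the urban market carries higher
commission-plus-charges (14% vs 4%) than the informal local market,
which nearly offsets its structural morning price advantage and keeps
the preference stock responsive; and peak yields were set so markets
saturate seasonally, without which no upgrade scenario could ever reduce
small-market availability and half the trade-off space would be
unreachable.

## Numerical choices and degenerate inputs

Forward-Euler integration at the native half-day step (the resolution
the system is specified at); all flows are capped so stocks cannot go
negative, and farmer-population conservation plus per-market mass
balance (purchases + carried-in = sales + spoilage + carried-out) hold
to machine precision over the full horizon. Ratio-type signals define
parity as 1 when both sides are non-positive; zero availability maps
offered prices to the upper clamp and zero remaining demand to the
lower. Inventory is FIFO in half-day age cohorts; cold capacity binding
spoils the oldest stock first. Trailing-window statistics use running
sums, and every stochastic input is pre-generated from the run seed in a
fixed order, which is what makes common-random-number pairing and
bit-identical reproduction possible.

## What the tests do and do not show

The suite verifies structural constants, conservation laws, the Bass
limit, classifier totality, the perturbation/KS machinery against
brute-force oracles, corridor calibration on synthetic data with known
noise, bit-level ensemble reproducibility, and direction-only scenario
behaviours (membership monotone in extension; access wins more frequent
with cold storage; profit wins fading above storage level ~1.5) on a
200-run ensemble. Test and acceptance problem sizes (100–200 runs,
15–50 sensitivity simulations per stage) are chosen as desk-scale
analyses; the engine accepts the full 5,000-run specification
unchanged. Published ensemble shares from the original study depend on
its unpublished full parameterisation and proprietary calibration data
and are treated as qualitative plausibility references, not targets:
with this package's default parameterisation the phase-1 ensemble
reproduces the broad structure (roughly half of futures improve
small-market purchases; most of those trade off against farmer profit;
three-way wins are rare and require high demand growth with minimal
subsidy) but not the printed percentages, and three-way wins are
substantially rarer in the refined phase-2 space than reported there.

## Known limitations

Homogeneous F&V (no crop disaggregation, no crop-specific health
outcomes); population-share (not agent-level) marketing choice; no
inter-market arbitrage or trader-farmer credit; trader profit margins
applied to same-step prices even for stock bought earlier; fixed
customer populations; investment evaluated only at season starts. The
synthetic fixtures reproduce the statistical *structure* the model
assumes (seasonality, weekly price steps, positive skew, cost
dispersion) but not the real dashboard's idiosyncrasies — conclusions
about the real deployment require its data.
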