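---
title: "A system dynamics model of commuter cycling policy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A system dynamics model of commuter cycling policy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclesim)
```

`cyclesim` simulates commuter bicycling in a car-dominated region of about
1.5 million people over 1991–2051, under five infrastructure policy
scenarios, and integrates the injury, air-pollution, greenhouse-gas,
fuel-cost and physical-activity consequences into undiscounted benefit–cost
ratios. This vignette records the model structure, the reasoning behind each
calibration choice, the numerical conventions, and what the test suite does
and does not establish.

## Feedback structure

The dynamic core is a small set of coupled loops:

* **Injury balance (dominant).** More cyclists → more cyclist–car
  collisions → lower population sense of safety → fewer cyclists. This
  balancing loop holds the baseline share in low-level oscillation near
  1–2% and is why naive extrapolations of cycling growth fail.
* **Safety in numbers (thresholded, reinforcing).** Above a 2.5% mode
  share, per-cyclist collision risk falls as `(share/0.025)^−0.3` — half
  the classic ecological power function, applied to per-cyclist risk. Below
  threshold there is no effect; historical validation favours this
  structure (see the structure-recovery study below).
* **Mode shift reduces collisions (reinforcing).** Cyclists drawn out of
  cars reduce vehicle volume, and collisions scale sublinearly
  (`volume^0.5`) with traffic.

Exogenous drivers: commuter growth (+40% over the 60-year study period from
400,000), fleet emission and fuel-efficiency improvement, fuel price growth,
and secularly declining all-cause mortality.

## Demand and mode choice

Shares follow a relative-utility form: `share_m ∝ base_m · A_m`, with
baseline shares 0.85 / 0.02 / 0.055 / 0.075 (car / bicycle / walk / public
transport) acting as alternative-specific constants. The bicycle share is
capped at the cycling-eligible trip pool (50% of commutes are ≤ 6 km) and
walking at its 2-km pool (27%), with excess renormalized over uncapped
modes.

The design question the source material leaves open is how strongly
perceptions move utilities. Choices made here, once, and their reasons:

* **Bicycle attractiveness** is
  `commuting-perception × (perceived-safe fraction / 0.19)^4`. The steep
  safety elasticity (4) encodes that safety is the dominant stated barrier
  to cycling: segregated-lane-class improvements in perceived safety must
  be able to move the share by an order of magnitude, as stated-choice
  studies and the bicycle-friendly-city contrast imply, while the
  commuting-convenience perception enters linearly.
* **Car attractiveness** responds to its convenience index with elasticity
  1.5 — entrenched habitual use responds less elastically than a marginal
  mode.
* **Historical trends 1991–2012.** Car convenience grows 1.2%/yr
  (motorway-era investment) and cycling's commuting perception decays 3%/yr
  (the helmet-law era and traffic growth), both frozen after 2012. These
  reproduce the observed decline from a 2% share toward the ~1% equilibrium
  that the census record shows; without them the injury-balance loop alone
  stabilizes the share near its 1991 level.
* **Perception delay.** Stated preference leads revealed mode share by a
  first-order delay of 1 year (the simplest delay consistent with "one year
  on average").

The injury → sense-of-safety curve is a power law in annual fatal + serious
counts relative to the calibration era, `0.19 · (I/I₀)^−0.15`, carried as a
piecewise-linear lookup, anchored so baseline-era counts map to the 19% of
survey respondents who considered cycling "always or mostly" safe, and
capped at 0.95. Policy perception boosts multiply this fraction. Because
the curve is anchored to the run's *own* baseline-era counts, the share
path is invariant to the injury model's absolute scale — which is what
makes two-parameter calibration of the injury scale well-posed.

## Injury model

Per road class (local, arterial; cyclists split 50/50 at baseline, vehicle
volume 20/80, mean speeds 40/55 km/h):

```
collisions_c = r0 · cyclists_c · (V_c/V_c,1991)^0.5 · RR_policy,c · SIN(share) · 0.4^(Δv_local/10)
```

* `r0 = 0.03` collisions per cyclist-year at 1991 conditions, and a
  serious-injury severity scale of 0.25, are **calibration inputs** chosen
  so the 1991 operating point is ≈1.5 fatal and ≈33 serious injuries per
  year among 8,000 bicycle commuters (regional crash-register scale for
  commute-time cyclist–car crashes, after doubling reported serious counts
  for known underreporting). `calibrate_injury()` re-fits both from any
  historical series in closed form (both enter linearly).
* The volume exponent 0.5 per class follows the sublinear crash-prediction
  relationship; it is config-exposed.
* Severity: logistic speed curves (fatal centred at 70 km/h, serious at
  45 km/h) split collisions into outcomes at each class's mean speed.
  **Convention:** the published "10 km/h slower ⇒ 60% fewer collisions"
  effect of traffic calming composes exponentially (`0.4^(Δv/10)`) and is
  applied to collision numbers; severity curves stay at the calibrated
  class operating points, so the traffic-calming literature estimate is not
  double-counted through the severity channel.
* Car-occupant fatalities scale with light-vehicle kilometres at 20 deaths
  per 10⁹ km, the ratio implied by the published cumulative outcome table.

## Policy scenarios

Effects scale with an S-shaped rollout fraction: a logistic clipped to 1% /
99% of its range at the window endpoints (2012 → 2040 for the regional
cycle network, 2012 → 2050 otherwise). Published effect sizes are encoded
as: perception increments per 10% of the class network treated (painted
lanes 4% safety / 3% commuting on 46% coverage; segregated lanes 6% / 4% on
full arterial coverage), off-road paths contributing 2% (commuting) and 5%
(safety) per doubling of km per 100,000 population (10 → 25 at full
rollout), and collision relative risks aggregated region-wide as
`1 − p·coverage·(1 − RR_eff)` with `RR_eff` the midblock/intersection mix
(0.5·0.72 + 0.5·0.8 = 0.76 for segregated lanes). Traffic calming scales
linearly in rollout to −15 km/h, −25% local volume, a 50→70% local share of
cycling distance, ±10% perception boosts and a 30% car-convenience
reduction. The combined scenario composes the two interventions
multiplicatively; shared bus/bike lanes (0.04% of the network, RR 1.0)
contribute nothing.

## Outcome sectors

* **Air pollution**: 1991 commuting-attributable baselines (100 deaths, 500
  hospitalisations, 100 COPD admissions, 30 cancers, 120,000 restricted
  activity days — calibration inputs at regional-model scale) scale
  linearly with vehicle-km, a PM₁₀-proxy emission factor declining 4.6%/yr,
  and exposed population. Removing a commuting vehicle-km is treated like
  removing any light-vehicle km over 24 h.
* **Greenhouse gases**: per-km factors for CO₂ (940 g), CO (25 g, GWP 1.9),
  CH₄ (0.6 g, GWP 25) and N₂O (0.05 g, GWP 298) declining 0.5%/yr. The CO₂
  factor reflects congested commute-time driving and is calibrated so the
  business-as-usual run passes through the published anchor of ≈3.1 t
  CO₂-eq per commuting person in 2007; per-capita emissions are therefore
  expressed per commuter, the only denominator consistent with that anchor
  and with the published cumulative tonnages.
* **Fuel**: 0.075 L/km improving 0.5%/yr; pump prices from $NZ1.00 (petrol)
  / $0.85 (diesel) growing 1.5%/yr with an 85% petrol fleet — prices
  outpace efficiency, so fuel savings grow over time.
* **Physical activity**: all-cause mortality relative risk 0.72 for regular
  commuter cyclists, linear dose response (scaling 1.0), applied to the
  excess bicycle commuters lagged by a first-order 2-year lead time —
  symmetric, so a collapse in cycling costs lives at the same lag. Baseline
  mortality is the stratum-share-weighted rate (ages 15–44 / 45–64 / 65+ at
  0.0011 / 0.0068 / 0.0280 per year, shares 0.55 / 0.41 / 0.04 — period
  life-table scale for a commuting-age population including high-mortality
  strata) declining 1.2%/yr.

## Cost–benefit accounting

Cumulative scenario-minus-baseline outcomes are trapezoid-integrated over
2012–2051 (negative = saving), monetized at $NZ3.1M per fatality of any
kind, $0.325M per serious cyclist injury, $0.75M per air-pollution death or
cancer, $0.003M per hospitalisation, $0.075M per COPD admission, $98 per
restricted activity day and $40 per tonne CO₂-eq; fuel is already monetary.
Nothing is discounted or inflated (a discount-rate option exists, default
0). Net benefit is minus the monetized sum; the benefit–cost ratio divides
by infrastructure costs of $NZ45M / 250M / 380M / 630M.

## Sensitivity analysis

Best/worst-case runs set every *intervention-effect* parameter
simultaneously to its favourable/unfavourable bound; structural and
epidemiological uncertainty (relative risk 0.72 with bounds 0.63–0.87, lead
time 1–5 yr, safety-in-numbers threshold and exponent, baseline collision
rate) is sampled only in the Monte Carlo, with independent triangular draws
(mode at the point estimate) and a mandatory seed. This split mirrors how
the effect bounds were derived (study confidence limits) versus how the
structural assumptions were tested (model comparison). Effects are
classified by the hierarchy of uncertainty: a changed terminal-decade trend
class (least-squares slope over the last 10 years, with a ±1%/yr relative
flatness band defining "flat") is a shape change; a ≥10× change in the 2051
level is an order-of-magnitude effect; anything else is within-order.

## Synthetic history and validation

`gen_history()` generates the 1991–2012 record the calibration and
validation machinery assumes: the deterministic baseline run plus an AR(1)
share oscillation (φ = 0.7, innovation SD 0.0008) observed at five-yearly
census points with 10% relative Gaussian noise, and annual Poisson fatal
and serious counts around the model means (injuries respond to the share
oscillation through cyclist numbers and the generating safety-in-numbers
structure). Zero-noise histories equal the deterministic run exactly, which
is what makes the 1%-accuracy calibration-recovery check meaningful.

The safety-in-numbers hypothesis test runs the baseline model under the
thresholded and the pure no-threshold (−0.6 power) structures and prefers
the one with the lower combined MAPE against the two longitudinal series
the comparison rests on — census shares and annual injuries. MAPE is used
because the validation standard is "shape and magnitude", and both series
are used because the share path itself separates the structures (the
no-threshold power law, applied to a declining share, both raises
per-cyclist risk and depresses the share through the safety feedback).

What the passing tests show: the generator and analysis pipeline are
mutually consistent, parameters are recoverable from clean data, and the
structure comparison reliably identifies the generating injury model under
realistic observation noise (≥90% of 100 seeded replicates in each
direction). What they do not show: anything about real census or crash
data, which the package does not ingest; the generator has no measurement
artefacts beyond simple Gaussian/Poisson noise, no secular reporting
changes, and no exogenous shocks.

## Numerical conventions

* Fixed-step Euler, dt = 0.25 yr, both endpoints recorded (241 states for
  the full run); halving dt changes every 2051 output by < 0.1%, so the
  solver error is immaterial next to parametric uncertainty.
* Delays are first-order exponential smoothing; lookups are
  piecewise-linear and clamp at their endpoint values rather than
  extrapolate, which keeps behaviour bounded outside calibrated ranges.
* Degenerate inputs: a zero-cyclist injury rate is `NA` (undefined), not an
  error; all-zero utilities are a hard error; a zero infrastructure cost
  with nonzero benefits yields an undefined (`NA`) benefit–cost ratio.
* Ties in the structure comparison prefer the thresholded variant (the
  null structure).
* Outputs are written with 6 significant digits and fixed newlines, so
  identical configurations produce byte-identical files.
* Test and acceptance problem sizes: full 1991–2051 runs at dt = 0.25;
  Monte Carlo ensembles of 30–200 runs; 100 replicates per direction in the
  structure-recovery study.

## Design decisions on open points

* "Half of the classic power function" is read as halving the per-cyclist
  risk exponent (−0.6 → −0.3); a config switch restores the full exponent
  or disables the threshold.
* The rollout-decade slope used in the plateau check for the combined
  scenario is taken over the decade spanning the logistic midpoint
  (2026–2036), when implementation is fastest; during the literal first
  decade (2012–2022) the rollout fraction is still below 0.1 and counts sit
  near their baseline level, so a comparison against it would measure the
  S-curve's flat tail rather than the plateau the safety-in-numbers
  crossing produces.
* The noncommuting working-population fraction (0.85) is carried as a
  labelled constant; commuter numbers are pinned directly by the 400,000
  baseline and +40% growth.

## Known limitations

* Magnitudes are reproduced as orderings and shapes, not point values: the
  original calibration constants (collision rates, severity curves, fleet
  tables, life tables) live in unavailable supplementary material, so this
  package's defaults are documented stand-ins calibrated to the printed
  anchors (19% perceived safety, 3.1 t/commuter in 2007, the 1991 injury
  scale). End-of-run mode shares, for instance, are compressed relative to
  the published trajectories (combined scenario ≈10% here versus ≈40%).
* Under this calibration the benefit–cost ratios are all well above 1 and
  the combined scenario's is largest, but the fine ordering among the three
  single policies does not match the published ratios (which are themselves
  inconsistent with the published cells); and in the traffic-calming
  scenario the fuel savings from its direct car-use reduction slightly
  exceed the physical-activity savings, so the claim that mortality savings
  dominate every category holds only for the bicycle-led scenarios.
* The perceived-safety target (>80% by 2040) is not approached by any
  scenario here; the published expert-opinion curve linking media-reported
  deaths to perception is reproducible only through its two anchors.
* Excluded by scope: heavy-vehicle, cyclist-only and cyclist–pedestrian
  injuries; walking/public-transport co-benefits beyond their effect on the
  car and bicycle shares; equity stratification; discounting.
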