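---
title: "Plant geographic range and the long-term carbon cycle: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plant geographic range and the long-term carbon cycle: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegcarb)
```

## The problem

On timescales of hundreds of thousands to millions of years, atmospheric
CO2 is set by the balance between volcanic/metamorphic degassing and the
sinks of silicate weathering and organic-carbon burial. Land plants
amplify silicate weathering where they grow — through root respiration,
organic acids and moisture retention — so the *geographic range* of
vegetation, not just its global mass, shapes the strength of the global
weathering thermostat. A compact supercontinent develops vast arid
interiors that host no plants and weather only abiotically; dispersed
continents of the same total area keep most land within reach of oceanic
moisture, spread the biotic enhancement widely, and pull steady-state CO2
down. `vegcarb` is a desk-scale simulator of exactly this mechanism: a
gridded vegetation kernel dynamically coupled to a reduced long-term
carbon cycle on synthetic paleogeographies.

Everything runs on an equal-angle latitude–longitude grid (40 × 48 by
default). Synthetic worlds stand in for reconstructed paleogeography and
an external climate emulator; they reproduce the *structure* that matters
for the mechanism — zonal temperature, subtropical dry belts,
continental-interior aridity — not any particular geological interval.

## The vegetation kernel

Three broad plant functional types (tropical, temperate, boreal) compete
in every land cell. Productivity is a multiplicative-limitation kernel,

NPP = min(NPPmax, NPPmax · gT · gW · gL · gC · gO · (1 − s)),

with

* **gT** — a trapezoidal temperature ramp per functional type
  (tropical 2/25/30/55 °C, temperate −4/15/25/38 °C, boreal
  −4/10/25/38 °C; LPJ-heritage limits, all overridable),
* **gW** = runoff/(runoff + 30 mm yr⁻¹) — water limitation through
  runoff (the synthetic climate carries no precipitation field),
* **gL** — relative insolation, cos(latitude) normalised to the
  present-day equator times the relative solar luminosity
  1/(1 + 0.4·t/4570) for an epoch t Myr before present (≈ 5 % dimmer in
  the earliest Phanerozoic),
* **gC** = RCO2·(1 + 0.5)/(RCO2 + 0.5) — a saturating CO2 response
  normalised to 1 at present-day relative CO2,
* **gO** = clamp(1 − 0.3·(O2 − 0.21)/0.21, 0, 1.1) — a mild
  photorespiration penalty, exactly 1 at present-day oxygen,
* **s** = (24/h)·a — leaf respiration with a seasonless 12-hour day, so
  s = 0.03 with the default a = 0.015. The coefficient a is a free
  parameter of the kernel.

A cell is *uninhabitable* — zero NPP, zero biomass — whenever runoff is
zero or annual temperature is below −10 °C (or outside the type's
window). The ceiling NPPmax = 3200 gC m⁻² yr⁻¹ is chosen so the
weathering enhancement below spans exactly its intended six-fold range.

Biomass turnover rises with atmospheric oxygen (fire):

turnover = min(max(0.0092·(100·O2 − 10), 0.08), 0.2) yr⁻¹,

i.e. 10.12 % yr⁻¹ at present oxygen, clamped at 8 % below and 20 % above
— double the present rate at high oxygen. As printed, the lower clamp
stays binding until about 18.7 % O2.

**Steady state.** Each coupled timestep re-seeds every cell at
2.5 × 10⁴ gC m⁻² (an average present-day biomass; biomass is *not*
carried between carbon-cycle steps) and iterates the yearly update
B ← B + NPP − turnover·B. Because the update is linear, the remaining
distance to the fixed point NPP/turnover equals the last change divided
by the turnover; we stop when that estimated distance falls below 1 % of
standing biomass in every colonised cell and in the global total. This
norm makes the convergence guarantee explicit: the returned biomass
matches the closed form within ~1 % everywhere, and the iteration count
equals the analytic geometric-decay prediction (the test suite checks
both). A stop based on the raw step-to-step change alone would satisfy a
"<1 % change" wording while leaving low-productivity cells far from
steady state, which is why we rescale by the turnover.

## Weathering and burial

Every land cell carries a biotic enhancement factor

f_biota = 0.0005·NPP + 0.32·RCO2^r,  r = 0.25,

so bare cells retain the abiotic pH-driven term 0.32·RCO2^0.25 and the
factor rises six-fold between bare ground and the productivity ceiling at
RCO2 = 1 — within the 4–7-fold envelope assumed across long-term
biogeochemical models. The exponent r is restricted to [0.25, 0.5];
0.25 is the conservative default.

Per-cell silicate weathering uses runoff-linear, Arrhenius-in-temperature
kinetics over a two-member lithology mix (basalt activation energy
50 kJ mol⁻¹, granite 63 kJ mol⁻¹, reference temperature 15 °C; basalt
weathers twice as fast as granite at reference before calibration).
Carbonate weathering shares the runoff-linear kernel with a single rate
constant and, on these timescales, is treated as carbon-neutral (returned
as deposition), so it is diagnosed but does not enter the carbon budget.
Erosion dependence is folded into the rate constants; there is no
explicit erosion field. Land organic-carbon burial scales linearly with
the global *relative vegetation* (area-weighted biomass over a reference
baseline); marine burial is held constant.

**Calibration.** The absolute rate constants are not meaningful a
priori: `calibrate_reference()` rescales them so that a chosen reference
world at RCO2 = 1 balances the reference degassing flux
(8 × 10¹² mol C yr⁻¹) with sink shares silicate 80 %, land burial 10 %,
marine burial 10 %, and sets the vegetation baseline so the reference
world sits at relative vegetation 1. The calibrated reference is then an
exact fixed point of the coupled system (residual < 10⁻¹⁰ of degassing),
and every other world or forcing is a perturbation of it. Calibration is
idempotent.

## Carbon cycle and coupling loop

A single lumped atmosphere–ocean inventory C (reference
3.2 × 10¹⁸ mol C) defines RCO2 = C/Cref, and global temperature follows
GAST = 14 °C + 5 °C · log2(RCO2) (a deliberately simple logarithmic
sensitivity; both constants are configuration keys). Each coupled step:

1. builds the synthetic climate at the current temperature offset,
2. re-seeds and spins vegetation to steady state,
3. evaluates the enhancement grid, global weathering totals, relative
   vegetation and burial,
4. advances the inventory by an explicit Euler step, and
5. adapts the timestep: a step changing RCO2 by more than 2 % is
   rejected and retried at half the step (the vegetation spin-up is not
   repeated — the pre-step state is unchanged); accepted steps grow the
   step by 1.2× up to 10⁶ yr, starting from 10⁵ yr (~100 kyr).

Runs end in a *steady state* (|tendency| below 10⁻³ of the reference
degassing flux), or in a classified failure recorded as data: RCO2
outside [0.05, 20] (runaway hot/cold) or total vegetation loss while the
budget is still unbalanced (extinction). The one-dimensional balance
makes an independent check easy: the steady state found by time
integration agrees with a scalar root of the carbon balance (bisection
with the vegetation response re-evaluated at each trial CO2) to well
within 2 %.

## Synthetic worlds and climate

`make_supercontinent()` accretes one connected block around a seed cell,
taking cells in order of grid (BFS) distance plus a small seeded uniform
jitter and cutting the ordering at the target area; with jitter below one
cell, every prefix of that ordering is connected, and the realised area is
within one cell of the target. `make_dispersed()` grows several blocks
round-robin inside non-overlapping "core" regions (cells at least two BFS
steps closer to their own seed than to any other), which provably keeps a
one-cell ocean gap between blocks and makes total area match the
supercontinent of the same land fraction within one cell. Both generators
are deterministic given their seed.

The synthetic climate is shaped by a handful of constants (all in
`climate_params()`):

* temperature 27 °C at the equator falling by 45 °C · sin²(lat) to the
  poles, cooled inland by 0.8 °C per cell of distance-to-coast (capped at
  8 °C); a global offset is applied with linear polar amplification
  (×1 at the equator to ×2 at the poles);
* zonal runoff peaking at 1500 mm yr⁻¹ in the equatorial band, dropping
  to 150 mm yr⁻¹ in the subtropical belts (15–35°), recovering to
  ~700 mm yr⁻¹ in mid-latitudes, dry poles; decayed inland with a
  3-cell e-folding, scaled by (1 + 0.03 · offset) for warming-enhanced
  hydrology;
* **full aridity beyond 6 cells inland** and a 20 mm yr⁻¹ floor below
  which runoff counts as zero. The hard cutoff is what gives a compact
  supercontinent its large arid interior: the exponential decay alone
  would leave deep equatorial interiors marginally wet, which is not the
  regime the mechanism needs.

These values were fixed once to produce a plausible contrast — with the
defaults, a 30 %-land supercontinent has ≈ 40 % of its land arid versus
≈ 11 % for four dispersed blocks of equal area — and are not fitted to
any dataset; external climate fields can be supplied through
`load_climate()` instead.

## The range-versus-CO2 experiment

The headline experiment (also the strongest test in the suite) calibrates
on a 35 %-land supercontinent and re-runs the *same* calibrated model on
progressively fragmented worlds of identical land area: 2, 3, 4 and 6
blocks. Block seeds are restricted to a 35° latitude band
(`max_seed_lat`), emulating the breakup of a low-latitude supercontinent:
fragmentation then changes the *range* of vegetation while holding the
latitudinal footprint roughly fixed. Habitable fraction rises
monotonically with fragmentation and steady-state CO2 falls
monotonically with habitable fraction. Without the latitude control the
trend can invert for legitimate physical reasons — blocks drifting
poleward are habitable but cold and weather weakly — which is the same
poleward-drift effect that raises CO2 in the model's warm intervals, not
a defect of the mechanism.

## Ensemble design

`run_ensemble()` reproduces the shape of a parametric sensitivity
analysis: members draw degassing (default interval [0.75, 1.25] of
reference — a declared stand-in, since published bounds are not printed)
and an additive lithology shift (±0.2 of basalt fraction, clamped to
[0, 1]) from independent uniforms under one seed; optional extra ranges
can target `f_minbiota`, climate sensitivity and a few kernel constants.
(The isotope-fractionation parameters varied by full-scale models have no
effect in this isotope-free reduction and are deliberately replaced by
those hooks.) Members run independently against the shared calibrated
reference; failures — typically runaway warming when a member's degassing
exceeds any reachable weathering sink — are recorded and never abort the
ensemble. The envelope reports 2.5/50/97.5 % quantiles over successful
members only; an all-failed ensemble is flagged, not raised.

## Numerical choices and degenerate inputs

* Connectivity is 4-neighbour everywhere, longitude-periodic, latitude
  closed; mask ties are resolved by seeded uniform jitter
  (Mersenne-Twister via `withr::with_seed`, so package RNG use never
  leaks into the caller's RNG state).
* An all-land grid has no coast; `distance_to_coast()` returns the grid
  diameter as an effective infinity (everything deeply continental). An
  all-ocean world is valid for climate but cannot calibrate.
* Functional-type ties go to the earlier listed type
  (tropical > temperate > boreal).
* Vegetation spin-up is capped at 2000 iterations and errors with
  diagnostics beyond that (with the 1 % tolerance, worst cases need a
  few hundred).
* The Euler step is clamped so the inventory cannot cross zero; if the
  minimum timestep still violates the stability threshold the step is
  accepted at `dt_min` rather than looping forever.
* Problem sizes: unit tests run on grids from 2 × 2 up to 24 × 30; the
  coupled experiments and the ensemble run at the native 40 × 48
  resolution, where a full steady state takes on the order of a second
  and a 20-member ensemble well under a minute.

## What the synthetic worlds do and do not show

The generators emulate the structural features the mechanism needs —
zonal climate, dry subtropics, arid interiors scaling with continental
compactness — but not reconstructed coastlines, orography, seasonality,
glaciation, or emulator-derived runoff magnitudes (runoff scales are
calibrated only to give plausible habitability fractions). Passing tests
therefore demonstrate the *mechanism* — range controls weathering
controls CO2 — under controlled geography, not a hindcast of any
geological interval. Also out of scope: nutrient (P) cycling, oxygen and
sulfur reservoirs, isotope systems, seafloor weathering, dispersal and
biome-turnover dynamics, angiosperm-specific weathering effects, and
transpiration feedback on the climate fields.

## Reproducing a run

```{r example, eval = FALSE}
g <- make_grid(40, 48)
super <- make_supercontinent(g, land_fraction = 0.35, center_lat = 0, seed = 11)
frag <- make_dispersed(g, 0.35, n_blocks = 4, seed = 14, max_seed_lat = 35)

model <- calibrate_reference(super, forcing_state())
run_s <- run_to_steady(carbon_state(1, model$config), forcing_state(), super, model)
run_d <- run_to_steady(carbon_state(1, model$config), forcing_state(), frag, model)

c(super = run_s$steady$rco2, dispersed = run_d$steady$rco2)
c(super = run_s$steady$habitable_fraction,
  dispersed = run_d$steady$habitable_fraction)
```

The same experiment is available from the shell as
`vegcarb compare-worlds config.yml` (dispatcher in `inst/scripts`), and
`scripts/acceptance.R` recomputes the package's exact headline constants.
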