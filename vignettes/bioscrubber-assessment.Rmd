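---
title: "Modeling and assessing flue-gas bioscrubbing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and assessing flue-gas bioscrubbing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bioscrub)
```

## The system and what the package computes

`bioscrub` models the treatment of sulfur-rich combustion off-gas
(32,000 m³/h at 3,120 ppmv SO2 in the baseline) by two alternative trains
and compares them environmentally and economically:

* **CS** — a conventional caustic wet scrubber. Absorbed SO2 is oxidized
  in the recirculating liquor and leaves as sulfate brine through a small
  purge; NaOH demand and brine disposal dominate the burden.
* **BS-PG / BS-PCG** — a bioscrubber: the same absorber followed by a
  sulfidogenic UASB reactor (sulfate/sulfite reduced to sulfide with
  glycerol as electron donor — fossil glycerin in BS-PG, purified crude
  glycerol in BS-PCG) and a microaerobic stirred tank where
  sulfur-oxidizing bacteria (SOB) convert the sulfide to elemental
  biosulfur, recovered by centrifugation and drying. Byproducts (biosulfur,
  biogas) return to the combustion process as credits.

The simulation layer couples the three units around the liquor
recirculation loop and emits an annualized life-cycle inventory; the
assessment layer characterizes it into midpoint impact categories,
normalizes to person-equivalents, compares scenarios through the Relative
Impact Ratio, and runs the cost model (cashflows, NPV, cumulative present
value, price breakeven surfaces) plus two-dimensional sensitivity sweeps.

## Acid-base speciation (the backbone)

Every liquid phase is a mixture of weak polyprotic systems — inorganic
carbon (pKa 6.35, 10.33), sulfurous acid (1.85, 7.2), sulfide (7.05;
the second ionization is negligible below pH 12) — plus strong ions
(Na⁺ from caustic, sulfate counted as a fully dissociated anion).
`species_fractions()` evaluates the closed-form ionization ladder;
`solve_ph()` brackets the unique root of the charge balance on pH ∈ [0, 14]
(Brent, residual < 1e-10 mol/L); `dose_to_setpoint()` returns the strong-ion
dose as the exact charge defect at the target pH. Activity corrections and
temperature dependence of the constants are deliberately omitted:
concentrations are treated as activities at 25 °C, consistent with
excluding temperature as a dynamic state. The absorber's integration loop
uses a bisection solver vectorized over stages; the scalar and vectorized
solvers are cross-checked in the test suite.

## Absorber

A cascade of `n_stages = 5` stirred stages (a spray tower has no published
stage count; five is a conventional discretization and is configurable),
wired counter-currently. Only the neutral dissolved species (SO2·H2O,
CO2·H2O) exchanges with the gas: flux = kLa·(C* − C_free) with
C* = p/(Vm·H) and dimensionless Henry coefficients H(SO2) = 0.0315,
H(CO2) = 1.20 at 25 °C. The gas phase is quasi-steady (seconds of
residence against minutes for the liquid); outlet ppmv are rebalanced for
the absorbed moles and the water vapor picked up by the gas (3.1%,
saturation at 25 °C).

The scrubber operates under pH control: `controlled_ph` holds every stage
at the set-point (default 7.0), representing distributed caustic dosing —
without it, half a gram of absorbed sulfur per liter would drive the
unbuffered stage pH below 3 and shut absorption down, which is precisely
why the real column is dosed. The caustic demand is then the
electroneutrality defect of the purged liquor at the set-point times the
purge flow: at steady state NaOH only replaces the Na⁺ leaving with the
brine.

The droplet-scale transfer correlation of the original column is not
reproducible from published information, so `kla` is a configurable
constant with a single overall scalar `kla_scale` calibrated by
`calibrate_absorber_kla()` so the baseline chemical-scrubber SO2 removal
is 59.3%. One scalar, one anchor; the bioscrubber liquor then yields its
removal efficiency with no further freedom.

## UASB reactor

Ten mini-CSTRs in series capture the plug-flow character of the granular
bed (count configurable). The biochemical engine is data-driven: a
reaction × species matrix plus a kinetics table, validated at load time
for elemental S and COD closure per reaction (tolerance 1e-6 relative), so
a published coefficient set can replace the default verbatim. The shipped
default has 15 reactions in 3 trophic groups: 8 fermentative glycerol
routes (1,3-propanediol, propionate, acetate/H2, butyrate/H2 and their
secondary fermentations), 5 complete-oxidizing sulfate-reduction routes
(H2, acetate, propionate, butyrate, glycerol as donors; electron
equivalents leave as sulfide-COD, 2 g COD per g S), and acetoclastic plus
hydrogenotrophic methanogenesis. Units: organics, H2, CH4 and biomass in
g COD/L; sulfur species in g S/L; inorganic carbon in g C/L (carbon is
tracked approximately and not balance-checked; S and COD are).

Kinetics are Monod with non-competitive total-sulfide inhibition
(Ki 0.80 / 0.55 / 0.25 g S/L for fermenters / sulfate reducers /
methanogens — typical mesophilic values; the methanogens are the most
sensitive group). Granules retain biomass: each tank releases only
`1 − retention` (default 0.5%) of its biomass to the effluent, and a
first-order decay (0.04 1/d, routed to acetate as lysis COD so the balance
closes) bounds the hold-up at realistic granular-bed densities. The
crude-glycerol impurity inhibition of the original model is omitted since
only purified substrates enter these scenarios.

Headspace transfer (CH4, CO2, H2S; kLa 200 1/d at the reactor top, 1.05 atm
overpressure) uses a quasi-steady vent: partial pressures solve
film-transfer = vent-outflow per species, which removes the extremely
stiff headspace states while preserving the same steady state; the vent
closes when the equilibrium pressures sum below the headspace pressure.
Only the free H2S fraction at the control pH (7.0) exchanges.

Each tank is integrated with `lsoda` in chunks and finished by a Newton
polish of the algebraic steady state, which also enables warm starts
(Newton from a previous solution) inside recycle iterations, calibrations
and sweeps. Residual sulfate is governed by the apparent sulfate
half-saturation `Ks_sulfate` — physically a granule diffusion limitation —
which `calibrate_uasb_residual()` fits so the purged liquor carries
0.3 g/L of sulfate/sulfite (as SO4 equivalents), the reported effluent
quality.

## Oxidation tank

A 2,277 m³ aerated CSTR. SOB kinetics follow the three-step electron-donor
chain — sulfide → S⁰ (oxygen half-saturation 0.02 mg/L), S⁰ → sulfate
(0.5 mg/L), thiosulfate → sulfate — dual-Monod in donor and dissolved
oxygen. The low DO set-point starves the sulfate route, which is what
makes partial oxidation selective for elemental sulfur; the selectivity is
asserted as a monotonicity property in the tests. Facultative heterotrophs
degrade residual soluble COD through a single aerobic growth process with
ASM2-typical parameters (μmax 6 1/d, Ks 4 g COD/m³, Y 0.63, K_O2
0.2 mg/L); at 0.1 mg/L DO they are oxygen-limited and largely wash out,
a plausible outcome of microaerobic operation.

DO is held at 0.1 mg O2/L by a PI controller on the air flow
(anti-windup: the integral freezes while the output saturates), with
kLa = α·(Q_air/V)^β (α = 40, β = 0.8 — a power-law stand-in for the
published aeration correlation, chosen to give kLa ≈ 3 1/h at the baseline
air flow). Infeasible control (demand above the air-flow bound with DO
below set-point) is flagged, never silent. The SOB sulfide capacity
(q1 = 42 g S/g COD/d with K1 = 0.35 g S/L) was chosen so that (i) SOB
persist against hydraulic washout at the sulfide level the UASB actually
delivers (≈1 g S/L at steady state) and (ii) the recovered-biosulfur share
of the absorbed sulfur lands near the reported ≈54% (the model yields
0.6–0.67 across the calibrated baseline; the suite asserts the 0.4–0.7
band). As in any chemostat, the residual sulfide equals the invasion
threshold: feeds below ≈0.8 g S/L cannot sustain the SOB population in
isolation — in the integrated loop the sulfide level settles above it by
construction.

## Plant loop, energy and inventory

The recirculation loop (220 m³/h at baseline, scaled with gas flow to
preserve the design G/L of 145.5) is torn at the absorber liquid inlet and
solved by fixed-point iteration with per-component secant acceleration far
from the fixed point and plain iteration near it (inner-solver noise makes
secant slopes meaningless once increments are small). Purely accumulating
species use their analytic purge balance C = a(1−p)/p. The purge (1% of
recirculation) and freshwater make-up (purge + evaporation into the gas
and the dryer) close the water balance exactly.

Heat integration: available heat is the sensible heat of the flue gas
between 400 °C (furnace outlet) and 80 °C (absorber inlet); demands are
process-water heating for the biological units (25 → 35 °C) and drying the
biosulfur cake from 65% to 10% moisture with 140 °C air. Both pass through
exchangers of limited effectiveness; at the baseline the demand exceeds
what the exchangers transfer, so the utilized fraction equals the
effectiveness, which `calibrate_energy_recovery()` pins to the reported
71.1%. The chemical scrubber has no heating demand and recovers 0%.

Electricity lines are computed from P = ρgQH/η (pumps) or Q·Δp/η
(blowers) with flows from the model and heads/pressure rises fitted once
to the published annual energies (e.g. 19.33 m for the 220 m³/h
recirculation duty at η = 0.65 reproduces 156,210 kWh/yr); they are fitted
constants, documented as such, not derived sizings. `build_inventory()`
assembles the full annualized exchange table — resources positive,
byproducts (biogas, sulfur) negative, scenario-specific zero lines
honored — and refuses non-converged simulations.

## Assessment layer

`characterize()` multiplies the inventory by a characterization-factor
table (18 midpoint categories); licensed database factors cannot be
shipped, so `generate_fixtures()` writes deterministic synthetic tables
keyed to the inventory line names (positive log-normal factors, seeded),
plus normalization factors and the published 2021 unit prices. Absolute
impact scores under synthetic factors are meaningless by construction;
everything structural — linearity, avoided-impact signs, normalization,
ranking, ≥95% coverage selection with GWP force-included, RIR classes at
±0.5 (boundaries are "comparable") — is exercised and tested. RIR with
net-avoided (negative) categories can leave [−1, 1]; it is flagged, not
clamped.

Costing uses quantity × unit price for every priced inventory line; the
volumetric wastewater price (7.23 €/m³) refers to the 50 km disposal
distance and therefore scales with the transport burden, which reproduces
the published disposal cost and makes distance a cost driver. Where the
published cost basis is not reproducible as quantity × price (several
line items are not), `reference_cost_summary()` carries the printed lines
and the cashflow/NPV/breakeven machinery runs on either basis. NPV
discounts 20 years at 1.5% with the investment undiscounted at year 0;
for an all-negative treatment line the IRR is undefined (reported as `NA`)
and the cumulative present value is the discount-rate sensitivity tool.
The breakeven surface rescales the carbon-source cost line with the
glycerol price and the biogas revenue (byproduct earnings minus the
sulfur revenue) with the gas price, anchored at the 520 €/t and
68.9 €/MWh market point.

## Sweeps

`sweep_2d()` re-runs the full pipeline per grid cell over gas flow ×
inlet SO2 or purge fraction × distance, warm-starting each scenario from
the neighboring cell (the loop solves a fixed point, so warm starts change
nothing but time). Reactor volumes, the recirculation loop and the
volume-proportional share of the bioscrubber investment scale with the
treated gas flow (constant retention times; the chemical-scrubber
investment is size-insensitive at this scale). Cell failures are recorded
with diagnostics and the sweep continues.

## Problem sizes and numerical choices

The shipped defaults — 5 absorber stages, 10 UASB tanks, chunked `lsoda`
(rtol 1e-8 to 1e-9) with Newton polishing to a relative stationarity of
1e-8 1/d, loop tolerance 1e-5 on the tear stream, 3×3 sweep grids in the
examples — were chosen so a full calibrated baseline resolves in a couple
of minutes on a single core while conservation audits still close to
1e-6 and better. Conservation is checked as in − out − accumulation over
the converged state, where accumulation uses the final derivatives, so the
audit verifies the consistency of the stoichiometry, transfer terms and
unit conversions rather than the integrator's step error.

## What the synthetic setup does and does not show

Passing tests demonstrate that the solvers honor their contracts
(closed forms, conservation, control set-points, monotonicities), that the
calibration procedure reproduces the published anchors (59.3/59.9% SO2
removal, 71.1% heat recovery, 0.3 g/L effluent sulfate) from one scalar
each, and that the assessment algebra is exact. They do not validate the
default kinetic parameters against laboratory data (the original
calibration data are not published in reusable form), nor absolute impact
scores (synthetic factors), nor the published NPV cells, which are not
reproducible from the printed cashflows and discount rate under any
standard convention — the package asserts the discounting formula's
self-consistency instead. Known limitations worth keeping in mind:
sulfide stripping in the absorber and H2S in the oxidation off-gas are
not modeled; carbon is not elementally balanced; the caustic demand of
the bioscrubber is nearly zero in this model (the biological units
regenerate alkalinity), which is directionally consistent with the
reported reduction in caustic use but far below the published bioscrubber
NaOH tonnage — the two published statements disagree with each other, and
this model takes the charge balance's side.
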