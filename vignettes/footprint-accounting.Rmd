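---
title: "Water and land footprint accounting for livestock: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water and land footprint accounting for livestock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoofprint)
```

## The accounting model

`hoofprint` is an accounting identity, not a statistical fit. For each cell
of the index space — animal category $a$ (cattle/shoats/camel × dairy/meat,
camel meat excluded), production system $s$ (arid, semi-arid, humid),
scenario (BAU, SDP, V2030) and year $t \in 2005..2040$ — it chains five
deterministic steps:

1. **Feed intake.** $Feed_{a,s} = FCR_{a,s} \cdot P_{a,s} / 1000$ tonnes of
   dry matter per animal per accounting period, from the feed conversion
   ratio (kg DM per kg product) and per-animal output (kg). The accounting
   period is one calendar year for dairy animals and lifetime-to-slaughter
   for meat animals, booked in the slaughter year — this matches a
   per-animal basis without modelling cohort age structure.
2. **Diet allocation.** Intake splits over four feed classes — pasture
   (incl. hay and silage), planted forage, crop residues, concentrates — by
   system- and category-specific basket fractions that sum to one.
   Allocation conserves dry matter exactly.
3. **Water footprint.** $WF = \sum_p Feed_p \, wf_p + WF_{drink} +
   WF_{service}$ (m³/animal). Feed water splits into green (soil moisture
   transpired by the crop or sward) and blue (irrigation) components carried
   as separate input columns. Drinking and service water are assigned
   entirely to blue water: they are abstractions of ground/surface water
   withdrawals. No grey-water term is carried.
4. **Land footprint.** $LF = \sum_p Feed_p / Y_p$ (ha/animal), with feed
   yield $Y_p$ in t DM/ha. Pasture accrues to grazing land, the other three
   classes to cropland; the land class is a property of the feed type, not
   of the consuming animal, because the split follows where the feed is
   grown. Housing and feed-storage land are excluded.
5. **Productivity and aggregation.** $WP = PO/WF$ (kg/m³), $LP = PO/LF$
   (kg/ha); per-tonne footprints are the per-animal values divided by
   output in tonnes, so $WP \times WF/\text{kg} = 1$ identically. Totals
   scale per-animal quantities by head counts and sum over categories and
   systems, per scenario × year × commodity (milk/meat). Productivities are
   computed from total water (green+blue) and total land
   (grazing+cropland); the components are emitted alongside for reporting.

Structural zeros are first-class: dairy shoats and dairy camels do not occur
in the humid system, so those cells carry zero herd and zero system share by
validation, and contribute nothing to any sum. Keeping the full cartesian
index with explicit zero masks (rather than ragged tables) is what makes the
conservation checks — allocation sums to intake, systems sum to the national
herd, green+blue = total, grazing+cropland = total — well defined everywhere.

## The projection layer

National herd and per-animal yield trajectories follow compound growth,
$x_t = x_0 (1+r)^{t-t_0}$, evaluated in closed form on an annual grid (no
iterative accumulation, hence no drift), and the national herd is split
across systems by fixed shares. This is a deliberately transparent stand-in
for the global economic model that produces such projections in the source
literature: footprint accounting consumes only the shape of those
trajectories, and multiplicative end-to-end changes ("doubles",
"quadruples") are exactly what compound growth parameterizes. Two
simplifications are documented rather than hidden:

- **Shares are constant over time.** The share tables are parameterized by
  (category, scenario) and could differ per scenario, but no time-varying
  mechanism is modelled; the default calibration uses the same shares for
  all scenarios.
- **FCR carries no year index.** Scenario-specific FCRs encode management
  improvements *between* scenarios, as data rather than code branches, but
  within a scenario the FCR of a cell is constant over time.

The second simplification has a consequence worth spelling out: the land
footprint per tonne of a single cell, $FCR \cdot \sum_p b_p / Y_p$, is
time-constant within a scenario, and the per-tonne *water* footprint of a
cell declines over time only through the drinking/service term being diluted
by growing per-animal output. Declining commodity-level per-tonne footprints
therefore arise from **composition**: production shifts toward
feed-efficient categories, pulling the production-weighted mean down. The
paperlike calibration makes this mechanism airtight rather than incidental —
in every scenario, category-mean per-tonne footprints are ordered inversely
to category production-growth rates (cattle dairy < camel < shoats for milk;
shoats < cattle for meat), and a weighted mean whose weights shift toward
the smaller values is monotone decreasing for *any* starting weights. The
per-tonne decline asserted in the test suite is thus a structural property
of the calibration, not a numerical accident.

## The synthetic generator

No parameter table used by studies of this system (FCRs, feed water
footprints, feed yields, diet baskets, drinking/service allowances, system
shares, base herds) is openly machine-readable, so the generator fabricates
them. Calibration `"paperlike"` is deterministic and pattern-matched to the
qualitative structure of the Kenyan system, never to unpublished values:

- Pasture dominates arid and semi-arid diets (75–85%); the concentrate
  share peaks in the humid dairy diet (15%); pasture consumes green water
  only.
- Dairy FCRs of 1.6–3.6 kg DM/kg milk and meat FCRs of 45–70 kg DM/kg
  carcass (whole-herd overhead folded in, as FCR-based accounting does),
  with SDP 3% and V2030 15% below BAU, encoding the scenarios' breed,
  feeding and range-management assumptions.
- Shoat-meat FCR is exactly cattle-meat FCR / 3.5 with identical baskets,
  pinning the shoat/beef water-productivity ratio near 3.5 in every system;
  drinking/service allowances (order-of-magnitude placeholders, e.g. 9 m³
  drinking + 2.5 m³ service per dairy cow per year) are kept small enough
  relative to feed water that the ratio stays inside 3–4 at every year.
- Growth multiples 2005→2040: the V2030 camel-dairy herd quadruples exactly
  ($r = 4^{1/35}-1$); camel yields never improve in any scenario; dairy
  shoat herds decline slightly while their yields improve; total milk
  production multiplies by 4 (V2030), 2.00 (BAU) and 2.04 (SDP), and total
  meat by 4 / 2.30 / 2.37, hit *exactly* by solving the cattle production
  multiple in closed form given the other categories' fixed multiples, then
  splitting production growth into herd growth (fixed per scenario) and
  yield growth (the remainder).
- Base herds (3.5M dairy + 1.0M slaughter cattle, 1.2M + 3.0M shoats, 0.4M
  camels) and yields (e.g. 250/450/1800 kg milk per cow per year across
  arid/semi-arid/humid) are round numbers at nationally plausible orders of
  magnitude.

Calibration `"random"` multiplies every positive parameter by a unit-mean
lognormal factor (CV `noise_cv`, default 0.1) and renormalizes baskets and
shares; zeros (structural shares, pasture blue water) stay zero. Each table
draws from its own sub-stream derived from the single seed by fixed offsets,
so any table can be regenerated independently and bitwise-identically;
generation saves and restores the caller's RNG state.

What passing tests on these inputs shows — and does not show: the test suite
proves the *arithmetic* (equation fidelity against scalar loop oracles at
1e-12 relative, conservation at 1e-9, scale invariance, monotonicity,
determinism) and the *generator's self-consistency* with the qualitative
patterns above. It does not validate the placeholder parameter values
against field data, and real systems have features the generator omits:
time-varying diets and FCRs, inter-annual climate variability, trade
feedbacks, cohort demography.

## Numerical choices

- Conservation and normalization assertions use relative tolerance 1e-9;
  equation-oracle comparisons use 1e-12 (pure floating-point reassociation
  headroom).
- CSV cells are written with `%.17g`, the shortest format guaranteeing that
  a written double re-reads bitwise-identically; this is what makes
  round-trip and byte-identity checks exact rather than approximate.
- Degenerate inputs are errors, not silent values: zero/negative FCR,
  output, or feed yield; footprints of zero (productivity undefined);
  baskets or shares off unity; NaN in a result table. A missing
  drinking/service-water table is the one forgiving case — it defaults to
  zero with a warning, since the feed term dominates and the table is
  genuinely optional in practice.
- Problem sizes: the full grid is 13 valid cells × 3 scenarios × 36 years =
  1404 rows; the oracle suite checks ≥ 1000 random cells; the entire test
  suite and the acceptance script each run in seconds on one CPU.

## Known limitations

Economic (per-dollar) productivities, grey water, comparisons of footprints
to basin-level water availability, climate-change effects on yields and
trade-equilibrium feedbacks are all out of scope. The accounting is linear
in herd size by construction; any density dependence (rangeland degradation
at high stocking rates, for instance) would break the scale-invariance
property that the linear model guarantees and the tests assert.
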