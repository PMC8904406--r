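# hoofprint

Water- and land-footprint accounting for ruminant milk and meat production
across heterogeneous production systems, with scenario projection to 2040.

## The problem

Growing demand for milk and meat in semi-arid countries is met largely by
expanding or intensifying livestock production, and the pressure lands on two
resources: freshwater and land. `hoofprint` quantifies that pressure. For
every animal category *a* (dairy/meat cattle, aggregated sheep-and-goats
"shoats", dairy camels), production system *s* (arid, semi-arid, humid) and
development scenario (BAU, SDP, V2030) over 2005–2040, it computes:

- **Feed demand** per animal: `Feed[a,s] = FCR[a,s] × P[a,s]`, the feed
  conversion ratio (kg feed dry matter per kg product) times per-animal
  product output, allocated across four feed classes (pasture, planted
  forage, crop residues, concentrates) by system-specific diet baskets.
- **Water footprint** per animal (m³):
  `WF[a,s] = WF_feed + WF_drink + WF_service`, with
  `WF_feed = Σ_p Feed[p] · wf[p]`, split into **green** water (rain stored in
  soil, transpired by feed crops and pasture) and **blue** water (irrigation,
  drinking and servicing — ground/surface water).
- **Land footprint** per animal (ha): `LF[a,s] = Σ_p Feed[p] / Y[p]`, feed
  demand over feed yield, split into **grazing land** (pasture) and
  **cropland** (all other feed classes). Housing land is not counted.
- **Water and land productivity**: `WP = PO / WF` (kg product per m³) and
  `LP = PO / LF` (kg per ha) — the inverses of the per-unit footprints — plus
  herd-level totals of production, water and land use by scenario, year and
  commodity.

National herds are split across the three systems by fixed shares, and herd
and yield trajectories follow compound growth rates per scenario — a
transparent stand-in for the economic-model layer that drives such
projections. Because the parameter tables underlying published studies of
this kind are not openly machine-readable, the package ships a seeded
synthetic generator with a `paperlike` calibration (pattern-matched to the
qualitative structure of the Kenya system: pasture-dominated dry-land diets,
green-water dominance, shoat meat 3–4× as water-productive as beef, camel
dairy herds quadrupling under V2030, milk production quadrupling under V2030
and doubling under BAU/SDP) and a `random` calibration for stress-testing
the arithmetic.

## Worked example

```r
library(hoofprint)

spec   <- synthetic_spec(seed = 1, calibration = "paperlike")
params <- generate_parameters(spec)
proj   <- generate_projection(spec)$projection
run    <- livestock_footprint(params, proj)
summary(run)
```

```
Accounting horizon: 2005 - 2040 

Production multiples 2005->2040 and per-tonne footprints:
  BAU    meat  x2.30   WF/t   42114 ->   41128 m3   LF/t  35.89 ->  35.12 ha
  BAU    milk  x2.00   WF/t    1210 ->    1197 m3   LF/t   0.63 ->   0.62 ha
  SDP    meat  x2.37   WF/t   40855 ->   39835 m3   LF/t  34.82 ->  34.02 ha
  SDP    milk  x2.04   WF/t    1174 ->    1161 m3   LF/t   0.61 ->   0.60 ha
  V2030  meat  x4.00   WF/t   35816 ->   35276 m3   LF/t  30.51 ->  30.13 ha
  V2030  milk  x4.00   WF/t    1030 ->    1011 m3   LF/t   0.53 ->   0.52 ha

Water productivity range: 0.0131 - 1.1422 kg/m3
Land productivity range:  12.3 - 2852.0 kg/ha
Green share of total water footprint: 96.2%
```

Reading it: milk production doubles by 2040 under business-as-usual and
quadruples under the V2030 plan; every tonne of milk needs ~1000–1200 m³ of
water (≈96% of it green water embedded in feed), and per-tonne footprints
fall over time as productivity gains and herd composition shift production
toward more feed-efficient animals. `run$footprints`, `run$productivity` and
`run$totals` hold the cell-level tables; `plot(run, product = "milk")` draws
the per-tonne footprint and productivity trajectories;
`write_footprint_tables(run, "out/")` writes tidy long CSVs.

A complete input directory (parameter CSVs + scenario JSONs) can be
materialized and read back with

```r
generate_inputs(seed = 1, calibration = "paperlike", out = "inputs/")
params <- read_parameter_bundle("inputs/")
```

or from the shell via `Rscript inst/scripts/generate_inputs.R --seed 1
--calibration paperlike --out inputs/`.

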