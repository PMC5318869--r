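---
title: "Methods: simulating crop water use over shallow groundwater"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating crop water use over shallow groundwater}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shallowcrop)
```

## The problem and the model

Where the water table sits 1–4 m below an irrigated field, capillary rise
supplies part of crop evapotranspiration, and deficit irrigation can
exploit it. `shallowcrop` couples three daily modules to quantify that
exchange: a four-zone soil water balance, an EPIC-style crop model, and a
canopy/moisture actual-ET module. This vignette records the model
equations as implemented, the defaults and why they were chosen, what the
synthetic weather generator does and does not emulate, and the numerical
and design decisions that were genuinely open.

### Soil column

The profile is split into the actual root zone (zone 1, growing from 10 cm
to `rd_mx` = 90 cm), the rest of the potential root zone (zone 2), a
transmission zone, and the saturated zone. Zones 1+2 form a single
Thornthwaite–Mather store of capacity $S_{fc} = 10\,\theta_{fc}\,rd_{mx}$
mm. On days when infiltration meets or exceeds the ET withdrawal the store
fills, surplus above $S_{fc}$ percolates, and the accumulated potential
water loss (APWL) is reset consistently with the new storage; on drier
days APWL grows by the shortfall and storage follows
$S = S_{fc} e^{-APWL/S_{fc}}$. Thornthwaite–Mather bookkeeping was
published as a monthly procedure; it is applied here at the daily step,
using the exponential-storage form exactly. Because the exponential
realises *less* withdrawal than demanded, the day's soil evaporation and
transpiration are rescaled to the realised total — this is what lets the
ledger

$$\text{rain} + \text{irrigation} + \text{capillary} - E - T -
\text{percolation} = \Delta S$$

close to 1e−9 mm every day (a tested invariant, not an approximation).

The transmission zone carries no storage: percolation reaches the water
table the same day. This is the simplest reading consistent with a column
model that names no zone-3 state variables, and it makes recharge events
immediately visible in the simulated water table.

### Capillary rise

Upward flux is capped by the steady-state limiting rate for the
conductivity family $K(h) = k_s/(1 + (\alpha h)^C)$. Rather than the
asymptotic power law $q_{max} = A\,k_s/(\alpha d)^C$ with tabulated
$A(C)$, the implementation solves the exact depth–flux relation

$$d = \frac{(\pi/C)\csc(\pi/C)}{\alpha}\;
      \frac{m^{-1/C}}{1+\beta},\qquad
      \beta = q/k_s,\; m = \frac{\beta}{1+\beta}$$

for $\beta$ by root finding. The two agree in the deep-table limit — the
closed form reproduces the tabulated constants $A(2)=2.46$, $A(3)=1.76$,
$A(4)=1.52$ exactly as $((\pi/C)\csc(\pi/C))^C$ — but at shallow depths
the power law overshoots a numerical steady-Richards integration by tens
of percent, while the exact solution matches it to machine precision.
The test suite keeps an independent numerical oracle (quadrature of the
suction profile plus root inversion) and requires 10% agreement across
twenty loam depths; in practice agreement is ~1e−10.

Capillary rise is demand-limited by the receiving zone's field-capacity
deficit plus any unmet ET, supply-limited by the Gardner rate, zero when
the receiving zone is at field capacity, and mutually exclusive with
percolation on any day. The `depth_gap` driving the Gardner rate is
measured from the bottom of the potential root zone (90 cm), because that
plane is where the seasonal groundwater contribution is evaluated.

### Water table

The table obeys specific-yield bookkeeping,
$\Delta gwd = (q_{up} - (1-dp)\,R)/(10\,m_f)$ cm, where $R$ is same-day
recharge and `dp` is the fraction of percolation lost below the simulated
column. `dp` defaults to 0; it is interpreted as a deep/lateral seepage
fraction because only by acting on the groundwater balance can it matter
to water-table dynamics. The table is floored at the potential root-zone
bottom (90 cm): a rise above that plane is absorbed as stored saturation
and logged, never propagated into the root-zone bookkeeping.

### Crop

Standard EPIC forms: daily heat units $(\bar T - t_b)^+$ accumulate into
the heat-unit index $HUI$; leaf area grows by increments of
$LAI_{mx}\,\Delta huf\,\sqrt{w_s}$ where
$huf(h) = h/(h + e^{l_1 - l_2 h})$ with $(l_1, l_2)$ solved from the
anchors $huf(0.15) = 0.05$, $huf(0.50) = 0.95$ (giving
$l_1 = 3.055$, $l_2 = 13.39$); after the decline point (`dlai` = 0.8 of
PHU) leaf area falls as $LAI_{peak}((1-HUI)/(1-d_{lai}))^{ad}$, a curve
continuous at the crossover by construction. Biomass accumulates as
$0.001\,be \cdot 0.5\,R_s(1-e^{-0.65\,LAI}) \cdot \min(w_s, t_s)$ with
the sinusoidal temperature factor $t_s$; roots deepen linearly in heat
units from 10 cm, reaching 90 cm at $HUI = 0.4$; yield is biomass times
the harvest index, scaled by $0.5 + 0.5\,\bar w_s$ over the reproductive
window $HUI \in [0.45, 0.80]$. The square-root stress adjustment on leaf
growth, the root parameters, and the reproductive window are EPIC
conventions exposed in `crop_params()` for calibration. Nutrient stress
is fixed at 1 (fertiliser non-limiting): the scenario engine varies only
water, and fertiliser entries in schedules are accepted but ignored.

### Actual evapotranspiration

Reference ET is daily FAO-56 Penman–Monteith (soil heat flux 0, actual
vapour pressure from mean relative humidity, shortwave from sunshine via
the Angström formula with a = 0.25, b = 0.50 when radiation is not
supplied). Potential crop ET applies a leaf-area crop coefficient
$k_c(LAI) = 1 + (k_{c,mx}-1)\min(LAI/LAI_{ref}, 1)$, defaults
$k_{c,mx} = 1.2$, $LAI_{ref} = 3$. The Beer's-law split
($k_{beer} = 0.5$) gives potential transpiration and soil evaporation;
each is reduced linearly with moisture — evaporation from air-dry to
field capacity, transpiration from wilting point to
$\theta_{crit} = \theta_{wp} + p(\theta_{fc} - \theta_{wp})$, $p = 0.5$.
The transpiration factor is the crop's water-stress factor. Evaporation
is judged on zone-1 moisture, transpiration on the current root zone
(zone 1); both withdrawals enter the Thornthwaite–Mather step as one
lumped demand, and zone moistures are rescaled proportionally. The
$k_c(LAI)$ form (rather than raw reference ET) was adopted so that
seasonal potential ET of a full canopy sits plausibly above reference ET,
consistent with a full-irrigation schedule amounting to roughly half of
potential ET.

### Daily operation order

Within a day: (1) reference and potential ET from *yesterday's* LAI;
(2) infiltration = rain + irrigation (no runoff — the reference
experiment is a lysimeter with no lateral loss); (3) ET partition and
moisture reduction; (4) Thornthwaite–Mather step, yielding percolation;
(5) capillary rise as the residual filler, never on a percolation day;
(6) water-table update; (7) crop advance and root-zone growth (which
conserves stored water exactly). The ordering — ET before percolation
before capillary — is a fixed design choice: capillary rise acts as the
day's residual deficit filler, which matches its role of supplying water
when the column is below field capacity.

## Synthetic weather: the stated world

The generator emulates the arid Hetao growing season so the package
builds and tests without observed data: monthly mean temperatures follow
the first-harmonic annual cycle through −10.1 °C (January) and 23.8 °C
(July); daily means add bounded AR(1) noise (sd ≈ 2 °C, clipped at
±5 °C) and a diurnal half-range around 6 °C generated jointly so
tmax ≥ tmin always; rain is drawn as per-month Poisson event counts with
exponential depths and rescaled month-by-month so the season total equals
the configured 128 mm *exactly* and July–August carry 72/95 ≈ 76% of it
(the district's >70% monsoon concentration holds by construction);
sunshine, humidity and wind are drawn around arid-climate values, duller
and moister on rain days. Latitude 40.75° N and elevation 1040 m feed
the FAO-56 routine.

What it does **not** emulate: multi-day synoptic persistence, the 2007 or
2008 observed sequences, spring dust/cloud regimes, or any correlation
between temperature and rain beyond the wet-day adjustments. A green
structural test therefore establishes that the *model* reproduces the
published qualitative structure (monotonicities, near-constant WP, the
irrigation × depth interaction) under a climate like the one stated — not
that it reproduces the calibrated seasonal magnitudes, which depend on
the unpublished observed weather and calibrated parameters. For the same
reason the acceptance report's simulation-free targets are the published
worked-example productivity numbers, recomputed from the printed inputs.

## Defaults and tunables

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ms, mfc, mwp, md` | 0.45, 0.33, 0.13, 0.05 | cm³ cm⁻³ | representative loam, the district's root-zone texture |
| `mf` | 0.10 | — | loam specific yield; dominant control on water-table swings |
| `ks, alpha, C` | 25, 0.02, 3 | cm d⁻¹, cm⁻¹, — | loam conductivity set used by the Gardner solution |
| `dp` | 0 | — | closed lysimeter column; no deep loss |
| `tb, t0, phu` | 8, 25, 1700 | °C, °C, °C d | EPIC maize recommendations |
| `lai_mx, dlai, ad` | 6, 0.8, 1 | — | EPIC maize recommendations |
| `be, hi` | 30, 0.5 | kg ha⁻¹/MJ m⁻², — | EPIC maize recommendations |
| `rd_mx` | 90 | cm | maximum rooting depth measured in the reference experiment |
| `k_beer, p, kc_mx, lai_ref` | 0.5, 0.5, 1.2, 3 | — | canopy extinction and stress conventions of the ET formulation |
| `theta0, gwd0` | 0.3, 150 | cm³ cm⁻³, cm | reference experiment's initial conditions |

All are exposed through `soil_params()`, `crop_params()`, `et_params()`
and the JSON run configuration (`default_config()`, `read_config()`).

## Numerical choices

* Root finding for the Gardner flux is done in log(β) over ±700, so the
  solution is accurate from the saturated clamp down to fluxes ~1e−300;
  results clamp to [0, ks].
* APWL is recomputed from storage whenever storage changes outside the
  Thornthwaite–Mather step (capillary additions), keeping state on the
  drying curve.
* Moisture bound violations during proportional rescaling are clamped to
  [md, ms] with compensation in the other zone, conserving the total;
  genuine clips (storage below the air-dry equivalent) are logged as
  messages, never raised as errors, with a 1e−9 mm closure tolerance.
* Quantiles in the d-factor use linear interpolation of order statistics
  (R type 7).
* Ties and degenerate inputs: constant observations make NSE/R²
  undefined (NA with a warning — near-constant groundwater series are
  exactly where these statistics are known to mislead); zero observations
  make MRE undefined; unirrigated seasons make IWP missing (NA), not an
  error.

## Open design decisions, as resolved

* **Reference-station correction.** Reference ET in the source setting
  came from a station 8 km away; no local correction is stated, so none
  is applied.
* **Retention vs conductivity families.** The calibrated parameter list
  (α, C, ks) matches the Gardner conductivity family, so
  K(h) = ks/(1+(αh)^C) is used analytically even though retention curves
  were fitted with van Genuchten in the field characterisation; the two
  are not reconciled here either.
* **Column bottom.** The column below the saturated zone is closed (the
  lysimeter's no-flux bottom); `dp` exists to represent any leakage when
  the model is applied outside a lysimeter.
* **Ensemble construction for the d-factor** is unstated in the source
  methods; `ensemble_predictions()` samples each parameter uniformly
  within ±25% of its base value (the sensitivity range), 200 members by
  default, seeded.

## Known limitations

* Radiation-use efficiency (`be`) has no feedback path to ET in this
  equation set — biomass does not influence leaf area or stomatal demand
  — and the leaf-area crop coefficient saturates at `lai_ref` = 3. The
  published qualitative sensitivity ranking that puts `lai_mx` first for
  ET therefore does not emerge under the well-watered default scenario;
  the package's sensitivity tests assert the ranking for the leaf-area
  index instead, where it does hold.
* One soil texture for zones 1 and 2; no layering, hysteresis, freezing,
  salinity or nutrient cycling (the simulation window is the frost-free
  season and fertiliser is assumed non-limiting).
* Irrigation infiltrates fully on its day; no runoff or interception.
* The simulator is deterministic given its inputs; randomness enters only
  through weather generation and ensemble sampling, both seeded.

## What the tests compute

Every empirical statement above is backed by a test or the acceptance
script: daily/seasonal closure (1e−9/1e−6 mm), Gardner-vs-oracle
agreement, the Thornthwaite–Mather closed form, fit-statistics against a
brute-force oracle (1e−12), the structural scenario-grid properties on
seeded synthetic weather, and the worked-example productivity targets.
No other numbers are claimed.
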