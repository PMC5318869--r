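# shallowcrop

Daily crop–water simulation over a shallow, dynamic water table.

In many arid irrigation districts (the package's presets emulate the Hetao
district of Inner Mongolia) the groundwater table sits only 1–4 m below the
surface, and capillary rise from it can supply a substantial share of crop
water use. Irrigation scheduling that ignores this upward flux over-applies
water; measuring the flux directly is impractical. `shallowcrop` is for
agronomists and irrigation engineers who want to quantify that contribution
with a model that needs only routinely available inputs: daily weather, a
handful of soil hydraulic parameters, a crop parameter set and the
irrigation schedule.

## The model

Three coupled modules run on a daily time step over a four-zone soil
column (actual root zone, remaining potential root zone, transmission
zone, saturated zone):

* **Soil water.** The root-zone column (0–90 cm by default) is a
  Thornthwaite–Mather bucket of capacity S_fc = 10·θ_fc·rd_mx mm: wet-day
  surplus above S_fc percolates to the water table the same day; dry-day
  shortfalls accumulate potential water loss so storage follows
  S = S_fc·exp(−APWL/S_fc). When the column is below field capacity, water
  rises from the table at up to the Gardner steady-state limiting flux for
  K(h) = ks/(1+(αh)^C) — solved exactly, which reduces to the familiar
  q_max = A·ks/(αd)^C (A = 2.46, 1.76, 1.52 for C = 2, 3, 4) as the table
  deepens. The table itself moves by specific yield:
  Δgwd = (capillary − (1−dp)·recharge)/(10·mf) cm.
* **Crop growth (EPIC-style).** Heat units (T̄ − tb)⁺ accumulate toward
  maturity (PHU); leaf area follows the sigmoid heat-unit factor
  huf(h) = h/(h + exp(l1 − l2·h)) up to lai_mx, declining after the
  heat-unit fraction `dlai`; biomass grows by radiation-use efficiency,
  ΔB = 0.001·be·PAR·min(ws, ts); yield = biomass × harvest index, with the
  harvest index scaled by (0.5 + 0.5·w̄s) over the reproductive window.
* **Actual ET.** FAO-56 Penman–Monteith reference ET is scaled by a
  leaf-area crop coefficient to potential ET, split into soil evaporation
  and transpiration by Beer's law (k = 0.5), and each component is reduced
  linearly by moisture: evaporation between air-dry and field capacity,
  transpiration between wilting point and a critical moisture. The
  transpiration reduction is the water-stress factor `ws` fed back to the
  crop.

Every day closes its water ledger exactly (tested to 1e−9 mm):
rain + irrigation + capillary − E − T − percolation = ΔS.

A scenario engine crosses nine deficit-irrigation treatments (D0 = the
full 360 mm experimental schedule … D8 = rainfed) with seven initial
water-table depths (1–4 m) and reports yield, ET, water productivity
(WP = 100·Y/ET, kg/m³), irrigation water productivity (IWP = 100·Y/I) and
the net water-table flux. An evaluation toolkit supplies the calibration
statistics (MRE, RMSE, NSE, R², regression-through-origin b),
one-at-a-time parameter sensitivity, and d-factor ensemble uncertainty.

## Worked example

```r
library(shallowcrop)

# one season: full irrigation, water table initially at 1.5 m,
# synthetic Hetao weather from seed 1
spec <- scenario_spec(gwd0 = 150, irrigation_schedule("D0", 2007), seed = 1)
res  <- run_season(spec)
print(res)
#> season result: 158 days
#>   yield 13.47 t/ha, ET 721 mm, PET 837 mm
#>   rain 128.0 mm, irrigation 360.0 mm, net water-table flux +243.9 mm
#>   WP 1.87 kg/m3, IWP 3.74 kg/m3
```

158 days run from 20 April to 24 September. The crop transpires 721 mm
while rain plus irrigation supply only 488 mm: the balance (+244 mm net
water-table flux) is capillary rise mined from the shallow groundwater,
which is why the season shows no water stress and yield reaches its
unstressed ceiling.

```r
grid <- run_scenario_grid(seed = 1, gwd_levels = c(100, 250, 400),
                          treatments = c("D0", "D4", "D8"))
print(grid, digits = 3)
#>   treatment gwd0     Y  ET   I   WP  IWP wf_net wf_et
#> 1        D0  100 13.47 737 360 1.83 3.74  272.3 0.369
#> 2        D0  250 13.46 691 360 1.95 3.74  187.4 0.271
#> 3        D0  400 12.65 611 360 2.07 3.51   91.9 0.150
#> 4        D4  100 13.47 688 180 1.96 7.48  356.4 0.518
#> 5        D4  250 13.46 626 180 2.15 7.48  259.6 0.415
#> 6        D4  400 11.95 522 180 2.29 6.64  145.7 0.279
#> 7        D8  100 12.90 567   0 2.27   NA  365.9 0.645
#> 8        D8  250  9.51 478   0 1.99   NA  260.4 0.545
#> 9        D8  400  7.16 372   0 1.92   NA  147.5 0.397
```

The grid shows the structural results the model is built to expose: ET
falls as the water table deepens at fixed irrigation; halving or removing
irrigation barely costs yield over a 1 m table (capillary rise makes up
the difference — at 1 m rainfed, 65% of ET is groundwater) but halves it
over a 4 m table; WP stays within a narrow band while IWP rises steeply
as irrigation is cut; IWP is undefined (NA) for the rainfed treatment.

A command-line entry point with the same workflows is installed at
`inst/cli/shallowcrop` (`run`, `grid`, `fixture`, `eval`, `config`).

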