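flux_closure <- function(fx) {
  fx$rain + fx$irrigation + fx$capillary - fx$soil_evap -
    fx$transpiration - fx$percolation - fx$d_storage
}

test_that("a day with no forcing at equilibrium is a fixed point", {
  wday <- data.frame(date = as.Date("2007-07-15"), tmax = 20, tmin = 20,
                     radiation = 0, rh = 100, wind = 0, rain = 0)
  sstate <- soil_state(loam$mfc, loam$mfc, rd = 30, rd_mx = 90,
                       gwd = 1000, loam)
  cstate <- crop_state(maize)
  out <- step_day(sstate, cstate, wday, et0 = 0, solar = 0, irr = 0,
                  soil = loam, crop = maize)
  fx <- out$flux
  expect_equal(unlist(fx[c("soil_evap", "transpiration", "percolation",
                           "capillary", "d_storage", "d_gwd")]),
               c(soil_evap = 0, transpiration = 0, percolation = 0,
                 capillary = 0, d_storage = 0, d_gwd = 0))
})

test_that("every random day closes its water ledger and never mixes fluxes", {
  set.seed(11)
  w <- random_weather(400, seed = 11)
  et0 <- et0_penman_monteith(w, hetao)
  solar <- solar_radiation(w, hetao)
  for (i in seq_len(nrow(w))) {
    ms <- mid_state(theta1 = runif(1, loam$md + 0.01, loam$ms),
                    theta2 = runif(1, loam$md + 0.01, loam$ms),
                    rd = runif(1, 10, 90), gwd = runif(1, 90, 500))
    irr <- if (runif(1) < 0.1) runif(1, 5, 100) else 0
    out <- step_day(ms$soil, ms$crop, w[i, ], et0[i], solar[i], irr,
                    loam, maize)
    expect_lt(abs(flux_closure(out$flux)), 1e-9)
    expect_true(out$flux$capillary * out$flux$percolation == 0)
    expect_gte(out$flux$capillary, 0)
    expect_gte(out$flux$percolation, 0)
  }
})

test_that("irrigation beyond capacity percolates and shuts off capillary rise", {
  wday <- data.frame(date = as.Date("2007-06-26"), tmax = 30, tmin = 16,
                     sunshine = 10, rh = 40, wind = 2, rain = 0)
  ms <- mid_state(theta1 = 0.30, theta2 = 0.30, rd = 60, gwd = 150)
  out <- step_day(ms$soil, ms$crop, wday,
                  et0_penman_monteith(wday, hetao),
                  solar_radiation(wday, hetao), irr = 97.5,
                  soil = loam, crop = maize)
  expect_gt(out$flux$percolation, 0)
  expect_equal(out$flux$capillary, 0)
  expect_lt(out$soil$gwd, 150)          # recharge raised the table
})

test_that("a season conserves water and is deterministic", {
  spec <- scenario_spec(150, irrigation_schedule("D0", 2007), seed = 5)
  res <- run_season(spec)
  res2 <- run_season(spec)
  expect_equal(res$daily, res2$daily)

  fx <- res$daily
  expect_lt(max(abs(flux_closure(fx))), 1e-9)
  dS <- sum(fx$d_storage)
  lhs <- res$rain_total + res$irrigation_total + sum(fx$capillary)
  rhs <- dS + res$et_total + sum(fx$percolation)
  expect_lt(abs(lhs - rhs), 1e-6)
  expect_equal(res$et_total, sum(fx$soil_evap + fx$transpiration))
  expect_equal(res$wf_net, sum(fx$capillary - fx$percolation))
  expect_equal(res$wp, 100 * res$yield / res$et_total)
})

test_that("a deep water table degenerates to a Thornthwaite-Mather bucket", {
  sp <- function(gwd, tr) scenario_spec(gwd, irrigation_schedule(tr, 2007),
                                        seed = 3)
  deep <- run_season(sp(3000, "D8"))
  deeper <- run_season(sp(5000, "D8"))
  expect_lt(sum(deep$daily$capillary), 0.5)
  # the two deep runs differ at most by the residual capillary trickle
  expect_lt(max(abs(deep$daily$storage - deeper$daily$storage)),
            sum(deep$daily$capillary) + 1e-9)
  # with full irrigation over a 10 m table the season is net recharge
  expect_lte(run_season(sp(1000, "D0"))$wf_net, 0)
})

test_that("recharge events become rarer as the initial table deepens", {
  n_events <- vapply(c(150, 200, 300, 400), function(g) {
    res <- run_season(scenario_spec(g, irrigation_schedule("D0", 2007),
                                    seed = 1))
    sum(res$daily$percolation > 0)
  }, numeric(1))
  expect_true(all(diff(n_events) <= 0))
  expect_gt(n_events[1], n_events[4])
})

test_that("a bare-soil run reduces to evaporation only", {
  nocrop <- crop_params(lai_mx = 1e-9, be = 1e-9)
  res <- run_season(scenario_spec(200, irrigation_schedule("D8", 2007),
                                  seed = 2), crop = nocrop)
  expect_lt(sum(res$daily$transpiration), 1e-6)
  expect_gt(sum(res$daily$soil_evap), 0)
  expect_equal(res$daily$pet, res$daily$et0, tolerance = 1e-6)
})

test_that("productivity metrics convert units as published", {
  expect_equal(water_productivity(12.44, 554), 2.24, tolerance = 0.005)
  expect_equal(water_productivity(12.43, 529), 2.35, tolerance = 0.005)
  expect_equal(water_productivity(0, 400), 0)
  expect_error(water_productivity(10, 0), "positive")

  expect_equal(irrigation_water_productivity(12.44, 360), 3.46,
               tolerance = 0.005)
  expect_equal(irrigation_water_productivity(9.29, 90), 10.32,
               tolerance = 0.005)
  expect_true(is.na(irrigation_water_productivity(10, 0)))
})

test_that("irrigation schedules scale the experimental events exactly", {
  d0 <- irrigation_schedule("D0", 2007)
  expect_equal(sum(d0$depth), 360)
  expect_equal(d0$depth, c(97.5, 90, 97.5, 75))
  expect_equal(format(d0$date, "%m-%d"),
               c("06-26", "07-17", "08-01", "08-22"))
  expect_equal(sum(irrigation_schedule("D4", 2007)$depth), 180)
  expect_equal(sum(irrigation_schedule("D7", 2007)$depth), 72)
  expect_equal(nrow(irrigation_schedule("D8", 2007)), 0)
  expect_error(irrigation_schedule("D9"), "unknown")
})

test_that("the lysimeter fixture reproduces the experimental setup", {
  f1 <- make_lysimeter_fixture(150, year_seed = 4)
  f2 <- make_lysimeter_fixture(150, year_seed = 4)
  expect_identical(f1, f2)
  expect_equal(sum(f1$irrigation$depth), 360)
  expect_equal(f1$theta0, 0.3)
  expect_equal(sum(f1$weather$rain), 128, tolerance = 1e-9)
  d4 <- make_lysimeter_fixture(200, year_seed = 4, treatment = "D4")
  expect_equal(sum(d4$irrigation$depth), 180)
  expect_error(make_lysimeter_fixture(120, 1), "150")
})

test_that("the scenario grid reports the published column set", {
  g <- run_scenario_grid(gwd_levels = c(150, 300),
                         treatments = c("D0", "D8"), seed = 1)
  expect_equal(nrow(g), 4)
  expect_true(all(c("treatment", "gwd0", "Y", "ET", "I", "WP", "IWP",
                    "wf_net", "wf_et") %in% names(g)))
  expect_true(all(is.na(g$IWP[g$treatment == "D8"])))
  expect_true(all(!is.na(g$IWP[g$treatment == "D0"])))
  expect_equal(g$I[g$treatment == "D0"], c(360, 360))
})
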