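test_that("Gardner limiting flux honours its anchors and monotonicity", {
  expect_equal(gardner_max_flux(0, loam), 10 * loam$ks)
  expect_lt(gardner_max_flux(1e6, loam), 1e-6)

  d <- c(5, 20, 50, 80, 120, 200, 400, 800)
  q <- gardner_max_flux(d, loam)
  expect_true(all(diff(q) < 0 | q[-length(q)] == 10 * loam$ks))
  expect_true(all(q >= 0 & q <= 10 * loam$ks))

  # increasing in ks at fixed geometry
  q_lo <- gardner_max_flux(150, soil_params(ks = 10))
  q_hi <- gardner_max_flux(150, soil_params(ks = 40))
  expect_gt(q_hi, q_lo)

  expect_error(gardner_max_flux(-1, loam), "depth_gap")
})

test_that("Gardner flux agrees with the numerical steady-Richards oracle", {
  depths <- c(40, 60, 80, 100, 150, 250)
  for (d in depths) {
    got <- gardner_max_flux(d, loam)
    want <- gardner_oracle(d, loam$ks, loam$alpha, loam$C)
    expect_lt(abs(got - want) / want, 0.10)
  }
})

test_that("capillary rise is demand- and supply-limited and gated by field capacity", {
  st <- soil_state(0.25, loam$mfc, rd = 30, rd_mx = 90, gwd = 150, loam)
  expect_equal(capillary_rise(st, loam, 5)$flux, 0)  # zone 2 at capacity

  st2 <- soil_state(0.25, 0.20, rd = 30, rd_mx = 90, gwd = 200, loam)
  qmax <- gardner_max_flux(200 - 90, loam)
  supply <- capillary_rise(st2, loam, qmax + 5)
  expect_equal(supply$flux, qmax)
  demand <- capillary_rise(st2, loam, qmax / 2)
  expect_equal(demand$flux, qmax / 2)
  # flux lands in zone-2 storage
  expect_equal(storage_mm(demand$state) - storage_mm(st2), qmax / 2)
})

test_that("Thornthwaite-Mather bookkeeping matches its closed forms", {
  s_fc <- 10 * loam$mfc * 90
  at_fc <- soil_state(loam$mfc, loam$mfc, rd = 30, rd_mx = 90,
                      gwd = 300, loam)
  # equilibrium fixed point
  eq <- tm_step(at_fc, loam, 0, 0)
  expect_equal(storage_mm(eq$state), s_fc)
  expect_equal(eq$percolation, 0)

  # saturated excess percolates the same day
  wet <- tm_step(at_fc, loam, 40, 0)
  expect_equal(wet$percolation, 40)
  expect_equal(storage_mm(wet$state), s_fc)

  # 10 days of 5 mm/d unmet demand: S = S_fc exp(-50/S_fc)
  st <- at_fc
  withdrawn <- 0
  for (i in 1:10) {
    out <- tm_step(st, loam, 0, 5)
    withdrawn <- withdrawn + out$et_realized
    st <- out$state
  }
  expect_equal(storage_mm(st), s_fc * exp(-50 / s_fc), tolerance = 1e-9)
  # realised withdrawal equals the storage drop (balance closes)
  expect_equal(withdrawn, s_fc - storage_mm(st), tolerance = 1e-9)

  # wet branch is plain mass accounting below capacity
  dry <- soil_state(0.20, 0.20, rd = 30, rd_mx = 90, gwd = 300, loam)
  out <- tm_step(dry, loam, 12, 3)
  expect_equal(storage_mm(out$state) - storage_mm(dry), 9)
  expect_equal(out$percolation, 0)
  expect_equal(out$state$apwl, -s_fc * log(storage_mm(out$state) / s_fc))
})

test_that("water table moves by the specific-yield rule and floors at the root zone", {
  st <- soil_state(0.25, 0.25, rd = 30, rd_mx = 90, gwd = 200, loam)
  expect_equal(update_water_table(st, loam, 0, 0)$gwd, 200)
  # upward withdrawal deepens the table by upflux / (10 mf)
  s05 <- soil_params(mf = 0.05)
  expect_equal(update_water_table(st, s05, 0, 5)$gwd, 200 + 10)
  # recharge raises it, deep loss discounted
  sdp <- soil_params(mf = 0.10, dp = 0.2)
  expect_equal(update_water_table(st, sdp, 10, 0)$gwd, 200 - 8)
  # table may not rise above the potential root zone bottom
  shallow <- soil_state(0.25, 0.25, rd = 30, rd_mx = 90, gwd = 95, loam)
  expect_message(out <- update_water_table(shallow, loam, 100, 0),
                 "held at")
  expect_equal(out$gwd, 90)
})

test_that("root-zone growth conserves stored water", {
  st <- soil_state(0.20, 0.30, rd = 30, rd_mx = 90, gwd = 300, loam)
  expect_identical(grow_root_zone(st, 30), st)

  hom <- soil_state(0.25, 0.25, rd = 30, rd_mx = 90, gwd = 300, loam)
  g <- grow_root_zone(hom, 60)
  expect_equal(g$theta1, 0.25)
  expect_equal(g$theta2, 0.25)

  # depth-weighted annexation, hand-checked
  g2 <- grow_root_zone(st, 60)
  expect_equal(g2$theta1, 0.25)
  expect_equal(storage_mm(g2), storage_mm(st), tolerance = 1e-9)

  expect_error(grow_root_zone(st, 20), "shrink")
  expect_error(grow_root_zone(st, 95), "rd_mx")

  # property: conservation over random growth steps
  set.seed(31)
  for (i in 1:50) {
    th <- sort(runif(2, loam$md, loam$ms))
    rd <- runif(1, 5, 80)
    s <- soil_state(th[1], th[2], rd = rd, rd_mx = 90, gwd = 300, loam)
    g <- grow_root_zone(s, runif(1, rd, 90))
    expect_equal(storage_mm(g), storage_mm(s), tolerance = 1e-9)
  }
})
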