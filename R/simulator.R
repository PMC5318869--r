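#' Irrigation treatments of the scenario engine
#'
#' Named fractions of the experimental four-event schedule: D0 is the full
#' schedule (360 mm), D1..D7 scale every event by 4/5, 3/4, 2/3, 1/2, 1/3,
#' 1/4 and 1/5, and D8 applies no irrigation.
#'
#' @return named numeric vector of schedule fractions.
#' @export
treatment_fractions <- function() {
  c(D0 = 1, D1 = 4 / 5, D2 = 3 / 4, D3 = 2 / 3, D4 = 1 / 2,
    D5 = 1 / 3, D6 = 1 / 4, D7 = 1 / 5, D8 = 0)
}

#' Irrigation schedule for a treatment
#'
#' The experimental schedule applies 97.5, 90, 97.5 and 75 mm on 26 June,
#' 17 July, 1 August and 22 August (360 mm total); deficit treatments
#' scale every event by the treatment fraction. Schedules are keyed by
#' month/day and realised in the season's calendar year.
#'
#' @param treatment one of `names(treatment_fractions())`, or a numeric
#'   fraction in [0, 1].
#' @param year calendar year for the event dates.
#' @return data frame with columns `date` and `depth` (mm); zero-depth
#'   events are dropped (D8 returns zero rows).
#' @export
irrigation_schedule <- function(treatment = "D0", year = 2007) {
  f <- if (is.numeric(treatment)) treatment else {
    fr <- treatment_fractions()
    if (!treatment %in% names(fr)) stop("unknown treatment: ", treatment)
    fr[[treatment]]
  }
  stopifnot(f >= 0, f <= 1)
  sched <- data.frame(
    date = as.Date(paste0(year, c("-06-26", "-07-17", "-08-01", "-08-22"))),
    depth = c(97.5, 90, 97.5, 75) * f)
  sched[sched$depth > 0, , drop = FALSE]
}

#' Scenario specification
#'
#' Everything one season run needs beyond the parameter sets: initial
#' water-table depth and soil moisture, the irrigation schedule, the season
#' window, and the weather source (a weather data frame, or a seed from
#' which synthetic weather is generated at run time).
#'
#' @param gwd0 initial water-table depth, cm (> 0).
#' @param irrigation data frame `date`/`depth` (mm), e.g. from
#'   [irrigation_schedule()].
#' @param theta0 initial volumetric moisture of both zones (default 0.3).
#' @param start,end season window (defaults 20 April - 24 September).
#' @param weather optional weather data frame covering the season.
#' @param seed integer seed for synthetic weather when `weather` is NULL.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(gwd0, irrigation, theta0 = 0.3,
                          start = "2007-04-20", end = "2007-09-24",
                          weather = NULL, seed = 1L) {
  stopifnot(gwd0 > 0)
  if (nrow(irrigation) && any(irrigation$depth < 0))
    stop("irrigation depths must be >= 0")
  structure(list(gwd0 = gwd0, irrigation = irrigation, theta0 = theta0,
                 start = as.Date(start), end = as.Date(end),
                 weather = weather, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' One coupled day of the simulator
#'
#' Fixed operation order: (1) reference and potential ET from yesterday's
#' LAI; (2) infiltration = rain + irrigation; (3) ET partitioned by canopy
#' and reduced by moisture; (4) Thornthwaite-Mather accounting yields
#' percolation (and the realised withdrawal, to which soil evaporation and
#' transpiration are rescaled so the daily ledger closes exactly); (5)
#' capillary rise fills the remaining field-capacity deficit plus unmet ET
#' up to the Gardner limit, and never on a percolation day; (6) the water
#' table responds through the specific yield; (7) the crop advances and the
#' root zone deepens.
#'
#' @param sstate [soil_state()]. @param cstate [crop_state()].
#' @param wday one-row weather data frame.
#' @param et0 reference ET for the day, mm. @param solar MJ m-2 d-1.
#' @param irr irrigation applied today, mm.
#' @param soil [soil_params()]. @param crop [crop_params()].
#' @param etp [et_params()].
#' @return list `soil` (state), `crop` (state), `flux` (one-row data frame:
#'   rain, irrigation, soil_evap, transpiration, percolation, capillary,
#'   deep_loss, d_storage in mm; d_gwd in cm; plus ws and pet).
#' @export
step_day <- function(sstate, cstate, wday, et0, solar, irr,
                     soil, crop, etp = et_params()) {
  out <- .step_day_core(sstate, cstate, wday$rain, wday$tmax, wday$tmin,
                        et0, solar, irr, soil, crop, etp)
  out$flux <- as.data.frame(as.list(out$flux))
  out
}

# fast inner loop: flux as a named numeric vector
.flux_names <- c("rain", "irrigation", "soil_evap", "transpiration",
                 "percolation", "capillary", "deep_loss", "d_storage",
                 "d_gwd", "ws", "pet")

.step_day_core <- function(sstate, cstate, rain, tmax, tmin, et0, solar,
                           irr, soil, crop, etp) {
  stopifnot(irr >= 0, et0 >= 0)
  s0 <- storage_mm(sstate)
  gwd0 <- sstate$gwd
  lai_prev <- cstate$lai

  pet <- potential_et(et0, lai_prev, etp)
  inf <- rain + irr
  part <- partition_et(pet, lai_prev, etp)
  e_act <- actual_soil_evap(part$ep, sstate$theta1, soil)
  tr <- actual_transpiration(part$tp, sstate$theta1, soil, etp)
  demand <- e_act + tr$t

  tm <- tm_step(sstate, soil, inf, demand)
  sstate <- tm$state
  r <- if (demand > 0) tm$et_realized / demand else 0
  e_act <- e_act * r
  t_act <- tr$t * r

  cap <- 0
  if (tm$percolation <= 0) {
    dz2 <- sstate$rd_mx - sstate$rd
    theta_recv <- if (dz2 > 0) sstate$theta2 else sstate$theta1
    dz_recv <- if (dz2 > 0) dz2 else sstate$rd
    deficit <- max(0, (soil$mfc - theta_recv) * 10 * dz_recv)
    unmet <- max(0, part$pet - (e_act + t_act))
    cr <- capillary_rise(sstate, soil, deficit + unmet)
    sstate <- cr$state
    cap <- cr$flux
  }

  sstate <- update_water_table(sstate, soil, tm$percolation, cap)
  cstate <- crop_advance(cstate, crop, tmax, tmin, solar, tr$ws)
  sstate <- grow_root_zone(sstate, max(sstate$rd, min(cstate$rd,
                                                      sstate$rd_mx)))

  flux <- c(rain, irr, e_act, t_act, tm$percolation, cap,
            soil$dp * tm$percolation, storage_mm(sstate) - s0,
            sstate$gwd - gwd0, tr$ws, pet)
  names(flux) <- .flux_names
  list(soil = sstate, crop = cstate, flux = flux)
}

#' Run one growing season
#'
#' Executes the daily coupling loop over the scenario window, harvesting on
#' the last day (or when the heat-unit index reaches 1, whichever comes
#' last within the window), and aggregates the season: total actual ET, the
#' net water flux at the maximum-root-depth plane (capillary minus
#' percolation), rain and irrigation totals, yield, water productivity and
#' irrigation water productivity.
#'
#' @param spec [scenario_spec()].
#' @param soil [soil_params()]. @param crop [crop_params()].
#' @param etp [et_params()]. @param normals [climate_normals()].
#' @return object of class `season_result`: `daily` (data frame of states
#'   and fluxes) and scalar aggregates `et_total`, `pet_total`, `wf_net`,
#'   `irrigation_total`, `rain_total`, `yield`, `wp`, `iwp`.
#' @export
run_season <- function(spec, soil = soil_params(), crop = crop_params(),
                       etp = et_params(), normals = hetao_normals()) {
  weather <- spec$weather
  if (is.null(weather))
    weather <- generate_weather(normals, spec$start, spec$end, spec$seed)
  weather <- validate_weather(weather)
  if (weather$date[1L] > spec$start ||
      weather$date[nrow(weather)] < spec$end)
    stop("weather does not cover the season")
  weather <- weather[weather$date >= spec$start &
                       weather$date <= spec$end, , drop = FALSE]

  et0 <- et0_penman_monteith(weather, normals)
  solar <- solar_radiation(weather, normals)
  irr <- numeric(nrow(weather))
  if (nrow(spec$irrigation)) {
    j <- match(as.Date(spec$irrigation$date), weather$date)
    if (anyNA(j)) stop("irrigation date outside the season")
    irr[j] <- irr[j] + spec$irrigation$depth
  }

  sstate <- soil_state(spec$theta0, spec$theta0, rd = crop$rd0,
                       rd_mx = crop$rd_mx, gwd = spec$gwd0, soil)
  cstate <- crop_state(crop)

  n <- nrow(weather)
  fx_mat <- matrix(NA_real_, n, length(.flux_names),
                   dimnames = list(NULL, .flux_names))
  st_mat <- matrix(NA_real_, n, 8L,
                   dimnames = list(NULL, c("theta1", "theta2", "rd",
                                           "gwd", "storage", "hui",
                                           "lai", "biomass")))
  rain_v <- weather$rain; tmax_v <- weather$tmax; tmin_v <- weather$tmin
  for (i in seq_len(n)) {
    out <- .step_day_core(sstate, cstate, rain_v[i], tmax_v[i],
                          tmin_v[i], et0[i], solar[i], irr[i],
                          soil, crop, etp)
    sstate <- out$soil; cstate <- out$crop
    fx_mat[i, ] <- out$flux
    st_mat[i, ] <- c(sstate$theta1, sstate$theta2, sstate$rd,
                     sstate$gwd, storage_mm(sstate), cstate$hui,
                     cstate$lai, cstate$biomass)
  }
  fx <- as.data.frame(fx_mat)
  daily <- cbind(data.frame(date = weather$date, et0 = et0,
                            solar = solar),
                 as.data.frame(st_mat), fx)

  yield <- harvest(cstate, crop)
  cstate$yield <- yield
  et_total <- sum(fx$soil_evap + fx$transpiration)
  irrigation_total <- sum(fx$irrigation)
  res <- list(daily = daily,
              et_total = et_total,
              pet_total = sum(fx$pet),
              wf_net = sum(fx$capillary - fx$percolation),
              irrigation_total = irrigation_total,
              rain_total = sum(fx$rain),
              yield = yield,
              wp = if (et_total > 0)
                water_productivity(yield, et_total) else NA_real_,
              iwp = irrigation_water_productivity(yield, irrigation_total),
              final_soil = sstate, final_crop = cstate)
  class(res) <- "season_result"
  res
}

#' @export
print.season_result <- function(x, ...) {
  cat("season result:", nrow(x$daily), "days\n")
  cat(sprintf("  yield %.2f t/ha, ET %.0f mm, PET %.0f mm\n",
              x$yield, x$et_total, x$pet_total))
  cat(sprintf("  rain %.1f mm, irrigation %.1f mm, net water-table flux %+.1f mm\n",
              x$rain_total, x$irrigation_total, x$wf_net))
  cat(sprintf("  WP %.2f kg/m3, IWP %s kg/m3\n", x$wp,
              if (is.na(x$iwp)) "--" else sprintf("%.2f", x$iwp)))
  invisible(x)
}

#' Run the groundwater-depth x deficit-irrigation scenario grid
#'
#' Crosses the irrigation treatments with the initial water-table depths
#' (defaults: D0..D8 by 100, 150, 200, 250, 300, 350, 400 cm = 63 cells),
#' using one shared weather realisation, and tabulates yield (Y, t/ha),
#' actual ET (mm), irrigation (I, mm), WP and IWP (kg/m3), the net
#' water-table flux `wf_net` (mm) and its ratio to ET (`wf_et`). IWP is
#' missing (NA) for unirrigated cells.
#'
#' @param gwd_levels initial water-table depths, cm.
#' @param treatments character vector of treatment names.
#' @param soil,crop,etp,normals parameter sets as in [run_season()].
#' @param theta0 initial moisture. @param start,end season window.
#' @param weather optional shared weather table; generated from `seed`
#'   when NULL.
#' @param seed weather seed.
#' @return data frame with one row per (treatment, depth) cell.
#' @export
run_scenario_grid <- function(gwd_levels = c(100, 150, 200, 250, 300,
                                             350, 400),
                              treatments = names(treatment_fractions()),
                              soil = soil_params(), crop = crop_params(),
                              etp = et_params(),
                              normals = hetao_normals(), theta0 = 0.3,
                              start = "2007-04-20", end = "2007-09-24",
                              weather = NULL, seed = 1L) {
  if (is.null(weather))
    weather <- generate_weather(normals, start, end, seed)
  year <- as.integer(format(as.Date(start), "%Y"))
  rows <- list()
  for (tr in treatments) {
    sched <- irrigation_schedule(tr, year)
    for (g in gwd_levels) {
      spec <- scenario_spec(g, sched, theta0 = theta0, start = start,
                            end = end, weather = weather)
      res <- run_season(spec, soil, crop, etp, normals)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, gwd0 = g, Y = res$yield, ET = res$et_total,
        I = res$irrigation_total, WP = res$wp, IWP = res$iwp,
        wf_net = res$wf_net,
        wf_et = if (res$et_total > 0) res$wf_net / res$et_total
        else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Water productivity
#'
#' Yield per unit evapotranspired water; with yield in t ha-1 and ET in mm
#' the conversion to kg m-3 is a factor 100.
#'
#' @param yield t ha-1. @param et seasonal actual ET, mm (> 0).
#' @return WP, kg m-3.
#' @export
water_productivity <- function(yield, et) {
  if (any(et <= 0)) stop("et must be positive")
  100 * yield / et
}

#' Irrigation water productivity
#'
#' Yield per unit irrigation water applied; undefined (NA, not an error)
#' for unirrigated seasons.
#'
#' @param yield t ha-1. @param irrigation seasonal irrigation, mm.
#' @return IWP, kg m-3; NA where `irrigation <= 0`.
#' @export
irrigation_water_productivity <- function(yield, irrigation) {
  n <- max(length(yield), length(irrigation))
  y <- rep_len(yield, n)
  i <- rep_len(irrigation, n)
  ifelse(i > 0, 100 * y / i, NA_real_)
}

#' Lysimeter-like scenario fixture
#'
#' Builds a [scenario_spec()] emulating one lysimeter column of the
#' calibration experiment: an initial water-table depth from the
#' experimental set, the four-event irrigation schedule (scaled by the
#' chosen treatment), initial moisture 0.3, the late-April to late-
#' September season, and synthetic Hetao weather from the given seed.
#'
#' @param gwd0 initial water-table depth, cm; one of 150, 200, 250, 300.
#' @param year_seed integer seed for the synthetic weather year.
#' @param treatment treatment name (default "D0", the full schedule).
#' @param normals [climate_normals()].
#' @return a [scenario_spec()] with the weather materialised.
#' @export
make_lysimeter_fixture <- function(gwd0, year_seed, treatment = "D0",
                                   normals = hetao_normals()) {
  if (!gwd0 %in% c(150, 200, 250, 300))
    stop("gwd0 must be one of 150, 200, 250, 300 cm")
  start <- "2007-04-20"; end <- "2007-09-24"
  scenario_spec(gwd0,
                irrigation_schedule(treatment, 2007),
                theta0 = 0.3, start = start, end = end,
                weather = generate_weather(normals, start, end, year_seed),
                seed = year_seed)
}
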