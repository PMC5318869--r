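#' Crop parameter set (EPIC-style maize defaults)
#'
#' Parameters of the heat-unit driven crop model. The shipped defaults are
#' the EPIC-recommended maize values and are meant as calibration starting
#' points: base temperature `tb` = 8 degC, optimum `t0` = 25 degC,
#' potential heat units `phu` = 1700 degC d, maximum LAI `lai_mx` = 6,
#' LAI decline starting at heat-unit fraction `dlai` = 0.8 with exponent
#' `ad` = 1, radiation-use efficiency `be` = 30 kg ha-1 per MJ m-2,
#' harvest index `hi` = 0.5 and maximum root depth `rd_mx` = 90 cm.
#'
#' The leaf-area development curve `huf(h) = h / (h + exp(l1 - l2 h))` has
#' its shape constants solved from the anchors `huf(0.15) = 0.05` and
#' `huf(0.50) = 0.95`; `rd0` is the initial depth of root influence and
#' `root_rate` the heat-unit multiplier of root deepening; `repro` is the
#' heat-unit window over which water stress is averaged for the
#' harvest-index adjustment.
#'
#' @param tb,t0 base and optimal temperature, degC (`tb < t0`).
#' @param phu potential heat units to maturity, degC d.
#' @param lai_mx maximum leaf area index.
#' @param dlai heat-unit fraction at the start of LAI decline, in (0, 1).
#' @param ad LAI decline exponent.
#' @param be radiation-use efficiency, kg ha-1 per MJ m-2.
#' @param hi potential harvest index, in (0, 1).
#' @param rd_mx maximum root depth, cm.
#' @param rd0 initial rooting depth, cm.
#' @param root_rate heat-unit multiplier for root deepening.
#' @param repro numeric(2), heat-unit window of the reproductive stage.
#' @param huf_anchors numeric(4) `(h1, f1, h2, f2)` fixing the LAI curve.
#' @return object of class `crop_params` (includes solved `l1`, `l2`).
#' @export
crop_params <- function(tb = 8, t0 = 25, phu = 1700, lai_mx = 6,
                        dlai = 0.8, ad = 1, be = 30, hi = 0.5,
                        rd_mx = 90, rd0 = 10, root_rate = 2.5,
                        repro = c(0.45, 0.80),
                        huf_anchors = c(0.15, 0.05, 0.50, 0.95)) {
  stopifnot(tb < t0, phu > 0, lai_mx > 0, dlai > 0, dlai < 1,
            ad >= 0, be > 0, hi > 0, hi < 1, rd_mx > 0,
            rd0 > 0, rd0 <= rd_mx, root_rate > 0,
            length(repro) == 2L, repro[1] < repro[2])
  h1 <- huf_anchors[1]; f1 <- huf_anchors[2]
  h2 <- huf_anchors[3]; f2 <- huf_anchors[4]
  # huf(h) = h/(h + exp(l1 - l2 h)) = f  =>  l1 - l2 h = log(h (1-f)/f)
  a1 <- log(h1 * (1 - f1) / f1)
  a2 <- log(h2 * (1 - f2) / f2)
  l2 <- (a1 - a2) / (h2 - h1)
  l1 <- a1 + l2 * h1
  structure(list(tb = tb, t0 = t0, phu = phu, lai_mx = lai_mx,
                 dlai = dlai, ad = ad, be = be, hi = hi,
                 rd_mx = rd_mx, rd0 = rd0, root_rate = root_rate,
                 repro = repro, l1 = l1, l2 = l2),
            class = "crop_params")
}

#' Initial crop state
#'
#' @param crop [crop_params()].
#' @return object of class `crop_state`: heat-unit index `hui` (and the
#'   previous day's `hui_prev`), `lai`, the LAI at the start of decline
#'   (`lai_peak`), above-ground `biomass` (t ha-1), root depth `rd` (cm),
#'   the running reproductive-stage stress average, and `yield` (NA until
#'   [harvest()]).
#' @export
crop_state <- function(crop = crop_params()) {
  structure(list(hui = 0, hui_prev = 0, lai = 0, lai_peak = NA_real_,
                 biomass = 0, rd = crop$rd0,
                 ws_repro_sum = 0, ws_repro_n = 0L,
                 yield = NA_real_),
            class = "crop_state")
}

#' Daily heat units
#'
#' `max(0, (tmax + tmin)/2 - tb)`; the heat-unit index advances by this
#' amount divided by `phu`.
#'
#' @param tmax,tmin daily extremes, degC (`tmax >= tmin`; vectorised).
#' @param crop [crop_params()].
#' @return degC d (>= 0).
#' @export
heat_units <- function(tmax, tmin, crop) {
  if (any(tmax < tmin)) stop("tmax < tmin")
  pmax(0, (tmax + tmin) / 2 - crop$tb)
}

#' Heat-unit factor of leaf development
#'
#' The sigmoid `huf(h) = h / (h + exp(l1 - l2 h))` governing the fraction
#' of maximum LAI attained at heat-unit index `h` during canopy growth.
#'
#' @param hui heat-unit index (vectorised).
#' @param crop [crop_params()].
#' @return dimensionless fraction in [0, 1).
#' @export
huf <- function(hui, crop) hui / (hui + exp(crop$l1 - crop$l2 * hui))

#' Daily leaf-area update
#'
#' Growth phase (`hui <= dlai`): LAI rises by the heat-unit-factor
#' increment times `lai_mx`, scaled by `sqrt(ws)` (the EPIC stress
#' adjustment of leaf growth). Decline phase (`hui > dlai`): LAI falls
#' from its value at the start of decline as
#' `lai_peak ((1 - hui)/(1 - dlai))^ad`, floored at zero; the curve is
#' continuous at `hui = dlai`.
#'
#' @param state [crop_state()] whose `hui`/`hui_prev` already reflect
#'   today's heat-unit advance.
#' @param ws water-stress factor in [0, 1].
#' @param crop [crop_params()].
#' @return updated [crop_state()] (fields `lai`, `lai_peak`).
#' @export
lai_update <- function(state, ws, crop) {
  stopifnot(ws >= 0, ws <= 1)
  if (state$hui <= crop$dlai) {
    dhuf <- huf(state$hui, crop) - huf(state$hui_prev, crop)
    state$lai <- state$lai + crop$lai_mx * dhuf * sqrt(ws)
  } else {
    if (is.na(state$lai_peak)) {
      # finish growth up to dlai within the crossing day, then decline
      dhuf <- huf(crop$dlai, crop) - huf(state$hui_prev, crop)
      state$lai_peak <- state$lai + crop$lai_mx * max(0, dhuf) * sqrt(ws)
    }
    frac <- max(0, (1 - state$hui) / (1 - crop$dlai))
    state$lai <- state$lai_peak * frac^crop$ad
  }
  state
}

#' Daily biomass increment
#'
#' Radiation-use efficiency growth: intercepted photosynthetically active
#' radiation `par = 0.5 solar (1 - exp(-0.65 LAI))`, temperature factor
#' `ts = sin((pi/2) clip((tday - tb)/(t0 - tb), 0, 1))`, and
#' `dB = 0.001 be par min(ws, ts)` tonnes per hectare per day (the 0.001
#' converts kg ha-1 to t ha-1).
#'
#' @param solar incoming shortwave radiation, MJ m-2 d-1.
#' @param lai leaf area index.
#' @param ws water-stress factor in [0, 1].
#' @param tday mean air temperature, degC.
#' @param crop [crop_params()].
#' @return biomass increment, t ha-1 d-1.
#' @export
biomass_increment <- function(solar, lai, ws, tday, crop) {
  stopifnot(solar >= 0, lai >= 0, ws >= 0, ws <= 1)
  par <- 0.5 * solar * (1 - exp(-0.65 * lai))
  tf <- pmin(1, pmax(0, (tday - crop$tb) / (crop$t0 - crop$tb)))
  ts <- sin(pi / 2 * tf)
  0.001 * crop$be * par * pmin(ws, ts)
}

#' Root-zone depth from phenology
#'
#' Roots deepen linearly with heat units from `rd0` at emergence, reaching
#' `rd_mx` at heat-unit index `1/root_rate` (0.4 with defaults):
#' `rd = min(rd_mx, rd0 + (rd_mx - rd0) min(root_rate hui, 1))`.
#'
#' @param hui heat-unit index (vectorised, >= 0).
#' @param crop [crop_params()].
#' @return root depth, cm.
#' @export
root_depth <- function(hui, crop) {
  stopifnot(all(hui >= 0))
  crop$rd0 + (crop$rd_mx - crop$rd0) * pmin(crop$root_rate * hui, 1)
}

#' Harvest-index yield
#'
#' `yield = biomass * hi * (0.5 + 0.5 * mean_ws_reproductive)` where the
#' stress average runs over the reproductive heat-unit window; an
#' unstressed season yields `hi * biomass`, complete reproductive stress
#' halves the harvest index. Harvesting before heat-unit index 0.5 warns
#' and scales the harvest index proportionally to `hui/0.5`.
#'
#' @param state [crop_state()] at the end of the season.
#' @param crop [crop_params()].
#' @param mean_ws_reproductive override for the reproductive-window stress
#'   average; by default taken from the state's running average (1 if the
#'   window was never entered).
#' @return yield, t ha-1 (also stored in the returned state's `yield` when
#'   called via [run_season()]).
#' @export
harvest <- function(state, crop, mean_ws_reproductive = NULL) {
  if (is.null(mean_ws_reproductive)) {
    mean_ws_reproductive <- if (state$ws_repro_n > 0L)
      state$ws_repro_sum / state$ws_repro_n else 1
  }
  hi <- crop$hi
  if (state$hui < 0.5) {
    warning("harvest before heat-unit index 0.5; harvest index scaled by ",
            format(state$hui / 0.5, digits = 3))
    hi <- hi * state$hui / 0.5
  }
  state$biomass * hi * (0.5 + 0.5 * mean_ws_reproductive)
}

#' Advance the crop by one day
#'
#' Composite daily update used by the simulator: heat units accrue, the
#' water-stress factor drives leaf growth and biomass, roots deepen, and
#' the reproductive-stage stress average is accumulated.
#'
#' @param state [crop_state()]. @param crop [crop_params()].
#' @param tmax,tmin daily temperature extremes, degC.
#' @param solar shortwave radiation, MJ m-2 d-1.
#' @param ws water-stress factor in [0, 1].
#' @return updated [crop_state()].
#' @export
crop_advance <- function(state, crop, tmax, tmin, solar, ws) {
  hu <- heat_units(tmax, tmin, crop)
  state$hui_prev <- state$hui
  state$hui <- state$hui + hu / crop$phu
  state <- lai_update(state, ws, crop)
  state$biomass <- state$biomass +
    biomass_increment(solar, state$lai, ws, (tmax + tmin) / 2, crop)
  state$rd <- max(state$rd, root_depth(state$hui, crop))
  if (state$hui >= crop$repro[1] && state$hui <= crop$repro[2]) {
    state$ws_repro_sum <- state$ws_repro_sum + ws
    state$ws_repro_n <- state$ws_repro_n + 1L
  }
  state
}
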