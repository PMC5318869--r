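#' Evapotranspiration coefficients
#'
#' Tunables of the canopy/moisture ET module: `k_beer` is the Beer's-law
#' extinction coefficient partitioning potential ET between soil
#' evaporation and transpiration; `p` sets the critical moisture
#' `theta_crit = mwp + p (mfc - mwp)` below which transpiration is reduced;
#' `kc_mx` and `lai_ref` define the leaf-area-driven crop coefficient
#' `kc(LAI) = 1 + (kc_mx - 1) min(LAI/lai_ref, 1)` that scales reference ET
#' to potential crop ET.
#'
#' @param k_beer canopy extinction coefficient (default 0.5).
#' @param p depletion fraction for transpiration stress (default 0.5).
#' @param kc_mx crop coefficient at full canopy (default 1.2).
#' @param lai_ref LAI at which the crop coefficient saturates (default 3).
#' @return object of class `et_params`.
#' @export
et_params <- function(k_beer = 0.5, p = 0.5, kc_mx = 1.2, lai_ref = 3) {
  stopifnot(k_beer > 0, p > 0, p < 1, kc_mx >= 1, lai_ref > 0)
  structure(list(k_beer = k_beer, p = p, kc_mx = kc_mx,
                 lai_ref = lai_ref), class = "et_params")
}

#' Potential crop evapotranspiration from reference ET and leaf area
#'
#' `pet = et0 * kc(LAI)`; bare soil (LAI = 0) evaporates at the reference
#' rate, a full canopy at `kc_mx` times it.
#'
#' @param et0 reference evapotranspiration, mm d-1 (vectorised).
#' @param lai leaf area index, >= 0.
#' @param etp [et_params()].
#' @return potential crop ET, mm d-1.
#' @export
potential_et <- function(et0, lai, etp = et_params()) {
  stopifnot(all(et0 >= 0), all(lai >= 0))
  et0 * (1 + (etp$kc_mx - 1) * pmin(lai / etp$lai_ref, 1))
}

#' Partition potential ET by canopy cover
#'
#' Beer's law split: potential transpiration
#' `tp = pet (1 - exp(-k_beer LAI))`, potential soil evaporation
#' `ep = pet - tp`.
#'
#' @param pet potential crop ET, mm d-1.
#' @param lai leaf area index.
#' @param etp [et_params()].
#' @return list with `pet`, `ep`, `tp` (mm d-1; `ep + tp == pet`).
#' @export
partition_et <- function(pet, lai, etp = et_params()) {
  stopifnot(all(pet >= 0), all(lai >= 0))
  tp <- pet * (1 - exp(-etp$k_beer * lai))
  list(pet = pet, ep = pet - tp, tp = tp)
}

#' Actual soil evaporation
#'
#' Linear reduction of potential soil evaporation between the air-dry
#' moisture `md` (no evaporation) and field capacity (unstressed):
#' `E = ep * clip((theta1 - md)/(mfc - md), 0, 1)`.
#'
#' @param ep potential soil evaporation, mm d-1.
#' @param theta1 zone-1 (surface/root zone) moisture, cm3 cm-3.
#' @param soil [soil_params()].
#' @return actual soil evaporation, mm d-1.
#' @export
actual_soil_evap <- function(ep, theta1, soil) {
  f <- (theta1 - soil$md) / (soil$mfc - soil$md)
  ep * pmin(1, pmax(0, f))
}

#' Actual transpiration and the water-stress factor
#'
#' Linear reduction of potential transpiration between the wilting point
#' (transpiration stops) and the critical moisture
#' `theta_crit = mwp + p (mfc - mwp)` (unstressed). The reduction factor
#' `ws` is the crop water-stress factor fed to leaf growth, biomass
#' accumulation and the harvest index.
#'
#' @param tp potential transpiration, mm d-1.
#' @param theta_rz root-zone moisture, cm3 cm-3.
#' @param soil [soil_params()].
#' @param etp [et_params()] (for the depletion fraction `p`).
#' @return list with `t` (mm d-1) and `ws` (dimensionless, in [0, 1]).
#' @export
actual_transpiration <- function(tp, theta_rz, soil, etp = et_params()) {
  theta_crit <- soil$mwp + etp$p * (soil$mfc - soil$mwp)
  ws <- (theta_rz - soil$mwp) / (theta_crit - soil$mwp)
  ws <- pmin(1, pmax(0, ws))
  list(t = ws * tp, ws = ws)
}
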