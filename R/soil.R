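#' Soil hydraulic parameter set
#'
#' Parameters of the four-zone soil column. Moistures are volumetric
#' (cm3 cm-3) and must be ordered `md < mwp < mfc < ms`; `mf` is the
#' drainable porosity (specific yield) governing water-table movement; `ks`
#' (cm d-1), `alpha` (cm-1) and `C` (dimensionless) define the unsaturated
#' conductivity `K(h) = ks / (1 + (alpha h)^C)` used by the Gardner
#' capillary-rise solution; `dp` is the fraction of percolation lost below
#' the simulated column (lateral/deep seepage) and so never reaching the
#' water table.
#'
#' The defaults are a loam set representative of the root-zone texture of
#' an arid irrigation district; they are calibration starting points, not
#' measurements.
#'
#' @param ms saturated moisture. @param mfc field capacity.
#' @param mwp wilting point. @param md air-dry/residual moisture.
#' @param mf drainable porosity / specific yield.
#' @param ks saturated hydraulic conductivity, cm d-1.
#' @param alpha retention shape parameter, cm-1.
#' @param C conductivity-function exponent (> 1).
#' @param dp deep-loss fraction of percolation, in [0, 1].
#' @return object of class `soil_params`.
#' @export
soil_params <- function(ms = 0.45, mfc = 0.33, mwp = 0.13, md = 0.05,
                        mf = 0.10, ks = 25, alpha = 0.02, C = 3, dp = 0) {
  p <- list(ms = ms, mfc = mfc, mwp = mwp, md = md, mf = mf,
            ks = ks, alpha = alpha, C = C, dp = dp)
  if (!all(vapply(p, function(x) is.numeric(x) && is.finite(x), TRUE)))
    stop("non-finite soil parameter")
  if (!(md < mwp && mwp < mfc && mfc < ms))
    stop("soil moistures must satisfy md < mwp < mfc < ms")
  if (mf <= 0 || mf >= ms) stop("mf must lie in (0, ms)")
  if (ks <= 0) stop("ks must be positive")
  if (alpha <= 0 || C <= 1) stop("alpha must be > 0 and C > 1")
  if (dp < 0 || dp > 1) stop("dp must lie in [0, 1]")
  structure(p, class = "soil_params")
}

#' Soil profile state
#'
#' Daily state of the unsaturated column: the actual root zone (zone 1,
#' depth `rd`), the remaining potential root zone (zone 2, from `rd` down to
#' `rd_mx`), the accumulated potential water loss of the
#' Thornthwaite-Mather bookkeeping (`apwl`, mm), and the water-table depth
#' `gwd` (cm below surface, positive downward). The transmission zone
#' (zone 3) carries no storage: percolation reaches the water table the
#' same day.
#'
#' @param theta1,theta2 mean volumetric moisture of zones 1 and 2.
#' @param rd root-zone depth, cm. @param rd_mx potential root-zone depth, cm.
#' @param gwd water-table depth, cm (> 0, at least `rd_mx`).
#' @param soil [soil_params()]; used to derive a consistent initial `apwl`
#'   and to check bounds.
#' @return object of class `soil_state`.
#' @export
soil_state <- function(theta1, theta2, rd = 10, rd_mx = 90, gwd, soil) {
  stopifnot(rd > 0, rd <= rd_mx, gwd > 0)
  if (theta1 < soil$md || theta1 > soil$ms ||
      theta2 < soil$md || theta2 > soil$ms)
    stop("initial moisture outside [md, ms]")
  if (gwd < rd_mx) {
    message("initial water table above the potential root zone bottom; ",
            "floored at rd_mx")
    gwd <- rd_mx
  }
  st <- structure(list(theta1 = theta1, theta2 = theta2, rd = rd,
                       rd_mx = rd_mx, gwd = gwd, apwl = 0),
                  class = "soil_state")
  st$apwl <- .apwl_of(storage_mm(st), .s_fc(st, soil))
  st
}

# column storage (zones 1+2), mm
#' Stored water in the potential root zone
#' @param state [soil_state()].
#' @return storage of zones 1+2, mm.
#' @export
storage_mm <- function(state) {
  10 * (state$theta1 * state$rd +
          state$theta2 * (state$rd_mx - state$rd))
}

.s_fc <- function(state, soil) 10 * soil$mfc * state$rd_mx
.s_md <- function(state, soil) 10 * soil$md * state$rd_mx
.apwl_of <- function(s, s_fc) if (s >= s_fc) 0 else -s_fc * log(s / s_fc)

# rescale zone moistures to a target storage, clamping at md
.set_storage <- function(state, soil, s_new) {
  s_old <- storage_mm(state)
  if (s_old <= 0) {
    th <- s_new / (10 * state$rd_mx)
    state$theta1 <- th; state$theta2 <- th
    return(state)
  }
  f <- s_new / s_old
  state$theta1 <- state$theta1 * f
  state$theta2 <- state$theta2 * f
  dz1 <- state$rd; dz2 <- state$rd_mx - state$rd
  # keep individual zones inside [md, ms], conserving the total
  for (pass in 1:2) {
    if (dz2 > 0 && state$theta2 < soil$md) {
      state$theta1 <- state$theta1 -
        (soil$md - state$theta2) * dz2 / dz1
      state$theta2 <- soil$md
    }
    if (state$theta1 < soil$md) {
      if (dz2 > 0) state$theta2 <- state$theta2 -
          (soil$md - state$theta1) * dz1 / dz2
      state$theta1 <- soil$md
    }
    if (state$theta1 > soil$ms) {
      if (dz2 > 0) state$theta2 <- state$theta2 +
          (state$theta1 - soil$ms) * dz1 / dz2
      state$theta1 <- soil$ms
    }
    if (dz2 > 0 && state$theta2 > soil$ms) {
      state$theta1 <- state$theta1 +
        (state$theta2 - soil$ms) * dz2 / dz1
      state$theta2 <- soil$ms
    }
  }
  state
}

#' Gardner steady-state limiting capillary flux
#'
#' Maximum steady upward flux from a water table a distance `depth_gap`
#' (cm) below the receiving zone, for the conductivity function
#' `K(h) = ks / (1 + (alpha h)^C)`. This is the exact analytical solution
#' of the steady unsaturated flow problem: the flux `q` satisfies
#' `depth_gap = (pi/C) csc(pi/C) / alpha * m^(-1/C) / (1 + q/ks)` with
#' `m = (q/ks) / (1 + q/ks)`, solved here by root finding. In the
#' deep-table limit it reduces to the familiar tabulated form
#' `q = A ks / (alpha d)^C` with `A = ((pi/C) csc(pi/C))^C` (2.46, 1.76,
#' 1.52 for C = 2, 3, 4). The result is clamped to `[0, ks]` and returned
#' in mm d-1; it tends to `ks` as `depth_gap -> 0` and to 0 as
#' `depth_gap -> Inf`.
#'
#' @param depth_gap distance from the receiving-zone bottom to the water
#'   table, cm (vectorised, >= 0).
#' @param soil [soil_params()].
#' @return limiting upward flux, mm d-1.
#' @export
gardner_max_flux <- function(depth_gap, soil) {
  if (any(!is.finite(depth_gap)) || any(depth_gap < 0))
    stop("depth_gap must be finite and >= 0")
  cA <- (pi / soil$C) / sin(pi / soil$C)
  one <- function(d) {
    if (d <= 0) return(soil$ks)
    # beta = q/ks solves f(beta) = 0, f strictly decreasing
    f <- function(beta) {
      m <- beta / (1 + beta)
      cA / soil$alpha * m^(-1 / soil$C) / (1 + beta) - d
    }
    g <- function(x) f(exp(x))          # solve in log(beta) for precision
    if (g(700) >= 0) return(soil$ks)    # unreachable in practice
    if (g(-700) <= 0) return(0)
    x <- stats::uniroot(g, c(-700, 700), tol = 1e-12)$root
    min(soil$ks, exp(x) * soil$ks)
  }
  10 * vapply(depth_gap, one, numeric(1))
}

#' Capillary rise into the unsaturated column
#'
#' Supplies at most the Gardner limiting flux, and no more than the day's
#' demand, to the zone just above the water table (zone 2 while roots are
#' shallower than `rd_mx`, zone 1 once `rd = rd_mx`). No rise occurs when
#' the receiving zone is at or above field capacity.
#'
#' @param state [soil_state()]. @param soil [soil_params()].
#' @param demand mm d-1, >= 0: unmet field-capacity deficit of the
#'   receiving zone plus unmet evapotranspiration.
#' @return list with `state` (flux added to storage, `apwl` recomputed) and
#'   `flux` (mm d-1).
#' @export
capillary_rise <- function(state, soil, demand) {
  stopifnot(demand >= 0)
  dz2 <- state$rd_mx - state$rd
  theta_recv <- if (dz2 > 0) state$theta2 else state$theta1
  if (theta_recv >= soil$mfc || demand <= 0)
    return(list(state = state, flux = 0))
  qmax <- gardner_max_flux(max(0, state$gwd - state$rd_mx), soil)
  flux <- min(demand, qmax)
  if (flux <= 0) return(list(state = state, flux = 0))
  if (dz2 > 0) {
    state$theta2 <- state$theta2 + flux / (10 * dz2)
  } else {
    state$theta1 <- state$theta1 + flux / (10 * state$rd)
  }
  state$apwl <- .apwl_of(storage_mm(state), .s_fc(state, soil))
  list(state = state, flux = flux)
}

#' Thornthwaite-Mather daily step
#'
#' Daily moisture accounting over the zone 1+2 column of capacity
#' `S_fc = mfc * rd_mx * 10` mm. On wet days (infiltration >= withdrawal)
#' storage rises by the surplus, anything above `S_fc` percolates out the
#' same day, and the accumulated potential water loss is reset to the value
#' consistent with the new storage (`apwl = -S_fc log(S/S_fc)`, 0 at or
#' above capacity). On dry days the shortfall is added to `apwl` and
#' storage follows the exponential drying curve `S = S_fc exp(-apwl/S_fc)`,
#' so the realised withdrawal is smaller than the demand; the realised
#' evapotranspiration is returned so callers can close the water balance.
#' Zone moistures are rescaled proportionally; storage is clipped (with a
#' message) at the air-dry equivalent.
#'
#' @param state [soil_state()]. @param soil [soil_params()].
#' @param infiltration mm, >= 0 (rain plus irrigation).
#' @param et_withdrawal mm, >= 0 (soil evaporation plus transpiration
#'   demand after the moisture-stress reductions).
#' @return list with `state`, `percolation` (mm) and `et_realized` (mm).
#' @export
tm_step <- function(state, soil, infiltration, et_withdrawal) {
  stopifnot(infiltration >= 0, et_withdrawal >= 0)
  s_fc <- .s_fc(state, soil)
  s <- storage_mm(state)
  perc <- 0
  if (infiltration >= et_withdrawal) {
    s_new <- s + infiltration - et_withdrawal
    if (s_new > s_fc) {
      perc <- s_new - s_fc
      s_new <- s_fc
    }
    et_real <- et_withdrawal
  } else {
    apwl <- .apwl_of(s, s_fc) + (et_withdrawal - infiltration)
    s_new <- s_fc * exp(-apwl / s_fc)
    et_real <- infiltration + (s - s_new)
  }
  s_md <- .s_md(state, soil)
  if (s_new < s_md) {
    message("column storage clipped at the air-dry equivalent (",
            format(s_md), " mm)")
    et_real <- et_real - (s_md - s_new)
    s_new <- s_md
  }
  state <- .set_storage(state, soil, s_new)
  state$apwl <- .apwl_of(s_new, s_fc)
  list(state = state, percolation = perc, et_realized = et_real)
}

#' Water-table response to recharge and capillary withdrawal
#'
#' Specific-yield bookkeeping: the table moves by
#' `(upflux - (1 - dp) * recharge) / (10 mf)` cm (deepening when capillary
#' withdrawal dominates, rising when recharge dominates). The table is not
#' allowed above the bottom of the potential root zone; excess rise is
#' absorbed there with a message.
#'
#' @param state [soil_state()]. @param soil [soil_params()].
#' @param recharge percolation reaching the saturated zone today, mm >= 0.
#' @param upflux capillary rise withdrawn from the saturated zone, mm >= 0.
#' @return updated [soil_state()].
#' @export
update_water_table <- function(state, soil, recharge, upflux) {
  stopifnot(recharge >= 0, upflux >= 0)
  if (soil$mf <= 0) stop("mf must be positive")
  gwd_new <- state$gwd +
    (upflux - (1 - soil$dp) * recharge) / (10 * soil$mf)
  if (gwd_new < state$rd_mx) {
    message("water table held at the potential root zone bottom (",
            state$rd_mx, " cm); excess stored as saturation")
    gwd_new <- state$rd_mx
  }
  state$gwd <- gwd_new
  state
}

#' Deepen the actual root zone
#'
#' Moves the zone 1/zone 2 boundary down to `new_rd`; zone 1 inherits the
#' moisture of the annexed zone-2 slab as a depth-weighted mean, so stored
#' water is conserved exactly.
#'
#' @param state [soil_state()].
#' @param new_rd new root-zone depth, cm, in `[rd, rd_mx]`.
#' @return updated [soil_state()].
#' @export
grow_root_zone <- function(state, new_rd) {
  if (new_rd < state$rd) stop("root zone may not shrink")
  if (new_rd > state$rd_mx) stop("root zone may not exceed rd_mx")
  if (new_rd == state$rd) return(state)
  state$theta1 <- (state$theta1 * state$rd +
                     state$theta2 * (new_rd - state$rd)) / new_rd
  state$rd <- new_rd
  state
}
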