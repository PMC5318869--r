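# Independent oracles used by the tests. These deliberately re-derive the
# quantities from first principles along a different code path than the
# package (scalar arithmetic, numerical integration) and must not call the
# implementation they check.

# FAO-56 daily reference ET, coded step by step from the worked procedure.
# Scalar inputs; sunshine hours + Angstrom (a=0.25, b=0.50); ea from mean RH.
fao56_oracle <- function(tmax, tmin, sunshine, rh, wind, doy, lat_deg,
                         elev) {
  tmean <- (tmax + tmin) / 2
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (e0(tmax) + e0(tmin)) / 2
  ea <- rh / 100 * es
  delta <- 4098 * e0(tmean) / (tmean + 237.3)^2
  p <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
  gamma <- 0.000665 * p
  phi <- pi / 180 * lat_deg
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  dec <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  ws <- acos(-tan(phi) * tan(dec))
  ra <- 24 * 60 / pi * 0.082 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  nn <- 24 / pi * ws
  rs <- (0.25 + 0.5 * sunshine / nn) * ra
  rso <- (0.75 + 2e-5 * elev) * ra
  rns <- 0.77 * rs
  sb <- 4.903e-9
  rnl <- sb * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * min(1, rs / rso) - 0.35)
  rn <- rns - rnl
  num <- 0.408 * delta * rn + gamma * 900 / (tmean + 273) * wind *
    (es - ea)
  max(0, num / (delta + gamma * (1 + 0.34 * wind)))
}

# Steady-Richards limiting upflux oracle for K(h) = ks/(1+(alpha h)^C):
# integrates the suction profile depth d(q) numerically and inverts it.
# Returns mm/d (ks in cm/d), clamped to [0, 10*ks].
gardner_oracle <- function(depth_gap, ks, alpha, C) {
  if (depth_gap <= 0) return(10 * ks)
  depth_of <- function(q) {
    h_up <- (1e10 * ks / q)^(1 / C) / alpha
    core <- stats::integrate(function(h)
      1 / (1 + (q / ks) * (1 + (alpha * h)^C)),
      0, h_up, rel.tol = 1e-10, subdivisions = 2000L)$value
    tail <- (ks / (q * alpha^C)) * h_up^(1 - C) / (C - 1)
    core + tail - depth_gap
  }
  if (depth_of(ks) > 0) return(10 * ks)   # saturated limit
  q <- stats::uniroot(depth_of, c(ks * 1e-12, ks), tol = 1e-12)$root
  10 * q
}

# Brute-force fit statistics written directly from the definitions.
fit_stats_brute <- function(pred, obs) {
  n <- length(obs)
  mre <- 100 / n * sum((pred - obs) / obs)
  rmse <- sqrt(sum((pred - obs)^2) / n)
  obar <- sum(obs) / n
  nse <- 1 - sum((pred - obs)^2) / sum((obs - obar)^2)
  pbar <- sum(pred) / n
  r2 <- (sum((pred - pbar) * (obs - obar)) /
           sqrt(sum((pred - pbar)^2) * sum((obs - obar)^2)))^2
  b <- sum(pred * obs) / sum(obs^2)
  list(mre = mre, rmse = rmse, nse = nse, r2 = r2, b = b)
}
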