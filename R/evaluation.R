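#' Goodness-of-fit statistics
#'
#' The five statistics used to judge calibration and validation:
#' observation-wise mean relative error `MRE = 100 mean((P - O)/O)` (%),
#' root mean square error, Nash-Sutcliffe efficiency
#' `NSE = 1 - sum((P - O)^2) / sum((O - mean(O))^2)`, the squared Pearson
#' correlation `R2`, and the regression-through-the-origin coefficient
#' `b = sum(P O) / sum(O^2)`. Negative MRE means underprediction. For
#' near-constant observations NSE (and R2) are unreliable; with exactly
#' constant observations both are reported as NA with a warning, as is MRE
#' when any observation is zero.
#'
#' @param pred predicted series.
#' @param obs observed series (same length, n >= 2).
#' @return object of class `fit_stats`: list with `mre`, `rmse`, `nse`,
#'   `r2`, `b`, `n`.
#' @export
fit_stats <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2L,
            is.finite(pred), is.finite(obs))
  n <- length(obs)
  mre <- if (any(obs == 0)) {
    warning("MRE undefined: zero observation")
    NA_real_
  } else 100 * mean((pred - obs) / obs)
  rmse <- sqrt(mean((pred - obs)^2))
  ss_obs <- sum((obs - mean(obs))^2)
  if (ss_obs == 0) {
    warning("NSE/R2 undefined: constant observations")
    nse <- NA_real_
    r2 <- NA_real_
  } else {
    nse <- 1 - sum((pred - obs)^2) / ss_obs
    r2 <- if (stats::var(pred) == 0) NA_real_ else
      stats::cor(pred, obs)^2
  }
  b <- sum(pred * obs) / sum(obs^2)
  structure(list(mre = mre, rmse = rmse, nse = nse, r2 = r2, b = b,
                 n = n), class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("n = %d  MRE %.2f%%  RMSE %.4g  NSE %.3f  R2 %.3f  b %.3f\n",
              x$n, x$mre, x$rmse, x$nse, x$r2, x$b))
  invisible(x)
}

# locate a scalar parameter by name across the parameter sets and return a
# modified copy of the base configuration
.perturb <- function(base, parameter, factor) {
  for (set in c("soil", "crop", "etp")) {
    p <- base[[set]]
    if (parameter %in% names(p)) {
      args <- unclass(p)
      if (set == "crop") args$l1 <- args$l2 <- NULL  # derived constants
      args[[parameter]] <- args[[parameter]] * factor
      ctor <- switch(set, soil = soil_params, crop = crop_params,
                     etp = et_params)
      base[[set]] <- do.call(ctor, args)
      return(base)
    }
  }
  stop("unknown parameter: ", parameter)
}

.index_value <- function(res, index) {
  switch(index,
         ET = res$et_total,
         GWD = mean(res$daily$gwd),
         LAI = max(res$daily$lai),
         SW90 = mean(res$daily$storage),
         stop("unknown index: ", index))
}

#' One-at-a-time parameter sensitivity
#'
#' Scales one parameter by `1 + delta` for each delta in the grid, reruns
#' the season on fixed weather, and reports the relative change of the
#' chosen seasonal index: actual ET, mean water-table depth (GWD), peak
#' leaf area (LAI), or mean stored water of the 90 cm column (SW90).
#'
#' @param base list with elements `spec` ([scenario_spec()]), `soil`,
#'   `crop`, `etp`, `normals`. The spec's weather is materialised once so
#'   every rerun sees identical forcing.
#' @param parameter parameter name, looked up in the soil, crop and ET
#'   parameter sets (in that order).
#' @param deltas fractional perturbations (default -25% to +25% by 5%).
#' @param index one of "ET", "GWD", "LAI", "SW90".
#' @return data frame with `delta`, `value`, `rel_change`.
#' @export
sensitivity_scan <- function(base, parameter,
                             deltas = seq(-0.25, 0.25, by = 0.05),
                             index = c("ET", "GWD", "LAI", "SW90")) {
  index <- match.arg(index)
  if (is.null(base$spec$weather)) {
    base$spec$weather <- generate_weather(base$normals, base$spec$start,
                                          base$spec$end, base$spec$seed)
  }
  run1 <- function(cfg) run_season(cfg$spec, cfg$soil, cfg$crop, cfg$etp,
                                   cfg$normals)
  ref <- .index_value(run1(base), index)
  vals <- vapply(deltas, function(d) {
    if (d == 0) return(ref)
    .index_value(run1(.perturb(base, parameter, 1 + d)), index)
  }, numeric(1))
  data.frame(parameter = parameter, index = index, delta = deltas,
             value = vals, rel_change = (vals - ref) / ref)
}

#' Ensemble predictions under parameter uncertainty
#'
#' Draws `n` parameter multipliers uniformly within `1 +- spread` of the
#' base value for each named parameter, reruns the season for every member
#' on fixed weather, and collects a daily prediction matrix for use with
#' [d_factor()].
#'
#' @param base configuration list as in [sensitivity_scan()].
#' @param parameters character vector of parameter names to vary jointly.
#' @param n ensemble size (default 200).
#' @param spread half-width of the uniform multiplier band (default 0.25,
#'   matching the sensitivity range).
#' @param seed RNG seed.
#' @param extractor function mapping a `season_result` to the daily series
#'   of interest (default: water-table depth).
#' @return numeric matrix, time points x ensemble members.
#' @export
ensemble_predictions <- function(base, parameters, n = 200L,
                                 spread = 0.25, seed = 1L,
                                 extractor = function(res) res$daily$gwd) {
  stopifnot(n >= 2L, spread > 0)
  if (is.null(base$spec$weather)) {
    base$spec$weather <- generate_weather(base$normals, base$spec$start,
                                          base$spec$end, base$spec$seed)
  }
  rng <- .seeded_rng(seed)
  factors <- matrix(stats::runif(n * length(parameters), 1 - spread,
                                 1 + spread),
                    nrow = n, dimnames = list(NULL, parameters))
  rng$restore()
  cols <- lapply(seq_len(n), function(i) {
    cfg <- base
    for (p in parameters) cfg <- .perturb(cfg, p, factors[i, p])
    extractor(run_season(cfg$spec, cfg$soil, cfg$crop, cfg$etp,
                         cfg$normals))
  })
  do.call(cbind, cols)
}

#' d-factor uncertainty index
#'
#' Width of the empirical 95% (by default) prediction band of an ensemble,
#' averaged over time and normalised by the standard deviation of the
#' observations: `d_bar = mean(X_U - X_L)` with `X_L`, `X_U` the
#' `(1 -+ level)/2` quantiles at each time point (linear interpolation of
#' order statistics), and `d_factor = d_bar / sd(obs)`. Dimensionless and
#' scale-invariant; larger values mean larger parameter uncertainty.
#'
#' @param ensemble matrix of predictions, time points x members
#'   (>= 2 members).
#' @param obs observed series, one value per time point; must not be
#'   constant.
#' @param level prediction-interval coverage (default 0.95).
#' @return object of class `uncertainty_result`: `d_bar`, `sigma_x`,
#'   `d_factor`.
#' @export
d_factor <- function(ensemble, obs, level = 0.95) {
  ensemble <- as.matrix(ensemble)
  stopifnot(ncol(ensemble) >= 2L, nrow(ensemble) == length(obs),
            level > 0, level < 1)
  sigma <- stats::sd(obs)
  if (sigma == 0) stop("constant observations: d-factor undefined")
  lo <- (1 - level) / 2
  xl <- apply(ensemble, 1L, stats::quantile, probs = lo, names = FALSE)
  xu <- apply(ensemble, 1L, stats::quantile, probs = 1 - lo,
              names = FALSE)
  d_bar <- mean(xu - xl)
  structure(list(d_bar = d_bar, sigma_x = sigma,
                 d_factor = d_bar / sigma),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("d-factor %.3f (mean band width %.4g, sd(obs) %.4g)\n",
              x$d_factor, x$d_bar, x$sigma_x))
  invisible(x)
}
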