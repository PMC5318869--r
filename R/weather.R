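#' Climate normals for a simulation site
#'
#' Bundles the monthly climatology and site geometry that the reference
#' evapotranspiration routine and the synthetic weather generator need:
#' twelve monthly mean air temperatures, twelve monthly rain fractions
#' (summing to 1), the target rain total for a growing season, and the site
#' latitude/elevation.
#'
#' @param t_month numeric(12), monthly mean air temperature, degC (Jan..Dec).
#' @param rain_frac numeric(12), fraction of annual rain falling in each
#'   month; non-negative, must sum to 1 (tolerance 1e-9).
#' @param rain_total seasonal (growing-season) rain total to impose on
#'   generated weather, mm.
#' @param latitude site latitude, decimal degrees (north positive).
#' @param elevation site elevation above sea level, m.
#' @return An object of class `climate_normals` (a list with the above
#'   fields).
#' @seealso [hetao_normals()] for the built-in arid Hetao preset.
#' @export
climate_normals <- function(t_month, rain_frac, rain_total, latitude,
                            elevation) {
  stopifnot(length(t_month) == 12L, length(rain_frac) == 12L,
            is.finite(t_month), is.finite(rain_frac),
            is.finite(rain_total), rain_total >= 0,
            abs(latitude) <= 90, is.finite(elevation))
  if (any(rain_frac < 0)) stop("rain fractions must be non-negative")
  if (abs(sum(rain_frac) - 1) > 1e-9)
    stop("rain fractions must sum to 1 (got ", format(sum(rain_frac)), ")")
  structure(list(t_month = as.numeric(t_month),
                 rain_frac = as.numeric(rain_frac),
                 rain_total = as.numeric(rain_total),
                 latitude = as.numeric(latitude),
                 elevation = as.numeric(elevation)),
            class = "climate_normals")
}

#' Built-in climate normals for the Hetao irrigation district
#'
#' Arid continental climate of the Hetao irrigation district (Inner
#' Mongolia): monthly mean temperature follows the annual sinusoid through
#' -10.1 degC in January and 23.8 degC in July (annual mean about 6.9 degC);
#' rain is strongly monsoonal, with July and August together carrying 72% of
#' the annual total; the default growing-season rain total is 128 mm.
#' Latitude and elevation are those of the district (Linhe area).
#'
#' @param rain_total growing-season rain total, mm; default 128.
#' @return A [climate_normals()] object.
#' @export
hetao_normals <- function(rain_total = 128) {
  m <- 1:12
  # first-harmonic annual cycle anchored at the Jan/Jul extremes
  t_month <- 6.85 - 16.95 * cos(2 * pi * (m - 1) / 12)
  rain_frac <- c(0.005, 0.005, 0.01, 0.02, 0.04, 0.09,
                 0.40, 0.32, 0.08, 0.02, 0.005, 0.005)
  climate_normals(t_month, rain_frac, rain_total,
                  latitude = 40.75, elevation = 1040)
}

.weather_cols <- c("date", "tmax", "tmin", "sunshine", "rh", "wind", "rain")

#' Validate a daily weather table
#'
#' Checks the invariants of a daily weather data frame: required columns,
#' strictly increasing gap-free dates, `tmax >= tmin`, non-negative rain,
#' relative humidity in [0, 100], and non-negative sunshine (or radiation).
#' Exactly one of `sunshine` (hours/day) or `radiation` (MJ m-2 d-1) must be
#' present.
#'
#' @param weather data frame with columns `date`, `tmax`, `tmin`, `rh`,
#'   `wind`, `rain` and one of `sunshine`/`radiation`.
#' @return The validated data frame, invisibly, with `date` coerced to
#'   `Date`.
#' @export
validate_weather <- function(weather) {
  stopifnot(is.data.frame(weather))
  has_sun <- "sunshine" %in% names(weather)
  has_rad <- "radiation" %in% names(weather)
  if (has_sun == has_rad)
    stop("weather must contain exactly one of 'sunshine' or 'radiation'")
  missing <- setdiff(c("date", "tmax", "tmin", "rh", "wind", "rain"),
                     names(weather))
  if (length(missing))
    stop("missing weather column(s): ", paste(missing, collapse = ", "))
  weather$date <- as.Date(weather$date)
  if (anyNA(weather$date)) stop("unparsable date in weather table")
  for (v in intersect(c("tmax", "tmin", "sunshine", "radiation",
                        "rh", "wind", "rain"), names(weather))) {
    weather[[v]] <- as.numeric(weather[[v]])
    if (anyNA(weather[[v]]))
      stop("unparsable value in weather column '", v, "'")
  }
  n <- nrow(weather)
  if (n == 0L) stop("empty weather table")
  if (n > 1L) {
    dd <- diff(as.integer(weather$date))
    if (any(dd <= 0L)) stop("weather dates must be strictly increasing")
    if (any(dd != 1L))
      stop("gap in weather dates after row ", which(dd != 1L)[1L])
  }
  bad <- which(weather$tmax < weather$tmin)
  if (length(bad))
    stop("tmax < tmin in weather row ", bad[1L],
         " (", format(weather$date[bad[1L]]), ")")
  if (any(weather$rain < 0)) stop("negative rain in weather table")
  if (any(weather$rh < 0 | weather$rh > 100))
    stop("relative humidity outside [0, 100]")
  if (has_sun && any(weather$sunshine < 0))
    stop("negative sunshine hours")
  if (has_rad && any(weather$radiation < 0))
    stop("negative solar radiation")
  if (any(weather$wind < 0)) stop("negative wind speed")
  invisible(weather)
}

#' Read a daily weather file
#'
#' Reads comma-delimited daily weather with a header row
#' `date,tmax,tmin,sunshine,rh,wind,rain` (a `radiation` column in
#' MJ m-2 d-1 may replace `sunshine`). Dates are ISO-8601. Alternative
#' column names can be mapped via `dialect`.
#'
#' @param path file path.
#' @param dialect optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(tmax = "TX")`.
#' @return A validated weather data frame (one row per day, contiguous
#'   dates).
#' @export
read_weather <- function(path, dialect = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  w <- validate_weather(raw)
  w
}

#' Write a daily weather file
#'
#' Inverse of [read_weather()]; numeric columns keep full precision so a
#' write/read round trip is lossless well below 1e-6.
#'
#' @param weather validated weather data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  w <- validate_weather(weather)
  w$date <- format(w$date, "%Y-%m-%d")
  utils::write.csv(w, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- FAO-56 Penman-Monteith ---------------------------------------------------

#' Extraterrestrial radiation and daylength
#'
#' Standard FAO-56 astronomy: extraterrestrial radiation Ra (MJ m-2 d-1) and
#' maximum daylight hours N for a day of year and latitude.
#'
#' @param doy day of year (1-366).
#' @param latitude decimal degrees.
#' @return list with numeric vectors `ra` and `daylength`.
#' @keywords internal
solar_geometry <- function(doy, latitude) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  ws <- acos(x)
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  list(ra = pmax(0, ra), daylength = 24 / pi * ws)
}

#' Incoming solar radiation for a weather table
#'
#' Returns the daily shortwave radiation Rs in MJ m-2 d-1: the `radiation`
#' column when present, otherwise the Angstrom formula
#' `Rs = (a + b n/N) Ra` with the FAO-56 default coefficients a = 0.25,
#' b = 0.50 applied to sunshine hours.
#'
#' @param weather validated weather data frame.
#' @param normals [climate_normals()] (for latitude).
#' @param angstrom numeric(2), Angstrom coefficients `c(a, b)`.
#' @return numeric vector of Rs, MJ m-2 d-1.
#' @export
solar_radiation <- function(weather, normals, angstrom = c(0.25, 0.50)) {
  if ("radiation" %in% names(weather)) return(weather$radiation)
  doy <- as.integer(format(as.Date(weather$date), "%j"))
  geo <- solar_geometry(doy, normals$latitude)
  n_over_N <- ifelse(geo$daylength > 0,
                     pmin(1, weather$sunshine / geo$daylength), 0)
  (angstrom[1] + angstrom[2] * n_over_N) * geo$ra
}

.svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Daily grass reference evapotranspiration ET0 (mm d-1) from the standard
#' FAO-56 formulation: soil heat flux taken as zero at the daily step,
#' psychrometric constant from site elevation, saturation vapour pressure as
#' the mean of the values at `tmax` and `tmin`, actual vapour pressure from
#' mean relative humidity, net longwave radiation from the Stefan-Boltzmann
#' term with the FAO cloudiness and humidity corrections, and shortwave
#' radiation from [solar_radiation()]. Negative balances are floored at
#' zero.
#'
#' @param weather validated weather data frame (one or more days).
#' @param normals [climate_normals()] with site latitude and elevation.
#' @return numeric vector, ET0 in mm d-1 (one value per row).
#' @export
et0_penman_monteith <- function(weather, normals) {
  w <- validate_weather(weather)
  doy <- as.integer(format(w$date, "%j"))
  geo <- solar_geometry(doy, normals$latitude)
  z <- normals$elevation
  tmean <- (w$tmax + w$tmin) / 2
  delta <- 4098 * .svp(tmean) / (tmean + 237.3)^2
  p_atm <- 101.3 * ((293 - 0.0065 * z) / 293)^5.26
  gamma <- 0.000665 * p_atm
  es <- (.svp(w$tmax) + .svp(w$tmin)) / 2
  ea <- pmin(es, w$rh / 100 * es)
  rs <- solar_radiation(w, normals)
  rso <- (0.75 + 2e-5 * z) * geo$ra
  rel <- ifelse(rso > 0, pmin(1, rs / rso), 0)
  rns <- (1 - 0.23) * rs
  rnl <- 4.903e-9 * ((w$tmax + 273.16)^4 + (w$tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * pmax(0, 1.35 * rel - 0.35)
  rn <- rns - rnl
  et0 <- (0.408 * delta * rn +
            gamma * 900 / (tmean + 273) * w$wind * (es - ea)) /
    (delta + gamma * (1 + 0.34 * w$wind))
  pmax(0, et0)
}

# -- synthetic weather --------------------------------------------------------

# smooth daily mean temperature from monthly normals (first harmonic fit)
.t_smooth <- function(doy, t_month) {
  mid <- 15.2 + 30.44 * (0:11)            # month-centre days of year
  a0 <- mean(t_month)
  c1 <- 2 / 12 * sum(t_month * cos(2 * pi * mid / 365.25))
  s1 <- 2 / 12 * sum(t_month * sin(2 * pi * mid / 365.25))
  a0 + c1 * cos(2 * pi * doy / 365.25) + s1 * sin(2 * pi * doy / 365.25)
}

#' Generate synthetic daily weather
#'
#' Draws a reproducible daily weather series consistent with a set of
#' [climate_normals()]: mean temperature follows the first-harmonic annual
#' cycle through the monthly normals plus bounded autocorrelated noise
#' (tmax/tmin generated jointly around a diurnal half-range so that
#' `tmax >= tmin` always holds); rain comes from per-month Poisson event
#' counts with exponential depths, rescaled month by month so that the
#' seasonal total equals `normals$rain_total` exactly and the monthly
#' concentration of the normals (e.g. the July-August monsoon peak) is
#' honoured; sunshine, humidity and wind are drawn around arid-climate
#' values, drier and sunnier on rain-free days.
#'
#' @param normals [climate_normals()].
#' @param start,end season start/end dates (same calendar year).
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return A validated weather data frame covering `start..end`.
#' @export
generate_weather <- function(normals, start, end, seed) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("empty season: end before start")
  if (format(start, "%Y") != format(end, "%Y"))
    stop("season must lie within one calendar year")
  dates <- seq(start, end, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  mon <- as.integer(format(dates, "%m"))

  rng <- .seeded_rng(seed)
  on.exit(rng$restore(), add = TRUE)

  tbar <- .t_smooth(doy, normals$t_month)
  # AR(1) noise on the daily mean, bounded at +-5 degC
  eps <- numeric(n)
  innov <- stats::rnorm(n, 0, 1.6)
  for (i in seq_len(n)) eps[i] <- if (i == 1L) innov[1L] else
    0.6 * eps[i - 1L] + innov[i]
  eps <- pmin(5, pmax(-5, eps))
  tmean <- tbar + eps
  half_range <- pmax(1, 6 + stats::rnorm(n, 0, 1.2))
  tmax <- tmean + half_range
  tmin <- tmean - half_range

  # rain: per-month events, exponential depths, exact monthly mass
  rain <- numeric(n)
  season_frac <- sum(normals$rain_frac[unique(mon)])
  for (m in unique(mon)) {
    idx <- which(mon == m)
    tgt <- normals$rain_total * normals$rain_frac[m] / season_frac
    if (tgt <= 0) next
    lambda <- 25 * normals$rain_frac[m] / season_frac
    k <- stats::rpois(1L, max(lambda, 0.2))
    if (k == 0L) k <- 1L
    k <- min(k, length(idx))
    days <- sample(idx, k)
    depths <- stats::rexp(k, rate = 1)
    rain[days] <- rain[days] + depths * (tgt / sum(depths))
  }
  # numerical guarantee on the seasonal total
  if (sum(rain) > 0) rain <- rain * (normals$rain_total / sum(rain))

  geo <- solar_geometry(doy, normals$latitude)
  rainy <- rain > 0.2
  frac <- 0.72 - 0.35 * rainy + stats::rnorm(n, 0, 0.08)
  sunshine <- pmin(geo$daylength, pmax(0, frac * geo$daylength))
  rh <- pmin(95, pmax(15, 45 + 25 * rainy + stats::rnorm(n, 0, 8)))
  wind <- pmin(8, pmax(0.3, exp(stats::rnorm(n, log(1.8), 0.35))))

  w <- data.frame(date = dates, tmax = tmax, tmin = tmin,
                  sunshine = sunshine, rh = rh, wind = wind, rain = rain)
  validate_weather(w)
}

# isolate RNG use: seed locally, restore the caller's RNG state on exit
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
}
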