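#' Default run configuration
#'
#' The full set of tunables as a nested list with blocks `weather`, `soil`,
#' `crop`, `et` and `scenario`, serialisable to/from JSON by
#' [write_config()]/[read_config()]. Values are the package defaults: the
#' Hetao climate preset, the loam soil set, the EPIC maize defaults, the
#' canopy/moisture ET coefficients, and the full-irrigation scenario at
#' 150 cm initial water-table depth.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  nrm <- hetao_normals()
  list(
    weather = list(source = "synthetic", seed = 1L,
                   t_month = nrm$t_month, rain_frac = nrm$rain_frac,
                   rain_total = nrm$rain_total, latitude = nrm$latitude,
                   elevation = nrm$elevation, file = NULL),
    soil = unclass(soil_params()),
    crop = unclass(crop_params())[
      setdiff(names(unclass(crop_params())), c("l1", "l2"))],
    et = unclass(et_params()),
    scenario = list(gwd0 = 150, treatment = "D0", theta0 = 0.3,
                    start = "2007-04-20", end = "2007-09-24"))
}

#' Read a run configuration file
#'
#' JSON with any subset of the blocks of [default_config()]; missing
#' entries fall back to the defaults.
#'
#' @param path JSON file path.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (blk in names(user)) {
    if (!blk %in% names(cfg)) stop("unknown configuration block: ", blk)
    for (key in names(user[[blk]])) cfg[[blk]][[key]] <- user[[blk]][[key]]
  }
  cfg
}

#' Write a run configuration file
#'
#' @param cfg configuration list. @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Materialise parameter objects from a configuration
#'
#' @param cfg configuration list from [read_config()] or
#'   [default_config()].
#' @return list with `normals`, `soil`, `crop`, `etp`, `spec`.
#' @export
config_objects <- function(cfg) {
  normals <- climate_normals(cfg$weather$t_month, cfg$weather$rain_frac,
                             cfg$weather$rain_total, cfg$weather$latitude,
                             cfg$weather$elevation)
  soil <- do.call(soil_params, cfg$soil)
  crop <- do.call(crop_params, cfg$crop)
  etp <- do.call(et_params, cfg$et)
  year <- as.integer(format(as.Date(cfg$scenario$start), "%Y"))
  weather <- NULL
  if (identical(cfg$weather$source, "file")) {
    if (is.null(cfg$weather$file)) stop("weather source 'file' needs a path")
    weather <- read_weather(cfg$weather$file)
  }
  spec <- scenario_spec(cfg$scenario$gwd0,
                        irrigation_schedule(cfg$scenario$treatment, year),
                        theta0 = cfg$scenario$theta0,
                        start = cfg$scenario$start, end = cfg$scenario$end,
                        weather = weather,
                        seed = cfg$weather$seed)
  list(normals = normals, soil = soil, crop = crop, etp = etp,
       spec = spec)
}

.cli_opt <- function(args, flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i)) return(default)
  if (i == length(args)) stop("missing value for ", flag)
  args[i + 1L]
}

#' Command-line interface
#'
#' Drives the simulator from the shell (see `inst/cli/shallowcrop`):
#' \describe{
#'   \item{`run --config FILE [--out DIR]`}{one season; writes `daily.csv`
#'     and `summary.json` to `--out` (or prints the summary).}
#'   \item{`grid --config FILE [--out DIR]`}{the treatment x depth grid;
#'     writes `grid.csv`.}
#'   \item{`fixture --gwd N --seed N [--treatment D0] [--out DIR]`}{a
#'     lysimeter-like scenario; writes `weather.csv` and `schedule.csv`.}
#'   \item{`eval --sim FILE --obs FILE`}{fit statistics between two
#'     single-column (or `value`-column) CSV series.}
#'   \item{`config --show-defaults`}{prints the default configuration as
#'     JSON.}
#' }
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
shallowcrop_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: shallowcrop <run|grid|fixture|eval|config> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]; rest <- args[-1L]
  if (cmd == "config") {
    cat(jsonlite::toJSON(default_config(), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null"), "\n")
    return(invisible(0L))
  }
  if (cmd == "eval") {
    read_series <- function(p) {
      d <- utils::read.csv(p)
      if ("value" %in% names(d)) d$value else d[[ncol(d)]]
    }
    fs <- fit_stats(read_series(.cli_opt(rest, "--sim")),
                    read_series(.cli_opt(rest, "--obs")))
    print(fs)
    return(invisible(0L))
  }
  if (cmd == "fixture") {
    gwd <- as.numeric(.cli_opt(rest, "--gwd", "150"))
    seed <- as.integer(.cli_opt(rest, "--seed", "1"))
    tr <- .cli_opt(rest, "--treatment", "D0")
    out <- .cli_opt(rest, "--out", ".")
    spec <- make_lysimeter_fixture(gwd, seed, tr)
    write_weather(spec$weather, file.path(out, "weather.csv"))
    utils::write.csv(spec$irrigation, file.path(out, "schedule.csv"),
                     row.names = FALSE)
    message("fixture written to ", out)
    return(invisible(0L))
  }
  cfgp <- .cli_opt(rest, "--config")
  cfg <- if (is.null(cfgp)) default_config() else read_config(cfgp)
  obj <- config_objects(cfg)
  out <- .cli_opt(rest, "--out")
  if (cmd == "run") {
    res <- run_season(obj$spec, obj$soil, obj$crop, obj$etp, obj$normals)
    if (is.null(out)) print(res) else {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(res$daily, file.path(out, "daily.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        res[c("et_total", "pet_total", "wf_net", "irrigation_total",
              "rain_total", "yield", "wp", "iwp")],
        file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
      message("season written to ", out)
    }
    return(invisible(0L))
  }
  if (cmd == "grid") {
    grid <- run_scenario_grid(soil = obj$soil, crop = obj$crop,
                              etp = obj$etp, normals = obj$normals,
                              theta0 = cfg$scenario$theta0,
                              start = cfg$scenario$start,
                              end = cfg$scenario$end,
                              weather = obj$spec$weather,
                              seed = cfg$weather$seed)
    if (is.null(out)) print(grid) else {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(grid, file.path(out, "grid.csv"),
                       row.names = FALSE)
      message("grid written to ", out)
    }
    return(invisible(0L))
  }
  stop("unknown command: ", cmd)
}
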