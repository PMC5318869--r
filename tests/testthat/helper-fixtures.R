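# Shared fixtures built in code.

loam <- soil_params()          # package loam defaults
maize <- crop_params()         # EPIC maize defaults
etp_def <- et_params()
hetao <- hetao_normals()

# a short, fully explicit weather table
tiny_weather <- function(n = 3, start = "2007-07-01") {
  data.frame(date = seq(as.Date(start), by = "day", length.out = n),
             tmax = 30 + seq_len(n) / 10, tmin = 17 - seq_len(n) / 10,
             sunshine = rep(10, n), rh = rep(45, n),
             wind = rep(2, n), rain = c(0, 5, rep(0, n - 2)))
}

# random but valid weather days for property tests
random_weather <- function(n, seed) {
  set.seed(seed)
  tmin <- runif(n, -5, 25)
  data.frame(date = seq(as.Date("2007-04-20"), by = "day",
                        length.out = n),
             tmax = tmin + runif(n, 0.5, 15), tmin = tmin,
             sunshine = runif(n, 0, 12), rh = runif(n, 10, 100),
             wind = runif(n, 0, 8),
             rain = ifelse(runif(n) < 0.25, rexp(n, 1 / 8), 0))
}

# a coupled state mid-season, for single-day property tests
mid_state <- function(theta1 = 0.25, theta2 = 0.28, rd = 50, gwd = 200,
                      soil = loam, crop = maize) {
  s <- soil_state(theta1, theta2, rd = rd, rd_mx = crop$rd_mx,
                  gwd = gwd, soil)
  c <- crop_state(crop)
  c$hui <- 0.5; c$hui_prev <- 0.49; c$lai <- 3; c$rd <- rd
  list(soil = s, crop = c)
}
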