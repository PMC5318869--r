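test_that("fit statistics hit their analytical anchors", {
  obs <- c(3.1, 4.7, 2.2, 5.9, 4.1)
  perfect <- fit_stats(obs, obs)
  expect_equal(perfect$mre, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$nse, 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$b, 1)

  # predicting the observed mean gives NSE exactly 0
  flat <- fit_stats(rep(mean(obs), 5), obs)
  expect_equal(flat$nse, 0)

  hand <- fit_stats(c(2, 2, 2), c(1, 2, 3))
  expect_equal(hand$rmse, sqrt(2 / 3))
  expect_equal(hand$nse, 0)
  expect_equal(hand$b, 12 / 14)   # sum(P*O)/sum(O^2) = (2+4+6)/14

  expect_warning(z <- fit_stats(c(1, 2), c(0, 2)), "zero")
  expect_true(is.na(z$mre))
  expect_warning(k <- fit_stats(c(1, 2), c(3, 3)), "constant")
  expect_true(is.na(k$nse))
})

test_that("fit statistics agree with a brute-force oracle on random pairs", {
  set.seed(2024)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    obs <- runif(n, 0.5, 50)
    pred <- obs * runif(1, 0.5, 1.5) + rnorm(n)
    got <- fit_stats(pred, obs)
    want <- fit_stats_brute(pred, obs)
    for (s in c("mre", "rmse", "nse", "r2", "b"))
      expect_equal(got[[s]], want[[s]], tolerance = 1e-12)
  }
})

test_that("NSE is affine-invariant while RMSE scales linearly", {
  set.seed(9)
  obs <- runif(20, 5, 15); pred <- obs + rnorm(20)
  a <- fit_stats(pred, obs)
  b <- fit_stats(2.5 * pred + 7, 2.5 * obs + 7)
  expect_equal(a$nse, b$nse, tolerance = 1e-12)
  expect_equal(b$rmse, 2.5 * a$rmse, tolerance = 1e-12)
  expect_equal(a$r2, b$r2, tolerance = 1e-12)
})

test_that("the d-factor measures normalised ensemble spread", {
  obs <- c(0, 1, 2) * 2            # sd = 2
  same <- matrix(5, nrow = 3, ncol = 10)
  expect_equal(d_factor(same, obs)$d_factor, 0)

  # equally spaced members: the 95% band is 0.95 of the full range
  ens <- t(sapply(c(10, 20, 30), function(c0)
    seq(c0 - 1, c0 + 1, length.out = 11)))
  df <- d_factor(ens, obs)
  expect_equal(df$d_bar, 0.95 * 2, tolerance = 1e-12)
  expect_equal(df$d_factor, 0.95 * 2 / 2, tolerance = 1e-12)

  # scale invariance: units cancel
  df2 <- d_factor(ens * 3.7, obs * 3.7)
  expect_equal(df2$d_factor, df$d_factor, tolerance = 1e-12)

  expect_error(d_factor(ens, c(4, 4, 4)), "constant")
})

eval_base <- function(seed = 1) {
  list(spec = scenario_spec(150, irrigation_schedule("D0", 2007),
                            seed = seed),
       soil = loam, crop = maize, etp = etp_def, normals = hetao)
}

test_that("sensitivity scans are exact at zero delta and respect decoupling", {
  base <- eval_base()
  sc <- sensitivity_scan(base, "hi", deltas = c(-0.2, 0, 0.2),
                         index = "ET")
  expect_equal(sc$rel_change[sc$delta == 0], 0)
  # harvest index never touches the water side
  expect_equal(max(abs(sc$rel_change)), 0)
  expect_error(sensitivity_scan(base, "nosuch"), "unknown parameter")
})

test_that("maximum leaf area dominates the leaf-area index response", {
  base <- eval_base()
  peak <- vapply(c("lai_mx", "hi", "be"), function(p) {
    sc <- sensitivity_scan(base, p, deltas = c(0, 0.25), index = "LAI")
    max(abs(sc$rel_change))
  }, numeric(1))
  expect_gt(peak[["lai_mx"]], peak[["hi"]])
  expect_gt(peak[["lai_mx"]], peak[["be"]])
  expect_gt(peak[["lai_mx"]], 0.1)      # a 25% change moves peak LAI
})

test_that("parameter ensembles give reproducible prediction bands", {
  base <- eval_base()
  ens <- ensemble_predictions(base, c("mf", "lai_mx"), n = 6, seed = 42,
                              extractor = function(r) r$daily$gwd)
  ens2 <- ensemble_predictions(base, c("mf", "lai_mx"), n = 6, seed = 42,
                               extractor = function(r) r$daily$gwd)
  expect_identical(ens, ens2)
  expect_equal(dim(ens), c(158L, 6L))
  obs <- ens[, 1] + stats::rnorm(nrow(ens))
  df <- d_factor(ens, obs)
  expect_gte(df$d_factor, 0)
})
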