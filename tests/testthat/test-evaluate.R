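test_that("fit statistics match hand-computed values", {
  # perfect fit
  fr <- fit_statistics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(fr$rmse, 0)
  expect_equal(fr$mae, 0)
  expect_equal(fr$mape, 0)
  expect_equal(fr$r_squared, 1)
  expect_equal(fr$r_squared_1to1, 1)

  # obs (2,4), pred (3,5): MAE 1, RMSE 1, MAPE (1/2 + 1/4)/2 = 37.5%
  fr <- fit_statistics(c(2, 4), c(3, 5))
  expect_equal(fr$mae, 1)
  expect_equal(fr$rmse, 1)
  expect_equal(fr$mape, 37.5)
  expect_equal(fr$mse, fr$rmse^2)
  expect_equal(fr$nrmse, 1 / 3 * 100)

  # constant predictions: 1:1 R2 may be <= 0 and is reported unclamped
  fr <- fit_statistics(c(1, 2, 3, 10), rep(2, 4))
  expect_lte(fr$r_squared_1to1, 0)

  expect_error(fit_statistics(1:3, 1:4), "equal length")
  expect_error(fit_statistics(c(0, 1), c(1, 2)), "MAPE")
})

test_that("divergence-line coverage counts points inside the CV envelope", {
  obs <- c(10, 12, 14, 16, 18, 20, 11, 13, 15, 17)
  # perfect predictions are always inside
  res <- divergence_coverage(obs, obs)
  expect_equal(res$coverage, 1)
  expect_true(res$pass)

  # exhaustive point-by-point oracle with two points pushed outside
  pred <- obs
  cv <- stats::sd(obs) / mean(obs)
  pred[c(2, 5)] <- obs[c(2, 5)] * (1 + cv + 0.05)
  res <- divergence_coverage(obs, pred)
  oracle <- mean(abs(pred - obs) <= cv * obs)
  expect_equal(res$coverage, oracle)
  expect_equal(res$coverage, 0.8)
  expect_true(res$pass)

  # one more point out: below the 0.80 threshold -> fail flag
  pred[8] <- obs[8] * (1 + cv + 0.05)
  expect_false(divergence_coverage(obs, pred)$pass)

  expect_error(divergence_coverage(5, 5), "single point")
})

test_that("the run manifest enumerates site-years x soils x cultivars", {
  m <- build_manifest("AllMali", 459, c("low_swhc", "high_swhc"),
                      c("CSM63E", "CSM335"))
  expect_equal(nrow(m), 1836)

  expect_equal(nrow(build_manifest("A", 1, "s", "c")), 1)
  expect_equal(nrow(build_manifest(c("A", "B", "C"), 10,
                                   c("s1", "s2"), c("c1", "c2"))), 120)

  # cardinality property over random counts
  set.seed(12)
  for (i in 1:10) {
    ns <- sample(1:4, 1); nsoil <- sample(1:3, 1); ncv <- sample(1:3, 1)
    seasons <- sample(1:20, ns, replace = TRUE)
    m <- build_manifest(paste0("S", seq_len(ns)), seasons,
                        paste0("soil", seq_len(nsoil)),
                        paste0("cv", seq_len(ncv)))
    expect_equal(nrow(m), sum(seasons) * nsoil * ncv)
  }

  # weather seeds are shared across soils and cultivars within a site-season
  m <- build_manifest(c("A", "B"), 3, c("s1", "s2"), c("c1", "c2"))
  key <- paste(m$site, m$season)
  expect_true(all(tapply(m$weather_seed, key, function(x) length(unique(x))) == 1))

  expect_error(build_manifest(character(), 1, "s", "c"), "counts")
})

test_that("the pipeline writes its artifacts and is reproducible", {
  config <- list(
    sites = list(
      list(name = "Nara", latitude = 15.2, isohyet = "400-600", n_seasons = 12),
      list(name = "Samanko", latitude = 12.5, isohyet = "800-1000",
           target_rainfall = 920, n_seasons = 12)),
    soils = c("low_swhc", "high_swhc"),
    cultivars = c("CSM63E", "CSM335"),
    seed = 5, output_dir = tempfile("pipe1"))
  res1 <- run_pipeline(config)
  files <- c("manifest.csv", "season_summary.csv", "trajectories.csv",
             "centroids.csv", "scenario_frequency.csv", "yield_cpf.csv",
             "exclusions.csv")
  expect_true(all(file.exists(file.path(config$output_dir, files))))
  expect_equal(nrow(res1$manifest), 24 * 2 * 2)

  # identical config + seed: byte-identical outputs
  config2 <- config; config2$output_dir <- tempfile("pipe2")
  run_pipeline(config2)
  for (f in files) {
    expect_identical(readLines(file.path(config$output_dir, f)),
                     readLines(file.path(config2$output_dir, f)))
  }
  unlink(config$output_dir, recursive = TRUE)
  unlink(config2$output_dir, recursive = TRUE)

  # unknown cultivar fails before any simulation
  bad <- config; bad$cultivars <- "CSM999"
  expect_error(run_pipeline(bad), "unknown cultivar")
  expect_error(run_pipeline(list(soils = "low_swhc")), "lacks")
})
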