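test_that("no distance decay in the draws gives a flat curve", {
  withr::with_seed(1, d <- make_draws(alpha = rnorm(200, 0.5, 0.2),
                                      beta_time = 0))
  cv <- treatment_curve(d, time_grid = c(0, 30, 120, 240))
  expect_true(all(abs(diff(cv$median)) < 1e-12))
  expect_true(all(abs(diff(cv$lo95)) < 1e-12))
})

test_that("a degenerate one-draw posterior collapses the interval", {
  d <- make_draws(alpha = 0, beta_time = 0, beta_urban = 0, c = 0.2)
  cv <- treatment_curve(d, time_grid = c(10, 60))
  expect_equal(cv$median, c(0.6, 0.6), tolerance = 1e-15)
  expect_equal(cv$hi95 - cv$lo95, c(0, 0), tolerance = 1e-15)
  expect_error(treatment_curve(d, time_grid = numeric()), "non-empty")
})

test_that("curve summaries equal a direct quantile computation and respect relabelling", {
  withr::with_seed(2, d <- make_draws(alpha = rnorm(1000, 0.5, 0.3),
                                      beta_time = -abs(rnorm(1000, 0.01, 0.003)),
                                      c = runif(1000, 0.1, 0.3)))
  grid <- c(10, 30, 60, 120)
  cv <- treatment_curve(d, grid)
  for (k in seq_along(grid)) {
    p <- item_probability(d$draws[1, , "alpha"] +
                            d$draws[1, , "beta_time"] * grid[k],
                          1, 0, d$draws[1, , "c"])
    expect_equal(cv$median[k], unname(quantile(p, 0.5)), tolerance = 1e-12)
    expect_equal(cv$lo95[k], unname(quantile(p, 0.025)), tolerance = 1e-12)
  }
  # permuting draws changes nothing
  perm <- d
  withr::with_seed(3, idx <- sample(1000))
  perm$draws <- d$draws[, idx, , drop = FALSE]
  expect_equal(treatment_curve(perm, grid)$median, cv$median, tolerance = 1e-12)
  # negative decay: medians non-increasing and floored by the median of c
  expect_true(all(diff(cv$median) <= 1e-12))
  expect_true(all(cv$median > median(d$draws[1, , "c"]) - 1e-12))
})

test_that("threshold summaries interpolate, format and validate", {
  d <- make_draws(alpha = c(0, 0), beta_time = c(0, 0), c = c(0.2, 0.2))
  cv <- treatment_curve(d, seq(0, 240, by = 5))
  tab <- summarize_at_thresholds(cv)
  expect_equal(tab$t_min, c(10, 30, 60, 120))
  expect_equal(tab$median, rep(0.6, 4), tolerance = 1e-12)
  expect_match(tab$formatted[1], "^0\\.60 \\(0\\.60-0\\.60\\)$")
  expect_equal(nrow(summarize_at_thresholds(cv, numeric())), 0)
  expect_error(summarize_at_thresholds(cv, 500), "outside")
})

test_that("floor summaries match a direct sorting oracle", {
  expect_equal(threshold_floor(make_draws(alpha = 0, c = 0.2))$median, 0.2)
  d3 <- make_draws(alpha = rep(0, 300), c = rep(c(0.1, 0.2, 0.3), 100))
  expect_equal(threshold_floor(d3)$median, 0.2)
  withr::with_seed(4, d <- make_draws(alpha = rep(0, 1000),
                                      c = rbeta(1000, 2, 5)))
  sorted <- sort(d$draws[1, , "c"])
  expect_equal(threshold_floor(d)$median, (sorted[500] + sorted[501]) / 2,
               tolerance = 1e-12)
})

test_that("probability maps agree with pointwise curve evaluation and keep nodata", {
  withr::with_seed(5, {
    d <- make_draws(alpha = rnorm(300, 0.4, 0.2),
                    beta_time = -abs(rnorm(300, 0.01, 0.002)),
                    beta_urban = rnorm(300, 0.3, 0.1),
                    c = runif(300, 0.15, 0.25))
    tt <- fever_raster(matrix(runif(64, 0, 300), 8, 8), 1000)
  })
  tt$values[3, 5] <- NA
  urb <- fever_raster(matrix(rep(0:1, 32), 8, 8), 1000)
  pm <- probability_raster(d, tt, urb)
  expect_true(is.na(pm$values[3, 5]))
  for (cell in list(c(1, 1), c(8, 8), c(4, 2))) {
    r <- cell[1]; c <- cell[2]
    res <- if (urb$values[r, c] == 1) "urban" else "rural"
    ref <- treatment_curve(d, tt$values[r, c], residence = res)$median
    expect_equal(pm$values[r, c], ref, tolerance = 1e-12)
  }
  bad <- fever_raster(matrix(0, 4, 4), 1000)
  expect_error(probability_raster(d, tt, bad), "same grid")
})

test_that("urban and rural strata shift the curve by the urban coefficient's sign", {
  d <- make_draws(alpha = rep(0.2, 50), beta_time = rep(-0.01, 50),
                  beta_urban = rep(0.4, 50), c = rep(0.2, 50))
  ru <- treatment_curve(d, c(30, 60), "rural")
  ur <- treatment_curve(d, c(30, 60), "urban")
  expect_true(all(ur$median > ru$median))
})
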