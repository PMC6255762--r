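test_that("retained-draw bookkeeping equals the closed form", {
  cases <- list(c(550000, 50000, 500, 1000),
                c(22000, 2000, 10, 2000),
                c(1000, 100, 7, 128),
                c(101, 100, 1, 1))
  for (cs in cases)
    expect_identical(retained_draws(mcmc_config(cs[1], cs[2], cs[3])),
                     as.integer(cs[4]))
  expect_error(mcmc_config(100, 100, 1), "burn_in")
  expect_error(mcmc_config(100, 10, 0), "thinning")
})

test_that("sampler moments match grid quadrature on the reduced model", {
  withr::with_seed(99, {
    t <- runif(20, 0, 120)
    y <- rbinom(20, 1, item_probability(0.5 - 0.01 * t, 1, 0, 0.2))
  })
  ch <- tibble::tibble(response = y, travel_time_min = t, urban = 0L)
  fit <- fit_treatment_irt(ch, config = mcmc_config(seed = 7),
                           fix = list(beta_time = -0.01, beta_urban = 0, c = 0.2))
  td <- tidy(fit)
  expect_identical(td$term, "alpha")

  # 1-D deterministic quadrature oracle for the alpha posterior; the grid
  # spans the prior tails because the flat 3PL floor leaves them heavy
  pr <- prior_spec()
  grid <- seq(-25, 25, length.out = 20001)
  ll <- vapply(grid, function(aa) {
    p <- item_probability(aa - 0.01 * t, 1, 0, 0.2)
    sum(ifelse(y == 1, log(p), log1p(-p)))
  }, numeric(1))
  lp <- ll + dnorm(grid, pr$alpha_mean, pr$alpha_sd, log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  q_mean <- sum(w * grid)
  q_sd <- sqrt(sum(w * grid^2) - q_mean^2)

  draws <- feverseek:::pooled_draws(fit$draws, "alpha")[, 1]
  mcse <- batch_mcse(fit$draws$draws[, , "alpha"])
  expect_lt(abs(mean(draws) - q_mean), 3 * mcse$mean)
  expect_lt(abs(sd(draws) - q_sd), 3 * mcse$sd + 0.02 * q_sd)
})

test_that("chains are reproducible, constraint-respecting and honestly bookkept", {
  ch <- make_children(rep(seq(0, 480, length.out = 40), each = 20), 0, seed = 3)
  cfg <- mcmc_config(3000, 500, 5, 2, seed = 42)
  f1 <- fit_treatment_irt(ch, config = cfg)
  f2 <- fit_treatment_irt(ch, config = cfg)
  expect_identical(f1$draws$draws, f2$draws$draws)
  expect_equal(dim(f1$draws$draws)[2], retained_draws(cfg))
  cdraws <- feverseek:::pooled_draws(f1$draws, "c")[, 1]
  expect_true(all(cdraws > 0 & cdraws < 1))
  expect_true(all(feverseek:::pooled_draws(f1$draws, "a")[, 1] > 0))
  # adapted acceptance lands in the targeted band
  expect_true(all(unlist(f1$acceptance) > 0.1 & unlist(f1$acceptance) < 0.6))
})

test_that("degenerate inputs are rejected", {
  empty <- tibble::tibble(response = c(NA_integer_, NA_integer_),
                          travel_time_min = c(1, 2), urban = 0L)
  expect_error(fit_treatment_irt(empty), "missing")
  bad <- tibble::tibble(response = 2L, travel_time_min = 1, urban = 0L)
  expect_error(fit_treatment_irt(bad), "0, 1 or missing")
})

test_that("the multi-item configuration anchors the first item and frees the rest", {
  withr::with_seed(8, {
    t <- runif(3000, 0, 300)
    item <- sample(c("hospital", "dispensary"), 3000, replace = TRUE)
    a <- ifelse(item == "hospital", 1, 1.3)
    b <- ifelse(item == "hospital", 0, -0.2)
    p <- item_probability(0.4 - 0.008 * t, a, b, 0.2)
    ch <- tibble::tibble(response = rbinom(3000, 1L, p),
                         travel_time_min = t, urban = 0L, item = item)
  })
  fit <- fit_treatment_irt(ch, config = mcmc_config(4000, 1000, 5, 2, seed = 5))
  terms <- tidy(fit)$term
  anchor <- fit$items[1]
  other <- setdiff(fit$items, anchor)
  expect_true(all(c("alpha", "beta_time",
                    paste0("a[", other, "]"), paste0("b[", other, "]"),
                    paste0("c[", fit$items, "]")) %in% terms))
  expect_false(paste0("a[", anchor, "]") %in% terms)  # anchor
})
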