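test_that("response probability has the 3PL floor, midpoint and arithmetic", {
  expect_equal(item_probability(-50, 1, 0, 0.3), 0.3, tolerance = 1e-15)
  expect_equal(item_probability(0, 1, 0, 0), 0.5, tolerance = 1e-15)
  expect_equal(item_probability(0, 1, 0, 0.2), 0.2 + 0.8 * 0.5, tolerance = 1e-15)
  # midpoint (1 + c) / 2 at a * theta = b
  expect_equal(item_probability(2, 1.5, 3, 0.4), (1 + 0.4) / 2, tolerance = 1e-15)
  # stable at extreme linear predictors
  expect_equal(item_probability(700, 1, 0, 0.1), 1, tolerance = 1e-12)
  expect_equal(item_probability(-700, 1, 0, 0.1), 0.1, tolerance = 1e-12)
})

test_that("probability is increasing in ability, decreasing in difficulty, bounded by the floor", {
  theta <- seq(-8, 8, length.out = 200)
  p <- item_probability(theta, a = 1.3, b = 0.4, c = 0.25)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0.25 & p < 1))
  b_grid <- seq(-3, 3, length.out = 50)
  expect_true(all(diff(item_probability(0.7, 1, b_grid, 0.1)) < 0))
  expect_error(item_probability(0, 1, 0, 1.2), "c must")
  expect_error(item_probability(0, -1, 0, 0.2), "a must")
})

test_that("log-likelihood matches a naive term-by-term oracle", {
  expect_equal(log_likelihood(tibble::tibble(response = integer(),
                                             travel_time_min = numeric(),
                                             urban = integer()),
                              tibble::tibble(item = "i", a = 1, b = 0, c = 0.2),
                              ability_model()), 0)
  one <- tibble::tibble(response = 1L, travel_time_min = 0, urban = 0L)
  expect_equal(log_likelihood(one, tibble::tibble(item = "i", a = 1, b = 0, c = 0.2),
                              ability_model(alpha = 0)),
               log(0.6), tolerance = 1e-15)

  withr::with_seed(42, {
    ch <- tibble::tibble(response = sample(c(0L, 1L, NA), 20, replace = TRUE),
                         travel_time_min = runif(20, 0, 200),
                         urban = sample(0:1, 20, replace = TRUE))
  })
  items <- tibble::tibble(item = "i", a = 1.4, b = -0.3, c = 0.15)
  ab <- ability_model(alpha = 0.6, beta_time = -0.008, beta_urban = 0.3)
  # independent summation loop
  oracle <- 0
  for (k in seq_len(20)) {
    y <- ch$response[k]
    if (is.na(y)) next
    th <- 0.6 - 0.008 * ch$travel_time_min[k] + 0.3 * ch$urban[k]
    pk <- 0.15 + 0.85 * exp(1.4 * th + 0.3) / (1 + exp(1.4 * th + 0.3))
    oracle <- oracle + if (y == 1) log(pk) else log(1 - pk)
  }
  expect_equal(log_likelihood(ch, items, ab), oracle, tolerance = 1e-12)
  # permutation invariance
  perm <- ch[sample(20), ]
  expect_equal(log_likelihood(perm, items, ab), oracle, tolerance = 1e-12)
  # invalid codes rejected
  ch$response[1] <- 2L
  expect_error(log_likelihood(ch, items, ab), "0, 1 or missing")
})

test_that("log-prior matches independently written textbook densities", {
  pr <- prior_spec()
  neg <- tibble::tibble(item = "i", a = -0.5, b = 0, c = 0.2)
  expect_equal(log_prior(neg, ability_model(), pr), -Inf)

  # uniform Beta(1, 1) contributes zero for c
  pr_flat <- prior_spec(c_shape1 = 1, c_shape2 = 1)
  base <- tibble::tibble(item = "i", a = 1, b = 0, c = 0.5)
  with_c <- log_prior(base, ability_model(), pr_flat)
  ref_no_c <- log(dnorm(1, 0, 2.5) / (1 - pnorm(0, 0, 2.5))) +
    dnorm(0, 0, 5, log = TRUE) +  # b
    dnorm(0, 0, 5, log = TRUE) +  # alpha
    dnorm(0, 0, 1, log = TRUE) * 2  # slopes at zero
  expect_equal(with_c, ref_no_c, tolerance = 1e-12)

  # full parameter set against hand-written density formulas
  items <- tibble::tibble(item = "i", a = 1.7, b = -0.4, c = 0.33)
  ab <- ability_model(alpha = 0.2, beta_time = -0.012, beta_urban = 0.5)
  ref <- log(dnorm(1.7, 0, 2.5)) - log(1 - pnorm(0, 0, 2.5)) +
    log(dbeta(0.33, 2, 5)) +
    log(dnorm(-0.4, 0, 5)) + log(dnorm(0.2, 0, 5)) +
    log(dnorm(-0.012 * 60, 0, 1)) + log(dnorm(0.5, 0, 1))
  expect_equal(log_prior(items, ab, pr), ref, tolerance = 1e-12)
})
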