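one_unit_world <- function(units = matrix(1L, 4, 4), pop = matrix(250, 4, 4)) {
  list(admin = fever_raster(units, 1000), population = fever_raster(pop, 1000))
}

test_that("a single unit reproduces the closed-form rate", {
  w <- one_unit_world()  # under-5 population 4000
  clusters <- tibble::tibble(cluster_id = "cl_01", x_pub = 500, y_pub = 500)
  children <- tibble::tibble(cluster_id = "cl_01",
                             fever = rep(1L, 20),
                             response = rep(c(1L, 0L), 10))
  agg <- admin_rates(children, clusters, w$admin, w$population)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$fever_n, 20)
  expect_equal(agg$treated_n, 10)
  expect_equal(agg$pop_u5, 4000)
  expect_equal(agg$rate_per_1000, 500)
})

test_that("zero treated cases give zero rates everywhere", {
  w <- one_unit_world(units = matrix(rep(1:2, each = 8), 4, 4))
  clusters <- tibble::tibble(cluster_id = c("a", "b"),
                             x_pub = c(500, 3500), y_pub = c(500, 500))
  children <- tibble::tibble(cluster_id = rep(c("a", "b"), each = 10),
                             fever = 1L, response = 0L)
  agg <- admin_rates(children, clusters, w$admin, w$population)
  expect_equal(agg$rate_per_1000, c(0, 0))
})

test_that("two units with distinct data match hand enumeration", {
  units <- matrix(rep(1:2, each = 8), 4, 4)  # columns 1-2 unit 1, 3-4 unit 2
  pop <- matrix(c(rep(100, 8), rep(300, 8)), 4, 4)
  w <- one_unit_world(units, pop)
  clusters <- tibble::tibble(cluster_id = c("a", "b"),
                             x_pub = c(1500, 2500), y_pub = c(2500, 1500))
  children <- dplyr::bind_rows(
    tibble::tibble(cluster_id = "a", fever = c(1L, 1L, 1L, 0L),
                   response = c(1L, 0L, NA, NA)),
    tibble::tibble(cluster_id = "b", fever = c(1L, 1L, 0L),
                   response = c(1L, 1L, NA)))
  agg <- admin_rates(children, clusters, w$admin, w$population)
  expect_equal(agg$fever_n, c(3, 2))
  expect_equal(agg$responded_n, c(2, 2))
  expect_equal(agg$treated_n, c(1, 2))
  expect_equal(agg$pop_u5, c(800, 2400))
  expect_equal(agg$rate_per_1000, c(500, 1000))
  # a unit with no sampled fever case is flagged missing
  children2 <- children[children$cluster_id == "a", ]
  agg2 <- admin_rates(children2, clusters, w$admin, w$population)
  expect_true(is.na(agg2$rate_per_1000[2]))
})

test_that("the national summary is the population-weighted unit mean", {
  agg <- tibble::tibble(admin_unit = 1:2, fever_n = c(5, 5),
                        responded_n = c(5, 5), treated_n = c(1, 3),
                        pop_u5 = c(1, 3), rate_per_1000 = c(2, 6))
  expect_equal(national_summary(agg), 5.0)
  agg$rate_per_1000 <- c(4, 4)
  expect_equal(national_summary(agg), 4)
  withr::with_seed(7, {
    agg10 <- tibble::tibble(admin_unit = 1:10, fever_n = 1, responded_n = 1,
                            treated_n = 1, pop_u5 = runif(10, 100, 1000),
                            rate_per_1000 = runif(10, 0, 900))
  })
  expect_equal(national_summary(agg10),
               sum(agg10$pop_u5 * agg10$rate_per_1000) / sum(agg10$pop_u5),
               tolerance = 1e-12)
  expect_gte(national_summary(agg10), min(agg10$rate_per_1000))
  expect_lte(national_summary(agg10), max(agg10$rate_per_1000))
  # doubling every population leaves the summary unchanged
  agg2 <- agg10; agg2$pop_u5 <- 2 * agg2$pop_u5
  expect_equal(national_summary(agg2), national_summary(agg10), tolerance = 1e-12)
  agg10$rate_per_1000 <- NA_real_
  expect_error(national_summary(agg10), "missing")
})

test_that("clusters outside every admin unit are rejected", {
  w <- one_unit_world()
  clusters <- tibble::tibble(cluster_id = "far", x_pub = 1e6, y_pub = 0)
  children <- tibble::tibble(cluster_id = "far", fever = 1L, response = 1L)
  expect_error(admin_rates(children, clusters, w$admin, w$population),
               "outside every admin unit")
})
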