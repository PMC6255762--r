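test_that("the holdout split is a reproducible partition with the right sizes", {
  ch <- tibble::tibble(child_id = 1:100, response = rep(0:1, 50),
                       travel_time_min = 1, urban = 0L)
  s1 <- holdout_split(ch, 0.10, seed = 5)
  s2 <- holdout_split(ch, 0.10, seed = 5)
  expect_equal(nrow(s1$test), 10)
  expect_equal(nrow(s1$train), 90)
  expect_identical(s1$test$child_id, s2$test$child_id)
  expect_length(intersect(s1$train$child_id, s1$test$child_id), 0)
  expect_setequal(c(s1$train$child_id, s1$test$child_id), ch$child_id)
  expect_error(holdout_split(ch, 0), "between 0 and 1")
  expect_error(holdout_split(ch, 1.2), "between 0 and 1")
})

test_that("multi-survey data is split within each survey", {
  ch <- tibble::tibble(child_id = 1:1000,
                       survey = rep(c("A", "B"), c(600, 400)),
                       response = rep(0:1, 500))
  s <- holdout_split(ch, 0.10, seed = 3)
  expect_equal(sum(s$test$survey == "A"), 60)
  expect_equal(sum(s$test$survey == "B"), 40)
})

test_that("children without an observed response stay in the training data", {
  ch <- tibble::tibble(child_id = 1:60,
                       response = c(rep(NA_integer_, 20), rep(0:1, 20)))
  s <- holdout_split(ch, 0.25, seed = 2)
  expect_equal(nrow(s$test), 10)  # 25% of the 40 observed
  expect_true(all(!is.na(s$test$response)))
})

test_that("holdout predictions reduce to the plug-in probability for a point posterior", {
  d <- make_draws(alpha = 0.5, beta_time = -0.01, beta_urban = 0.3, c = 0.2)
  test <- tibble::tibble(travel_time_min = c(0, 60, 120), urban = c(0L, 1L, 0L))
  preds <- predict_holdout(d, test)
  ref <- item_probability(0.5 - 0.01 * test$travel_time_min + 0.3 * test$urban,
                          1, 0, 0.2)
  expect_equal(preds, ref, tolerance = 1e-15)
  # distance decay orders predictions
  expect_gt(preds[1], preds[3])
})

test_that("predictions match a per-child quantile oracle and flag missing covariates", {
  withr::with_seed(6, {
    d <- make_draws(alpha = rnorm(400, 0.5, 0.2),
                    beta_time = -abs(rnorm(400, 0.01, 0.002)),
                    beta_urban = rnorm(400, 0.3, 0.1), c = runif(400, 0.1, 0.3))
    test <- tibble::tibble(travel_time_min = runif(50, 0, 300),
                           urban = sample(0:1, 50, replace = TRUE))
  })
  preds <- predict_holdout(d, test)
  for (k in c(1, 17, 50)) {
    p <- item_probability(d$draws[1, , "alpha"] +
                            d$draws[1, , "beta_time"] * test$travel_time_min[k] +
                            d$draws[1, , "beta_urban"] * test$urban[k],
                          1, 0, d$draws[1, , "c"])
    expect_equal(preds[k], median(p), tolerance = 1e-12)
  }
  test$travel_time_min[3] <- NA
  test$child_id <- sprintf("ch_%02d", 1:50)
  expect_error(predict_holdout(d, test), "ch_03")
})

test_that("misclassification counts binarised disagreements", {
  expect_equal(misclassification(rep(0.9, 5), rep(1, 5)), 0)
  expect_equal(misclassification(rep(0.9, 5), rep(0, 5)), 1)
  preds <- c(0.9, 0.8, 0.2, 0.6, 0.4, 0.51, 0.49, 0.5, 0.1, 0.95)
  obs <- c(1, 0, 0, 1, 1, 0, 1, 1, 0, 1)
  # hand count at cutoff 0.5: predicted pos = {1,2,4,6,8,10}
  expect_equal(misclassification(preds, obs), 4 / 10)
  expect_error(misclassification(numeric(), integer()), "empty")
  # boundary cutoffs recover the class prevalences
  expect_equal(misclassification(preds, obs, cutoff = 0), mean(obs == 0))
  expect_equal(misclassification(preds, obs, cutoff = 1.01), mean(obs == 1))
})

test_that("ROC handles perfect separation and all-tied scores exactly", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1.0)
  tied <- roc_curve(rep(0.5, 10), rep(0:1, 5))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)), "both outcome classes")
})

test_that("trapezoid AUC equals the Mann-Whitney pair count on random instances", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(10:200, 1)
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
      labels <- rbinom(n, 1, 0.4)
    })
    if (length(unique(labels)) < 2) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, pair_count_auc(scores, labels), tolerance = 1e-12)
    # ROC path is a monotone sweep from (0,0) to (1,1)
    expect_equal(c(r$points$fpr[1], r$points$tpr[1]), c(0, 0))
    expect_equal(c(tail(r$points$fpr, 1), tail(r$points$tpr, 1)), c(1, 1))
    expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  }
})

test_that("our AUC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  withr::with_seed(30, {
    scores <- runif(150)
    labels <- rbinom(150, 1, plogis(3 * scores - 1.5))
  })
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
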