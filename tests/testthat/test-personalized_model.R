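# in-memory feature matrix: per-sensor force proportional to total weight
# plus optional Gaussian feature noise, n_rows windows per weight
make_fm <- function(body_weight, weights = c(0, 2, 3, 5, 7, 9, 11, 13),
                    n_rows = 25, noise = 0, iteration = 1L, pid = "T01",
                    scale = 1, seed = 1) {
  set.seed(seed)
  rows <- lapply(weights, function(w) {
    f <- 4.448 * (body_weight + w) * scale
    raw <- matrix(f / 32, n_rows, 32)
    raw <- raw * (1 + matrix(rnorm(n_rows * 32, 0, noise), n_rows, 32))
    raw <- cbind(raw / 10, rowSums(raw[, 1:16]), rowSums(raw[, 17:32]))
    colnames(raw) <- raw_feature_names()
    out <- data.frame(synthesize_features(raw), check.names = FALSE)
    out$label <- body_weight + w
    out$participant_id <- pid
    out$carried_weight <- w
    out$iteration <- iteration
    out$window <- seq_len(n_rows)
    out
  })
  structure(do.call(rbind, rows), class = c("feature_matrix", "data.frame"))
}

test_that("the five metrics follow their definitions", {
  r <- evaluate_predictions(c(100, 110), c(101, 108))
  expect_equal(r$mae, 1.5)
  expect_equal(r$mse, 2.5)
  expect_equal(r$rmse, sqrt(2.5))
  expect_equal(r$r2, 1 - 2.5 / 25)
  expect_equal(r$mape, (1 / 100 + 2 / 110) / 2)

  perfect <- evaluate_predictions(c(150, 155, 160), c(150, 155, 160))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)

  expect_warning(z <- evaluate_predictions(c(5, 5), c(4, 6)), "R\\^2")
  expect_true(is.nan(z$r2))
  expect_error(evaluate_predictions(c(0, 1), c(1, 1)), "MAPE")

  # identities on random inputs
  set.seed(3)
  for (i in 1:20) {
    y <- runif(50, 100, 200)
    p <- y + rnorm(50)
    r <- evaluate_predictions(y, p)
    expect_equal(r$rmse^2, r$mse, tolerance = 1e-9)
    expect_lte(r$mae, r$rmse + 1e-12)
    expect_lte(r$r2, 1)
  }
})

test_that("per-weight MAE breakdown groups on carried weight", {
  r <- evaluate_predictions(c(150, 150, 155), c(151, 149, 157),
                            carried_weight = c(0, 0, 5))
  expect_equal(r$per_weight_mae$carried_weight, c(0, 5))
  expect_equal(r$per_weight_mae$mae, c(1, 2))
})

test_that("aggregate_reports is the unweighted metric mean", {
  r1 <- evaluate_predictions(c(100, 110), c(101, 108))
  r2 <- evaluate_predictions(c(200, 150), c(199, 152))
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(agg$mae, mean(c(r1$mae, r2$mae)))
  expect_equal(agg$rmse, mean(c(r1$rmse, r2$rmse)))
  expect_lte(agg$mae, agg$rmse)
  # single report aggregates to itself
  one <- aggregate_reports(list(r1))
  expect_equal(one$mae, r1$mae)
  expect_equal(one$mape, r1$mape)
})

test_that("training validates its preconditions", {
  fm <- make_fm(150)
  single <- fm[fm$carried_weight == 0, ]
  expect_error(train_participant(single), "single label")
  expect_error(train_participant(fm[c(1, 30, 60), ],
                                 model_config(cv_folds = 2L)),
               "at least 4 rows")
  two <- make_fm(160, pid = "T02")
  expect_error(train_participant(rbind(fm, two)), "per participant")
  expect_error(train_participant(fm[, -3], model_config()), "missing columns")
})

test_that("a noise-free participant is learned almost exactly", {
  fm <- make_fm(150)
  m <- train_participant(fm, model_config(seed = 5))
  expect_lt(m$validation$mae, 0.01)
  expect_length(m$importance, 40)
  expect_true(all(m$importance >= 0))
  expect_equal(sum(m$importance), 1, tolerance = 1e-9)
  expect_length(m$cv_mae, 5)
  # unconstrained forests interpolate their training rows
  expect_equal(unname(predict(m, fm)), fm$label, tolerance = 1e-9)
})

test_that("fits are deterministic given the seed", {
  fm <- make_fm(170, noise = 0.01)
  m1 <- train_participant(fm, model_config(seed = 9))
  m2 <- train_participant(fm, model_config(seed = 9))
  expect_identical(m1$cv_mae, m2$cv_mae)
  expect_identical(predict(m1, fm), predict(m2, fm))
  m3 <- train_participant(fm, model_config(seed = 10))
  expect_false(identical(m1$cv_mae, m3$cv_mae))
})

test_that("noisy monotone data still rank-correlates", {
  fm <- make_fm(140, noise = 0.03, seed = 2)
  m <- train_participant(fm, model_config(cv_folds = 0L, seed = 2))
  test <- make_fm(140, noise = 0.03, seed = 3)
  p <- predict(m, test)
  expect_gt(cor(p, test$label, method = "spearman"), 0.95)
})

test_that("personalized models do not transfer between participants", {
  # same feature ranges (scale adjusted), different body weights
  a <- make_fm(130, pid = "A", noise = 0.005, seed = 4)
  b <- make_fm(190, pid = "B", noise = 0.005, scale = 130 / 190, seed = 5)
  expect_equal(mean(a$force_sum), mean(b$force_sum), tolerance = 0.05)
  ma <- train_participant(a, model_config(cv_folds = 0L, seed = 1))
  mb <- train_participant(b, model_config(cv_folds = 0L, seed = 1))
  own_a <- evaluate_predictions(a$label, predict(ma, a))$mae
  cross_a <- evaluate_predictions(a$label, predict(mb, a))$mae
  expect_lt(own_a, 0.5)
  expect_gt(cross_a, 20)
})

test_that("prediction rejects schema mismatches", {
  fm <- make_fm(150)
  m <- train_participant(fm, model_config(cv_folds = 0L))
  expect_error(predict(m, fm[, 1:10]), "missing feature columns")
})

test_that("unavailable learners raise an informative error", {
  expect_error(model_config(learner = "lightgbm"), "not available")
  expect_error(model_config(learner = "nonsense"))
})
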