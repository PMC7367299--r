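make_linear_sim <- function(n, seed, sigma = 0.5, p_noise = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * (1 + p_noise)), n)
  y <- 2 * x[, 1] + rnorm(n, 0, sigma)
  list(frame = continuous_frame(x), y = y)
}

test_that("unshrunk boosting without bagging interpolates the data", {
  set.seed(1)
  n <- 50
  x <- matrix(rnorm(n * 2), n)
  y <- rnorm(n)
  cfg <- brt_config(learning_rate = 1, bag_fraction = 1,
                    tree_complexity = n - 1, max_trees = 60, rng_seed = 1)
  fit <- fit_brt(continuous_frame(x), y, cfg, cv = FALSE)
  rms <- sqrt(mean((predict(fit) - y)^2))
  expect_lt(rms, 1e-6)
})

test_that("training deviance is non-increasing without bagging", {
  sim <- make_linear_sim(120, seed = 2)
  cfg <- brt_config(learning_rate = 0.1, bag_fraction = 1, max_trees = 150,
                    rng_seed = 2)
  fit <- fit_brt(sim$frame, sim$y, cfg, cv = FALSE)
  expect_true(all(diff(fit$train_deviance) <= 1e-12))
})

test_that("cross-validation recovers a linear signal well above the null", {
  for (seed in 1:5) {
    sim <- make_linear_sim(200, seed = seed)
    cfg <- brt_config(learning_rate = 0.05, step_size = 25, n_folds = 5,
                      max_trees = 1500, rng_seed = seed)
    fit <- fit_brt(sim$frame, sim$y, cfg)
    expect_lt(fit$cv_deviance, 0.4 * fit$null_deviance)
    # CV estimate should sit within 10 points of the analytic noise floor
    expected <- 100 * (1 - 0.5^2 / var(sim$y))
    expect_lt(abs(percent_deviance_explained(fit) - expected), 10)
  }
})

test_that("identical config and seed give bit-identical fits", {
  sim <- make_linear_sim(80, seed = 3)
  cfg <- brt_config(learning_rate = 0.05, step_size = 25, n_folds = 5,
                    max_trees = 300, rng_seed = 99)
  f1 <- fit_brt(sim$frame, sim$y, cfg)
  f2 <- fit_brt(sim$frame, sim$y, cfg)
  expect_identical(f1$trees, f2$trees)
  expect_identical(variable_importance(f1), variable_importance(f2))
  expect_identical(f1$cv_trace, f2$cv_trace)
})

test_that("halving the learning rate and doubling the trees is consistent", {
  sim <- make_linear_sim(150, seed = 4)
  base <- fit_brt(sim$frame, sim$y,
                  brt_config(learning_rate = 0.1, bag_fraction = 1,
                             max_trees = 200, rng_seed = 1), cv = FALSE)
  half <- fit_brt(sim$frame, sim$y,
                  brt_config(learning_rate = 0.05, bag_fraction = 1,
                             max_trees = 400, rng_seed = 1), cv = FALSE)
  rel_rms <- sqrt(mean((predict(base) - predict(half))^2)) / sd(sim$y)
  expect_lt(rel_rms, 0.05)
})

test_that("training predictions agree with an established gbm
           implementation", {
  skip_if_not_installed("xgboost")
  sim <- make_linear_sim(200, seed = 5)
  cfg <- brt_config(learning_rate = 0.1, tree_complexity = 1,
                    bag_fraction = 1, max_trees = 150, rng_seed = 1)
  ours <- fit_brt(sim$frame, sim$y, cfg, cv = FALSE)
  enc <- phylobrt:::encode_model_frame(sim$frame)
  dm <- xgboost::xgb.DMatrix(enc$x, label = sim$y)
  xgb <- xgboost::xgb.train(
    params = list(eta = 0.1, max_depth = 1, lambda = 0, gamma = 0,
                  min_child_weight = 0, subsample = 1,
                  base_score = mean(sim$y), objective = "reg:squarederror"),
    data = dm, nrounds = 150
  )
  theirs <- predict(xgb, dm)
  expect_gt(cor(predict(ours), theirs), 0.99)
})

test_that("degenerate responses and tiny inputs raise errors", {
  x <- matrix(rnorm(40), 20)
  expect_error(fit_brt(continuous_frame(x), rep(1, 20)), "degenerate")
  expect_error(
    fit_brt(continuous_frame(x[1:5, , drop = FALSE]), rnorm(5),
            brt_config(n_folds = 10)),
    "n_folds"
  )
})

test_that("a reloaded model reproduces predictions and importance exactly", {
  sim <- make_linear_sim(60, seed = 6)
  cfg <- brt_config(learning_rate = 0.1, max_trees = 100, n_folds = 5,
                    step_size = 25, rng_seed = 7)
  fit <- fit_brt(sim$frame, sim$y, cfg)
  tf <- tempfile(fileext = ".json")
  write_brt(fit, tf)
  back <- read_brt(tf)
  expect_equal(predict(back, sim$frame), predict(fit, sim$frame),
               tolerance = 1e-12)
  expect_equal(variable_importance(back)$vi, variable_importance(fit)$vi,
               tolerance = 1e-12)
})
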