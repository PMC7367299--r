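fit_quick <- function(frame, y, seed = 1, max_trees = 200, ...) {
  fit_brt(frame, y, brt_config(learning_rate = 0.1, bag_fraction = 1,
                               max_trees = max_trees, rng_seed = seed, ...),
          cv = FALSE)
}

test_that("importance sums to 100, zeroes unused predictors, and is
           order-invariant", {
  set.seed(8)
  n <- 150
  x <- matrix(rnorm(n * 5), n)
  y <- 3 * x[, 2] + rnorm(n, 0, 0.3)
  frame <- continuous_frame(x)
  fit <- fit_quick(frame, y)
  vi <- variable_importance(fit)
  expect_equal(sum(vi$vi), 100, tolerance = 1e-9)
  expect_true(all(vi$vi >= 0))
  expect_equal(vi$vi[vi$term == "x2"], max(vi$vi))

  # an all-missing-signal predictor never splits and scores exactly zero
  x2 <- cbind(x, x6 = rep(1, n))
  fit2 <- fit_quick(continuous_frame(x2), y)
  vi2 <- variable_importance(fit2)
  expect_identical(vi2$vi[vi2$term == "x6"], 0)

  # permuting predictor columns leaves per-term scores unchanged (away
  # from the interpolation regime, where exact split-gain ties can arise)
  fit30 <- fit_quick(frame, y, max_trees = 30)
  vi <- variable_importance(fit30)
  xp <- x[, c(3, 1, 5, 2, 4)]
  colnames(xp) <- paste0("x", c(3, 1, 5, 2, 4))
  fitp <- fit_quick(continuous_frame(xp), y, max_trees = 30)
  vip <- variable_importance(fitp)
  expect_equal(
    setNames(vip$vi, vip$term)[paste0("x", 1:5)],
    setNames(vi$vi, vi$term)[paste0("x", 1:5)],
    tolerance = 1e-9
  )
})

test_that("a single informative predictor dominates importance", {
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    n <- 300
    x <- matrix(rnorm(n * 11), n)
    y <- 4 * x[, 1] + rnorm(n, 0, 0.5)
    fit <- fit_quick(continuous_frame(x), y, seed = seed)
    vi <- variable_importance(fit)
    if (vi$vi[vi$term == "x1"] > 80) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("partial dependence is flat for unused predictors and recovers
           additive component shapes", {
  set.seed(9)
  n <- 500
  x <- matrix(runif(n * 3, -2, 2), n)
  # piecewise-constant components: representable exactly by the learner,
  # so deviations measure the partial-dependence machinery itself
  f1 <- function(v) ifelse(v > 0.5, 1, ifelse(v > -0.5, 0.2, -0.8))
  f2 <- function(v) ifelse(v > 0, 0.7, -0.7)
  y <- f1(x[, 1]) + f2(x[, 2]) + rnorm(n, 0, 0.1)
  frame <- continuous_frame(x)
  fit <- fit_brt(frame, y, brt_config(learning_rate = 0.05,
                                      bag_fraction = 1, max_trees = 800,
                                      rng_seed = 1), cv = FALSE)
  # 24 points so no grid value sits exactly on a step discontinuity
  grid <- seq(-1.8, 1.8, length.out = 24)
  pd1 <- partial_dependence(fit, frame, "x1", grid = grid)
  pd2 <- partial_dependence(fit, frame, "x2", grid = grid)
  ctr <- function(v) v - mean(v)
  expect_lt(max(abs(ctr(pd1$yhat) - ctr(f1(grid)))), 0.1)
  expect_lt(max(abs(ctr(pd2$yhat) - ctr(f2(grid)))), 0.1)
  # a predictor absent from every split has an exactly flat curve
  vi <- variable_importance(fit)
  if (vi$vi[vi$term == "x3"] == 0) {
    pd3 <- partial_dependence(fit, frame, "x3")
    expect_lt(diff(range(pd3$yhat)), 1e-9)
  }
})

test_that("nominal partial dependence uses one point per level", {
  set.seed(10)
  n <- 200
  lv <- letters[1:10]
  df <- tibble::tibble(
    species = sprintf("s%03d", 1:n),
    hab = factor(sample(lv, n, replace = TRUE), levels = lv),
    x = rnorm(n)
  )
  y <- as.integer(df$hab) * 0.5 + rnorm(n, 0, 0.2)
  frame <- build_model_frame(df, NULL)
  fit <- fit_quick(frame, y)
  pd <- partial_dependence(fit, frame, "hab")
  expect_equal(nrow(pd), 10)
  expect_setequal(pd$value, lv)
  expect_error(partial_dependence(fit, frame, "hab", grid = "zzz"),
               "level set")
})

test_that("interaction strength separates additive from multiplicative
           ground truth", {
  additive_top <- numeric(0)
  mult_rank1 <- logical(0)
  for (seed in 1:2) {
    set.seed(seed)
    n <- 500
    x <- matrix(runif(n * 3, -1, 1), n)
    frame <- continuous_frame(x)
    cfg <- brt_config(learning_rate = 0.05, bag_fraction = 1,
                      max_trees = 500, rng_seed = seed)
    y_add <- x[, 1] + 0.8 * x[, 2]^2 + 0.5 * x[, 3] + rnorm(n, 0, 0.1)
    fit_add <- fit_brt(frame, y_add, cfg, cv = FALSE)
    it_add <- interaction_table(fit_add, frame, top_n = 3)
    additive_top <- c(additive_top, max(it_add$strength_rel))

    y_mul <- 2 * x[, 1] * x[, 2] + 0.3 * x[, 3] + rnorm(n, 0, 0.1)
    fit_mul <- fit_brt(frame, y_mul, cfg, cv = FALSE)
    it_mul <- interaction_table(fit_mul, frame, top_n = 3)
    top_pair <- sort(c(it_mul$term_i[1], it_mul$term_j[1]))
    mult_rank1 <- c(mult_rank1, identical(top_pair, c("x1", "x2")))
  }
  expect_true(all(additive_top < 0.05))
  expect_true(all(mult_rank1))
})

test_that("tidy and glance summarise the fit", {
  set.seed(11)
  x <- matrix(rnorm(200), 100)
  y <- x[, 1] + rnorm(100, 0, 0.3)
  frame <- continuous_frame(x)
  fit <- fit_brt(frame, y, brt_config(learning_rate = 0.1, max_trees = 200,
                                      step_size = 50, n_folds = 5,
                                      rng_seed = 1))
  td <- tidy(fit)
  expect_named(td, c("term", "group", "improvement", "vi"))
  expect_true(!is.unsorted(rev(td$vi)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$deviance_explained_cv <= 100)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
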