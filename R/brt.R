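#' Boosted regression tree configuration
#'
#' Hyperparameters follow the `gbm.step` tradition for ecological BRTs:
#' slow learning (0.01), three splits per tree (enough to expose pairwise
#' interactions), 75% bagging, and ten-fold cross-validation evaluated
#' every 50 trees.
#'
#' @param learning_rate Shrinkage applied to every tree, in `(0, 1]`.
#' @param tree_complexity Maximum number of splits per tree (>= 1).
#' @param bag_fraction Fraction of rows subsampled (without replacement)
#'   for each tree, in `(0, 1]`.
#' @param step_size Trees added between cross-validation evaluations.
#' @param n_folds Number of cross-validation folds (>= 2).
#' @param max_trees Upper bound on the ensemble size.
#' @param min_obs Minimum rows per child node.
#' @param cv_patience Stop growing once this many consecutive evaluations
#'   fail to improve the running CV minimum.
#' @param rng_seed Optional integer; when set, `fit_brt` seeds R's RNG so
#'   fold assignment and bagging are bit-reproducible.
#' @return A `brt_config` list.
#' @export
brt_config <- function(learning_rate = 0.01, tree_complexity = 3,
                       bag_fraction = 0.75, step_size = 50, n_folds = 10,
                       max_trees = 10000, min_obs = 1, cv_patience = 10,
                       rng_seed = NULL) {
  stopifnot(
    learning_rate > 0, learning_rate <= 1,
    tree_complexity >= 1,
    bag_fraction > 0, bag_fraction <= 1,
    step_size >= 1, n_folds >= 2, max_trees >= 1, min_obs >= 1,
    cv_patience >= 1
  )
  structure(
    list(learning_rate = learning_rate, tree_complexity = tree_complexity,
         bag_fraction = bag_fraction, step_size = step_size,
         n_folds = n_folds, max_trees = max_trees, min_obs = min_obs,
         cv_patience = cv_patience, rng_seed = rng_seed),
    class = "brt_config"
  )
}

#' Fit a single least-squares regression tree
#'
#' Grows one tree by greedy best-first splitting: at each step the leaf
#' offering the largest squared-error reduction is split, up to
#' `max_splits` splits. Nominal predictors are searched over level subsets
#' (exhaustively for up to 10 levels, by a mean-ordered scan otherwise);
#' rows with a missing value in the split column are routed to the child
#' holding more rows. Mostly useful for inspecting the learner; boosting
#' calls the same engine internally.
#'
#' @param frame A `model_frame` (see [build_model_frame()]).
#' @param y Numeric response/residual vector, one value per frame row.
#' @param max_splits Maximum number of splits.
#' @param min_obs Minimum rows per child.
#' @return A `brt_tree`: the node matrix plus term names.
#' @export
fit_regression_tree <- function(frame, y, max_splits = 3, min_obs = 1) {
  enc <- encode_model_frame(frame)
  stopifnot(length(y) == nrow(enc$x), all(is.finite(y)))
  if (nrow(enc$x) < 2) stop("need at least 2 rows", call. = FALSE)
  m <- .fit_tree_cpp(enc$x, enc$kind_int, y,
                     seq_len(nrow(enc$x)) - 1L, as.integer(max_splits),
                     as.integer(min_obs))
  structure(list(nodes = m, terms = colnames(enc$x)), class = "brt_tree")
}

#' @export
print.brt_tree <- function(x, ...) {
  n_splits <- sum(x$nodes[, 1] != 0)
  cat("<brt_tree> ", n_splits, " splits, total improvement ",
      format(sum(x$nodes[, 8]), digits = 6), "\n", sep = "")
  invisible(x)
}

# stratified fold assignment: blocks of consecutive response ranks get a
# random permutation of fold ids, stabilising small-n folds
assign_folds <- function(y, n_folds) {
  n <- length(y)
  ord <- order(y, runif(n))
  folds <- integer(n)
  ids <- seq_len(n_folds)
  for (start in seq(1, n, by = n_folds)) {
    block <- ord[start:min(start + n_folds - 1, n)]
    folds[block] <- sample(ids)[seq_along(block)]
  }
  folds
}

#' Fit a boosted regression tree ensemble
#'
#' Stagewise least-squares boosting: each stage fits a regression tree to
#' the current residuals on a bagged subsample and adds `learning_rate`
#' times its predictions. With `cv = TRUE` (default) the ensemble size is
#' chosen to minimise the k-fold cross-validated predictive squared-error
#' deviance, evaluated every `step_size` trees, and the final model is
#' refit on all rows to the selected size. With `cv = FALSE` the model is
#' trained on all rows to `max_trees` (training mode).
#'
#' @param frame A `model_frame`.
#' @param y Numeric response vector, or a response tibble from
#'   [build_response()] (aligned to the frame by `species`).
#' @param config A [brt_config()].
#' @param cv Select the tree count by cross-validation?
#' @return A `brt` model object; see [tidy.brt()], [glance.brt()],
#'   [variable_importance()], [partial_dependence()].
#' @export
fit_brt <- function(frame, y, config = brt_config(), cv = TRUE) {
  stopifnot(inherits(frame, "model_frame"), inherits(config, "brt_config"))
  if (is.data.frame(y)) {
    if (!all(c("species", "response") %in% names(y))) {
      stop("response data frame needs 'species' and 'response' columns",
           call. = FALSE)
    }
    miss <- setdiff(frame$species, y$species)
    if (length(miss) > 0) {
      stop("no response for species: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    y <- y$response[match(frame$species, y$species)]
  }
  enc <- encode_model_frame(frame)
  n <- nrow(enc$x)
  stopifnot(length(y) == n, all(is.finite(y)))
  if (var(y) == 0) stop("response is degenerate (zero variance)",
                        call. = FALSE)
  if (cv && n < config$n_folds) {
    stop("need at least n_folds = ", config$n_folds, " rows", call. = FALSE)
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  init <- mean(y)
  null_deviance <- mean((y - init)^2)
  warnings <- character(0)
  cv_trace <- NULL
  cv_pred_best <- NULL
  n_selected <- config$max_trees

  if (cv) {
    folds <- assign_folds(y, config$n_folds)
    state <- lapply(seq_len(config$n_folds), function(f) {
      tr <- which(folds != f); te <- which(folds == f)
      list(train = tr, test = te,
           pred = rep(mean(y[tr]), length(tr)),
           pred_test = rep(mean(y[tr]), length(te)))
    })
    n_evals <- ceiling(config$max_trees / config$step_size)
    trace_n <- integer(0); trace_dev <- numeric(0)
    heldout <- vector("list", n_evals)
    best_i <- 0L; best_dev <- Inf
    for (i in seq_len(n_evals)) {
      chunk <- min(config$step_size, config$max_trees -
                     (i - 1L) * config$step_size)
      sse <- 0
      ho <- numeric(n)
      for (f in seq_len(config$n_folds)) {
        st <- state[[f]]
        res <- .boost_cpp(enc$x[st$train, , drop = FALSE], enc$kind_int,
                          y[st$train], st$pred,
                          enc$x[st$test, , drop = FALSE], st$pred_test,
                          as.integer(chunk), config$learning_rate,
                          config$bag_fraction,
                          as.integer(config$tree_complexity),
                          as.integer(config$min_obs))
        st$pred <- res$pred
        st$pred_test <- res$pred_test
        state[[f]] <- st
        sse <- sse + sum((y[st$test] - st$pred_test)^2)
        ho[st$test] <- st$pred_test
      }
      trace_n <- c(trace_n, (i - 1L) * config$step_size + chunk)
      dev <- sse / n
      trace_dev <- c(trace_dev, dev)
      heldout[[i]] <- ho
      if (dev < best_dev) { best_dev <- dev; best_i <- i }
      if (i - best_i >= config$cv_patience) break
    }
    if (trace_n[length(trace_n)] >= config$max_trees &&
        best_i == length(trace_n)) {
      warnings <- c(warnings,
                    "max_trees reached with CV deviance still improving")
    }
    cv_trace <- tibble::tibble(n_trees = trace_n, cv_deviance = trace_dev)
    n_selected <- trace_n[best_i]
    cv_pred_best <- heldout[[best_i]]
  }

  fit <- .boost_cpp(enc$x, enc$kind_int, y, rep(init, n), NULL, NULL,
                    as.integer(n_selected), config$learning_rate,
                    config$bag_fraction, as.integer(config$tree_complexity),
                    as.integer(config$min_obs))

  structure(
    list(
      trees = fit$trees,
      init = init,
      n_trees = n_selected,
      config = config,
      cv = cv,
      cv_trace = cv_trace,
      cv_deviance = if (cv) cv_trace$cv_deviance[cv_trace$n_trees ==
                                                   n_selected] else NA_real_,
      cv_pred = cv_pred_best,
      train_deviance = fit$train_deviance,
      null_deviance = null_deviance,
      fitted = fit$pred,
      y = y,
      species = frame$species,
      terms = colnames(enc$x),
      kind = frame$kind,
      group = frame$group,
      levels = enc$levels,
      warnings = warnings
    ),
    class = "brt"
  )
}

#' @export
print.brt <- function(x, ...) {
  cat("<brt> ", x$n_trees, " trees (lr ", x$config$learning_rate,
      ", complexity ", x$config$tree_complexity, ")\n", sep = "")
  cat("  deviance explained: ",
      format(percent_deviance_explained(x), digits = 3), "% (",
      if (x$cv) "cross-validated" else "training", ")\n", sep = "")
  invisible(x)
}

#' Predict from a fitted BRT
#'
#' @param object A `brt` model.
#' @param newdata A `model_frame`, or `NULL` for fitted values.
#' @param n_trees Number of leading trees to use (default: all selected).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.brt <- function(object, newdata = NULL, n_trees = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(n_trees)) return(object$fitted)
    stop("predicting at a reduced tree count needs newdata; pass the frame",
         call. = FALSE)
  }
  nt <- n_trees %||% length(object$trees)
  enc <- encode_model_frame(newdata)
  if (!identical(colnames(enc$x), object$terms)) {
    stop("newdata columns do not match the fitted frame", call. = FALSE)
  }
  .predict_trees_cpp(object$trees, enc$x, object$config$learning_rate,
                     object$init, as.integer(nt))
}

#' Relative-influence variable importance
#'
#' For each predictor, sums the squared-error improvements of every split
#' on that predictor across the selected trees, then rescales so all
#' scores sum to 100. Predictors never used in any split score exactly 0.
#'
#' @param model A fitted `brt`.
#' @return A tibble with `term`, `group`, `improvement`, `vi` (percent),
#'   in frame column order.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "brt"))
  if (length(model$trees) < 1) stop("model has no trees", call. = FALSE)
  imp <- numeric(length(model$terms))
  for (tr in model$trees) {
    used <- tr[, 1] != 0
    if (any(used)) {
      agg <- tapply(tr[used, 8], tr[used, 1], sum)
      idx <- as.integer(names(agg))
      imp[idx] <- imp[idx] + as.numeric(agg)
    }
  }
  total <- sum(imp)
  if (total <= 0) {
    warning("degenerate model: no split improved the fit; ",
            "uniform importance returned")
    vi <- rep(100 / length(imp), length(imp))
  } else {
    vi <- 100 * imp / total
  }
  tibble::tibble(term = model$terms, group = unname(model$group),
                 improvement = imp, vi = vi)
}

#' Percent of response deviance explained
#'
#' `100 * (1 - deviance / null deviance)` with squared-error deviance. For
#' cross-validated fits the predictive (held-out) deviance at the selected
#' tree count is the primary figure; `type = "train"` reports the
#' in-sample equivalent.
#'
#' @param model A fitted `brt`.
#' @param type `"cv"` or `"train"`; defaults to how the model was fitted.
#' @return A percentage (can be negative for a model worse than the mean).
#' @export
percent_deviance_explained <- function(model,
                                       type = if (model$cv) "cv" else "train") {
  stopifnot(inherits(model, "brt"))
  type <- match.arg(type, c("cv", "train"))
  if (type == "cv" && !model$cv) {
    stop("model was fitted without cross-validation", call. = FALSE)
  }
  dev <- if (type == "cv") model$cv_deviance
  else model$train_deviance[length(model$train_deviance)]
  100 * (1 - dev / model$null_deviance)
}

# resolve a term name to its column index
term_index <- function(model, term) {
  i <- match(term, model$terms)
  if (is.na(i)) stop("unknown predictor: ", term, call. = FALSE)
  i
}

# encoded grid for a term: nominal -> level codes, ordered -> observed
# codes, continuous -> evenly spaced over the observed range
term_grid <- function(model, frame, term, n_grid) {
  i <- term_index(model, term)
  enc <- encode_model_frame(frame)
  xv <- enc$x[, i]
  if (model$kind[[term]] == "nominal" || !is.null(model$levels[[term]])) {
    sort(unique(xv[!is.na(xv)]))
  } else if (model$kind[[term]] == "ordered") {
    sort(unique(xv[!is.na(xv)]))
  } else {
    rng <- range(xv, na.rm = TRUE)
    if (rng[1] == rng[2]) rng[1] else seq(rng[1], rng[2], length.out = n_grid)
  }
}

#' Partial dependence of the model on one predictor
#'
#' For each grid value, the predictor is clamped to that value in every
#' observed row and the model predictions are averaged. Nominal predictors
#' use one grid point per observed level.
#'
#' @param model A fitted `brt`.
#' @param frame The `model_frame` the model was fitted on.
#' @param term Predictor name.
#' @param grid Optional grid. For nominal terms, level labels (must belong
#'   to the observed level set); otherwise numeric values.
#' @param n_grid Grid resolution for continuous predictors.
#' @return A tibble with `term`, `value` (labels for nominal terms,
#'   numbers otherwise), and `yhat` (centred ensemble prediction scale).
#' @export
partial_dependence <- function(model, frame, term, grid = NULL, n_grid = 25) {
  stopifnot(inherits(model, "brt"), inherits(frame, "model_frame"))
  i <- term_index(model, term)
  enc <- encode_model_frame(frame)
  levels <- model$levels[[term]]
  if (!is.null(grid)) {
    if (!is.null(levels) && (is.character(grid) || is.factor(grid))) {
      bad <- setdiff(as.character(grid), levels)
      if (length(bad) > 0) {
        stop("grid value(s) outside the observed level set for '", term,
             "': ", paste(bad, collapse = ", "), call. = FALSE)
      }
      gx <- match(as.character(grid), levels)
    } else if (!is.null(levels)) {
      if (!all(grid %in% seq_along(levels))) {
        stop("grid value(s) outside the observed level set for '", term, "'",
             call. = FALSE)
      }
      gx <- as.numeric(grid)
    } else {
      gx <- as.numeric(grid)
    }
  } else {
    gx <- term_grid(model, frame, term, n_grid)
  }
  yhat <- .partial_dependence_cpp(
    model$trees, enc$x, model$config$learning_rate, model$init,
    as.integer(length(model$trees)), as.integer(i),
    matrix(gx, ncol = 1)
  )
  value <- if (!is.null(levels)) levels[as.integer(gx)] else gx
  tibble::tibble(term = term, value = value, yhat = yhat)
}

#' Pairwise interaction strength between two predictors
#'
#' Computes the bivariate partial-dependence surface of the pair, removes
#' the best additive (row + column effects) fit, and returns the residual
#' variance of the surface. A perfectly additive model scores 0; either
#' predictor being unused in any split also returns 0.
#'
#' @param model A fitted `brt`.
#' @param frame The fitted `model_frame`.
#' @param term_i,term_j Predictor names.
#' @param n_grid Grid resolution per continuous predictor.
#' @return A nonnegative scalar in squared response units.
#' @export
interaction_strength <- function(model, frame, term_i, term_j, n_grid = 10) {
  stopifnot(inherits(model, "brt"))
  vi <- variable_importance(model)
  if (vi$improvement[term_index(model, term_i)] == 0 ||
      vi$improvement[term_index(model, term_j)] == 0) {
    return(0)
  }
  gi <- term_grid(model, frame, term_i, n_grid)
  gj <- term_grid(model, frame, term_j, n_grid)
  grid <- as.matrix(expand.grid(gi, gj))
  enc <- encode_model_frame(frame)
  pd <- .partial_dependence_cpp(
    model$trees, enc$x, model$config$learning_rate, model$init,
    as.integer(length(model$trees)),
    as.integer(c(term_index(model, term_i), term_index(model, term_j))),
    grid
  )
  surf <- matrix(pd, nrow = length(gi))
  additive <- outer(rowMeans(surf), colMeans(surf), "+") - mean(surf)
  mean((surf - additive)^2)
}

#' Screen pairwise interactions among the top predictors
#'
#' @param model A fitted `brt`.
#' @param frame The fitted `model_frame`.
#' @param top_n Screen the `top_n` predictors by variable importance.
#' @param n_grid Grid resolution per continuous predictor.
#' @return A tibble with `term_i`, `term_j`, `strength` (residual variance
#'   of the bivariate partial-dependence surface) and `strength_rel`
#'   (strength relative to the response variance), sorted descending.
#' @export
interaction_table <- function(model, frame, top_n = 6, n_grid = 10) {
  vi <- dplyr::arrange(variable_importance(model), dplyr::desc(.data$vi))
  terms <- head(vi$term[vi$improvement > 0], top_n)
  if (length(terms) < 2) {
    return(tibble::tibble(term_i = character(), term_j = character(),
                          strength = numeric(), strength_rel = numeric()))
  }
  pairs <- utils::combn(terms, 2)
  strength <- vapply(seq_len(ncol(pairs)), function(k) {
    interaction_strength(model, frame, pairs[1, k], pairs[2, k],
                         n_grid = n_grid)
  }, numeric(1))
  dplyr::arrange(
    tibble::tibble(term_i = pairs[1, ], term_j = pairs[2, ],
                   strength = strength,
                   strength_rel = strength / var(model$y)),
    dplyr::desc(.data$strength)
  )
}

#' @describeIn fit_brt Tidy the fitted model: the variable-importance table
#'   sorted by descending influence.
#' @param x A fitted `brt`.
#' @param ... Unused.
#' @export
tidy.brt <- function(x, ...) {
  dplyr::arrange(variable_importance(x), dplyr::desc(.data$vi))
}

#' @describeIn fit_brt One-row model summary: tree count, percent deviance
#'   explained (CV and training), and deviance components.
#' @export
glance.brt <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    deviance_explained_cv = if (x$cv) percent_deviance_explained(x, "cv")
    else NA_real_,
    deviance_explained_train = percent_deviance_explained(x, "train"),
    cv_deviance = if (x$cv) x$cv_deviance else NA_real_,
    null_deviance = x$null_deviance
  )
}

#' Serialise a fitted BRT to JSON (and back)
#'
#' Stores the tree node matrices, configuration, traces and metadata at
#' full numeric precision, so a reloaded model reproduces predictions,
#' importance scores and partitions exactly.
#'
#' @param model A fitted `brt`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_brt <- function(model, path) {
  stopifnot(inherits(model, "brt"))
  payload <- list(
    # trees as flat column-major vectors: row objects would drop NA fields
    trees = lapply(model$trees, function(m) {
      list(nrow = nrow(m), values = as.vector(m))
    }),
    init = model$init,
    n_trees = model$n_trees,
    config = unclass(model$config),
    cv = model$cv,
    cv_trace = if (!is.null(model$cv_trace)) as.list(model$cv_trace),
    cv_deviance = model$cv_deviance,
    train_deviance = model$train_deviance,
    null_deviance = model$null_deviance,
    fitted = model$fitted,
    y = model$y,
    species = model$species,
    terms = model$terms,
    kind = as.list(model$kind),
    group = as.list(model$group),
    levels = model$levels
  )
  # digits = I(17): doubles must survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_brt
#' @export
read_brt <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  model <- list(
    trees = lapply(p$trees, function(tr) {
      matrix(as.numeric(tr$values), nrow = tr$nrow)
    }),
    init = p$init,
    n_trees = p$n_trees,
    config = do.call(brt_config, as.list(p$config[!vapply(p$config, is.null,
                                                          logical(1))])),
    cv = p$cv,
    cv_trace = if (!is.null(p$cv_trace)) tibble::as_tibble(p$cv_trace),
    cv_deviance = p$cv_deviance %||% NA_real_,
    train_deviance = p$train_deviance,
    null_deviance = p$null_deviance,
    fitted = p$fitted,
    y = p$y,
    species = p$species,
    terms = p$terms,
    kind = unlist(p$kind),
    group = unlist(p$group),
    levels = p$levels
  )
  class(model) <- "brt"
  model
}
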