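vi_features <- c("mtvi1", "ndvi", "osavi", "rdvi")

regressor_names <- c("polynomial", "ridge", "lasso", "svr", "random_forest",
                     "extra_trees", "gradient_boosting", "hist_gradient_boosting",
                     "xgb_style", "lightgbm_style", "dnn")

#' Specify a regression model for LAI estimation
#'
#' A lightweight description of one member of the benchmarked regressor
#' family: the family name, optional hyperparameter overrides, and the seed
#' controlling any stochastic training step.
#'
#' Default hyperparameters: ridge penalty alpha = 0.1 and lasso penalty
#' alpha = 0.01 (in the conventional `RSS/(2n) + alpha * penalty`
#' parameterisation, mapped onto glmnet's lambda); tree ensembles use 500
#' trees and unlimited depth; SVR a radial-basis kernel with unit cost;
#' polynomial degree 2 with all pairwise interactions; the feed-forward
#' network 6 ReLU hidden layers of widths 1000, 800, 600, 400, 200, 100 with
#' dropout 0.17, Adam (lr 0.001), 1000 epochs, batch size 100. Features are
#' standardized for polynomial/ridge/lasso/svr/dnn and used raw for trees.
#'
#' @param name one of `"polynomial"`, `"ridge"`, `"lasso"`, `"svr"`,
#'   `"random_forest"`, `"extra_trees"`, `"gradient_boosting"`,
#'   `"hist_gradient_boosting"`, `"xgb_style"`, `"lightgbm_style"`, `"dnn"`.
#' @param hyperparameters named list of overrides (family-specific).
#' @param seed integer seed for stochastic fitting.
#' @return An object of class `regressor_spec`.
#' @export
regressor_spec <- function(name, hyperparameters = list(), seed = 0L) {
  assert_that(is.character(name) && length(name) == 1L && name %in% regressor_names,
              sprintf("unknown regressor family %s; must be one of: %s",
                      deparse(name), paste(regressor_names, collapse = ", ")),
              class = "rscmlai_config_error")
  assert_that(is.list(hyperparameters), "hyperparameters must be a named list",
              class = "rscmlai_config_error")
  structure(list(name = name, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "regressor_spec")
}

#' The default benchmarked regressor family
#'
#' The ten standard regression families compared in the LAI-from-VI
#' benchmark (the optional feed-forward network is not included; add a
#' `regressor_spec("dnn")` explicitly to benchmark it).
#'
#' @param seed integer seed shared by all specs.
#' @return A named list of [regressor_spec()] objects.
#' @export
default_regressor_specs <- function(seed = 0L) {
  nm <- setdiff(regressor_names, "dnn")
  stats::setNames(lapply(nm, regressor_spec, seed = seed), nm)
}

check_dataset <- function(data, min_rows = 1L) {
  assert_that(is.data.frame(data) && all(c(vi_features, "lai") %in% names(data)),
              sprintf("dataset must have columns %s",
                      paste(c(vi_features, "lai"), collapse = ", ")))
  cols <- data[c(vi_features, "lai")]
  assert_that(all(vapply(cols, function(x) all(is.finite(x)), logical(1))),
              "dataset contains missing or non-finite values")
  assert_that(all(data$lai >= 0), "LAI targets must be nonnegative")
  assert_that(nrow(data) >= min_rows,
              sprintf("dataset needs at least %d rows, got %d", min_rows, nrow(data)))
  invisible(TRUE)
}

#' Split a LAI-VI dataset into training and test subsets
#'
#' Random, disjoint, exhaustive partition with test size
#' `ceiling((1 - ratio) * n)`, reproducible under `seed`.
#'
#' @param data data.frame with columns `mtvi1`, `ndvi`, `osavi`, `rdvi`,
#'   `lai`.
#' @param ratio training fraction in (0, 1); default 0.8 (an 80:20 split).
#' @param seed integer seed.
#' @return A list with elements `train` and `test` (data.frames) and the
#'   integer `test_idx`.
#' @export
split_dataset <- function(data, ratio = 0.8, seed = 0L) {
  check_dataset(data, min_rows = 10L)
  assert_that(is_number(ratio) && ratio > 0 && ratio < 1,
              "ratio must lie strictly between 0 and 1")
  n <- nrow(data)
  n_test <- as.integer(ceiling((1 - ratio) * n))
  assert_that(n_test >= 1 && n_test < n,
              "degenerate split: empty training or test subset")
  test_idx <- sort(with_rng_seed(seed, sample.int(n, n_test)))
  list(train = data[-test_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE],
       test_idx = test_idx)
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1  # constant columns pass through centred
  list(center = ctr, scale = scl)
}

standardize_apply <- function(x, sc) {
  scale(x, center = sc$center, scale = sc$scale)[, , drop = FALSE]
}

poly2_expand <- function(x) {
  # degree-2 expansion: linear terms, squares, all pairwise interactions
  p <- ncol(x)
  out <- list(x)
  nms <- colnames(x)
  sq <- x^2
  colnames(sq) <- paste0(nms, "_sq")
  out[[2]] <- sq
  inter <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      inter[[length(inter) + 1L]] <-
        stats::setNames(data.frame(x[, i] * x[, j]), paste0(nms[i], "_x_", nms[j]))
    }
  }
  cbind(do.call(cbind, out), do.call(cbind, inter))
}

hp <- function(spec, key, default) {
  v <- spec$hyperparameters[[key]]
  if (is.null(v)) default else v
}

#' Fit a LAI regressor
#'
#' Trains one regression family on a LAI-VI training subset. Linear/kernel
#' families (polynomial, ridge, lasso, svr, dnn) see standardized features;
#' tree ensembles see raw features. The fitted artifact stores its spec, the
#' training data and a manifest describing resolved hyperparameters, so that
#' training-set scores and reproducibility checks need no external state.
#'
#' @param spec a [regressor_spec()].
#' @param train training data.frame (columns `mtvi1`, `ndvi`, `osavi`,
#'   `rdvi`, `lai`).
#' @return An object of class `lai_regressor`.
#' @export
fit_regressor <- function(spec, train) {
  assert_that(inherits(spec, "regressor_spec"), "spec must be a regressor_spec",
              class = "rscmlai_config_error")
  check_dataset(train, min_rows = 2L)
  x <- as.matrix(train[vi_features])
  y <- train$lai
  name <- spec$name
  scaler <- NULL
  manifest <- list(family = name, seed = spec$seed, n_train = nrow(train),
                   standardized = name %in% c("polynomial", "ridge", "lasso", "svr", "dnn"))

  model <- with_rng_seed(spec$seed, switch(name,
    polynomial = {
      scaler <- standardize_fit(x)
      xs <- poly2_expand(standardize_apply(x, scaler))
      df <- data.frame(xs, .lai = y)
      manifest$degree <- 2
      stats::lm(.lai ~ ., data = df)
    },
    ridge = {
      scaler <- standardize_fit(x)
      alpha <- hp(spec, "alpha", 0.1)
      manifest$alpha <- alpha
      if (all(apply(x, 2, stats::sd) == 0)) {
        # zero-variance design: the penalized fit degenerates to the intercept
        list(constant_mean = mean(y))
      } else {
        glmnet::glmnet(standardize_apply(x, scaler), y, alpha = 0,
                       lambda = alpha / nrow(train), standardize = FALSE)
      }
    },
    lasso = {
      scaler <- standardize_fit(x)
      alpha <- hp(spec, "alpha", 0.01)
      manifest$alpha <- alpha
      if (all(apply(x, 2, stats::sd) == 0)) {
        list(constant_mean = mean(y))
      } else {
        glmnet::glmnet(standardize_apply(x, scaler), y, alpha = 1,
                       lambda = alpha, standardize = FALSE)
      }
    },
    svr = {
      scaler <- standardize_fit(x)
      manifest$kernel <- "radial"; manifest$cost <- hp(spec, "cost", 1)
      e1071::svm(standardize_apply(x, scaler), y, kernel = "radial",
                 cost = manifest$cost, scale = FALSE)
    },
    random_forest = {
      manifest$num_trees <- hp(spec, "num_trees", 500)
      ranger::ranger(x = x, y = y, num.trees = manifest$num_trees,
                     min.node.size = 5, seed = spec$seed, num.threads = 1)
    },
    extra_trees = {
      manifest$num_trees <- hp(spec, "num_trees", 500)
      ranger::ranger(x = x, y = y, num.trees = manifest$num_trees,
                     splitrule = "extratrees", num.random.splits = 1,
                     replace = FALSE, sample.fraction = 1, mtry = ncol(x),
                     min.node.size = 2, seed = spec$seed, num.threads = 1)
    },
    gradient_boosting = fit_xgb(spec, x, y, manifest, tree_method = "exact",
                                eta = 0.1, max_depth = 3, nrounds = 100),
    hist_gradient_boosting = fit_xgb(spec, x, y, manifest, tree_method = "hist",
                                     eta = 0.1, max_depth = 0, nrounds = 100,
                                     grow_policy = "lossguide", max_leaves = 31),
    xgb_style = fit_xgb(spec, x, y, manifest, tree_method = "exact",
                        eta = 0.3, max_depth = 6, nrounds = 100),
    lightgbm_style = {
      # no native backend installed; leaf-wise histogram boosting stands in
      message("lightgbm backend unavailable; using histogram gradient boosting")
      fit_xgb(spec, x, y, manifest, tree_method = "hist",
              eta = 0.1, max_depth = 0, nrounds = 100,
              grow_policy = "lossguide", max_leaves = 31)
    },
    dnn = {
      scaler <- standardize_fit(x)
      mlp_fit(standardize_apply(x, scaler), y,
              widths = hp(spec, "widths", c(1000, 800, 600, 400, 200, 100)),
              dropout = hp(spec, "dropout", 0.17),
              lr = hp(spec, "lr", 0.001),
              epochs = hp(spec, "epochs", 1000),
              batch_size = hp(spec, "batch_size", 100))
    }
  ))
  if (name %in% c("gradient_boosting", "hist_gradient_boosting",
                  "xgb_style", "lightgbm_style")) {
    manifest <- model$manifest
    model <- model$booster
  }

  structure(list(model = model, spec = spec, scaler = scaler,
                 train = train, manifest = manifest),
            class = "lai_regressor")
}

fit_xgb <- function(spec, x, y, manifest, tree_method, eta, max_depth, nrounds,
                    grow_policy = "depthwise", max_leaves = 0) {
  params <- list(
    objective = "reg:squarederror",
    eta = hp(spec, "eta", eta),
    max_depth = hp(spec, "max_depth", max_depth),
    tree_method = tree_method,
    grow_policy = grow_policy,
    max_leaves = max_leaves,
    nthread = 1,
    seed = spec$seed
  )
  nrounds <- hp(spec, "nrounds", nrounds)
  manifest <- c(manifest, params[c("eta", "max_depth", "tree_method")],
                list(nrounds = nrounds))
  booster <- xgboost::xgb.train(params = params,
                                data = xgboost::xgb.DMatrix(x, label = y),
                                nrounds = nrounds, verbose = 0)
  list(booster = booster, manifest = manifest)
}

#' Predict LAI from vegetation-index features
#'
#' @param object a fitted `lai_regressor`.
#' @param newdata data.frame or matrix with the four VI columns/features in
#'   the order `mtvi1`, `ndvi`, `osavi`, `rdvi`; zero rows give a
#'   zero-length result.
#' @param ... unused.
#' @return Numeric predictions, clamped at 0 from below (LAI cannot be
#'   negative).
#' @export
predict.lai_regressor <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    assert_that(all(vi_features %in% names(newdata)),
                sprintf("newdata must contain columns %s",
                        paste(vi_features, collapse = ", ")))
    x <- as.matrix(newdata[vi_features])
  } else {
    x <- as.matrix(newdata)
    assert_that(ncol(x) == length(vi_features),
                sprintf("feature dimensionality mismatch: expected %d columns, got %d",
                        length(vi_features), ncol(x)))
    colnames(x) <- vi_features
  }
  if (nrow(x) == 0) return(numeric(0))
  assert_that(all(is.finite(x)), "features must be finite")

  name <- object$spec$name
  pred <- switch(name,
    polynomial = {
      xs <- poly2_expand(standardize_apply(x, object$scaler))
      as.numeric(stats::predict(object$model, newdata = as.data.frame(xs)))
    },
    ridge = ,
    lasso = {
      if (!is.null(object$model$constant_mean)) {
        rep(object$model$constant_mean, nrow(x))
      } else {
        as.numeric(stats::predict(object$model,
                                  newx = standardize_apply(x, object$scaler)))
      }
    },
    svr = as.numeric(stats::predict(object$model,
                                    standardize_apply(x, object$scaler))),
    random_forest = ,
    extra_trees = stats::predict(object$model, data = as.data.frame(x),
                                 num.threads = 1)$predictions,
    gradient_boosting = ,
    hist_gradient_boosting = ,
    xgb_style = ,
    lightgbm_style = as.numeric(stats::predict(object$model,
                                               xgboost::xgb.DMatrix(x))),
    dnn = mlp_predict(object$model, standardize_apply(x, object$scaler))
  )
  pmax(as.numeric(pred), 0)
}

#' Evaluate a fitted LAI regressor
#'
#' Computes the coefficient of determination on the artifact's own training
#' subset (`train_score`) and on the supplied test subset (`test_score`),
#' plus RMSE, MAE and NSE of the test predictions.
#'
#' @param artifact a fitted `lai_regressor`.
#' @param test test data.frame (same columns as training).
#' @return A one-row data.frame: `regressor`, `train_score`, `test_score`,
#'   `rmse`, `mae`, `nse`.
#' @export
evaluate_regressor <- function(artifact, test) {
  check_dataset(test, min_rows = 2L)
  pred_tr <- predict(artifact, artifact$train)
  pred_te <- predict(artifact, test)
  data.frame(
    regressor = artifact$spec$name,
    train_score = coefficient_of_determination(pred_tr, artifact$train$lai),
    test_score = coefficient_of_determination(pred_te, test$lai),
    rmse = rmse(pred_te, test$lai),
    mae = mae(pred_te, test$lai),
    nse = nse(pred_te, test$lai)
  )
}

#' Benchmark a family of LAI regressors on one shared split
#'
#' Fits and evaluates every spec on the same train/test partition, in the
#' order given, mirroring a training-score/test-score comparison table. A
#' family that fails to fit yields a row of NAs with a warning and the
#' remaining families still run.
#'
#' @param data full LAI-VI dataset.
#' @param specs list of [regressor_spec()] objects (default:
#'   [default_regressor_specs()]).
#' @param ratio training fraction (default 0.8).
#' @param seed integer split seed.
#' @return A data.frame with one row per spec: `regressor`, `train_score`,
#'   `test_score`, `rmse`, `mae`, `nse`.
#' @examples
#' d <- generate_dataset(synthetic_config("rice"), seed = 42)
#' benchmark_regressors(d, default_regressor_specs()[c("ridge", "extra_trees")])
#' @export
benchmark_regressors <- function(data, specs = default_regressor_specs(),
                                 ratio = 0.8, seed = 0L) {
  assert_that(length(specs) >= 1, "at least one regressor spec is required")
  sp <- split_dataset(data, ratio = ratio, seed = seed)
  rows <- lapply(specs, function(spec) {
    tryCatch(
      evaluate_regressor(fit_regressor(spec, sp$train), sp$test),
      error = function(e) {
        warning(sprintf("regressor %s failed: %s", spec$name, conditionMessage(e)),
                call. = FALSE)
        data.frame(regressor = spec$name, train_score = NA_real_,
                   test_score = NA_real_, rmse = NA_real_, mae = NA_real_,
                   nse = NA_real_)
      }
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exponential LAI-VI baseline regression
#'
#' Fits the single-index exponential relationship LAI = u * exp(v * VI) by
#' nonlinear least squares, initialized from the closed-form log-linear fit
#' (ordinary least squares of log LAI on the VI). Rows with LAI <= 0 cannot
#' enter the log-linear initializer and are excluded (with a message).
#'
#' @param train data.frame with the chosen VI column and `lai`.
#' @param vi_name which index to regress on: `"ndvi"` (default), `"osavi"`,
#'   `"mtvi1"` or `"rdvi"`.
#' @return An object of class `exp_vi_fit`: list with `u`, `v`, `vi_name`,
#'   `n_used`, `rmse_fit`, `rmse_init`.
#' @export
fit_exponential_vi <- function(train, vi_name = c("ndvi", "osavi", "mtvi1", "rdvi")) {
  vi_name <- match.arg(vi_name)
  assert_that(is.data.frame(train) && all(c(vi_name, "lai") %in% names(train)),
              sprintf("train must have columns %s and lai", vi_name))
  usable <- is.finite(train$lai) & train$lai > 0 & is.finite(train[[vi_name]])
  if (any(!usable)) {
    message(sprintf("excluding %d rows with nonpositive or missing LAI", sum(!usable)))
  }
  d <- data.frame(vi = train[[vi_name]][usable], lai = train$lai[usable])
  assert_that(nrow(d) >= 3, "need at least 3 usable rows for the exponential fit")
  assert_that(stats::sd(d$vi) > 0,
              sprintf("VI column %s is constant: rank-deficient design", vi_name),
              class = "rscmlai_degenerate_input")

  init <- stats::lm(log(lai) ~ vi, data = d)
  u0 <- exp(stats::coef(init)[[1]]); v0 <- stats::coef(init)[[2]]
  pred_init <- u0 * exp(v0 * d$vi)

  fit <- tryCatch(
    minpack.lm::nlsLM(lai ~ u * exp(v * vi), data = d,
                      start = list(u = u0, v = v0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop_rscmlai(sprintf(
        "exponential fit did not converge (%s); log-linear fallback u=%.6g v=%.6g",
        conditionMessage(e), u0, v0), "rscmlai_optimization_error")
    }
  )
  cf <- stats::coef(fit)
  assert_that(is.finite(cf[["u"]]) && cf[["u"]] > 0 && is.finite(cf[["v"]]),
              "exponential fit produced invalid coefficients")
  structure(list(u = cf[["u"]], v = cf[["v"]], vi_name = vi_name,
                 n_used = nrow(d),
                 rmse_fit = rmse(as.numeric(stats::predict(fit)), d$lai),
                 rmse_init = rmse(pred_init, d$lai)),
            class = "exp_vi_fit")
}

#' @export
predict.exp_vi_fit <- function(object, newdata, ...) {
  vi <- if (is.data.frame(newdata)) newdata[[object$vi_name]] else as.numeric(newdata)
  assert_that(!is.null(vi), sprintf("newdata lacks column %s", object$vi_name))
  pmax(object$u * exp(object$v * vi), 0)
}

#' @export
print.exp_vi_fit <- function(x, ...) {
  cat(sprintf("<exp_vi_fit> LAI = %.4g * exp(%.4g * %s), n = %d, rmse %.3f\n",
              x$u, x$v, x$vi_name, x$n_used, x$rmse_fit))
  invisible(x)
}
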