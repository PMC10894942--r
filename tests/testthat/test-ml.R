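linear_dataset <- function(n = 500, seed = 13) {
  set.seed(seed)
  ndvi <- runif(n, 0.05, 0.95)
  data.frame(mtvi1 = runif(n, 0, 1), ndvi = ndvi,
             osavi = runif(n, 0, 0.8), rdvi = runif(n, 0, 1),
             lai = 2 * ndvi)
}

test_that("the 80:20 split uses the ceiling convention and is a seeded partition", {
  d <- generate_dataset(synthetic_config("rice"), seed = 1)
  sp <- split_dataset(d, ratio = 0.8, seed = 10)
  expect_equal(nrow(d), 552)
  expect_equal(nrow(sp$test), 111)  # ceiling(0.2 * 552)
  expect_equal(nrow(sp$train), 441)
  sp2 <- split_dataset(d, ratio = 0.8, seed = 10)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_setequal(c(sp$test_idx, setdiff(seq_len(552), sp$test_idx)), seq_len(552))
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)
  expect_error(split_dataset(d, ratio = 1.2), "between 0 and 1")
  expect_error(split_dataset(d[1:5, ], 0.8), "at least 10")
})

test_that("extra trees learn a noiseless relationship nearly exactly", {
  d <- linear_dataset()
  sp <- split_dataset(d, seed = 2)
  art <- fit_regressor(regressor_spec("extra_trees", seed = 2), sp$train)
  ev <- evaluate_regressor(art, sp$test)
  expect_gte(ev$test_score, 0.99)
  expect_lt(max(abs(predict(art, sp$train) - sp$train$lai)), 0.05)
})

test_that("every regressor family fits, predicts finitely and deterministically", {
  d <- generate_dataset(synthetic_config("rice", n_samples = 150), seed = 3)
  sp <- split_dataset(d, seed = 3)
  fams <- setdiff(rscmlai:::regressor_names, "dnn")
  for (fam in fams) {
    spec <- regressor_spec(fam, seed = 7)
    art <- suppressMessages(fit_regressor(spec, sp$train))
    p1 <- predict(art, sp$test)
    p2 <- predict(suppressMessages(fit_regressor(spec, sp$train)), sp$test)
    expect_length(p1, nrow(sp$test))
    expect_true(all(is.finite(p1)), info = fam)
    expect_true(all(p1 >= 0), info = fam)
    expect_identical(p1, p2, info = fam)
  }
  # scaled-down feed-forward network
  spec <- regressor_spec("dnn", seed = 7,
                         hyperparameters = list(widths = c(16, 8), epochs = 100,
                                                batch_size = 50))
  art <- fit_regressor(spec, sp$train)
  ev <- evaluate_regressor(art, sp$test)
  expect_gt(ev$test_score, 0.5)
  expect_error(regressor_spec("mystery_model"), class = "rscmlai_config_error")
})

test_that("degenerate and edge predictions behave as contracted", {
  d <- linear_dataset(n = 60)
  zero <- d
  zero[c("mtvi1", "ndvi", "osavi", "rdvi")] <- 0
  art0 <- fit_regressor(regressor_spec("ridge"), zero)
  expect_equal(predict(art0, data.frame(mtvi1 = 0.5, ndvi = 0.2, osavi = 0.1,
                                        rdvi = 0.9)),
               mean(zero$lai), tolerance = 1e-6)
  art <- fit_regressor(regressor_spec("lasso"), d)
  expect_identical(predict(art, d[0, ]), numeric(0))
  # extreme negative VIs extrapolate below zero and are clamped
  ext <- data.frame(mtvi1 = -50, ndvi = -50, osavi = -50, rdvi = -50)
  expect_equal(predict(art, ext), 0)
  expect_error(predict(art, matrix(1, 2, 3)), "dimensionality")
})

test_that("evaluation reports equal direct metric calls", {
  d <- generate_dataset(synthetic_config("rice", n_samples = 200), seed = 4)
  sp <- split_dataset(d, seed = 4)
  art <- fit_regressor(regressor_spec("random_forest", seed = 4), sp$train)
  ev <- evaluate_regressor(art, sp$test)
  pred <- predict(art, sp$test)
  expect_equal(ev$rmse, rmse(pred, sp$test$lai))
  expect_equal(ev$mae, mae(pred, sp$test$lai))
  expect_equal(ev$nse, nse(pred, sp$test$lai))
  expect_equal(ev$test_score, coefficient_of_determination(pred, sp$test$lai))
  expect_gte(ev$rmse, ev$mae)
  expect_lte(ev$test_score, 1)
})

test_that("benchmark shares one split, keeps order, reproduces, ranks trees over linear", {
  d <- generate_dataset(synthetic_config("rice"), seed = 42)
  specs <- default_regressor_specs(seed = 42)[c("ridge", "lasso", "extra_trees",
                                                "random_forest")]
  t1 <- benchmark_regressors(d, specs, seed = 42)
  t2 <- benchmark_regressors(d, specs, seed = 42)
  expect_identical(t1, t2)
  expect_identical(t1$regressor, c("ridge", "lasso", "extra_trees", "random_forest"))
  expect_gte(t1$test_score[t1$regressor == "extra_trees"],
             t1$test_score[t1$regressor == "ridge"])
  expect_gte(min(t1$test_score[3:4]), max(t1$test_score[1:2]))
  # single spec equals fit + evaluate
  sp <- split_dataset(d, seed = 42)
  solo <- benchmark_regressors(d, specs["ridge"], seed = 42)
  direct <- evaluate_regressor(fit_regressor(specs$ridge, sp$train), sp$test)
  expect_equal(solo, direct)
})

test_that("exponential LAI-VI baseline recovers coefficients and refines its initializer", {
  set.seed(17)
  ndvi <- runif(300, 0.05, 0.9)
  exact <- data.frame(ndvi = ndvi, lai = 0.5 * exp(3 * ndvi))
  f <- fit_exponential_vi(exact, "ndvi")
  expect_equal(f$u, 0.5, tolerance = 1e-6)
  expect_equal(f$v, 3, tolerance = 1e-6)
  expect_equal(unname(predict(f, data.frame(ndvi = 0.5))), 0.5 * exp(1.5),
               tolerance = 1e-5)

  noisy <- exact
  noisy$lai <- noisy$lai * exp(rnorm(300, 0, 0.05)) + abs(rnorm(300, 0, 0.2))
  fn <- fit_exponential_vi(noisy, "ndvi")
  expect_lte(fn$rmse_fit, fn$rmse_init + 1e-12)

  # multiplicative log-normal noise: nls stays near the log-linear OLS answer
  lognorm <- exact
  lognorm$lai <- lognorm$lai * exp(rnorm(300, 0, 0.05))
  fl <- fit_exponential_vi(lognorm, "ndvi")
  ols <- lm(log(lai) ~ ndvi, data = lognorm)
  expect_equal(fl$v, unname(coef(ols)[2]), tolerance = 0.05)
  expect_equal(fl$u, exp(unname(coef(ols)[1])), tolerance = 0.05)

  const <- data.frame(ndvi = rep(0.4, 20), lai = runif(20, 1, 3))
  expect_error(fit_exponential_vi(const, "ndvi"), class = "rscmlai_degenerate_input")
  expect_error(fit_exponential_vi(exact[1:2, ], "ndvi"), "at least 3")
})
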