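#' Evaluation statistics for paired simulated/observed series
#'
#' Root mean square error, mean absolute error, Nash-Sutcliffe efficiency and
#' the coefficient of determination used for regression score tables. All
#' follow the population (divide-by-n) convention:
#' \deqn{RMSE = \sqrt{\frac{1}{n}\sum_i (S_i - O_i)^2}}
#' \deqn{MAE  = \frac{1}{n}\sum_i |S_i - O_i|}
#' \deqn{NSE  = 1 - \frac{\sum_i (S_i - O_i)^2}{\sum_i (O_i - \bar O)^2}}
#' where \eqn{S_i} are simulated (or predicted) and \eqn{O_i} observed values.
#'
#' NSE ranges over \eqn{(-\infty, 1]}: 1 is a perfect fit and 0 the skill of
#' the constant mean-of-observations predictor. A zero-variance observed
#' series makes NSE undefined and raises an error rather than returning
#' NaN or -Inf.
#'
#' @param simulated numeric vector of simulated/predicted values.
#' @param observed numeric vector of observed values, same length.
#' @return A single numeric value.
#' @examples
#' rmse(c(1, 2, 4), c(1, 3, 5))  # sqrt(2/3)
#' nse(c(1, 2, 4), c(1, 3, 5))   # 0.75
#' @name metrics
NULL

check_pairs <- function(simulated, observed, min_n = 1L) {
  assert_that(is.numeric(simulated) && is.numeric(observed),
              "simulated and observed must be numeric vectors")
  assert_that(length(simulated) == length(observed),
              sprintf("length mismatch: %d simulated vs %d observed",
                      length(simulated), length(observed)))
  assert_that(length(observed) >= min_n,
              sprintf("need at least %d paired values, got %d", min_n, length(observed)))
  assert_that(all(is.finite(simulated)) && all(is.finite(observed)),
              "all paired values must be finite")
  invisible(TRUE)
}

#' @rdname metrics
#' @export
rmse <- function(simulated, observed) {
  check_pairs(simulated, observed)
  sqrt(mean((simulated - observed)^2))
}

#' @rdname metrics
#' @export
mae <- function(simulated, observed) {
  check_pairs(simulated, observed)
  mean(abs(simulated - observed))
}

#' @rdname metrics
#' @export
nse <- function(simulated, observed) {
  check_pairs(simulated, observed, min_n = 2L)
  ss_obs <- sum((observed - mean(observed))^2)
  if (ss_obs == 0) {
    stop_rscmlai("NSE undefined: observed series has zero variance",
                 "rscmlai_undefined_statistic")
  }
  1 - sum((simulated - observed)^2) / ss_obs
}

#' @rdname metrics
#' @export
coefficient_of_determination <- function(simulated, observed) {
  # Same formula as NSE applied to (prediction, target) pairs; named alias so
  # score tables are self-describing.
  nse(simulated, observed)
}
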