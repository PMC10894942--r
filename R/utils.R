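#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_rscmlai <- function(msg, class) {
  stop(structure(
    class = c(class, "rscmlai_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(ok, msg, class = "rscmlai_validation_error") {
  if (!isTRUE(ok)) stop_rscmlai(msg, class)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  assert_that(!anyNA(out),
              sprintf("unparseable %s value(s): %s", what,
                      paste(utils::head(as.character(x)[is.na(out)], 3), collapse = ", ")))
  out
}
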