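table_schemas <- list(
  weather = list(cols = c("date", "tmax_c", "tmin_c", "srad_mj_m2", "prcp_mm"),
                 numeric = c("tmax_c", "tmin_c", "srad_mj_m2", "prcp_mm")),
  reflectance = list(cols = c("date", "plot_id", "r560", "r660", "r800"),
                     numeric = c("r560", "r660", "r800")),
  lai_obs = list(cols = c("date", "plot_id", "lai", "source"),
                 numeric = "lai"),
  dataset = list(cols = c("mtvi1", "ndvi", "osavi", "rdvi", "lai"),
                 numeric = c("mtvi1", "ndvi", "osavi", "rdvi", "lai"))
)

#' Read one of the package's CSV table formats
#'
#' Validated CSV readers for the four canonical table kinds (one CSV
#' dialect: comma-separated, UTF-8, ISO-8601 dates, `.` decimal):
#' \describe{
#'   \item{weather}{`date, tmax_c, tmin_c, srad_mj_m2, prcp_mm`}
#'   \item{reflectance}{`date, plot_id, r560, r660, r800`}
#'   \item{lai_obs}{`date, plot_id, lai, source`}
#'   \item{dataset}{`mtvi1, ndvi, osavi, rdvi, lai` (+ optional `date`,
#'     `plot_id`, `treatment`, `crop`)}
#' }
#' Violations are reported with file, row and column. Reflectance values are
#' converted to the canonical \[0, 1\] fraction according to `units`.
#'
#' @param path CSV file path.
#' @param kind `"weather"`, `"reflectance"`, `"lai_obs"` or `"dataset"`.
#' @param units reflectance units, `"percent"` (default) or `"fraction"`;
#'   only used for `kind = "reflectance"`.
#' @return A validated data.frame.
#' @export
read_table <- function(path, kind = c("weather", "reflectance", "lai_obs", "dataset"),
                       units = c("percent", "fraction")) {
  kind <- match.arg(kind)
  units <- match.arg(units)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  schema <- table_schemas[[kind]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(schema$cols, names(df))
  if (kind == "dataset") missing <- setdiff(schema$cols, names(df))
  assert_that(length(missing) == 0,
              sprintf("%s: missing column(s) %s for kind '%s'",
                      path, paste(missing, collapse = ", "), kind))
  for (col in schema$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop_rscmlai(sprintf("%s: row %d, column %s: unparseable or non-finite value '%s'",
                           path, bad[1], col, as.character(df[[col]][bad[1]])),
                   "rscmlai_validation_error")
    }
    df[[col]] <- v
  }
  if ("date" %in% names(df)) df$date <- as_date_strict(df$date)
  if (kind == "reflectance") {
    for (col in c("r560", "r660", "r800")) {
      df[[col]] <- normalize_reflectance(df[[col]], units = units)
    }
  }
  if (kind == "weather") check_weather(df)
  if (kind == "lai_obs") {
    assert_that(all(df$lai >= 0), sprintf("%s: negative LAI observation", path))
  }
  if (kind == "dataset") check_dataset(df)
  df
}

#' Write one of the package's CSV table formats
#'
#' Deterministic output: fixed column order (schema columns first) and fixed
#' 6-decimal formatting of reals, so identical records produce byte-identical
#' files.
#'
#' @param records data.frame to write.
#' @param path output CSV path.
#' @param kind table kind, as in [read_table()].
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, kind = c("weather", "reflectance", "lai_obs", "dataset")) {
  kind <- match.arg(kind)
  schema <- table_schemas[[kind]]
  assert_that(is.data.frame(records), "records must be a data.frame")
  have <- intersect(schema$cols, names(records))
  extra <- setdiff(names(records), schema$cols)
  out <- records[c(have, extra)]
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !inherits(out[[col]], "Date")) {
      out[[col]] <- sprintf("%.6f", out[[col]])
    } else if (inherits(out[[col]], "Date")) {
      out[[col]] <- format(out[[col]], "%Y-%m-%d")
    }
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_rscmlai(
                    sprintf("cannot open %s for writing", path), "rscmlai_io_error"))
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  }
  invisible(path)
}

config_known_keys <- list(
  top = c("crop", "reflectance_units", "vi_dialect", "coefficients", "params",
          "senescence", "calibration", "ml", "synthetic", "output_dir",
          "verbosity"),
  coefficients = c("epsilon", "k", "s_leaf", "t_base", "beta"),
  params = c("l0", "a", "b", "c"),
  senescence = "enabled",
  calibration = c("tol", "maxit"),
  ml = c("seed", "ratio", "specs"),
  synthetic = c("start", "end", "mean_temp", "temp_amplitude", "temp_noise_sd",
                "diurnal_range", "mean_srad", "srad_noise_sd", "treatments",
                "reflectance_noise_sd", "lai_noise_sd", "n_samples")
)

#' Load and resolve a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys by name, and resolves
#' defaults: crop-specific coefficients from [crop_coefficients()], initial
#' calibration parameters from [default_initial_params()], `literature` VI
#' dialect, percent reflectance units, senescence enabled.
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @param crop used when the file does not name a crop (default `"rice"`).
#' @return A list of class `run_config` with elements `crop`,
#'   `reflectance_units`, `vi_dialect`, `coefficients`, `params`,
#'   `senescence`, `calibration`, `ml`, `synthetic`, `output_dir`,
#'   `verbosity`.
#' @export
load_config <- function(path = NULL, crop = "rice") {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    assert_that(length(unknown) == 0,
                sprintf("unknown configuration key '%s' in %s",
                        unknown[1], where),
                class = "rscmlai_config_error")
  }
  check_keys(raw, config_known_keys$top, "top level")
  for (sec in c("coefficients", "params", "senescence", "calibration", "ml",
                "synthetic")) {
    if (!is.null(raw[[sec]])) check_keys(raw[[sec]], config_known_keys[[sec]], sec)
  }

  crop <- if (!is.null(raw$crop)) raw$crop else crop
  assert_that(crop %in% c("rice", "soybean"),
              sprintf("unknown crop '%s'", crop), class = "rscmlai_config_error")
  coeff <- do.call(crop_coefficients, c(list(crop = crop), raw$coefficients))
  p0 <- default_initial_params()
  for (nm in names(raw$params)) p0[[nm]] <- raw$params[[nm]]
  params <- calibration_params(p0$l0, p0$a, p0$b, p0$c)

  structure(list(
    crop = crop,
    reflectance_units = if (!is.null(raw$reflectance_units)) raw$reflectance_units else "percent",
    vi_dialect = check_dialect(if (!is.null(raw$vi_dialect)) raw$vi_dialect else "literature"),
    coefficients = coeff,
    params = params,
    senescence = if (!is.null(raw$senescence$enabled)) isTRUE(raw$senescence$enabled) else TRUE,
    calibration = list(tol = if (!is.null(raw$calibration$tol)) raw$calibration$tol else 1e-6,
                       maxit = if (!is.null(raw$calibration$maxit)) raw$calibration$maxit else 1000),
    ml = list(seed = if (!is.null(raw$ml$seed)) as.integer(raw$ml$seed) else 0L,
              ratio = if (!is.null(raw$ml$ratio)) raw$ml$ratio else 0.8,
              specs = if (!is.null(raw$ml$specs)) raw$ml$specs
                      else setdiff(regressor_names, "dnn")),
    synthetic = do.call(synthetic_config, c(list(crop = crop), raw$synthetic)),
    output_dir = if (!is.null(raw$output_dir)) raw$output_dir else ".",
    verbosity = if (!is.null(raw$verbosity)) raw$verbosity else "info"
  ), class = "run_config")
}
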