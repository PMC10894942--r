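#' Vegetation indices from three-band canopy reflectance
#'
#' Computes MTVI1, NDVI, OSAVI and RDVI from canopy reflectance at 560, 660
#' and 800 nm. Reflectances are dimensionless fractions in \[0, 1\]
#' (use [normalize_reflectance()] for percent-unit inputs).
#'
#' Two formula dialects are supported for MTVI1 and RDVI:
#' \describe{
#'   \item{`"literature"` (default)}{the forms of the original index
#'     publications: MTVI1 = 1.2·\[1.2·(R800 − R560) − 2.5·(R660 − R560)\]
#'     (Haboudane), RDVI = (R800 − R660)/sqrt(R800 + R660) (Roujean-Bréon).}
#'   \item{`"as_printed"`}{MTVI1 = 1.2·(R800 − R660) − 2.5·(R660 + R560) and
#'     RDVI = (R800 − R660)/(R800 + R660), i.e. RDVI coincides with NDVI.
#'     Retained for strict fidelity to sources that typeset the indices this
#'     way.}
#' }
#' NDVI = (R800 − R660)/(R800 + R660) and
#' OSAVI = (R800 − R660)/(R800 + R660 + 0.16) are dialect-independent.
#'
#' @param r560,r660,r800 reflectance fractions (numeric vectors, recycled to
#'   a common length).
#' @param dialect `"literature"` or `"as_printed"`.
#' @return Numeric vector of index values.
#' @examples
#' compute_ndvi(r660 = 0.1, r800 = 0.5)             # 0.6667
#' compute_mtvi1(0.12, 0.1, 0.5, "literature")      # 0.6072
#' @name vegetation_indices
NULL

vi_dialects <- c("literature", "as_printed")

check_dialect <- function(dialect) {
  assert_that(is.character(dialect) && length(dialect) == 1L && dialect %in% vi_dialects,
              sprintf("unknown VI dialect %s; must be one of: %s",
                      deparse(dialect), paste(vi_dialects, collapse = ", ")),
              class = "rscmlai_config_error")
  dialect
}

check_bands <- function(r560, r660, r800) {
  v <- c(r560, r660, r800)
  assert_that(all(is.finite(v)), "reflectance bands must be finite and present")
  assert_that(all(v >= 0 & v <= 1),
              "reflectance must be a fraction in [0, 1]; use normalize_reflectance() for percent units")
  invisible(TRUE)
}

#' Convert reflectance to the canonical \[0, 1\] fraction
#'
#' Proximal radiometers commonly report percent reflectance; all index
#' computations here use fractions. The unit must be declared, not sniffed.
#'
#' @param x numeric reflectance values.
#' @param units `"percent"` or `"fraction"`.
#' @return Reflectance fractions in \[0, 1\].
#' @export
normalize_reflectance <- function(x, units = c("percent", "fraction")) {
  units <- match.arg(units)
  if (units == "percent") x <- x / 100
  assert_that(all(is.finite(x) & x >= 0 & x <= 1),
              sprintf("reflectance out of [0, 1] after %s-unit normalization", units))
  x
}

#' @rdname vegetation_indices
#' @export
compute_ndvi <- function(r560 = NULL, r660, r800) {
  check_bands(numeric(0), r660, r800)
  den <- r800 + r660
  if (any(den == 0)) {
    stop_rscmlai("NDVI undefined: R800 + R660 is zero", "rscmlai_degenerate_input")
  }
  (r800 - r660) / den
}

#' @rdname vegetation_indices
#' @export
compute_osavi <- function(r560 = NULL, r660, r800) {
  check_bands(numeric(0), r660, r800)
  (r800 - r660) / (r800 + r660 + 0.16)
}

#' @rdname vegetation_indices
#' @export
compute_mtvi1 <- function(r560, r660, r800, dialect = c("literature", "as_printed")) {
  dialect <- check_dialect(match.arg(dialect))
  check_bands(r560, r660, r800)
  if (dialect == "as_printed") {
    1.2 * (r800 - r660) - 2.5 * (r660 + r560)
  } else {
    1.2 * (1.2 * (r800 - r560) - 2.5 * (r660 - r560))
  }
}

#' @rdname vegetation_indices
#' @export
compute_rdvi <- function(r560 = NULL, r660, r800, dialect = c("literature", "as_printed")) {
  dialect <- check_dialect(match.arg(dialect))
  check_bands(numeric(0), r660, r800)
  if (dialect == "as_printed") {
    compute_ndvi(r660 = r660, r800 = r800)
  } else {
    den <- r800 + r660
    if (any(den <= 0)) {
      stop_rscmlai("RDVI undefined: sqrt(R800 + R660) requires a positive argument",
                   "rscmlai_degenerate_input")
    }
    (r800 - r660) / sqrt(den)
  }
}

#' Compute all four vegetation indices for a reflectance table
#'
#' @param reflectance a data.frame with columns `r560`, `r660`, `r800`
#'   (fractions; see [normalize_reflectance()]) and optionally `date` and
#'   `plot_id`, which are carried through.
#' @inheritParams vegetation_indices
#' @return A data.frame with columns `mtvi1`, `ndvi`, `osavi`, `rdvi`,
#'   `dialect`, preceded by any `date`/`plot_id` columns of the input.
#' @export
compute_vi_table <- function(reflectance, dialect = c("literature", "as_printed")) {
  dialect <- check_dialect(match.arg(dialect))
  assert_that(is.data.frame(reflectance) &&
                all(c("r560", "r660", "r800") %in% names(reflectance)),
              "reflectance must be a data.frame with columns r560, r660, r800")
  out <- data.frame(
    mtvi1 = compute_mtvi1(reflectance$r560, reflectance$r660, reflectance$r800, dialect),
    ndvi  = compute_ndvi(r660 = reflectance$r660, r800 = reflectance$r800),
    osavi = compute_osavi(r660 = reflectance$r660, r800 = reflectance$r800),
    rdvi  = compute_rdvi(r660 = reflectance$r660, r800 = reflectance$r800, dialect = dialect),
    dialect = dialect
  )
  keep <- intersect(c("date", "plot_id"), names(reflectance))
  if (length(keep)) out <- cbind(reflectance[keep], out)
  rownames(out) <- NULL
  out
}
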