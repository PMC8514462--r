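#' Latitudinal richness gradient (quadratic)
#'
#' OLS of crop-group richness on absolute latitude and its square, using the
#' raw (non-orthogonal) polynomial basis so the coefficients are directly
#' interpretable. The peak of the fitted parabola, `-beta1 / (2 * beta2)`,
#' is reported when the quadratic term is negative (hump-shaped gradient).
#'
#' @param latitude Absolute centroid latitude per country, degrees in
#'   `[0, 90]`.
#' @param S Crop-group richness per country for one comparison year.
#' @param year Year label recorded in the result.
#' @param min_countries Minimum number of countries required.
#' @return List of class `lat_gradient_fit`: `year`, coefficients `beta0`,
#'   `beta1`, `beta2` with standard errors `se0`, `se1`, `se2`, `r2`, `p`
#'   (overall F), `peak_latitude` (`NA` when `beta2 >= 0`), `n`.
#' @export
fit_latitude_gradient <- function(latitude, S, year = NA_integer_,
                                  min_countries = 10L) {
  stopifnot(length(latitude) == length(S))
  ok <- is.finite(latitude) & is.finite(S)
  latitude <- latitude[ok]; S <- S[ok]
  if (length(S) < min_countries) {
    stop("need at least ", min_countries, " countries with data")
  }
  if (length(unique(latitude)) < 3L) {
    stop("rank error: fewer than 3 distinct latitudes")
  }
  fit <- stats::lm(S ~ latitude + I(latitude^2))
  sm <- summary(fit)
  co <- sm$coefficients
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  b1 <- co[2L, 1L]; b2 <- co[3L, 1L]
  structure(list(
    year = year,
    beta0 = co[1L, 1L], beta1 = b1, beta2 = b2,
    se0 = co[1L, 2L], se1 = co[2L, 2L], se2 = co[3L, 2L],
    r2 = sm$r.squared, p = unname(p),
    peak_latitude = if (b2 < 0) peak_latitude(b1, b2) else NA_real_,
    n = length(S)
  ), class = "lat_gradient_fit")
}

#' @export
print.lat_gradient_fit <- function(x, ...) {
  cat(sprintf(
    "Latitudinal richness gradient%s: S = %.2f + %.3f*L %+.4f*L^2 (n = %d)\n",
    if (is.na(x$year)) "" else paste0(" (", x$year, ")"),
    x$beta0, x$beta1, x$beta2, x$n))
  cat(sprintf("  r2 = %.3f, p = %.3g, peak latitude = %s\n", x$r2, x$p,
              if (is.na(x$peak_latitude)) "none (beta2 >= 0)"
              else sprintf("%.2f deg", x$peak_latitude)))
  invisible(x)
}

#' Latitude of peak richness
#'
#' Vertex of the fitted parabola: `-beta1 / (2 * beta2)`, defined only for a
#' hump-shaped (concave, `beta2 < 0`) gradient.
#'
#' @param beta1 Linear latitude coefficient.
#' @param beta2 Quadratic latitude coefficient; must be negative.
#' @return Peak latitude in degrees.
#' @export
peak_latitude <- function(beta1, beta2) {
  if (beta2 >= 0) {
    stop("no interior maximum: quadratic coefficient is not negative")
  }
  -beta1 / (2 * beta2)
}

#' Indicator-versus-area diagnostic regressions
#'
#' Simple OLS of each indicator on a country-area measure (total or
#' cultivated area), reported as a diagnostics table. Used to verify that
#' change indicators are unrelated to country size. Degenerate inputs
#' (fewer than 3 pairs, constant predictor) are skipped with a warning.
#'
#' @param indicators Data frame from [indicator_table()].
#' @param areas Named numeric vector: country -> area (ha).
#' @param area_label Label for the area measure in the output.
#' @return Data frame `indicator`, `area_measure`, `r2`, `p`, `n` (one row
#'   per indicator; `NA` row when skipped).
#' @export
area_regression <- function(indicators, areas,
                            area_label = "total_area") {
  cols <- c(onset = 1L, duration = 2L, rate = 3L)
  rows <- lapply(names(cols), function(nm) {
    x <- unname(areas[indicators$country])
    y <- indicators[[nm]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || length(unique(x)) < 2L) {
      warning("area regression skipped for indicator ", cols[[nm]],
              ": insufficient or constant data")
      return(data.frame(indicator = cols[[nm]], area_measure = area_label,
                        r2 = NA_real_, p = NA_real_, n = length(x),
                        stringsAsFactors = FALSE))
    }
    sm <- summary(stats::lm(y ~ x))
    fstat <- sm$fstatistic
    data.frame(
      indicator = cols[[nm]], area_measure = area_label,
      r2 = sm$r.squared,
      p = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                           lower.tail = FALSE)),
      n = length(x), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
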