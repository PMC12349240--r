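#' Geographic-gradient regression of a hydrothermal index
#'
#' Ordinary least squares of an index on longitude, latitude and altitude
#' with an intercept: `index ~ LON + LAT + ALT`. This is the standard way of
#' summarising how accumulated warmth, coldness or humidity vary along the
#' three geographic dimensions of a study region.
#'
#' @param samples data frame with columns `lon`, `lat`, `alt` and the
#'   response column named by `response`.
#' @param response which index is being modelled (column name; also stored
#'   as the response tag, e.g. `"wi"`).
#' @return An object of class `geo_regression` wrapping the `lm` fit, with
#'   `print`, `coef` and `predict` methods, plus `r_squared` and `p_values`.
#' @export
fit_geo_regression <- function(samples, response = "wi") {
  need <- c("lon", "lat", "alt", response)
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- samples[is.finite(samples[[response]]), need]
  if (nrow(d) < 5) stop("need at least 5 samples with a finite response")
  names(d)[4] <- ".y"
  fit <- stats::lm(.y ~ lon + lat + alt, data = d)
  if (fit$rank < 4)
    stop("rank-deficient design: lon/lat/alt are collinear in these samples")
  sm <- summary(fit)
  co <- stats::coef(fit)
  geo_regression_model(
    intercept = unname(co[1]), coef_lon = unname(co["lon"]),
    coef_lat = unname(co["lat"]), coef_alt = unname(co["alt"]),
    response = response, r_squared = sm$r.squared,
    p_values = sm$coefficients[, "Pr(>|t|)"], lm_fit = fit)
}

#' Build a geographic-gradient model from known coefficients
#'
#' Constructs the same object [fit_geo_regression()] returns, but from
#' explicit coefficients — e.g. a published regression equation — so it can
#' be evaluated or summarised without the underlying data.
#'
#' @param intercept,coef_lon,coef_lat,coef_alt model coefficients
#'   (per degree longitude, per degree latitude, per metre altitude).
#' @param response response tag.
#' @param r_squared,p_values,lm_fit optional fit diagnostics.
#' @return An object of class `geo_regression`.
#' @export
geo_regression_model <- function(intercept, coef_lon, coef_lat, coef_alt,
                                 response = "wi", r_squared = NA_real_,
                                 p_values = NULL, lm_fit = NULL) {
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]")
  structure(list(response = response, intercept = intercept,
                 coef_lon = coef_lon, coef_lat = coef_lat,
                 coef_alt = coef_alt, r_squared = r_squared,
                 p_values = p_values, lm_fit = lm_fit),
            class = "geo_regression")
}

#' @export
print.geo_regression <- function(x, ...) {
  cat(sprintf("%s = %.3f %+.3f LON %+.3f LAT %+.3f ALT",
              toupper(x$response), x$intercept, x$coef_lon, x$coef_lat,
              x$coef_alt))
  if (!is.na(x$r_squared)) cat(sprintf("   (R2 = %.3f)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' @export
coef.geo_regression <- function(object, ...) {
  c(intercept = object$intercept, lon = object$coef_lon,
    lat = object$coef_lat, alt = object$coef_alt)
}

#' @export
predict.geo_regression <- function(object, newdata, ...) {
  stopifnot(all(c("lon", "lat", "alt") %in% names(newdata)))
  object$intercept + object$coef_lon * newdata$lon +
    object$coef_lat * newdata$lat + object$coef_alt * newdata$alt
}

#' Per-unit geographic gradients of a fitted index regression
#'
#' Converts regression coefficients into the deltas practitioners quote:
#' change per 1 degree of latitude, per 1 degree of longitude, and per
#' 100 m of elevation gain.
#'
#' @param model a `geo_regression`.
#' @return Named numeric vector `c(per_deg_lat, per_deg_lon, per_100m_alt)`.
#' @export
gradient_summary <- function(model) {
  stopifnot(inherits(model, "geo_regression"))
  c(per_deg_lat = model$coef_lat,
    per_deg_lon = model$coef_lon,
    per_100m_alt = model$coef_alt * 100)
}
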