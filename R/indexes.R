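#' Kira's warmth index
#'
#' Accumulated warmth over the growing season: the sum of monthly mean
#' temperature excesses above 5 degrees C, taken over the months whose mean
#' exceeds 5 degrees C. Units are degree C-months; the index is always
#' non-negative.
#'
#' @param monthly_mean_temp numeric vector of exactly 12 monthly mean
#'   temperatures (degrees C).
#' @return Warmth index (degree C-month), a single non-negative number.
#' @seealso [coldness_index()], [humidity_index()]
#' @export
#' @examples
#' warmth_index(rep(10, 12))  # 60
warmth_index <- function(monthly_mean_temp) {
  check_monthly(monthly_mean_temp)
  sum(pmax(monthly_mean_temp - 5, 0))
}

#' Kira's coldness index
#'
#' Accumulated coldness: minus the sum of deficits below 5 degrees C over the
#' months whose mean falls below 5 degrees C. Always non-positive, in
#' degree C-months. Together with the warmth index it satisfies the identity
#' `WI + CI = 12 * (mean(t) - 5)` (months at exactly 5 degrees C contribute
#' to neither side).
#'
#' @inheritParams warmth_index
#' @return Coldness index (degree C-month), a single non-positive number.
#' @export
coldness_index <- function(monthly_mean_temp) {
  check_monthly(monthly_mean_temp)
  -sum(pmax(5 - monthly_mean_temp, 0))
}

check_monthly <- function(t) {
  if (length(t) != 12) stop("need exactly 12 monthly temperatures, got ",
                            length(t))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("monthly temperatures must be finite numbers")
  invisible(t)
}

#' Xu's humidity index
#'
#' Annual precipitation divided by the warmth index, in mm per degree
#' C-month. Larger values mean wetter conditions relative to accumulated
#' warmth. Where the warmth index is not positive the ratio is undefined and
#' `NA` is returned (recorded and excluded downstream rather than raised as
#' an error).
#'
#' @param annual_precip annual precipitation (mm, >= 0).
#' @param wi warmth index (degree C-month).
#' @return Humidity index (mm per degree C-month), or `NA` when `wi <= 0`.
#' @export
humidity_index <- function(annual_precip, wi) {
  if (any(annual_precip < 0)) stop("annual precipitation must be >= 0")
  ifelse(wi > 0, annual_precip / wi, NA_real_)
}

#' Station-level hydrothermal indexes
#'
#' Applies [warmth_index()], [coldness_index()] and [humidity_index()] to a
#' table of station climate normals.
#'
#' @param records data frame with columns `station_id`, `lon`, `lat`, `alt`,
#'   `t01`..`t12` (monthly mean temperature, degrees C) and `precip_ann`
#'   (annual precipitation, mm), as produced by
#'   [generate_station_network()] or read from a station CSV.
#' @return A data frame with one row per station: `station_id`, `lon`,
#'   `lat`, `alt`, `wi`, `ci`, `hi` (`hi` is `NA` where `wi <= 0`).
#' @export
station_indexes <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data frame")
  tc <- sprintf("t%02d", 1:12)
  need <- c("station_id", "lon", "lat", "alt", tc, "precip_ann")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$station_id))
    stop("duplicate station_id: ",
         paste(unique(records$station_id[duplicated(records$station_id)]),
               collapse = ", "))
  tm <- as.matrix(records[, tc])
  wi <- apply(tm, 1, warmth_index)
  ci <- apply(tm, 1, coldness_index)
  data.frame(station_id = records$station_id, lon = records$lon,
             lat = records$lat, alt = records$alt,
             wi = wi, ci = ci,
             hi = humidity_index(records$precip_ann, wi))
}
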