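EARTH_RADIUS_KM <- 6371.0088  # IUGG mean Earth radius

#' Classify a suitability grid into four classes
#'
#' Bins `[0, 0.2)` non-suitable, `[0.2, 0.4)` minimally, `[0.4, 0.6)`
#' moderately and `[0.6, 1]` highly suitable (lower-inclusive breaks);
#' nodata cells are preserved.
#'
#' @param suitability a [hydro_grid()] with values in \[0, 1\].
#' @param breaks strictly increasing class breaks in (0, 1)
#'   (default `c(0.2, 0.4, 0.6)`).
#' @return An object of class `suitability_classes`: the classified grid
#'   (`integer codes 1-4` in `$grid`), `labels`, `breaks` and per-class
#'   `areas` in 1e4 km2 (see [class_areas()]).
#' @export
classify_suitability <- function(suitability, breaks = c(0.2, 0.4, 0.6)) {
  stopifnot(inherits(suitability, "hydro_grid"))
  if (any(diff(breaks) <= 0) || any(breaks <= 0) || any(breaks >= 1))
    stop("breaks must be strictly increasing within (0, 1)")
  v <- suitability$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("suitability values outside [0, 1]")
  cls <- findInterval(v, breaks) + 1L
  cls[is.na(v)] <- NA_integer_
  g <- hydro_grid(matrix(cls, nrow(v), ncol(v)), suitability$bbox,
                  suitability$resolution, var = "class")
  labels <- c("non-suitable", "minimally", "moderately", "highly")
  out <- structure(list(grid = g, breaks = breaks, labels = labels),
                   class = "suitability_classes")
  out$areas <- class_areas(out)
  out
}

#' @export
print.suitability_classes <- function(x, ...) {
  cat("suitability_classes (breaks",
      paste(x$breaks, collapse = "/"), "):\n")
  print(round(x$areas, 2))
  invisible(x)
}

#' Spherical area of a latitude-longitude cell
#'
#' Spherical-zone formula `R^2 * dlambda * (sin(lat_top) - sin(lat_bottom))`
#' with R = 6371.0088 km.
#'
#' @param lat_bottom,lat_top cell edge latitudes (degrees,
#'   `lat_top > lat_bottom`).
#' @param lon_width cell width in degrees of longitude.
#' @return Cell area in km2.
#' @export
cell_area <- function(lat_bottom, lat_top, lon_width) {
  if (any(lat_top <= lat_bottom)) stop("lat_top must exceed lat_bottom")
  rad <- pi / 180
  EARTH_RADIUS_KM^2 * (lon_width * rad) *
    (sin(lat_top * rad) - sin(lat_bottom * rad))
}

# km2 area of every cell of a grid, as a vector in storage order
grid_cell_areas <- function(grid) {
  d <- dim(grid$values)
  res <- grid$resolution / 60
  lat_top <- grid$bbox[4] - (seq_len(d[1]) - 1) * res
  a_row <- cell_area(lat_top - res, lat_top, res)
  rep(a_row, each = d[2])
}

#' Per-class areas of a classified grid
#'
#' Sums latitude-corrected cell areas per suitability class. The total of
#' the minimally, moderately and highly suitable classes is the potential
#' distribution area; all four classes together conserve the unmasked
#' study area.
#'
#' @param classes a `suitability_classes` object.
#' @return Named numeric vector of areas in 1e4 km2, one per class plus
#'   `potential` (sum of the three suitable classes).
#' @export
class_areas <- function(classes) {
  stopifnot(inherits(classes, "suitability_classes"))
  cls <- as.vector(t(classes$grid$values))
  a <- grid_cell_areas(classes$grid)
  out <- vapply(1:4, function(k) sum(a[!is.na(cls) & cls == k]),
                numeric(1)) / 1e4
  names(out) <- classes$labels
  c(out, potential = sum(out[2:4]))
}

#' Binary presence mask from suitability
#'
#' A cell is a potential-presence cell iff its suitability strictly
#' exceeds the threshold.
#'
#' @param suitability a [hydro_grid()] in \[0, 1\].
#' @param threshold presence cutoff (default 0.2, strict `>`).
#' @return A [hydro_grid()] of 0/1 values (NA preserved).
#' @export
binary_presence <- function(suitability, threshold = 0.2) {
  stopifnot(inherits(suitability, "hydro_grid"))
  v <- suitability$values
  m <- (v > threshold) * 1
  hydro_grid(m, suitability$bbox, suitability$resolution, var = "presence")
}

#' Range-change map between two presence masks
#'
#' Cell categories: `never` (absent in both), `loss` (current only),
#' `gain` (future only), `stable` (both). Gain and loss are disjoint by
#' construction and the four categories partition the unmasked grid.
#'
#' @param current,future aligned 0/1 presence [hydro_grid()]s.
#' @return An object of class `change_map` with the coded grid
#'   (0 = never, 1 = loss, 2 = gain, 3 = stable) and per-category `areas`
#'   (1e4 km2).
#' @export
change_map <- function(current, future) {
  if (!same_grid_spec(current, future)) stop("misaligned grids")
  c0 <- current$values > 0
  f0 <- future$values > 0
  code <- ifelse(c0 & f0, 3L, ifelse(c0 & !f0, 1L, ifelse(!c0 & f0, 2L, 0L)))
  g <- hydro_grid(code, current$bbox, current$resolution, var = "change")
  a <- grid_cell_areas(g)
  v <- as.vector(t(code))
  areas <- vapply(0:3, function(k) sum(a[!is.na(v) & v == k]),
                  numeric(1)) / 1e4
  names(areas) <- c("never", "loss", "gain", "stable")
  structure(list(grid = g, areas = areas), class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  cat("change_map areas (1e4 km2):\n")
  print(round(x$areas, 2))
  invisible(x)
}

#' Area-weighted centroid of a predicted range
#'
#' Mean of presence-cell center coordinates weighted by spherical cell
#' area (optionally additionally by suitability). Uses a planar mean of
#' lon/lat, which assumes the extent does not span the antimeridian.
#'
#' @param suitability a [hydro_grid()] in \[0, 1\].
#' @param threshold presence cutoff (strict `>`; default 0.2).
#' @param weight_by_suitability if `TRUE`, weight each presence cell by
#'   area x suitability instead of area alone.
#' @return Named numeric `c(lon, lat)`.
#' @export
range_centroid <- function(suitability, threshold = 0.2,
                           weight_by_suitability = FALSE) {
  stopifnot(inherits(suitability, "hydro_grid"))
  if (suitability$bbox[1] < -180 || suitability$bbox[2] > 180)
    stop("extent spans the antimeridian; planar centroid not valid")
  cells <- grid_cells(suitability)
  a <- grid_cell_areas(suitability)
  keep <- !is.na(cells$value) & cells$value > threshold
  if (!any(keep)) stop("empty presence mask")
  w <- a[keep]
  if (weight_by_suitability) w <- w * cells$value[keep]
  c(lon = sum(w * cells$lon[keep]) / sum(w),
    lat = sum(w * cells$lat[keep]) / sum(w))
}

#' Centroid migration vector
#'
#' Great-circle displacement between two centroids: haversine distance
#' (R = 6371.0088 km), initial bearing from north in \[0, 360) and the
#' 45-degree-sector cardinal label. Identical points return distance 0 and
#' bearing 0 by convention.
#'
#' @param from,to `c(lon, lat)` coordinate pairs (degrees).
#' @return A list of class `migration_vector`: `from`, `to`, `distance_km`,
#'   `bearing_deg`, `cardinal`.
#' @export
migration_vector <- function(from, to) {
  stopifnot(length(from) == 2, length(to) == 2)
  if (isTRUE(all.equal(as.numeric(from), as.numeric(to)))) {
    d <- 0; b <- 0
  } else {
    d <- geosphere::distHaversine(from, to, r = EARTH_RADIUS_KM)
    b <- geosphere::bearing(from, to) %% 360
  }
  sector <- (floor((b + 22.5) / 45) %% 8) + 1
  structure(list(from = c(lon = from[[1]], lat = from[[2]]),
                 to = c(lon = to[[1]], lat = to[[2]]),
                 distance_km = d, bearing_deg = b,
                 cardinal = c("N", "NE", "E", "SE",
                              "S", "SW", "W", "NW")[sector]),
            class = "migration_vector")
}

#' @export
print.migration_vector <- function(x, ...) {
  cat(sprintf(
    "migration: (%.4f, %.4f) -> (%.4f, %.4f)  %.2f km, bearing %.1f (%s)\n",
    x$from[1], x$from[2], x$to[1], x$to[2], x$distance_km, x$bearing_deg,
    x$cardinal))
  invisible(x)
}
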