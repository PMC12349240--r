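# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-world configuration
#'
#' Parameters of the simulated study region used to exercise the whole
#' pipeline against a known ground truth. Monthly station temperature is
#' `monthly_profile[m] - lat_gradient * (lat - lat_min) -
#' lapse_per_100m * alt / 100 + N(0, noise_sd_temp)` and annual
#' precipitation is `precip_base + precip_lon_gradient * (lon - lon_min) +
#' N(0, noise_sd_precip)`, floored at zero.
#'
#' The defaults describe a 5 x 5 degree mid-latitude continental box at
#' 2.5 arc-minute resolution with a temperate monthly profile, a 0.8
#' degree C per degree-latitude cooling, the standard 0.6 degree C per
#' 100 m lapse rate, and a west-to-east precipitation gradient — the kind
#' of hydrothermal structure found across northern-China drylands.
#'
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)` degrees.
#' @param resolution cell size, arc-minutes.
#' @param n_stations number of climate stations.
#' @param seed integer seed driving all generators built from this config.
#' @param lapse_per_100m temperature lapse, degrees C per 100 m.
#' @param lat_gradient cooling per degree of northward latitude, degrees C.
#' @param monthly_profile 12 baseline monthly mean temperatures (degrees C)
#'   at the reference point (`lat_min`, altitude 0).
#' @param precip_base annual precipitation at `lon_min` (mm).
#' @param precip_lon_gradient precipitation change per degree of eastward
#'   longitude (mm).
#' @param noise_sd_temp,noise_sd_precip i.i.d. noise SDs (>= 0).
#' @return A list of class `world_config`.
#' @export
world_config <- function(bbox = c(100, 105, 35, 40), resolution = 2.5,
                         n_stations = 300, seed = 1,
                         lapse_per_100m = 0.6, lat_gradient = 0.8,
                         monthly_profile = c(-8, -4, 2, 10, 17, 21, 23,
                                             22, 16, 9, 0, -6),
                         precip_base = 400, precip_lon_gradient = 15,
                         noise_sd_temp = 0.3, noise_sd_precip = 20) {
  if (!(bbox[1] < bbox[2] && bbox[3] < bbox[4])) stop("invalid bbox")
  if (resolution <= 0) stop("resolution must be > 0")
  if (length(monthly_profile) != 12) stop("monthly_profile needs 12 values")
  if (noise_sd_temp < 0 || noise_sd_precip < 0) stop("noise SDs must be >= 0")
  if (n_stations < 1) stop("n_stations must be >= 1")
  structure(list(bbox = bbox, resolution = resolution,
                 n_stations = n_stations, seed = seed,
                 lapse_per_100m = lapse_per_100m,
                 lat_gradient = lat_gradient,
                 monthly_profile = monthly_profile,
                 precip_base = precip_base,
                 precip_lon_gradient = precip_lon_gradient,
                 noise_sd_temp = noise_sd_temp,
                 noise_sd_precip = noise_sd_precip),
            class = "world_config")
}

# deterministic monthly temperature (no noise) at (lat, alt), one month
world_monthly_temp <- function(cfg, lat, alt) {
  # returns length(lat) x 12 matrix
  base <- matrix(cfg$monthly_profile, nrow = length(lat), ncol = 12,
                 byrow = TRUE)
  base - cfg$lat_gradient * (lat - cfg$bbox[3]) -
    cfg$lapse_per_100m * alt / 100
}

world_precip <- function(cfg, lon) {
  cfg$precip_base + cfg$precip_lon_gradient * (lon - cfg$bbox[1])
}

#' Synthetic digital elevation model
#'
#' @param cfg a [world_config()].
#' @param kind `"flat"` (constant `base`) or `"ramp"` (rising west to east
#'   by `amplitude` metres with a gentle north-south sinusoid).
#' @param base base elevation (m).
#' @param amplitude total relief of the ramp (m).
#' @return A [hydro_grid()] of elevations.
#' @export
generate_dem <- function(cfg, kind = c("flat", "ramp"), base = 0,
                         amplitude = 1500) {
  kind <- match.arg(kind)
  tmpl <- hydro_grid(0, cfg$bbox, cfg$resolution, var = "alt")
  cells <- grid_cells(tmpl)
  alt <- if (kind == "flat") rep(base, nrow(cells)) else {
    fx <- (cells$lon - cfg$bbox[1]) / (cfg$bbox[2] - cfg$bbox[1])
    fy <- (cells$lat - cfg$bbox[3]) / (cfg$bbox[4] - cfg$bbox[3])
    base + amplitude * fx + 0.1 * amplitude * sin(2 * pi * fy)
  }
  hydro_grid(matrix(alt, nrow = dim(tmpl)[1], byrow = TRUE), cfg$bbox,
             cfg$resolution, var = "alt")
}

#' Generate a synthetic climate-station network
#'
#' Stations are placed at distinct cell centers of the DEM (altitude taken
#' from the DEM), so station indexes computed from noise-free stations agree
#' exactly with the analytic index surfaces at the station cells.
#'
#' @param cfg a [world_config()].
#' @param dem a [hydro_grid()] of elevations covering `cfg$bbox` at
#'   `cfg$resolution`; default flat at 0 m.
#' @return Data frame with columns `station_id`, `lon`, `lat`, `alt`,
#'   `t01`..`t12`, `precip_ann`. Identical `cfg` (including seed) gives an
#'   identical table.
#' @export
generate_station_network <- function(cfg, dem = generate_dem(cfg)) {
  stopifnot(inherits(cfg, "world_config"))
  tmpl <- hydro_grid(0, cfg$bbox, cfg$resolution)
  if (!same_grid_spec(tmpl, dem)) stop("dem does not match cfg bbox/resolution")
  cells <- grid_cells(dem)
  cells <- cells[!is.na(cells$value), ]
  if (cfg$n_stations > nrow(cells))
    stop("n_stations exceeds the number of land cells")
  with_seed(cfg$seed, {
    pick <- cells[sample.int(nrow(cells), cfg$n_stations), ]
    tm <- world_monthly_temp(cfg, pick$lat, pick$value)
    if (cfg$noise_sd_temp > 0)
      tm <- tm + matrix(stats::rnorm(length(tm), 0, cfg$noise_sd_temp),
                        nrow(tm), ncol(tm))
    pr <- world_precip(cfg, pick$lon)
    if (cfg$noise_sd_precip > 0)
      pr <- pr + stats::rnorm(length(pr), 0, cfg$noise_sd_precip)
    pr <- pmax(pr, 0)
    out <- data.frame(station_id = sprintf("S%04d", seq_len(nrow(pick))),
                      lon = pick$lon, lat = pick$lat, alt = pick$value)
    colnames(tm) <- sprintf("t%02d", 1:12)
    out <- cbind(out, as.data.frame(tm))
    out$precip_ann <- pr
    rownames(out) <- NULL
    out
  })
}

#' Analytic (noise-free) index surfaces of the synthetic world
#'
#' Computes WI, CI and HI cell-wise from the same climate formulas that
#' drive the station generator, with noise forced to zero — the ground
#' truth against which kriging recovery is judged.
#'
#' @inheritParams generate_station_network
#' @return Named list of three [hydro_grid()]s: `wi`, `ci`, `hi`.
#' @export
generate_true_index_surfaces <- function(cfg, dem = generate_dem(cfg)) {
  stopifnot(inherits(cfg, "world_config"))
  tmpl <- hydro_grid(0, cfg$bbox, cfg$resolution)
  if (!same_grid_spec(tmpl, dem)) stop("dem does not match cfg bbox/resolution")
  cells <- grid_cells(dem)
  tm <- world_monthly_temp(cfg, cells$lat, cells$value)
  wi <- rowSums(pmax(tm - 5, 0))
  ci <- -rowSums(pmax(5 - tm, 0))
  hi <- humidity_index(pmax(world_precip(cfg, cells$lon), 0), wi)
  nr <- dim(tmpl)[1]
  mask <- is.na(cells$value)
  wi[mask] <- NA; ci[mask] <- NA; hi[mask] <- NA
  list(wi = hydro_grid(matrix(wi, nr, byrow = TRUE), cfg$bbox,
                       cfg$resolution, var = "WI"),
       ci = hydro_grid(matrix(ci, nr, byrow = TRUE), cfg$bbox,
                       cfg$resolution, var = "CI"),
       hi = hydro_grid(matrix(hi, nr, byrow = TRUE), cfg$bbox,
                       cfg$resolution, var = "HI"))
}

#' Virtual-species definition
#'
#' A unimodal Gaussian suitability kernel in (WI, HI) space with known
#' optima — the simplest niche consistent with the normal-curve assumption
#' behind the peak-width-at-half-height range.
#'
#' @param name species name.
#' @param wi_optimum,wi_tolerance optimum and kernel SD on the warmth-index
#'   axis (degree C-month, tolerance > 0).
#' @param hi_optimum,hi_tolerance optimum and kernel SD on the
#'   humidity-index axis (mm per degree C-month, tolerance > 0).
#' @param n_occurrences number of occurrence points to draw (>= 5, the
#'   minimum record count a species needs to enter the analysis).
#' @param seed integer seed.
#' @return A list of class `species_spec`.
#' @export
species_spec <- function(name, wi_optimum, wi_tolerance,
                         hi_optimum, hi_tolerance,
                         n_occurrences = 100, seed = 1) {
  if (wi_tolerance <= 0 || hi_tolerance <= 0) stop("tolerances must be > 0")
  if (n_occurrences < 5) stop("n_occurrences must be >= 5")
  structure(list(name = name, wi_optimum = wi_optimum,
                 wi_tolerance = wi_tolerance, hi_optimum = hi_optimum,
                 hi_tolerance = hi_tolerance,
                 n_occurrences = as.integer(n_occurrences), seed = seed),
            class = "species_spec")
}

#' Sample virtual-species occurrences
#'
#' Cells are drawn with replacement with probability proportional to
#' `exp(-0.5 ((WI - wi_opt)/wi_tol)^2 - 0.5 ((HI - hi_opt)/hi_tol)^2)` over
#' land (non-NA) cells; each draw is jittered uniformly within its cell.
#'
#' @param spec a [species_spec()].
#' @param wi,hi aligned [hydro_grid()]s of warmth and humidity index.
#' @return Data frame `species`, `lon`, `lat` with exactly
#'   `spec$n_occurrences` rows.
#' @export
generate_occurrences <- function(spec, wi, hi) {
  stopifnot(inherits(spec, "species_spec"))
  if (!same_grid_spec(wi, hi)) stop("wi and hi grids are not aligned")
  cells <- grid_cells(wi)
  hiv <- as.vector(t(hi$values))
  ok <- !is.na(cells$value) & !is.na(hiv)
  w <- rep(0, nrow(cells))
  w[ok] <- exp(-0.5 * ((cells$value[ok] - spec$wi_optimum) /
                         spec$wi_tolerance)^2 -
               0.5 * ((hiv[ok] - spec$hi_optimum) / spec$hi_tolerance)^2)
  if (!any(w > 0)) stop("no cell has positive sampling weight")
  res <- wi$resolution / 60
  with_seed(spec$seed, {
    idx <- sample.int(nrow(cells), spec$n_occurrences, replace = TRUE,
                      prob = w)
    data.frame(species = spec$name,
               lon = cells$lon[idx] + stats::runif(length(idx), -res / 2,
                                                   res / 2),
               lat = cells$lat[idx] + stats::runif(length(idx), -res / 2,
                                                   res / 2))
  })
}

#' Perturb climate layers into a scenario
#'
#' Applies a uniform warming and a fractional precipitation change: every
#' layer with role `"temperature"` is shifted by `+delta_t`, every layer
#' with role `"precipitation"` is scaled by `1 + delta_p_fraction`; other
#' layers and all nodata masks are untouched.
#'
#' @param stack an [env_stack()].
#' @param delta_t additive temperature change (degrees C).
#' @param delta_p_fraction fractional precipitation change (> -1).
#' @return A perturbed [env_stack()].
#' @seealso [scenario_config()] for regenerating index surfaces under a
#'   scenario at the climate-formula level.
#' @export
generate_scenario_climate <- function(stack, delta_t, delta_p_fraction) {
  stopifnot(inherits(stack, "env_stack"))
  if (delta_p_fraction <= -1) stop("delta_p_fraction must be > -1")
  for (nm in names(stack$layers)) {
    role <- stack$meta$role[stack$meta$name == nm]
    if (role == "temperature")
      stack$layers[[nm]]$values <- stack$layers[[nm]]$values + delta_t
    else if (role == "precipitation")
      stack$layers[[nm]]$values <-
        stack$layers[[nm]]$values * (1 + delta_p_fraction)
  }
  stack
}

#' Scenario variant of a world configuration
#'
#' Shifts the monthly temperature profile by `delta_t` and scales the
#' precipitation field by `1 + delta_p_fraction`, so index surfaces
#' regenerated from the returned config reflect the scenario climate.
#'
#' @inheritParams generate_scenario_climate
#' @param cfg a [world_config()].
#' @return A modified [world_config()].
#' @export
scenario_config <- function(cfg, delta_t, delta_p_fraction) {
  stopifnot(inherits(cfg, "world_config"))
  if (delta_p_fraction <= -1) stop("delta_p_fraction must be > -1")
  cfg$monthly_profile <- cfg$monthly_profile + delta_t
  cfg$precip_base <- cfg$precip_base * (1 + delta_p_fraction)
  cfg$precip_lon_gradient <- cfg$precip_lon_gradient * (1 + delta_p_fraction)
  cfg
}

#' Environmental layer stack
#'
#' Aligned single-band layers keyed by name, with a type (`numeric` or
#' `categorical`) and a role (`temperature`, `precipitation`, `derived`,
#' `other`) per layer.
#'
#' @param layers named list of aligned [hydro_grid()]s.
#' @param types named character vector, `"numeric"` or `"categorical"`;
#'   default all numeric.
#' @param roles named character vector of scenario roles; default
#'   `"other"`.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, types = NULL, roles = NULL) {
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("layers must be uniquely named")
  tmpl <- layers[[1]]
  for (l in layers) if (!same_grid_spec(tmpl, l))
    stop("all layers must share one grid spec")
  nm <- names(layers)
  t <- stats::setNames(rep("numeric", length(nm)), nm)
  if (!is.null(types)) t[names(types)] <- types
  r <- stats::setNames(rep("other", length(nm)), nm)
  if (!is.null(roles)) r[names(roles)] <- roles
  structure(list(layers = layers,
                 meta = data.frame(name = nm, type = unname(t[nm]),
                                   role = unname(r[nm]))),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("env_stack: %d layers on a %d x %d grid\n",
              length(x$layers), d[1], d[2]))
  print(x$meta)
  invisible(x)
}

#' Extract stack values at points
#'
#' @param stack an [env_stack()].
#' @param lon,lat point coordinates.
#' @return Data frame with one column per layer (containing-cell values).
#' @export
extract_env <- function(stack, lon, lat) {
  stopifnot(inherits(stack, "env_stack"))
  out <- lapply(stack$layers, grid_value_at, lon = lon, lat = lat)
  as.data.frame(out)
}

#' Build the synthetic environmental stack
#'
#' Deterministic layers derived from the world's climate formulas — warmth,
#' coldness and humidity indexes, annual mean temperature, annual
#' precipitation, elevation — plus a categorical soil-class layer (altitude
#' quartiles). Several layers are strongly collinear by construction
#' (WI/CI/annual mean temperature), which is what the variable-screening
#' stage is there to handle.
#'
#' @inheritParams generate_station_network
#' @return An [env_stack()] with layers `wi`, `ci`, `hi`, `tmean`,
#'   `precip`, `alt` and categorical `soil_class`.
#' @export
build_env_stack <- function(cfg, dem = generate_dem(cfg)) {
  surf <- generate_true_index_surfaces(cfg, dem)
  cells <- grid_cells(dem)
  tm <- world_monthly_temp(cfg, cells$lat, cells$value)
  nr <- dim(dem)[1]
  as_grid <- function(v, var) hydro_grid(matrix(v, nr, byrow = TRUE),
                                         cfg$bbox, cfg$resolution, var = var)
  tmean <- as_grid(rowMeans(tm), "tmean")
  precip <- as_grid(pmax(world_precip(cfg, cells$lon), 0), "precip")
  q <- stats::quantile(cells$value, c(0.25, 0.5, 0.75), na.rm = TRUE)
  soil <- as_grid(findInterval(cells$value, unique(q)) + 1, "soil_class")
  env_stack(
    list(wi = surf$wi, ci = surf$ci, hi = surf$hi, tmean = tmean,
         precip = precip, alt = dem, soil_class = soil),
    types = c(soil_class = "categorical"),
    roles = c(tmean = "temperature", precip = "precipitation",
              wi = "derived", ci = "derived", hi = "derived"))
}
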