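# half-away-from-zero rounding, the convention used in report tables
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Spatially thin occurrence records
#'
#' Keeps at most one occurrence per grid cell at the given resolution,
#' retaining the first record (input order) within each cell; output order
#' is stable. Cells are defined by the floor convention
#' `floor((coord - origin) / cellsize)` with the origin at the grid's
#' lower-left corner, so a point exactly on a shared edge belongs to the
#' cell whose south/west edge it is.
#'
#' @param occ data frame with columns `species`, `lon`, `lat`.
#' @param resolution cell size in arc-minutes (default 2.5).
#' @param origin `c(lon, lat)` of the thinning lattice origin.
#' @return Thinned data frame; the number of removed rows is attached as
#'   attribute `"n_removed"`. Thinning is per species.
#' @export
thin_occurrences <- function(occ, resolution = 2.5, origin = c(0, 0)) {
  if (!is.data.frame(occ) || nrow(occ) == 0) stop("occ must be non-empty")
  stopifnot(all(c("species", "lon", "lat") %in% names(occ)))
  res <- resolution / 60
  key <- paste(occ$species,
               floor((occ$lon - origin[1]) / res),
               floor((occ$lat - origin[2]) / res))
  keep <- !duplicated(key)
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Extract index values at occurrence locations
#'
#' Containing-cell lookup of WI/CI/HI surfaces at each occurrence;
#' occurrences falling on nodata cells (or outside the grids) are dropped
#' and counted.
#'
#' @param occ data frame with `species`, `lon`, `lat`.
#' @param surfaces named list of aligned [hydro_grid()]s `wi`, `ci`, `hi`.
#' @return Data frame `species`, `lon`, `lat`, `wi`, `ci`, `hi`; dropped
#'   row count attached as attribute `"n_dropped"`.
#' @export
extract_index_values <- function(occ, surfaces) {
  stopifnot(all(c("wi", "ci", "hi") %in% names(surfaces)))
  if (!same_grid_spec(surfaces$wi, surfaces$ci) ||
      !same_grid_spec(surfaces$wi, surfaces$hi))
    stop("index surfaces are not aligned")
  out <- data.frame(species = occ$species, lon = occ$lon, lat = occ$lat,
                    wi = grid_value_at(surfaces$wi, occ$lon, occ$lat),
                    ci = grid_value_at(surfaces$ci, occ$lon, occ$lat),
                    hi = grid_value_at(surfaces$hi, occ$lon, occ$lat))
  drop <- is.na(out$wi)
  if (all(drop)) stop("all occurrences fall on nodata cells")
  res <- out[!drop, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(drop)
  res
}

#' Peak width at half height
#'
#' Full width at half maximum of a normal curve with standard deviation
#' `s`: `2.354 * s`. About 78% of a normally distributed population falls
#' within half this width of the mean.
#'
#' @param s standard deviation (>= 0).
#' @return PWHH, same units as `s`.
#' @export
pwhh <- function(s) {
  if (any(s < 0)) stop("standard deviation must be >= 0")
  2.354 * s
}

#' Optimal thermal range from mean and SD
#'
#' The species' optimal warmth-index range `X - 0.5 PWH` to `X + 0.5 PWH`
#' with `PWH = 2.354 S`, i.e. the interval holding roughly 78% of its
#' occurrences under a normal thermal response.
#'
#' @param wi_mean mean warmth index `X`.
#' @param wi_sd standard deviation `S` (>= 0).
#' @return For scalar input, named numeric `c(lower, upper)` (unrounded);
#'   vector input gives a two-column matrix. Report tables round to one
#'   decimal (half away from zero).
#' @export
optimal_range <- function(wi_mean, wi_sd) {
  half <- pwhh(wi_sd) / 2
  out <- cbind(lower = wi_mean - half, upper = wi_mean + half)
  if (length(wi_mean) == 1) out[1, ] else out
}

#' Per-species index statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and full range of
#' each index per species, dropping species with fewer than `min_n`
#' records.
#'
#' @param values per-occurrence index table from [extract_index_values()].
#' @param min_n minimum record count for a species to be profiled
#'   (default 5).
#' @return Data frame with one row per retained species (`species`, `n`,
#'   and `*_min`, `*_max`, `*_mean`, `*_sd` for `wi`, `ci`, `hi`); excluded
#'   species names attached as attribute `"excluded"`. HI statistics use
#'   only records with defined HI.
#' @export
summarize_species <- function(values, min_n = 5) {
  if (!is.data.frame(values) || nrow(values) == 0)
    stop("values must be non-empty")
  sp <- split(values, values$species)
  n <- vapply(sp, nrow, integer(1))
  excluded <- names(sp)[n < min_n]
  sp <- sp[n >= min_n]
  stat <- function(d, col) {
    v <- d[[col]][is.finite(d[[col]])]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(min(v), max(v), mean(v), stats::sd(v))
  }
  rows <- lapply(sp, function(d) {
    s <- c(stat(d, "wi"), stat(d, "ci"), stat(d, "hi"))
    data.frame(species = d$species[1], n = nrow(d),
               wi_min = s[1], wi_max = s[2], wi_mean = s[3], wi_sd = s[4],
               ci_min = s[5], ci_max = s[6], ci_mean = s[7], ci_sd = s[8],
               hi_min = s[9], hi_max = s[10], hi_mean = s[11], hi_sd = s[12])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

mt_type_names <- c("Cold-Temperate Humid", "Mesothermal Xeric",
                   "Mesothermal Humid", "Warm-Temperate Hyperxeric",
                   "Warm-Temperate Xeric")

wi_bin_of <- function(wi) ifelse(wi < 20, NA_character_,
                          ifelse(wi < 60, "20~60",
                          ifelse(wi < 75, "60~75", "75~")))
hi_bin_of <- function(hi) ifelse(hi < 3.5, "<3.5",
                          ifelse(hi <= 7.5, "3.5~7.5", ">7.5"))

#' Five-type moisture-temperature classification
#'
#' Assigns each species a moisture-temperature distribution type from its
#' mean warmth and humidity indexes. WI bins `[20,60)`, `[60,75)` and
#' `[75, Inf)` are crossed with HI bins `< 3.5`, `[3.5, 7.5]` and `> 7.5`;
#' the five observed combinations are (1) Cold-Temperate Humid
#' (20-60, > 7.5), (2) Mesothermal Xeric (60-75, 3.5-7.5),
#' (3) Mesothermal Humid (60-75, > 7.5), (4) Warm-Temperate Hyperxeric
#' (>= 75, < 3.5) and (5) Warm-Temperate Xeric (>= 75, 3.5-7.5). WI below
#' 20 and bin combinations outside those five return `NA` with the raw bin
#' pair reported in the `"bins"` attribute.
#'
#' @param wi_mean,hi_mean species mean warmth and humidity indexes
#'   (vectors of equal length; `hi_mean` must be defined).
#' @return Integer vector of type codes 1-5 (`NA` = unclassified), with
#'   attributes `"bins"` (data frame of `wi_bin`, `hi_bin`) and
#'   `"type_names"`.
#' @export
classify_moisture_temperature <- function(wi_mean, hi_mean) {
  stopifnot(length(wi_mean) == length(hi_mean))
  if (any(is.na(hi_mean))) stop("hi_mean contains undefined values")
  wb <- wi_bin_of(wi_mean)
  hb <- hi_bin_of(hi_mean)
  code <- rep(NA_integer_, length(wi_mean))
  code[wb == "20~60" & hb == ">7.5"]   <- 1L
  code[wb == "60~75" & hb == "3.5~7.5"] <- 2L
  code[wb == "60~75" & hb == ">7.5"]   <- 3L
  code[wb == "75~"   & hb == "<3.5"]   <- 4L
  code[wb == "75~"   & hb == "3.5~7.5"] <- 5L
  attr(code, "bins") <- data.frame(wi_bin = wb, hi_bin = hb)
  attr(code, "type_names") <- mt_type_names
  code
}

#' Aridity zone from the humidity index
#'
#' @param hi_mean humidity index (defined, i.e. not `NA`).
#' @return Character vector: `"arid"` (< 3.5), `"semi-arid"` (3.5-5.5,
#'   lower-inclusive), `"semi-humid"` (5.5-7.5, lower-inclusive) or
#'   `"humid"` (>= 7.5).
#' @export
aridity_zone <- function(hi_mean) {
  if (any(is.na(hi_mean))) stop("hi_mean contains undefined values")
  c("arid", "semi-arid", "semi-humid", "humid")[
    findInterval(hi_mean, c(3.5, 5.5, 7.5)) + 1]
}

#' Species-count grid of the moisture-temperature classification
#'
#' Counts species per (WI bin, HI bin) cell, for species with mean WI of at
#' least 20, and adds row, column and grand totals.
#'
#' @param profiles data frame with `wi_mean` and `hi_mean` columns (e.g.
#'   from [species_profiles()] or [caragana_profiles()]).
#' @return 4 x 4 integer matrix: rows `20~60`, `60~75`, `75~`, `Total`;
#'   columns `<3.5`, `3.5~7.5`, `>7.5`, `Total`.
#' @export
build_classification_table <- function(profiles) {
  wi_levels <- c("20~60", "60~75", "75~")
  hi_levels <- c("<3.5", "3.5~7.5", ">7.5")
  m <- matrix(0L, 3, 3, dimnames = list(wi_levels, hi_levels))
  if (nrow(profiles)) {
    wb <- wi_bin_of(profiles$wi_mean)
    hb <- hi_bin_of(profiles$hi_mean)
    ok <- !is.na(wb) & !is.na(hb)
    t <- table(factor(wb[ok], wi_levels), factor(hb[ok], hi_levels))
    m[] <- as.integer(t)
  }
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  storage.mode(m) <- "integer"
  m
}

#' Species thermal profiles with optimal ranges and types
#'
#' The full per-species profiling stage: index statistics
#' ([summarize_species()]), peak-width-at-half-height optimal warmth range
#' ([optimal_range()]), moisture-temperature type
#' ([classify_moisture_temperature()]) and aridity zone
#' ([aridity_zone()]).
#'
#' @inheritParams summarize_species
#' @return Data frame of class `species_profile_table` with the summary
#'   columns plus `pwh`, `wi_opt_lo`, `wi_opt_hi`, `type` and
#'   `aridity_zone` (values unrounded; see `print` for the 1-decimal report
#'   view).
#' @export
species_profiles <- function(values, min_n = 5) {
  prof <- summarize_species(values, min_n = min_n)
  prof$pwh <- pwhh(prof$wi_sd)
  opt <- optimal_range(prof$wi_mean, prof$wi_sd)
  if (is.null(dim(opt))) opt <- matrix(opt, 1, 2)
  prof$wi_opt_lo <- opt[, 1]
  prof$wi_opt_hi <- opt[, 2]
  hi_ok <- !is.na(prof$hi_mean)
  prof$type <- NA_integer_
  prof$type[hi_ok] <- classify_moisture_temperature(prof$wi_mean[hi_ok],
                                                    prof$hi_mean[hi_ok])
  prof$aridity_zone <- NA_character_
  prof$aridity_zone[hi_ok] <- aridity_zone(prof$hi_mean[hi_ok])
  class(prof) <- c("species_profile_table", "data.frame")
  prof
}

#' @export
print.species_profile_table <- function(x, ...) {
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round_half_up, digits = 1)
  d$n <- x$n
  print(d, row.names = FALSE)
  ex <- attr(x, "excluded")
  if (length(ex))
    cat("excluded (n < min_n):", paste(ex, collapse = ", "), "\n")
  invisible(x)
}

#' Published Caragana moisture-temperature statistics
#'
#' Per-species warmth, coldness and humidity index statistics (record
#' count, full range, mean, SD, published optimal range and type code) for
#' the 44 Caragana species of China's Three Northern Regions, as bundled
#' with the package. Used as a worked input for the classification and
#' optimal-range operations.
#'
#' @return Data frame with 44 rows.
#' @export
caragana_profiles <- function() {
  path <- system.file("extdata", "caragana_thermal_profiles.csv",
                      package = "hydrotherm", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
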