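#' Regular geographic grid
#'
#' A lightweight container for a single-band raster on a regular WGS84
#' longitude/latitude grid. Values are stored as a matrix in row-major
#' north-to-south order (row 1 is the northernmost band of cells, column 1
#' the westernmost), cell registration is cell-center, and missing cells are
#' `NA`. Resolution is given in arc-minutes (2.5 by default, the resolution
#' used throughout the pipeline).
#'
#' @param values numeric matrix, or a single number recycled to the grid
#'   dimensions implied by `bbox` and `resolution`.
#' @param bbox numeric length-4 vector `c(lon_min, lon_max, lat_min, lat_max)`
#'   in decimal degrees.
#' @param resolution cell size in arc-minutes (> 0).
#' @param var optional variable tag (e.g. `"WI"`, `"HI"`, `"suitability"`).
#' @return An object of class `hydro_grid`.
#' @export
hydro_grid <- function(values, bbox, resolution = 2.5, var = NULL) {
  stopifnot(length(bbox) == 4, is.numeric(bbox))
  if (!(bbox[1] < bbox[2] && bbox[3] < bbox[4]))
    stop("invalid bbox: need lon_min < lon_max and lat_min < lat_max")
  if (resolution <= 0) stop("resolution must be > 0")
  res_deg <- resolution / 60
  nc <- round((bbox[2] - bbox[1]) / res_deg)
  nr <- round((bbox[4] - bbox[3]) / res_deg)
  if (nc < 1 || nr < 1) stop("bbox smaller than one cell")
  if (length(values) == 1) values <- matrix(values, nr, nc)
  if (!is.matrix(values)) stop("values must be a matrix or a single number")
  if (nrow(values) != nr || ncol(values) != nc)
    stop(sprintf("values are %d x %d but bbox/resolution imply %d x %d",
                 nrow(values), ncol(values), nr, nc))
  structure(list(values = values, bbox = as.numeric(bbox),
                 resolution = resolution, var = var),
            class = "hydro_grid")
}

#' @export
print.hydro_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("hydro_grid%s: %d rows x %d cols at %.4g' (%.6g deg)\n",
              if (is.null(x$var)) "" else paste0(" [", x$var, "]"),
              nrow(v), ncol(v), x$resolution, x$resolution / 60))
  cat(sprintf("  bbox: lon %.6g..%.6g, lat %.6g..%.6g\n",
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  cat(sprintf("  cells: %d (%d NA); range %s\n", length(v), sum(is.na(v)),
              if (all(is.na(v))) "all NA" else
                paste(signif(range(v, na.rm = TRUE), 6), collapse = " .. ")))
  invisible(x)
}

#' @export
dim.hydro_grid <- function(x) dim(x$values)

#' Cell-center coordinates of a grid
#'
#' @param grid a [hydro_grid()].
#' @return A data frame with one row per cell in storage order (row-major,
#'   north to south) and columns `row`, `col`, `lon`, `lat`, `value`.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "hydro_grid"))
  d <- dim(grid$values)
  res <- grid$resolution / 60
  lons <- grid$bbox[1] + (seq_len(d[2]) - 0.5) * res
  lats <- grid$bbox[4] - (seq_len(d[1]) - 0.5) * res
  data.frame(row = rep(seq_len(d[1]), each = d[2]),
             col = rep(seq_len(d[2]), times = d[1]),
             lon = rep(lons, times = d[1]),
             lat = rep(lats, each = d[2]),
             value = as.vector(t(grid$values)))
}

#' Locate points on a grid
#'
#' Maps longitude/latitude points to row/column indices using the floor
#' convention with the grid origin at the lower-left (south-west) corner:
#' a point exactly on a shared cell edge belongs to the cell whose
#' south/west edge it is. Points on the outer north/east boundary of the
#' bbox are kept in the outermost cell so the closed bbox is fully covered.
#'
#' @param grid a [hydro_grid()].
#' @param lon,lat numeric vectors of equal length.
#' @return A data frame with columns `row`, `col` (NA for points outside the
#'   bbox).
#' @export
grid_locate <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "hydro_grid"), length(lon) == length(lat))
  res <- grid$resolution / 60
  d <- dim(grid$values)
  inside <- lon >= grid$bbox[1] & lon <= grid$bbox[2] &
            lat >= grid$bbox[3] & lat <= grid$bbox[4]
  col <- floor((lon - grid$bbox[1]) / res) + 1
  row_s <- floor((lat - grid$bbox[3]) / res) + 1   # 1 = southernmost
  col <- pmin(col, d[2])      # closed east/north boundary
  row_s <- pmin(row_s, d[1])
  row <- d[1] - row_s + 1
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at points
#'
#' Nearest-cell (containing-cell) lookup.
#'
#' @inheritParams grid_locate
#' @return Numeric vector; NA for points outside the bbox or on NA cells.
#' @export
grid_value_at <- function(grid, lon, lat) {
  idx <- grid_locate(grid, lon, lat)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$row)
  out[ok] <- grid$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

same_grid_spec <- function(a, b, tol = 1e-9) {
  inherits(a, "hydro_grid") && inherits(b, "hydro_grid") &&
    all(abs(a$bbox - b$bbox) < tol) &&
    abs(a$resolution - b$resolution) < tol &&
    identical(dim(a$values), dim(b$values))
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster exchange in the ESRI ASCII grid (`.asc`)
#' format, cell-center registration, WGS84 longitude/latitude. Values are
#' written with 17 significant digits so a write/read round trip is
#' value-identical, and NA cells map to the `NODATA_value` (-9999).
#'
#' @param path file path.
#' @param grid a [hydro_grid()].
#' @param var optional variable tag attached on read.
#' @return `read_ascii_grid` returns a [hydro_grid()]; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "hydro_grid"))
  d <- dim(grid$values)
  res <- grid$resolution / 60
  hdr <- c(sprintf("ncols %d", d[2]),
           sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.17g", grid$bbox[1]),
           sprintf("yllcorner %.17g", grid$bbox[3]),
           sprintf("cellsize %.17g", res),
           "NODATA_value -9999")
  v <- grid$values
  v[is.na(v)] <- -9999
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, var = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header keys ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body has wrong number of values")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  bbox <- c(hdr$xllcorner, hdr$xllcorner + hdr$ncols * hdr$cellsize,
            hdr$yllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize)
  if (bbox[1] < -360 || bbox[2] > 360 || bbox[3] < -90 || bbox[4] > 90)
    stop("grid coordinates (x ", bbox[1], "..", bbox[2], ", y ", bbox[3],
         "..", bbox[4], ") lie outside the geographic lon/lat range; ",
         "projected coordinate systems are not supported")
  hydro_grid(m, bbox, resolution = hdr$cellsize * 60, var = var)
}
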