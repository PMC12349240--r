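#' Kriging configuration
#'
#' Settings for ordinary kriging of station indexes. By default the
#' variogram (exponential model) is fitted to the empirical semivariogram by
#' weighted least squares; fixed parameters can be supplied instead with
#' `fit = FALSE`, which is also how the linear-system oracle in the test
#' suite pins the model down.
#'
#' @param model variogram family: `"exponential"` (default), `"spherical"`
#'   or `"gaussian"`.
#' @param nugget,psill,range fixed variogram parameters (nugget >= 0,
#'   partial sill >= 0, range > 0); ignored when `fit = TRUE`.
#' @param fit logical; fit the variogram from the data (default `TRUE`).
#' @param max_neighbors number of nearest stations used per prediction
#'   point; `Inf` (default) uses all stations.
#' @param n_bins number of lag bins for the empirical variogram.
#' @return A list of class `kriging_config`.
#' @export
kriging_config <- function(model = c("exponential", "spherical", "gaussian"),
                           nugget = NULL, psill = NULL, range = NULL,
                           fit = TRUE, max_neighbors = Inf, n_bins = 15) {
  model <- match.arg(model)
  if (!fit) {
    if (is.null(nugget) || is.null(psill) || is.null(range))
      stop("with fit = FALSE, nugget, psill and range must all be given")
    if (nugget < 0 || psill < 0 || range <= 0)
      stop("need nugget >= 0, psill >= 0, range > 0")
  }
  structure(list(model = model, nugget = nugget, psill = psill,
                 range = range, fit = fit, max_neighbors = max_neighbors,
                 n_bins = n_bins), class = "kriging_config")
}

# semivariance of the three supported models
variogram_value <- function(h, model, nugget, psill, range) {
  g <- switch(model,
    exponential = psill * (1 - exp(-h / range)),
    gaussian    = psill * (1 - exp(-(h / range)^2)),
    spherical   = ifelse(h < range,
                         psill * (1.5 * h / range - 0.5 * (h / range)^3),
                         psill))
  ifelse(h > 0, nugget + g, 0)
}

#' Empirical semivariogram
#'
#' Bins squared pairwise half-differences by planar (degree-space) distance.
#'
#' @param x,y,z coordinates and values (equal-length numeric vectors).
#' @param n_bins number of lag bins.
#' @param cutoff maximum lag considered; default one third of the maximum
#'   pairwise distance.
#' @return Data frame with columns `dist` (bin mean lag), `gamma`
#'   (semivariance) and `n` (pair count); empty bins are dropped.
#' @export
empirical_variogram <- function(x, y, z, n_bins = 15, cutoff = NULL) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  d <- as.vector(stats::dist(cbind(x, y)))
  sv <- as.vector(stats::dist(z))^2 / 2
  if (is.null(cutoff)) cutoff <- max(d) / 3
  keep <- d <= cutoff & d > 0
  d <- d[keep]; sv <- sv[keep]
  if (!length(d)) stop("no station pairs within the variogram cutoff")
  bin <- pmin(floor(d / cutoff * n_bins) + 1, n_bins)
  out <- data.frame(
    dist  = tapply(d, bin, mean),
    gamma = tapply(sv, bin, mean),
    n     = as.vector(table(bin)))
  out[!is.na(out$gamma), , drop = FALSE]
}

# WLS fit (weights = pair counts) of a variogram model to the empirical one
fit_variogram_wls <- function(ev, model, z_var) {
  obj <- function(p) {
    g <- variogram_value(ev$dist, model, p[1], p[2], p[3])
    sum(ev$n * (ev$gamma - g)^2)
  }
  init <- c(nugget = 0, psill = max(z_var, 1e-12),
            range = max(ev$dist) / 2)
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(0, 0, max(ev$dist) * 1e-6))
  as.list(stats::setNames(fit$par, c("nugget", "psill", "range")))
}

#' Fit an ordinary kriging model to scattered stations
#'
#' Ordinary kriging: the best linear unbiased predictor whose weights sum to
#' one, built on a variogram either fitted from the data (weighted least
#' squares on the empirical semivariogram) or fixed in the
#' [kriging_config()]. Distances are planar Euclidean in degrees, which is
#' adequate for the sub-continental extents this package targets.
#'
#' @param x,y station coordinates (lon, lat in degrees).
#' @param z station values.
#' @param config a [kriging_config()].
#' @return An object of class `ok_fit` with `predict` and `print` methods.
#' @export
fit_ordinary_kriging <- function(x, y, z, config = kriging_config()) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  if (length(z) < 3) stop("ordinary kriging needs at least 3 stations")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("non-finite station coordinates or values")
  zv <- stats::var(z)
  if (config$fit) {
    if (zv < 1e-12 * max(1, mean(z)^2)) {
      pars <- list(nugget = 0, psill = 0, range = 1)
    } else {
      ev <- empirical_variogram(x, y, z, n_bins = config$n_bins)
      pars <- fit_variogram_wls(ev, config$model, zv)
    }
  } else {
    pars <- config[c("nugget", "psill", "range")]
  }
  structure(list(x = x, y = y, z = z, model = config$model,
                 nugget = pars$nugget, psill = pars$psill,
                 range = pars$range, max_neighbors = config$max_neighbors),
            class = "ok_fit")
}

#' @export
print.ok_fit <- function(x, ...) {
  cat(sprintf(
    "Ordinary kriging fit: %d stations\n  %s variogram: nugget %.6g, partial sill %.6g, range %.6g\n",
    length(x$z), x$model, x$nugget, x$psill, x$range))
  invisible(x)
}

# Solve the OK system for one target; returns prediction (and weights).
ok_solve_one <- function(fit, x0, y0, details = FALSE) {
  xs <- fit$x; ys <- fit$y; zs <- fit$z
  if (is.finite(fit$max_neighbors) && fit$max_neighbors < length(zs)) {
    d0 <- (xs - x0)^2 + (ys - y0)^2
    keep <- order(d0)[seq_len(fit$max_neighbors)]
    xs <- xs[keep]; ys <- ys[keep]; zs <- zs[keep]
  }
  n <- length(zs)
  if (fit$nugget + fit$psill <= 1e-12) {
    # flat variogram (constant field): every weighting is equivalent,
    # return the station mean
    w <- rep(1 / n, n)
    pred <- mean(zs)
    if (details) return(list(pred = pred, weights = w))
    return(pred)
  }
  h <- as.matrix(stats::dist(cbind(xs, ys)))
  G <- variogram_value(h, fit$model, fit$nugget, fit$psill, fit$range)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  h0 <- sqrt((xs - x0)^2 + (ys - y0)^2)
  b <- c(variogram_value(h0, fit$model, fit$nugget, fit$psill, fit$range), 1)
  sol <- tryCatch(solve(A, b), error = function(e)
    stop("singular kriging system near (", signif(x0, 6), ", ",
         signif(y0, 6), "): ", conditionMessage(e), call. = FALSE))
  w <- sol[seq_len(n)]
  pred <- sum(w * zs)
  if (details) list(pred = pred, weights = w) else pred
}

#' Predict from an ordinary kriging fit
#'
#' @param object an `ok_fit`.
#' @param x,y prediction coordinates.
#' @param details if `TRUE`, also return the kriging weights per point.
#' @param ... unused.
#' @return Numeric vector of predictions, or (with `details = TRUE`) a list
#'   with `pred` and a `weights` list.
#' @export
predict.ok_fit <- function(object, x, y, details = FALSE, ...) {
  stopifnot(length(x) == length(y))
  if (!details)
    return(vapply(seq_along(x), function(i)
      ok_solve_one(object, x[i], y[i]), numeric(1)))
  res <- lapply(seq_along(x), function(i)
    ok_solve_one(object, x[i], y[i], details = TRUE))
  list(pred = vapply(res, `[[`, numeric(1), "pred"),
       weights = lapply(res, `[[`, "weights"))
}

#' Interpolate station indexes to a grid by ordinary kriging
#'
#' @param stations data frame with `lon`, `lat` and the value column.
#' @param bbox grid bounding box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param resolution cell size in arc-minutes.
#' @param value_col name of the value column (e.g. `"wi"`).
#' @param config a [kriging_config()].
#' @param mask optional [hydro_grid()] on the same spec; its NA cells are
#'   carried over as nodata.
#' @return A [hydro_grid()] with the fitted `ok_fit` attached as attribute
#'   `"fit"`.
#' @export
krige_index_surface <- function(stations, bbox, resolution = 2.5,
                                value_col = "wi",
                                config = kriging_config(), mask = NULL) {
  if (!value_col %in% names(stations))
    stop("stations has no column '", value_col, "'")
  keep <- is.finite(stations[[value_col]])
  st <- stations[keep, , drop = FALSE]
  fit <- fit_ordinary_kriging(st$lon, st$lat, st[[value_col]], config)
  tmpl <- hydro_grid(0, bbox, resolution, var = value_col)
  cells <- grid_cells(tmpl)
  todo <- rep(TRUE, nrow(cells))
  if (!is.null(mask)) {
    if (!same_grid_spec(tmpl, mask)) stop("mask grid spec mismatch")
    todo <- !is.na(as.vector(t(mask$values)))
  }
  vals <- rep(NA_real_, nrow(cells))
  vals[todo] <- predict(fit, cells$lon[todo], cells$lat[todo])
  m <- matrix(vals, nrow = dim(tmpl)[1], byrow = TRUE)
  out <- hydro_grid(m, bbox, resolution, var = value_col)
  attr(out, "fit") <- fit
  out
}

#' Leave-one-out cross-validation of kriging
#'
#' Predicts each station from all the others (variogram fixed at the
#' full-data fit) and reports the root-mean-square error.
#'
#' @inheritParams krige_index_surface
#' @return A list with `rmse` and a per-station `residuals` data frame.
#' @export
crossvalidate_kriging <- function(stations, value_col = "wi",
                                  config = kriging_config()) {
  if (!value_col %in% names(stations))
    stop("stations has no column '", value_col, "'")
  st <- stations[is.finite(stations[[value_col]]), , drop = FALSE]
  n <- nrow(st)
  if (n < 4) stop("leave-one-out cross-validation needs at least 4 stations")
  full <- fit_ordinary_kriging(st$lon, st$lat, st[[value_col]], config)
  pred <- vapply(seq_len(n), function(i) {
    f <- full
    f$x <- full$x[-i]; f$y <- full$y[-i]; f$z <- full$z[-i]
    ok_solve_one(f, st$lon[i], st$lat[i])
  }, numeric(1))
  res <- st[[value_col]] - pred
  list(rmse = sqrt(mean(res^2)),
       residuals = data.frame(lon = st$lon, lat = st$lat,
                              observed = st[[value_col]],
                              predicted = pred, residual = res))
}
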