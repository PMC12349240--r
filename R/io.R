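#' Read occurrence records from CSV
#'
#' Expects mandatory columns `species`, `lon`, `lat` (extra columns are
#' preserved). Rows with unparseable coordinates or coordinates outside
#' \[-180, 180\] x \[-90, 90\] are rejected into a sidecar report; exact
#' duplicate rows are dropped and counted.
#'
#' @param path CSV file path.
#' @return Data frame of valid, de-duplicated occurrences with attributes
#'   `"rejected"` (data frame of rejected rows with a `reason` column) and
#'   `"n_duplicates"`.
#' @export
read_occurrences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("species", "lon", "lat"), names(d))
  if (length(miss))
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  lon <- suppressWarnings(as.numeric(d$lon))
  lat <- suppressWarnings(as.numeric(d$lat))
  bad <- is.na(lon) | is.na(lat) | abs(lon) > 180 | abs(lat) > 90
  rejected <- d[bad, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- ifelse(is.na(lon[bad]) | is.na(lat[bad]),
                              "unparseable coordinate",
                              "coordinate out of bounds")
  d <- d[!bad, , drop = FALSE]
  d$lon <- lon[!bad]; d$lat <- lat[!bad]
  dup <- duplicated(d)
  out <- d[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Write occurrences / stations to CSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_defaults <- function() {
  list(resolution = 2.5, min_n = 5,
       n_per_set = 8000, n_pa_sets = 2, n_runs = 10,
       tss_min = 0.55, train_frac = 0.8,
       r_max = 0.7, vif_max = 5,
       breaks = c(0.2, 0.4, 0.6), presence_threshold = 0.2,
       learners = c("glm", "rf", "xgb", "maxent_like"),
       variogram = "exponential", seed = 1)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML or JSON file (by extension) or a plain list, injects the
#' package defaults (2.5 arc-minute resolution, 8000 x 2 pseudo-absences,
#' 10 runs, TSS cutoff 0.55, suitability breaks 0.2/0.4/0.6, minimum 5
#' records per species), and rejects unknown keys and out-of-range values,
#' naming the offending key.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return The completed configuration list (class `hydrotherm_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config)
  chk <- function(ok, key, what)
    if (!ok) stop("config key '", key, "': ", what)
  chk(out$resolution > 0, "resolution", "must be > 0")
  chk(out$min_n >= 1, "min_n", "must be >= 1")
  chk(out$n_per_set >= 1, "n_per_set", "must be >= 1")
  chk(out$n_pa_sets >= 1, "n_pa_sets", "must be >= 1")
  chk(out$n_runs >= 1, "n_runs", "must be >= 1")
  chk(out$tss_min >= -1 && out$tss_min <= 1, "tss_min",
      "must lie in [-1, 1]")
  chk(out$train_frac > 0 && out$train_frac < 1, "train_frac",
      "must lie in (0, 1)")
  chk(out$r_max > 0 && out$r_max <= 1, "r_max", "must lie in (0, 1]")
  chk(out$vif_max > 1, "vif_max", "must be > 1")
  chk(length(out$breaks) == 3 && all(diff(out$breaks) > 0) &&
        all(out$breaks > 0 & out$breaks < 1), "breaks",
      "must be 3 strictly increasing values in (0, 1)")
  chk(out$presence_threshold >= 0 && out$presence_threshold < 1,
      "presence_threshold", "must lie in [0, 1)")
  chk(out$variogram %in% c("exponential", "spherical", "gaussian"),
      "variogram", "must be exponential, spherical or gaussian")
  class(out) <- c("hydrotherm_config", "list")
  out
}

#' Build a run manifest
#'
#' A machine-readable record of a pipeline run: package version,
#' configuration (with an md5 digest), per-stage seeds and any
#' stage-specific decisions, so a run can be replayed bit-identically.
#'
#' @param config a validated configuration list.
#' @param seeds named list of per-stage seeds.
#' @param stages named list of stage records (decision logs, counts,
#'   timings).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds = list(), stages = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  structure(list(
    tool = "hydrotherm",
    version = as.character(utils::packageVersion("hydrotherm")),
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp)),
    seeds = seeds, stages = stages),
    class = "run_manifest")
}

#' Write / read a run manifest as JSON
#'
#' @param manifest a `run_manifest` (or any list).
#' @param path JSON path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the parsed list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::fromJSON(path,
                                                   simplifyVector = TRUE)
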