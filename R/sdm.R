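#' Collinearity screening of environmental variables
#'
#' Two greedy passes at the sample locations. Pass 1 (Pearson): while any
#' pair of numeric variables has `|r| >= r_max`, take the worst pair and
#' drop its member with the larger mean absolute correlation against all
#' remaining variables. Pass 2 (VIF): iteratively drop the variable with
#' the largest variance inflation factor until all VIF < `vif_max`.
#' Categorical layers bypass both passes and are always retained. Every
#' drop is logged with the statistic that caused it.
#'
#' @param stack an [env_stack()].
#' @param samples data frame of `lon`, `lat` sample locations (>= 30).
#' @param r_max pairwise correlation threshold (default 0.7).
#' @param vif_max VIF threshold (default 5).
#' @return List with `selected` (character vector of retained layer names)
#'   and `log` (data frame of drops: `pass`, `dropped`, `statistic`).
#' @export
screen_variables <- function(stack, samples, r_max = 0.7, vif_max = 5) {
  stopifnot(inherits(stack, "env_stack"))
  if (nrow(samples) < 30) stop("need at least 30 sample locations")
  num <- stack$meta$name[stack$meta$type == "numeric"]
  cat_ <- stack$meta$name[stack$meta$type == "categorical"]
  if (length(num) < 2) stop("need at least 2 numeric variables")
  V <- extract_env(stack, samples$lon, samples$lat)[, num, drop = FALSE]
  V <- V[stats::complete.cases(V), , drop = FALSE]
  log <- data.frame(pass = character(), dropped = character(),
                    statistic = numeric())
  keep <- names(V)[vapply(V, function(x) stats::sd(x) > 0, logical(1))]
  # pass 1: pairwise Pearson
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(V[keep]))
    diag(cm) <- 0
    if (max(cm) < r_max) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_r <- rowMeans(cm[pair, , drop = FALSE])
    drop <- pair[which.max(mean_r)]
    log <- rbind(log, data.frame(pass = "pearson", dropped = drop,
                                 statistic = max(cm)))
    keep <- setdiff(keep, drop)
  }
  # pass 2: VIF from the inverse correlation matrix; an exactly singular
  # correlation matrix means infinite VIF — the variable loading heaviest
  # on the null space is dropped
  repeat {
    if (length(keep) < 2) break
    C <- stats::cor(V[keep])
    vif <- tryCatch(diag(solve(C)), error = function(e) NULL)
    if (is.null(vif)) {
      ev <- eigen(C, symmetric = TRUE)
      load <- abs(ev$vectors[, length(keep)])
      drop <- keep[which.max(load)]
      log <- rbind(log, data.frame(pass = "vif", dropped = drop,
                                   statistic = Inf))
      keep <- setdiff(keep, drop)
      next
    }
    if (max(vif) < vif_max) break
    drop <- keep[which.max(vif)]
    log <- rbind(log, data.frame(pass = "vif", dropped = drop,
                                 statistic = max(vif)))
    keep <- setdiff(keep, drop)
  }
  if (length(keep) < 2)
    warning("fewer than 2 numeric variables survived screening")
  list(selected = c(keep, cat_), log = log)
}

#' Sample pseudo-absence point sets
#'
#' Uniform random cells without replacement from the unmasked cells that do
#' not contain a presence; sets are drawn independently (one seeded stream
#' per set). If fewer eligible cells than `n_per_set` exist the set is
#' capped at that count with a warning.
#'
#' @param stack an [env_stack()] (the nodata mask of its first layer
#'   defines eligibility).
#' @param presences data frame of `lon`, `lat` presence points.
#' @param n_per_set points per set (default 8000).
#' @param n_sets number of independent sets (default 2).
#' @param seed integer seed.
#' @return List of `n_sets` data frames with columns `lon`, `lat`.
#' @export
sample_pseudo_absences <- function(stack, presences, n_per_set = 8000,
                                   n_sets = 2, seed = 1) {
  stopifnot(inherits(stack, "env_stack"))
  g <- stack$layers[[1]]
  cells <- grid_cells(g)
  pres_idx <- grid_locate(g, presences$lon, presences$lat)
  pres_key <- unique(stats::na.omit((pres_idx$row - 1) * dim(g)[2] +
                                      pres_idx$col))
  cell_key <- (cells$row - 1) * dim(g)[2] + cells$col
  elig <- which(!is.na(cells$value) & !(cell_key %in% pres_key))
  if (!length(elig)) stop("no eligible pseudo-absence cells")
  n_take <- min(n_per_set, length(elig))
  if (n_take < n_per_set)
    warning(sprintf("only %d eligible cells; n_per_set reduced from %d",
                    n_take, n_per_set))
  lapply(seq_len(n_sets), function(s)
    with_seed(seed + 131071 * s, {
      pick <- elig[sample.int(length(elig), n_take)]
      data.frame(lon = cells$lon[pick], lat = cells$lat[pick])
    }))
}

#' TSS-weighted ensemble of fitted models
#'
#' Retains the members whose held-out TSS exceeds `tss_min` and combines
#' their predictions as a convex combination with weights proportional to
#' raw TSS.
#'
#' @param models list of `fitted_sdm` objects.
#' @param tss_min retention cutoff on held-out TSS (default 0.55, strictly
#'   greater-than).
#' @return An object of class `sdm_ensemble` with `predict` and `print`
#'   methods; also carries the pooled held-out evaluation of the retained
#'   members (`evaluation`).
#' @export
build_ensemble <- function(models, tss_min = 0.55) {
  tss <- vapply(models, function(m) m$evaluation$tss, numeric(1))
  keep <- which(tss > tss_min)
  if (!length(keep))
    stop(sprintf("no model passes tss_min = %.2f (max observed TSS %.3f)",
                 tss_min, max(tss)))
  w <- tss[keep] / sum(tss[keep])
  pooled_scores <- unlist(lapply(models[keep], `[[`, "test_scores"))
  pooled_labels <- unlist(lapply(models[keep], `[[`, "test_labels"))
  structure(list(members = models[keep], weights = w, tss_min = tss_min,
                 evaluation = evaluate_predictions(pooled_scores,
                                                   pooled_labels)),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("sdm_ensemble: %d members (TSS > %.2f), weights by raw TSS\n",
              length(x$members), x$tss_min))
  for (i in seq_along(x$members))
    cat(sprintf("  %-12s w = %.3f  TSS %.3f  AUC %.3f\n",
                x$members[[i]]$learner_id, x$weights[i],
                x$members[[i]]$evaluation$tss,
                x$members[[i]]$evaluation$auc))
  cat("pooled held-out: ")
  print(x$evaluation)
  invisible(x)
}

#' Predict ensemble suitability for a data frame of predictors
#'
#' @param object an `sdm_ensemble`.
#' @param newdata data frame with the predictor columns the members were
#'   trained on.
#' @param ... unused.
#' @return Numeric suitability scores in \[0, 1\].
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members,
                  function(m) m$predict(m$fit, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  as.numeric(preds %*% object$weights)
}

#' Project an ensemble onto an environmental stack
#'
#' Member predictions are computed cell-wise on the scenario stack and
#' combined with the frozen ensemble weights; masked cells stay nodata.
#'
#' @param ensemble an `sdm_ensemble`.
#' @param stack an [env_stack()] holding every selected variable.
#' @param vars character vector of the predictor names used in training.
#' @return A suitability [hydro_grid()] in \[0, 1\].
#' @export
project_ensemble <- function(ensemble, stack, vars) {
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss))
    stop("scenario stack is missing variables: ",
         paste(miss, collapse = ", "))
  g <- stack$layers[[1]]
  cells <- grid_cells(g)
  X <- extract_env(stack, cells$lon, cells$lat)[, vars, drop = FALSE]
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok))
    out[ok] <- predict(ensemble, X[ok, , drop = FALSE])
  hydro_grid(matrix(out, dim(g)[1], byrow = TRUE), g$bbox, g$resolution,
             var = "suitability")
}

#' Run the full ensemble-SDM procedure
#'
#' Variable screening, pseudo-absence sampling, repeated seeded 80/20
#' fits of every learner on every pseudo-absence set, TSS-filtered
#' weighted-mean ensemble, and projection onto the training stack and any
#' scenario stacks. All randomness flows from `seed`; rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param occurrences data frame of presence points (`lon`, `lat`).
#' @param stack training-period [env_stack()].
#' @param scenarios named list of scenario [env_stack()]s (may be empty).
#' @param learners character vector of learner ids (default
#'   `c("glm", "rf", "xgb", "maxent_like")`).
#' @param n_runs repeated fits per learner and pseudo-absence set
#'   (default 10).
#' @param n_pa_sets,n_per_set pseudo-absence sets and points per set
#'   (defaults 2 and 8000).
#' @param tss_min ensemble retention cutoff (default 0.55).
#' @param train_frac training fraction per run (default 0.8).
#' @param r_max,vif_max screening thresholds (defaults 0.7 and 5).
#' @param seed root integer seed.
#' @param registry learner registry (default [default_learners()]).
#' @return An object of class `sdm_result`: `selected` variables and
#'   screening log, `models` (all `fitted_sdm`s), `report` (one row per
#'   fit), `ensemble`, `projections` (named list of suitability grids,
#'   `"current"` first), and a `manifest` list recording every seed and
#'   setting.
#' @export
run_sdm_pipeline <- function(occurrences, stack, scenarios = list(),
                             learners = c("glm", "rf", "xgb",
                                          "maxent_like"),
                             n_runs = 10, n_pa_sets = 2, n_per_set = 8000,
                             tss_min = 0.55, train_frac = 0.8,
                             r_max = 0.7, vif_max = 5, seed = 1,
                             registry = default_learners()) {
  stopifnot(inherits(stack, "env_stack"))
  # screening sample: presences plus a seeded background draw
  g <- stack$layers[[1]]
  cells <- grid_cells(g)
  land <- which(!is.na(cells$value))
  bg <- with_seed(seed + 17, land[sample.int(length(land),
                                             min(1000, length(land)))])
  scr_pts <- rbind(occurrences[, c("lon", "lat")],
                   data.frame(lon = cells$lon[bg], lat = cells$lat[bg]))
  scr <- screen_variables(stack, scr_pts, r_max = r_max, vif_max = vif_max)
  pa_sets <- sample_pseudo_absences(stack, occurrences,
                                    n_per_set = n_per_set,
                                    n_sets = n_pa_sets, seed = seed)
  X_pres <- extract_env(stack, occurrences$lon,
                        occurrences$lat)[, scr$selected, drop = FALSE]
  models <- list()
  report <- NULL
  for (pa in seq_len(n_pa_sets)) {
    X_abs <- extract_env(stack, pa_sets[[pa]]$lon,
                         pa_sets[[pa]]$lat)[, scr$selected, drop = FALSE]
    X <- rbind(X_pres, X_abs)
    y <- c(rep(1L, nrow(X_pres)), rep(0L, nrow(X_abs)))
    ok <- stats::complete.cases(X)
    X <- X[ok, , drop = FALSE]; yk <- y[ok]
    for (li in seq_along(learners)) {
      for (run in seq_len(n_runs)) {
        fit_seed <- (seed + 1009L * li + 10007L * pa + 100003L * run) %%
          2147483647L
        m <- fit_single_model(learners[li], X, yk, seed = fit_seed,
                              train_frac = train_frac, registry = registry)
        m$pa_set <- pa; m$run <- run
        models[[length(models) + 1]] <- m
        report <- rbind(report, data.frame(
          learner = learners[li], pa_set = pa, run = run, seed = fit_seed,
          auc = m$evaluation$auc, tss = m$evaluation$tss,
          threshold = m$evaluation$optimal_threshold))
      }
    }
  }
  report$retained <- report$tss > tss_min
  ens <- build_ensemble(models, tss_min = tss_min)
  projections <- c(list(current = project_ensemble(ens, stack,
                                                   scr$selected)),
                   lapply(scenarios, project_ensemble, ensemble = ens,
                          vars = scr$selected))
  manifest <- list(
    seed = seed, learners = learners, n_runs = n_runs,
    n_pa_sets = n_pa_sets, n_per_set = n_per_set, tss_min = tss_min,
    train_frac = train_frac, r_max = r_max, vif_max = vif_max,
    selected = scr$selected,
    screening_log = scr$log,
    pa_set_sizes = vapply(pa_sets, nrow, integer(1)),
    fits = report)
  structure(list(selected = scr$selected, screening_log = scr$log,
                 pa_sets = pa_sets, models = models, report = report,
                 ensemble = ens, projections = projections,
                 manifest = manifest),
            class = "sdm_result")
}

#' @export
print.sdm_result <- function(x, ...) {
  cat(sprintf(
    "sdm_result: %d fits (%s x %d PA sets x %d runs), %d retained\n",
    nrow(x$report), paste(unique(x$report$learner), collapse = "/"),
    length(unique(x$report$pa_set)), max(x$report$run),
    sum(x$report$retained)))
  cat("selected variables:", paste(x$selected, collapse = ", "), "\n")
  print(x$ensemble)
  invisible(x)
}
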