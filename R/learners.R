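# --- design-matrix plumbing -------------------------------------------------
# Characters become factors with levels frozen at training time so the
# scenario/projection design expands to identical columns.

freeze_levels <- function(X) {
  lev <- list()
  for (nm in names(X)) {
    if (is.character(X[[nm]]) || is.factor(X[[nm]])) {
      X[[nm]] <- factor(X[[nm]])
      lev[[nm]] <- levels(X[[nm]])
    }
  }
  list(X = X, levels = lev)
}

apply_levels <- function(X, lev) {
  for (nm in names(lev)) X[[nm]] <- factor(X[[nm]], levels = lev[[nm]])
  X
}

one_hot <- function(X) {
  fac <- Filter(is.factor, X)
  if (length(fac))
    stats::model.matrix(~ . - 1, data = X,
                        contrasts.arg = lapply(fac, stats::contrasts,
                                               contrasts = FALSE))
  else stats::model.matrix(~ . - 1, data = X)
}

# hinge features pmax(x - knot, 0) at training-quantile knots, per numeric var
hinge_features <- function(X, knots) {
  out <- list()
  for (nm in names(knots)) {
    for (k in seq_along(knots[[nm]])) {
      out[[paste0(nm, "_h", k)]] <- pmax(X[[nm]] - knots[[nm]][k], 0)
    }
    out[[paste0(nm, "_sq")]] <- X[[nm]]^2
  }
  as.data.frame(out)
}

#' Base-learner registry
#'
#' The pluggable pool of presence/pseudo-absence classifiers used by the
#' ensemble procedure. Each entry has a `fit(X, y)` and a
#' `predict(model, X)` returning suitability scores in \[0, 1\]:
#' \describe{
#'   \item{glm}{logistic regression (binomial GLM);}
#'   \item{rf}{random forest (classification, 500 trees);}
#'   \item{xgb}{gradient-boosted trees (logistic objective, 100 rounds,
#'     single-threaded for reproducibility);}
#'   \item{maxent_like}{L1-regularised logistic regression on linear,
#'     quadratic and hinge features, a MaxEnt-style feature expansion.}
#' }
#' All learners run with their default settings; randomness is controlled
#' by the caller seeding R's RNG before `fit`.
#'
#' @return Named list of learner definitions.
#' @export
default_learners <- function() {
  list(
    glm = list(
      fit = function(X, y) {
        fr <- freeze_levels(X)
        d <- cbind(.y = y, fr$X)
        m <- suppressWarnings(stats::glm(.y ~ ., data = d,
                                         family = stats::binomial()))
        list(model = m, levels = fr$levels)
      },
      predict = function(fit, X) {
        X <- apply_levels(X, fit$levels)
        as.numeric(stats::predict(fit$model, newdata = X,
                                  type = "response"))
      }),
    rf = list(
      fit = function(X, y) {
        fr <- freeze_levels(X)
        m <- randomForest::randomForest(fr$X, factor(y, levels = c(0, 1)),
                                        ntree = 500)
        list(model = m, levels = fr$levels)
      },
      predict = function(fit, X) {
        X <- apply_levels(X, fit$levels)
        as.numeric(predict(fit$model, newdata = X, type = "prob")[, "1"])
      }),
    xgb = list(
      fit = function(X, y) {
        fr <- freeze_levels(X)
        mm <- one_hot(fr$X)
        m <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", nthread = 1,
                        seed = sample.int(.Machine$integer.max, 1)),
          data = xgboost::xgb.DMatrix(mm, label = y), nrounds = 100,
          verbose = 0)
        list(model = m, levels = fr$levels, cols = colnames(mm))
      },
      predict = function(fit, X) {
        mm <- one_hot(apply_levels(X, fit$levels))
        mm <- mm[, fit$cols, drop = FALSE]
        as.numeric(predict(fit$model, newdata = xgboost::xgb.DMatrix(mm)))
      }),
    maxent_like = list(
      fit = function(X, y) {
        fr <- freeze_levels(X)
        num <- names(fr$X)[vapply(fr$X, is.numeric, logical(1))]
        knots <- lapply(fr$X[num], stats::quantile,
                        probs = c(0.25, 0.5, 0.75), names = FALSE)
        mm <- one_hot(cbind(fr$X, hinge_features(fr$X, knots)))
        m <- glmnet::glmnet(mm, y, family = "binomial", alpha = 1)
        # deterministic lambda choice: AIC along the regularisation path
        dev <- (1 - m$dev.ratio) * m$nulldev
        lam <- m$lambda[which.min(dev + 2 * m$df)]
        list(model = m, lambda = lam, levels = fr$levels, knots = knots,
             cols = colnames(mm))
      },
      predict = function(fit, X) {
        X <- apply_levels(X, fit$levels)
        mm <- one_hot(cbind(X, hinge_features(X, fit$knots)))
        mm <- mm[, fit$cols, drop = FALSE]
        as.numeric(predict(fit$model, newx = mm, s = fit$lambda,
                           type = "response"))
      })
  )
}

# stratified train indices: frac of each class, at least one per class held out
stratified_split <- function(y, frac) {
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  n1 <- max(1, min(length(idx1) - 1, round(frac * length(idx1))))
  n0 <- max(1, min(length(idx0) - 1, round(frac * length(idx0))))
  c(sample(idx1, n1), sample(idx0, n0))
}

#' Fit and evaluate one base learner
#'
#' Draws a seeded stratified 80/20 train/validation split, trains the
#' learner on the training rows only, and evaluates AUC/TSS on the held-out
#' rows.
#'
#' @param learner_id name of a learner in `registry`.
#' @param X data frame of predictors (presences and pseudo-absences).
#' @param y 0/1 labels.
#' @param seed integer seed for the split and any learner randomness.
#' @param train_frac training fraction (default 0.8).
#' @param registry learner registry, [default_learners()] by default.
#' @return An object of class `fitted_sdm`: `learner_id`, `seed`, `fit`,
#'   `evaluation` (a `model_evaluation`), `test_scores`, `test_labels`.
#' @export
fit_single_model <- function(learner_id, X, y, seed, train_frac = 0.8,
                             registry = default_learners()) {
  if (!learner_id %in% names(registry))
    stop("unknown learner '", learner_id, "'")
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stop("training data has a single class")
  lrn <- registry[[learner_id]]
  with_seed(seed, {
    tr <- stratified_split(y, train_frac)
    fit <- lrn$fit(X[tr, , drop = FALSE], y[tr])
    te <- setdiff(seq_along(y), tr)
    sc <- lrn$predict(fit, X[te, , drop = FALSE])
    ev <- evaluate_predictions(sc, y[te])
    structure(list(learner_id = learner_id, seed = seed, fit = fit,
                   predict = lrn$predict, evaluation = ev,
                   test_scores = sc, test_labels = y[te]),
              class = "fitted_sdm")
  })
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("fitted_sdm [%s, seed %d]: ", x$learner_id, x$seed))
  print(x$evaluation)
  invisible(x)
}
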