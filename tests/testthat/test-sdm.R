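make_stack <- function(layers_list, types = NULL) {
  bbox <- c(100, 101, 35, 36)
  gl <- lapply(layers_list, function(m) hydro_grid(m, bbox, 6))
  env_stack(gl, types = types)
}

rand_layers <- function(n_layers, seed, nr = 10, nc = 10) {
  set.seed(seed)
  stats::setNames(lapply(seq_len(n_layers),
                         function(i) matrix(rnorm(nr * nc), nr, nc)),
                  paste0("x", seq_len(n_layers)))
}

test_that("identical layers collapse to one under Pearson screening", {
  m <- matrix(rnorm(100), 10, 10)
  stack <- make_stack(list(a = m, b = m, c = matrix(rnorm(100), 10, 10)))
  pts <- grid_cells(stack$layers$a)[, c("lon", "lat")]
  scr <- screen_variables(stack, pts)
  expect_length(intersect(scr$selected, c("a", "b")), 1)
  expect_true("c" %in% scr$selected)
  expect_equal(scr$log$pass[1], "pearson")
})

test_that("independent layers all survive screening", {
  stack <- make_stack(rand_layers(5, seed = 41))
  pts <- grid_cells(stack$layers$x1)[, c("lon", "lat")]
  scr <- screen_variables(stack, pts)
  expect_setequal(scr$selected, paste0("x", 1:5))
  expect_equal(nrow(scr$log), 0)
})

test_that("an exact linear combination is removed by the VIF pass", {
  ls <- rand_layers(2, seed = 42)
  # x3 = x1 + x2: pairwise r stays moderate but VIF is infinite
  ls$x3 <- ls$x1 + ls$x2
  stack <- make_stack(ls)
  pts <- grid_cells(stack$layers$x1)[, c("lon", "lat")]
  scr <- screen_variables(stack, pts)
  expect_lt(length(scr$selected), 3)
  # post-hoc: every retained variable has brute-force VIF < 5
  V <- extract_env(stack, pts$lon, pts$lat)[, scr$selected, drop = FALSE]
  expect_true(all(vif_oracle(V) < 5))
})

test_that("categorical layers bypass screening and are retained", {
  ls <- rand_layers(2, seed = 43)
  ls$soil <- matrix(sample(1:3, 100, TRUE), 10, 10)
  stack <- make_stack(ls, types = c(soil = "categorical"))
  pts <- grid_cells(stack$layers$x1)[, c("lon", "lat")]
  scr <- screen_variables(stack, pts)
  expect_true("soil" %in% scr$selected)
})

test_that("pseudo-absences avoid presence cells and respect the cap", {
  stack <- make_stack(rand_layers(2, seed = 44))
  cells <- grid_cells(stack$layers$x1)
  pres <- cells[1:50, c("lon", "lat")]  # half the grid occupied
  w <- capture_warnings(
    sets <- sample_pseudo_absences(stack, pres, n_per_set = 8000,
                                   n_sets = 2, seed = 3))
  expect_match(w, "reduced", all = TRUE)
  expect_equal(nrow(sets[[1]]), 50)
  pres_cells <- grid_locate(stack$layers$x1, pres$lon, pres$lat)
  pa_cells <- grid_locate(stack$layers$x1, sets[[1]]$lon, sets[[1]]$lat)
  expect_equal(nrow(merge(pres_cells, pa_cells)), 0)
  # determinism and set independence
  sets2 <- suppressWarnings(
    sample_pseudo_absences(stack, pres, 8000, 2, seed = 3))
  expect_identical(sets, sets2)
  expect_false(identical(sets[[1]], sets[[2]]))
})

test_that("AUC and TSS match worked examples", {
  ev <- evaluate_predictions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(c(ev$auc, ev$tss), c(1, 1))
  ev2 <- evaluate_predictions(c(0.9, 0.6, 0.55, 0.4), c(1, 0, 1, 0))
  expect_equal(ev2$auc, 0.75)
  expect_equal(ev2$tss, 0.5)
  expect_equal(ev2$optimal_threshold, 0.55)
  ev3 <- evaluate_predictions(rep(0.4, 10), rep(c(0, 1), 5))
  expect_equal(c(ev3$auc, ev3$tss), c(0.5, 0))
  expect_error(evaluate_predictions(1:3 / 3, c(1, 1, 1)), "both classes")
})

test_that("fast AUC/TSS agree with exhaustive oracles on random instances", {
  set.seed(45)
  for (i in 1:200) {
    n <- sample(4:60, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    ev <- evaluate_predictions(scores, labels)
    expect_identical(ev$auc, auc_oracle(scores, labels))
    or <- tss_oracle(scores, labels)
    expect_equal(ev$tss, or$tss, tolerance = 1e-12)
    expect_equal(ev$optimal_threshold, or$threshold)
  }
})

test_that("single-model fits separate a separable niche and are seeded", {
  set.seed(46)
  X <- data.frame(a = c(rnorm(100, 3), rnorm(100, -3)))
  y <- rep(c(1, 0), each = 100)
  m <- fit_single_model("glm", X, y, seed = 7)
  expect_equal(m$evaluation$tss, 1)
  m2 <- fit_single_model("glm", X, y, seed = 7)
  expect_identical(m$evaluation, m2$evaluation)
  expect_error(fit_single_model("glm", X, rep(1, 200), seed = 1),
               "single class")
  expect_error(fit_single_model("nope", X, y, seed = 1), "unknown learner")
})

test_that("every registry learner scores a separable problem highly", {
  set.seed(47)
  X <- data.frame(a = c(rnorm(150, 2.5), rnorm(150, -2.5)),
                  b = rnorm(300),
                  soil = factor(sample(c("s", "t"), 300, TRUE)))
  y <- rep(c(1, 0), each = 150)
  for (id in names(default_learners())) {
    m <- fit_single_model(id, X, y, seed = 11)
    expect_gt(m$evaluation$auc, 0.95)
  }
})

test_that("shuffled labels give near-zero TSS on average", {
  set.seed(48)
  X <- data.frame(a = rnorm(2000), b = rnorm(2000))
  y <- sample(rep(0:1, 1000))
  tss <- vapply(1:10, function(i)
    fit_single_model("glm", X, y, seed = i)$evaluation$tss, numeric(1))
  expect_lt(abs(mean(tss)), 0.15)
})

test_that("ensemble weights are TSS-proportional over retained members", {
  mk <- function(tss) structure(list(learner_id = "m", evaluation =
    list(tss = tss, auc = 0.9), test_scores = c(0.8, 0.2),
    test_labels = c(1, 0),
    predict = function(fit, X) rep(tss, nrow(X)), fit = NULL),
    class = "fitted_sdm")
  ens <- build_ensemble(list(mk(0.6), mk(0.5), mk(0.7)), tss_min = 0.55)
  expect_length(ens$members, 2)
  expect_equal(ens$weights, c(0.6, 0.7) / 1.3, tolerance = 1e-12)
  one <- build_ensemble(list(mk(0.8), mk(0.1)), tss_min = 0.55)
  expect_equal(one$weights, 1)
  eq <- build_ensemble(list(mk(0.7), mk(0.7)), tss_min = 0.55)
  X <- data.frame(a = 1:3)
  expect_equal(predict(eq, X), rep(0.7, 3))
  expect_error(build_ensemble(list(mk(0.3)), 0.55), "max observed TSS")
})

test_that("ensemble scores are convex combinations of member scores", {
  set.seed(49)
  X <- data.frame(a = c(rnorm(80, 1.5), rnorm(80, -1.5)))
  y <- rep(c(1, 0), each = 80)
  models <- lapply(1:4, function(i)
    fit_single_model("glm", X, y, seed = i))
  ens <- build_ensemble(models, tss_min = 0.1)
  newX <- data.frame(a = rnorm(50))
  preds <- vapply(ens$members, function(m) m$predict(m$fit, newX),
                  numeric(50))
  e <- predict(ens, newX)
  expect_true(all(e >= apply(preds, 1, min) - 1e-12))
  expect_true(all(e <= apply(preds, 1, max) + 1e-12))
})

test_that("the pipeline counts fits, projects scenarios, and shifts poleward
           under warming", {
  cfg <- world_config(bbox = c(100, 102, 33, 41), resolution = 15,
                      n_stations = 30, lat_gradient = 1.2,
                      noise_sd_temp = 0, noise_sd_precip = 0, seed = 2)
  stack <- build_env_stack(cfg)
  surf <- generate_true_index_surfaces(cfg)
  sp <- species_spec("v", wi_optimum = 70, wi_tolerance = 4,
                     hi_optimum = 6, hi_tolerance = 1.5,
                     n_occurrences = 150, seed = 3)
  occ <- generate_occurrences(sp, surf$wi, surf$hi)
  warm_stack <- build_env_stack(scenario_config(cfg, 1.5, 0))
  res <- suppressWarnings(run_sdm_pipeline(
    occ, stack, scenarios = list(warm = warm_stack),
    learners = c("glm", "rf"), n_runs = 2, n_pa_sets = 2,
    n_per_set = 200, seed = 5))
  expect_length(res$models, 2 * 2 * 2)
  expect_equal(nrow(res$report), 8)
  expect_named(res$projections, c("current", "warm"))
  expect_true(all(res$projections$current$values >= 0 &
                    res$projections$current$values <= 1, na.rm = TRUE))
  # warming pushes suitable warmth poleward (higher latitudes)
  mean_lat <- function(g) {
    cells <- grid_cells(g)
    mean(cells$lat[!is.na(cells$value) & cells$value > 0.2])
  }
  expect_gt(mean_lat(res$projections$warm),
            mean_lat(res$projections$current))
  # missing scenario variable is a hard error
  broken <- stack
  broken$layers <- broken$layers[setdiff(names(broken$layers),
                                         res$selected[1])]
  expect_error(project_ensemble(res$ensemble, broken, res$selected),
               "missing variables")
})
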