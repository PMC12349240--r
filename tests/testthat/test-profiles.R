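test_that("thinning keeps the first record per cell, in stable order", {
  occ <- data.frame(species = "A",
                    lon = c(100.01, 100.02, 100.03, 103.2),
                    lat = c(35.01, 35.02, 35.03, 38.2))
  th <- thin_occurrences(occ, resolution = 150)  # 2.5-degree cells
  expect_equal(nrow(th), 2)
  expect_equal(th$lon, c(100.01, 103.2))
  expect_equal(attr(th, "n_removed"), 2)
  # ten distinct cells -> all retained
  occ10 <- data.frame(species = "A", lon = 100 + (0:9) * 0.5, lat = 35)
  expect_equal(nrow(thin_occurrences(occ10, resolution = 15)), 10)
  expect_error(thin_occurrences(occ10[0, ]), "non-empty")
})

test_that("a point on a cell edge thins into the north/east cell", {
  # edge at lon 100.5 with 30-arcmin cells from origin 100
  occ <- data.frame(species = "A", lon = c(100.5, 100.6), lat = c(35.1, 35.1))
  th <- thin_occurrences(occ, resolution = 30, origin = c(100, 35))
  expect_equal(nrow(th), 1)  # both in the eastern cell under floor()
  occ2 <- data.frame(species = "A", lon = c(100.49, 100.5), lat = c(35.1, 35.1))
  expect_equal(nrow(thin_occurrences(occ2, 30, origin = c(100, 35))), 2)
})

test_that("index extraction uses the containing cell and drops nodata", {
  m <- matrix(5, 2, 2); m[1, 1] <- NA
  bbox <- c(100, 101, 35, 36)
  surf <- list(wi = hydro_grid(m, bbox, 30),
               ci = hydro_grid(m * 0, bbox, 30),
               hi = hydro_grid(m / 2, bbox, 30))
  surf$ci$values[1, 1] <- NA; surf$hi$values[1, 1] <- NA
  occ <- data.frame(species = "A",
                    lon = c(100.75, 100.25), lat = c(35.25, 35.25))
  out <- extract_index_values(occ, surf)
  expect_equal(out$wi, c(5, 5))
  # NW cell is nodata
  occ_bad <- data.frame(species = "A", lon = 100.25, lat = 35.75)
  out2 <- extract_index_values(rbind(occ, occ_bad), surf)
  expect_equal(nrow(out2), 2)
  expect_equal(attr(out2, "n_dropped"), 1)
  expect_error(extract_index_values(occ_bad, surf), "nodata")
})

test_that("species summaries use the sample SD and the min-n filter", {
  v <- data.frame(species = "A", lon = 0, lat = 0,
                  wi = c(50, 60, 70, 80, 90), ci = -10, hi = 5)
  s <- summarize_species(v)
  expect_equal(s$wi_mean, 70)
  expect_equal(s$wi_sd, sqrt(250))  # 15.811, n-1 denominator
  expect_equal(c(s$wi_min, s$wi_max), c(50, 90))
  cons <- data.frame(species = "B", lon = 0, lat = 0, wi = rep(60, 5),
                     ci = 0, hi = 5)
  sc <- summarize_species(cons)
  expect_equal(c(sc$wi_mean, sc$wi_sd, sc$wi_min, sc$wi_max),
               c(60, 0, 60, 60))
  four <- data.frame(species = "C", lon = 0, lat = 0, wi = 1:4, ci = 0,
                     hi = 1)
  s4 <- summarize_species(rbind(v, four))
  expect_equal(s4$species, "A")
  expect_equal(attr(s4, "excluded"), "C")
})

test_that("optimal ranges follow the half-height width of a normal curve", {
  expect_equal(pwhh(8.8), 2.354 * 8.8)
  r <- optimal_range(87.3, 8.8)
  expect_equal(round(unname(r), 1), c(76.9, 97.7))
  r2 <- optimal_range(108.8, 5.5)
  expect_equal(round(unname(r2), 1), c(102.3, 115.3))
  expect_equal(unname(optimal_range(100, 0)), c(100, 100))
  # width and midpoint identities, unrounded
  set.seed(31)
  for (i in 1:50) {
    x <- runif(1, 20, 120); s <- runif(1, 0, 30)
    rr <- optimal_range(x, s)
    expect_equal(unname(diff(rr)), 2.354 * s, tolerance = 1e-12)
    expect_equal(unname(mean(rr)), x, tolerance = 1e-12)
  }
  expect_error(optimal_range(50, -1), ">= 0")
})

test_that("the five-type classifier reproduces published species types", {
  expect_equal(classify_moisture_temperature(44.5, 14.1)[1], 1L)
  expect_equal(classify_moisture_temperature(65.5, 10.7)[1], 3L)
  expect_equal(classify_moisture_temperature(78.7, 4.8)[1], 5L)
  expect_equal(classify_moisture_temperature(69.0, 6.4)[1], 2L)
  expect_equal(classify_moisture_temperature(101.5, 1.9)[1], 4L)
})

test_that("classification boundaries and unclassified bins behave as stated", {
  # HI = 7.5 ties to the xeric/mesic bin, not humid
  expect_equal(classify_moisture_temperature(70, 7.5)[1], 2L)
  expect_equal(classify_moisture_temperature(70, 7.50001)[1], 3L)
  # WI = 75 enters the warm bin; WI top bin is open-ended
  expect_equal(classify_moisture_temperature(75, 5)[1], 5L)
  expect_equal(classify_moisture_temperature(108.8, 5.1)[1], 5L)
  # WI below 20 and unobserved combinations -> NA with bins reported
  low <- classify_moisture_temperature(15, 8)
  expect_true(is.na(low[1]))
  unobs <- classify_moisture_temperature(c(40, 85), c(2, 9))
  expect_true(all(is.na(unobs)))
  expect_equal(attr(unobs, "bins")$wi_bin, c("20~60", "75~"))
  expect_error(classify_moisture_temperature(70, NA), "undefined")
})

test_that("aridity zones use the 3.5 / 5.5 / 7.5 cut points", {
  expect_equal(aridity_zone(c(5.6, 4.8, 3.5, 3.4, 7.5, 29.1)),
               c("semi-humid", "semi-arid", "semi-arid", "arid",
                 "humid", "humid"))
  expect_error(aridity_zone(NA), "undefined")
})

test_that("the published statistics reproduce the group-count grid", {
  p <- caragana_profiles()
  tab <- build_classification_table(p)
  expect_equal(unname(tab["Total", "Total"]), 44)
  expect_equal(unname(tab["20~60", "Total"]), 7)
  expect_equal(unname(tab["Total", "<3.5"]), 10)
  expect_equal(unname(tab["Total", ">7.5"]), 8)
  expect_equal(unname(tab["Total", "3.5~7.5"]), 26)
  # computed types match the published ones for 43 of 44 species; the one
  # divergence is the species whose rounded mean WI sits exactly on the
  # 75 boundary
  code <- classify_moisture_temperature(p$wi_mean, p$hi_mean)
  expect_equal(sum(code == p$published_type, na.rm = TRUE), 43)
  expect_identical(p$species[which(code != p$published_type)],
                   "C. stenophylla")
  empty <- build_classification_table(p[0, ])
  expect_true(all(empty == 0))
})

test_that("species_profiles composes statistics, ranges and labels", {
  set.seed(33)
  v <- data.frame(species = rep(c("A", "B"), each = 40), lon = 0, lat = 0,
                  wi = c(rnorm(40, 85, 6), rnorm(40, 45, 5)),
                  ci = rnorm(80, -40, 5),
                  hi = c(rnorm(40, 5, 0.5), rnorm(40, 12, 1)))
  prof <- species_profiles(v)
  expect_s3_class(prof, "species_profile_table")
  expect_equal(prof$pwh, 2.354 * prof$wi_sd)
  expect_equal(prof$wi_opt_hi - prof$wi_opt_lo, prof$pwh)
  expect_equal(prof$type[prof$species == "A"], 5L)
  expect_equal(prof$type[prof$species == "B"], 1L)
  expect_equal(prof$aridity_zone, c("semi-arid", "humid"))
})
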