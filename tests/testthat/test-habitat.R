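test_that("suitability classes use lower-inclusive breaks", {
  g <- suit_grid(matrix(c(0.19, 0.2, 0.39, 0.4, 0.59, 0.61), 2, 3))
  cls <- classify_suitability(g)
  expect_equal(as.vector(cls$grid$values),
               c(1, 2, 2, 3, 3, 4))
  expect_error(classify_suitability(suit_grid(matrix(1.2, 2, 3))),
               "outside")
  expect_error(classify_suitability(g, breaks = c(0.4, 0.2, 0.6)),
               "increasing")
})

test_that("an all-nodata grid classifies to zero areas", {
  g <- suit_grid(matrix(NA_real_, 2, 2))
  cls <- classify_suitability(g)
  expect_true(all(is.na(cls$grid$values)))
  expect_equal(unname(cls$areas), rep(0, 5))
})

test_that("cell areas follow the spherical-zone formula", {
  res <- 2.5 / 60
  expect_equal(round(cell_area(0, res, res), 2), 21.47)
  # cosine scaling at 60 degrees: about half the equatorial area
  a60 <- cell_area(60, 60 + res, res)
  a0 <- cell_area(0, res, res)
  expect_equal(a60 / a0, cos(pi / 3), tolerance = 0.01)
  expect_equal(cell_area(10, 11, 0), 0)
  expect_error(cell_area(10, 10, 1), "exceed")
  # cosine-midpoint approximation within 0.01% below 70 degrees
  for (lat in c(-65, -30, 0, 30, 55, 69)) {
    exact <- cell_area(lat, lat + res, res)
    approx <- 6371.0088^2 * (res * pi / 180)^2 * cos((lat + res / 2) *
                                                       pi / 180)
    expect_equal(exact, approx, tolerance = 1e-4)
  }
})

test_that("class areas conserve the study area and match brute force", {
  set.seed(51)
  m <- matrix(runif(200), 10, 20)
  m[sample(200, 10)] <- NA
  g <- suit_grid(m)
  cls <- classify_suitability(g)
  # conservation: four classes sum to the unmasked study area
  cells <- grid_cells(g)
  a <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    res <- g$resolution / 60
    a[i] <- cell_area(cells$lat[i] - res / 2, cells$lat[i] + res / 2, res)
  }
  study <- sum(a[!is.na(cells$value)]) / 1e4
  expect_equal(sum(cls$areas[1:4]), study, tolerance = 1e-6 * study)
  expect_equal(unname(cls$areas["potential"]),
               unname(sum(cls$areas[2:4])))
  # checkerboard against a cell-by-cell oracle
  cb <- matrix(rep(c(0.1, 0.9), 50), 10, 10)
  gcb <- suit_grid(cb)
  acb <- classify_suitability(gcb)$areas
  cellscb <- grid_cells(gcb)
  res <- gcb$resolution / 60
  oracle_high <- sum(vapply(which(cellscb$value == 0.9), function(i)
    cell_area(cellscb$lat[i] - res / 2, cellscb$lat[i] + res / 2, res),
    numeric(1))) / 1e4
  expect_equal(unname(acb["highly"]), oracle_high, tolerance = 1e-12)
})

test_that("binary presence uses a strict threshold", {
  g <- suit_grid(matrix(c(0.2, 0.200001, 0, 0.5), 2, 2))
  p <- binary_presence(g)
  expect_equal(sum(p$values), 2)
  expect_equal(p$values[1, 1], 0)  # 0.2 itself is absent (strict >)
  expect_equal(p$values[2, 1], 1)  # 0.200001 is present
  empty <- binary_presence(suit_grid(matrix(0, 2, 2)))
  expect_true(all(empty$values == 0))
})

test_that("change maps partition the grid and match a truth table", {
  m1 <- suit_grid(matrix(1, 4, 4)); m0 <- suit_grid(matrix(0, 4, 4))
  same <- change_map(m1, m1)
  expect_equal(unname(same$areas[c("loss", "gain")]), c(0, 0))
  all_loss <- change_map(m1, m0)
  expect_equal(unname(all_loss$areas["never"]), 0)
  expect_equal(unname(all_loss$areas["loss"]), sum(all_loss$areas))
  # random 100-cell masks vs exhaustive per-cell evaluation
  set.seed(52)
  a <- matrix(rbinom(100, 1, 0.5), 10, 10)
  b <- matrix(rbinom(100, 1, 0.5), 10, 10)
  cm <- change_map(suit_grid(a), suit_grid(b))
  expected <- ifelse(a & b, 3, ifelse(a & !b, 1, ifelse(!a & b, 2, 0)))
  expect_equal(cm$grid$values, expected, ignore_attr = TRUE)
  expect_error(change_map(m1, suit_grid(matrix(1, 5, 5))), "misaligned")
})

test_that("centroids are area-weighted means of presence cells", {
  m <- matrix(0, 3, 3); m[2, 2] <- 1
  g <- suit_grid(m)
  cells <- grid_cells(g)
  ctr <- range_centroid(g, threshold = 0.2)
  expect_equal(unname(ctr), c(cells$lon[5], cells$lat[5]))
  # plus sign symmetric about the center keeps the center coordinates
  plus <- matrix(0, 3, 3); plus[2, ] <- 1; plus[, 2] <- 1
  expect_equal(unname(range_centroid(suit_grid(plus))[1]), cells$lon[5])
  # two cells at lat 0 and 60: the larger equatorial cell wins
  big <- hydro_grid(matrix(c(1, rep(0, 13), 1, 0), 8, 2, byrow = TRUE),
                    c(0, 16, 0, 64), resolution = 8 * 60)
  # cells at lat centers 60 (row 1, col 1) and 4 (row 8, col 1): rebuild
  gc <- grid_cells(big)
  pres <- gc[!is.na(gc$value) & gc$value > 0.2, ]
  res <- big$resolution / 60
  w <- cell_area(pres$lat - res / 2, pres$lat + res / 2, res)
  expect_equal(unname(range_centroid(big)["lat"]),
               sum(w * pres$lat) / sum(w))
  expect_lt(unname(range_centroid(big)["lat"]), mean(pres$lat))
  expect_error(range_centroid(suit_grid(matrix(0, 2, 2))), "empty")
})

test_that("a longitudinally mirrored mask centers on the mirror meridian", {
  set.seed(53)
  half <- matrix(rbinom(50, 1, 0.4), 10, 5)
  m <- cbind(half, half[, 5:1])
  g <- hydro_grid(m, c(100, 101, 35, 36), resolution = 6)
  expect_equal(unname(range_centroid(g)["lon"]), 100.5, tolerance = 1e-9)
})

test_that("migration vectors follow haversine distance and bearing", {
  zero <- migration_vector(c(100, 40), c(100, 40))
  expect_equal(c(zero$distance_km, zero$bearing_deg), c(0, 0))
  north <- migration_vector(c(100, 40), c(100, 41))
  expect_equal(north$distance_km, 6371.0088 * pi / 180, tolerance = 1e-6)
  expect_equal(north$bearing_deg, 0)
  expect_equal(north$cardinal, "N")
  east <- migration_vector(c(100, 40), c(101, 40))
  expect_equal(east$bearing_deg, 90, tolerance = 0.5)
  expect_equal(east$cardinal, "E")
  # symmetry and back-azimuth
  set.seed(54)
  for (i in 1:20) {
    a <- c(runif(1, 80, 120), runif(1, 20, 50))
    b <- c(runif(1, 80, 120), runif(1, 20, 50))
    ab <- migration_vector(a, b); ba <- migration_vector(b, a)
    expect_equal(ab$distance_km, ba$distance_km, tolerance = 1e-9)
    back <- (geosphere::bearing(b, a) %% 360)
    expect_equal(ba$bearing_deg, back, tolerance = 1e-9)
  }
})
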