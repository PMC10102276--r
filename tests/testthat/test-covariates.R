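make_eb_row <- function(dist = 2, dur = 2, obs = 2, time = "08:00") {
  data.frame(x = 10, y = 10, year = 2001L, stream = "ebird",
             effort_distance = dist, effort_duration = dur,
             n_observers = obs, start_time = time, complete = TRUE,
             stringsAsFactors = FALSE)
}

test_that("checklist filters honor the declared boundary conventions", {
  rows <- rbind(make_eb_row(dist = 6),            # > 5 km -> removed
                make_eb_row(dist = 4.9),          # kept
                make_eb_row(time = "04:30"),      # before 5 am -> removed
                make_eb_row(time = "05:00"),      # boundary inclusive
                make_eb_row(time = "21:00"),      # boundary inclusive
                make_eb_row(time = "21:01"),      # removed
                make_eb_row(obs = 10),            # inclusive -> kept
                make_eb_row(obs = 11),            # removed
                make_eb_row(dur = 5),             # strict -> removed
                make_eb_row(dur = 4.99))          # kept
  nest <- data.frame(x = 1, y = 1, year = 2001L, stream = "nest",
                     effort_distance = NA, effort_duration = NA,
                     n_observers = NA, start_time = NA, complete = NA)
  tab <- point_table(rbind(rows, nest))
  out <- filter_checklists(tab)
  expect_equal(sum(out$stream == "ebird"), 5L)
  expect_equal(sum(out$stream == "nest"), 1L)   # nests untouched
  # subset + idempotence
  expect_true(nrow(out) <= nrow(tab))
  expect_equal(filter_checklists(out), out)
  # incomplete checklists are retained (presence-only records)
  inc <- point_table(transform(make_eb_row(), complete = FALSE))
  expect_equal(nrow(filter_checklists(inc)), 1L)
})

test_that("surface water reclassification keeps only high-confidence water", {
  g <- tiny_grid(2, 2)
  acq <- function(v) raster_layer(g, v)
  out <- reclassify_dswe(list(acq(c(0, 3, NA, 0)), acq(c(2, 4, NA, 0)),
                              acq(c(1, 2, NA, 0))))
  expect_equal(as.vector(t(out$values)), c(1, 0, NA, 0))
  expect_error(reclassify_dswe(list(acq(c(0, 0, 0, 9)))), "out-of-range")
})

test_that("max composite ignores missing acquisitions", {
  g <- tiny_grid(2, 2)
  out <- max_composite(list(raster_layer(g, c(0.1, NA, NA, 0.5)),
                            raster_layer(g, c(0.7, 0.2, NA, 0.4)),
                            raster_layer(g, c(0.3, NA, NA, 0.6))))
  expect_equal(as.vector(t(out$values)), c(0.7, 0.2, NA, 0.6))
  r <- raster_layer(g, 1:4)
  expect_raster_equal(max_composite(list(r)), r)
  g2 <- tiny_grid(3, 3)
  expect_error(max_composite(list(r, raster_layer(g2, 1:9))), "mismatch")
})

test_that("slope is exact on analytic planes", {
  g <- tiny_grid(6, 6, dx = 30)
  flat <- raster_layer(g, 5)
  expect_true(all(slope_degrees(flat)$values == 0))
  cc <- cell_centers_xy(g)
  # plane rising 1 m per m easting -> 45 degrees
  p45 <- raster_layer(g, matrix(cc[, 1], 6, 6, byrow = TRUE))
  expect_equal(slope_degrees(p45)$values[3, 3], 45, tolerance = 1e-10)
  # plane rising 1 m per 30 m -> atan(1/30)
  p1 <- raster_layer(g, matrix(cc[, 1] / 30, 6, 6, byrow = TRUE))
  expect_equal(slope_degrees(p1)$values[4, 4], atan(1 / 30) * 180 / pi,
               tolerance = 1e-10)
  expect_error(slope_degrees(raster_layer(tiny_grid(1, 1), 1)), "2x2")
})

test_that("distance_to matches the brute-force oracle on raster features", {
  set.seed(31)
  for (rep in 1:3) {
    n <- sample(3:9, 1)
    g <- tiny_grid(n, n)
    v <- matrix(0, n, n)
    v[sample(n * n, sample(1:3, 1))] <- 1
    feat <- raster_layer(g, v)
    d <- distance_to(feat, g)
    cc <- cell_centers_xy(g)
    fsel <- which(raster_values_rowmajor(feat) == 1)
    oracle <- sapply(seq_len(nrow(cc)), function(i)
      min(sqrt((cc[i, 1] - cc[fsel, 1])^2 + (cc[i, 2] - cc[fsel, 2])^2)))
    expect_equal(raster_values_rowmajor(d), oracle, tolerance = 1e-10)
  }
  g5 <- tiny_grid(5, 5)
  v <- matrix(0, 5, 5); v[3, 3] <- 1
  d <- distance_to(raster_layer(g5, v), g5)
  expect_equal(d$values[3, 3], 0)
  expect_equal(d$values[3, 4], 30)
  expect_error(distance_to(raster_layer(g5, 0), g5), "empty")
})

test_that("distance_to handles polygons, lines and points", {
  g <- tiny_grid(6, 6)
  sq <- list(cbind(c(40, 100, 100, 40), c(40, 40, 100, 100)))
  d <- distance_to(geo_features(polygons = list(sq)), g)
  # cells inside the polygon are 0
  expect_equal(d$values[4, 3], 0)   # center (75, 75)
  # far corner cell center (165, 165): nearest polygon point is (100, 100)
  expect_equal(d$values[1, 6], sqrt(2 * 65^2), tolerance = 1e-9)
  dl <- distance_to(geo_features(lines = list(cbind(c(0, 180), c(90, 90)))), g)
  expect_equal(dl$values[1, 2], 75)   # center y = 165
  dp <- distance_to(geo_features(points = rbind(c(15, 15))), g)
  expect_equal(dp$values[6, 1], 0)
})

test_that("exponential distance transform evaluates and saturates", {
  expect_equal(exp_distance(0, 100), 0)
  expect_equal(exp_distance(100, 100), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(exp_distance(100, 100), 0.63212, tolerance = 1e-5)
  d <- seq(0, 5000, by = 100)
  v <- exp_distance(d, 700)
  expect_true(all(diff(v) > 0) && all(v >= 0 & v < 1))
  expect_error(exp_distance(10, 0), "mu")
})

test_that("binary distance classification uses the declared tie rule", {
  expect_equal(binarize_distance(c(150, 50, 100), 100), c(1, 0, 1))
  # binarize(distance) is idempotent under re-thresholding at 0.5
  b <- binarize_distance(c(150, 50, 100), 100)
  expect_equal(binarize_distance(b * 200, 100), b)
})

test_that("moving window statistics follow the membership rules", {
  g <- tiny_grid(3, 3)
  r <- raster_layer(g, 1:9)
  expect_equal(moving_window(r, "neighbor", "mean")$values[2, 2], 5)
  # constant raster: mean preserved, sd 0 at any scale
  k <- raster_layer(g, 7)
  expect_true(all(moving_window(k, "r90", "mean")$values == 7))
  expect_true(all(moving_window(k, "r150", "sd")$values == 0))
  expect_raster_equal(moving_window(r, "pixel30", "mean"), r)
  # r90 window at 30 m cells: all cells with center distance <= 90
  g7 <- tiny_grid(7, 7)
  set.seed(9)
  v <- matrix(rnorm(49), 7, 7)
  rr <- raster_layer(g7, v)
  mw <- moving_window(rr, "r90", "mean")
  offs <- expand.grid(di = -3:3, dj = -3:3)
  offs <- offs[30 * sqrt(offs$di^2 + offs$dj^2) <= 90, ]
  oracle <- mean(mapply(function(di, dj) v[4 + dj, 4 + di], offs$di, offs$dj))
  expect_equal(mw$values[4, 4], oracle, tolerance = 1e-12)
  # affine equivariance of mean; shift invariance of sd
  a <- moving_window(rr, "r90", "mean")
  b <- moving_window(raster_layer(g7, 2 * v + 3), "r90", "mean")
  expect_equal(b$values, 2 * a$values + 3, tolerance = 1e-12)
  s1 <- moving_window(rr, "r90", "sd")
  s2 <- moving_window(raster_layer(g7, v + 10), "r90", "sd")
  expect_equal(s1$values, s2$values, tolerance = 1e-10)
})

test_that("land-cover masks follow the class-code table", {
  g <- tiny_grid(2, 2)
  lc <- raster_layer(g, c(82, 81, 11, 41))
  expect_equal(as.vector(t(crop_binary(lc)$values)), c(1, 1, 0, 0))
  expect_equal(as.vector(t(trees_mask(lc)$values)), c(0, 0, 0, 1))
  expect_true(all(crop_binary(raster_layer(g, 81))$values == 1))
  expect_error(crop_binary(raster_layer(g, c(82, 81, 11, 99))), "99")
})

test_that("road density matches chord geometry and is linear", {
  g <- tiny_grid(3, 3, dx = 100)
  ctr <- cell_centers_xy(g)[5, ]   # center cell
  R <- 120
  road <- geo_features(lines = list(cbind(c(ctr[1] - 500, ctr[1] + 500),
                                          c(ctr[2], ctr[2]))))
  d <- road_density(road, g, radius = R)
  expect_equal(d$values[2, 2], (2 * R / 1000) / (pi * (R / 1000)^2),
               tolerance = 1e-9)
  d2 <- road_density(geo_features(lines = rep(road$lines, 2)), g, radius = R)
  expect_equal(d2$values, 2 * d$values, tolerance = 1e-9)
  expect_true(all(road_density(geo_features(), g)$values == 0))
})

test_that("standardization is exact, persistent and strict", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 8))
  st <- standardize(x)
  expect_equal(st$x[, "a"], c(-1, 0, 1))   # sample sd convention
  expect_equal(colMeans(st$x), c(a = 0, b = 0))
  expect_equal(apply(st$x, 2, sd), c(a = 1, b = 1))
  # idempotence and replay
  st2 <- standardize(st$x)
  expect_equal(st2$x, st$x, tolerance = 1e-12)
  expect_equal(apply_standardize(x, st$center, st$scale), st$x)
  expect_error(standardize(cbind(ok = 1:3, flat = rep(2, 3))), "flat")
})

test_that("correlation screen flags pairs but exempts quadratic partners", {
  set.seed(4)
  x <- cbind(a = rnorm(100))
  x <- cbind(x, a_sq = x[, "a"]^2, b = x[, "a"], c = -x[, "a"],
             d = rnorm(100))
  out <- correlation_screen(x, threshold = 0.7)
  get <- function(a, b) out[(out$a == a & out$b == b) |
                              (out$a == b & out$b == a), ]
  expect_false(get("a", "a_sq")$flagged)      # exempt pair
  expect_true(get("a", "b")$flagged)
  expect_equal(get("a", "b")$r, 1)
  expect_true(get("a", "c")$flagged)
  expect_equal(abs(get("a", "c")$r), 1)
  expect_false(get("a", "d")$flagged)
})

test_that("design assembly expands quadratics and samples exactly at centers", {
  w <- small_world()
  specs <- list(cov_spec("percent_water", quadratic = TRUE),
                cov_spec("slope"))
  X <- assemble_design(w$layers, specs, 2001, grid = w$grid)
  expect_equal(colnames(X), c("percent_water", "percent_water_sq", "slope"))
  cc <- cell_centers_xy(w$grid)
  at <- data.frame(x = cc[5, 1], y = cc[5, 2])
  X1 <- assemble_design(w$layers, specs, 2001, at = at)
  expect_equal(X1[1, ], X[5, ])   # cell center -> exact cell value
  X2 <- assemble_design(w$layers, specs, 2001, at = at)
  expect_identical(X1, X2)
  expect_error(assemble_design(w$layers, list(cov_spec("nope")), 2001,
                               grid = w$grid), "nope")
  expect_error(assemble_design(w$layers, list(cov_spec("percent_water")),
                               1990, grid = w$grid), "1990")
})
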