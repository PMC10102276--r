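test_that("AUC equals brute-force pair counting", {
  expect_equal(auc(c(3, 1), c(2, 0)), 0.75)
  expect_equal(auc(5, 1), 1)
  expect_equal(auc(c(1, 1), c(1, 1)), 0.5)
  set.seed(70)
  for (rep in 1:20) {
    n1 <- sample(2:40, 1); n0 <- sample(2:60, 1)
    p <- sample(0:5, n1, TRUE) + rnorm(n1, 0, 0.01)
    b <- sample(0:5, n0, TRUE) + rnorm(n0, 0, 0.01)
    brute <- mean(outer(p, b, function(a, c2) (a > c2) + 0.5 * (a == c2)))
    expect_equal(auc(p, b), brute, tolerance = 1e-12)
  }
})

test_that("temporal folds reproduce period boundaries and partition", {
  pts <- point_table(data.frame(x = 1, y = 1,
                                year = 2000:2019, stream = "nest"))
  periods <- list(c(2000, 2006), c(2007, 2012), c(2013, 2019))
  fa <- temporal_folds(pts, periods)
  expect_equal(fa$fold[pts$year == 2006], 1L)
  expect_equal(fa$fold[pts$year == 2007], 2L)
  expect_equal(fa$fold[pts$year == 2012], 2L)
  expect_equal(fa$fold[pts$year == 2013], 3L)
  expect_equal(length(fa$fold), nrow(pts))
  expect_equal(sum(table(fa$fold)), nrow(pts))   # exact partition
  expect_true(all(table(fa$fold) > 0))
  # single period puts everything in one fold
  fa1 <- temporal_folds(pts, list(c(2000, 2019)))
  expect_true(all(fa1$fold == 1L))
  expect_error(temporal_folds(pts, list(c(2005, 2019))), "2000")
})

test_that("spatial blocks partition points with balanced allocation", {
  set.seed(71)
  g <- grid_spec(0, 300e3, 1000, 1000, 300, 300, years = 2001L)
  pts <- point_table(data.frame(x = runif(400, 0, 300e3),
                                y = runif(400, 0, 300e3),
                                year = 2001L, stream = "nest"))
  fa <- spatial_folds(pts, g, block_size = 100e3, k = 3, seed = 72)
  expect_equal(nrow(fa$blocks), 9L)
  expect_equal(as.numeric(table(fa$blocks$fold)), rep(3, 3))  # 3 per fold
  expect_equal(length(fa$fold), 400L)
  expect_false(anyNA(fa$fold))
  # same block -> same fold
  key <- paste(floor(pts$x / 100e3), floor((300e3 - pts$y) / 100e3))
  expect_true(all(tapply(fa$fold, key, function(v) length(unique(v))) == 1))
  expect_error(spatial_folds(pts, g, block_size = 400e3, k = 3, seed = 1),
               "non-empty blocks")
})

test_that("variogram-informed block size tracks the generating range", {
  g <- grid_spec(0, 48 * 30, 30, 30, 48, 48, years = 2001L)
  # white noise: suggested size collapses toward the lattice scale
  set.seed(73)
  noise <- raster_layer(g, rnorm(48 * 48))
  expect_lt(suggest_block_size(list(noise), seed = 74), 220)
  # fields with a known range: the median suggestion over three
  # realizations lands within a factor of ~2 of the 400 m range
  op <- spatial_precision(g, 400, 1)
  us <- lapply(75:77, function(s)
    raster_layer(g, sample_gmrf(op, 1, seed = s)[, 1]))
  sug <- suggest_block_size(us, seed = 76)
  expect_gt(sug, 200)
  expect_lt(sug, 800)
  # constant layers are skipped; all-constant errors
  expect_error(suggest_block_size(list(raster_layer(g, 1))), "variogram")
})

test_that("cross-validation runs per scheme and respects the partition", {
  w <- small_world()
  ms <- model_spec(w$grid, w$truth$specs_eco, w$truth$specs_obs,
                   field_coarsen = 8, sample_method = "nearest")
  fa <- random_folds(w$points, k = 3, seed = 77)
  res <- suppressMessages(cv_run(fa, ms, w$layers, w$points, seed = 78))
  expect_true(res$auc > 0 && res$auc < 1)
  expect_true(res$rmse > 0)
  expect_equal(nrow(res$per_fold), 3L)
  # a well-specified model on its own data discriminates clearly
  expect_gt(res$auc, 0.6)
  # duplicate scheme gives identical metrics
  res2 <- suppressMessages(cv_run(fa, ms, w$layers, w$points, seed = 78))
  expect_equal(res$auc, res2$auc)
  expect_equal(res$rmse, res2$rmse)
})

test_that("random scores give chance-level AUC", {
  set.seed(79)
  p <- runif(400); b <- runif(600)
  expect_equal(auc(p, b), 0.5, tolerance = 0.08)
})

test_that("buffered evaluation scores by the maximum within the buffer", {
  g <- tiny_grid(5, 5)
  v <- matrix(0.01, 5, 5)
  v[2, 4] <- 5   # hot cell center (105, 105)
  surf <- structure(list(lambda = raster_layer(g, v), year = 2001),
                    class = "prediction_surface")
  cl <- data.frame(x = c(45, 45, 45), y = c(105, 105, 105),
                   effort_distance = c(0, 0.0601, 0.5))
  lab <- c(TRUE, TRUE, FALSE)
  # radius 0: containing cell; 60.1 m: reaches the hot cell two columns away
  res <- buffered_eval(cl, surf, lab)
  expect_equal(res$scores[1], 0.01)
  expect_equal(res$scores[2], 5)
  expect_equal(res$scores[3], 5)   # radius covers the whole raster
  # monotone in radius
  radii <- c(0, 0.03, 0.06, 0.09, 0.2)
  sc <- sapply(radii, function(r)
    buffered_eval(data.frame(x = 45, y = 105, effort_distance = r),
                  surf, c(TRUE))$scores[1])
  expect_true(all(diff(sc) >= 0))
})

test_that("stream ablation pairs folds between the two models", {
  w <- small_world()
  ms <- model_spec(w$grid, w$truth$specs_eco, w$truth$specs_obs,
                   field_coarsen = 8, sample_method = "nearest")
  tab <- suppressMessages(
    stream_ablation(ms, w$layers, w$points, folds = 3, seed = 80))
  expect_equal(tab$model, c("integrated", "nests_only"))
  expect_true(all(is.finite(tab$auc)))
  fa <- attr(tab, "folds")
  expect_s3_class(fa, "fold_assignment")
  expect_equal(length(fa$fold), nrow(w$points))
})
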