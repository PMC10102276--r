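test_that("quadrature schemes conserve area and honor the uniform example", {
  g <- tiny_grid(10, 10, dx = 1)   # |A| = 100
  set.seed(2)
  pres <- point_table(data.frame(x = runif(50, 0, 10), y = runif(50, 0, 10),
                                 year = 2001L, stream = "nest"))
  q <- build_quadrature(g, pres, m = 1000, seed = 1, weighting = "uniform")
  expect_equal(unique(q$w), 100 / 1050, tolerance = 1e-12)
  expect_equal(sum(q$w), 100, tolerance = 1e-9)
  expect_equal(sum(q$presence), 50)
  # counting weights conserve area per year too
  g2 <- grid_spec(0, 10, 1, 1, 10, 10, years = 2001:2002)
  pres2 <- point_table(data.frame(x = runif(40, 0, 10), y = runif(40, 0, 10),
                                  year = rep(2001:2002, 20), stream = "nest"))
  q2 <- build_quadrature(g2, pres2, m = 500, seed = 1)
  expect_equal(as.numeric(tapply(q2$w, q2$year, sum)), c(100, 100),
               tolerance = 1e-9)
  expect_true(all(q2$w > 0))
  # grid quadrature covers every cell-year
  q3 <- build_quadrature(g2, pres2, type = "grid")
  expect_equal(sum(q3$presence == 0), 200L)
  # determinism
  qa <- build_quadrature(g, pres, m = 500, seed = 9)
  qb <- build_quadrature(g, pres, m = 500, seed = 9)
  expect_identical(qa, qb)
})

test_that("unpenalized DWPR recovers the homogeneous-process MLE", {
  g <- tiny_grid(10, 10, dx = 1)
  set.seed(3)
  pres <- point_table(data.frame(x = runif(50, 0, 10), y = runif(50, 0, 10),
                                 year = 2001L, stream = "nest"))
  q <- build_quadrature(g, pres, m = 5000, seed = 4, weighting = "uniform")
  fit <- dwpr_fit(NULL, q)
  expect_equal(unname(fit$coef[1]), log(50 / 100), tolerance = 1e-8)
  # a constant-zero covariate changes nothing
  fit2 <- dwpr_fit(cbind(z = rep(0, nrow(q))), q)
  expect_equal(unname(fit2$coef["z"]), 0)
  expect_equal(unname(fit2$coef[1]), log(50 / 100), tolerance = 1e-8)
})

test_that("penalty-0 DWPR agrees with the weighted Poisson GLM oracle", {
  w <- small_world()
  nests <- w$points[w$points$stream == "nest", ]
  q <- build_quadrature(w$grid, nests, m = 2000, seed = 5,
                        weighting = "uniform")
  set.seed(6)
  X <- cbind(a = rnorm(nrow(q)), b = rnorm(nrow(q)))
  fit <- dwpr_fit(X, q)
  or <- suppressWarnings(
    stats::glm(q$presence / q$w ~ X, family = stats::poisson(),
               weights = q$w))
  expect_equal(unname(fit$coef), unname(coef(or)), tolerance = 1e-6)
})

test_that("penalized DWPR matches glmnet at the mapped penalty", {
  skip_if_not_installed("glmnet")
  w <- small_world()
  nests <- w$points[w$points$stream == "nest", ]
  q <- build_quadrature(w$grid, nests, m = 1500, seed = 7,
                        weighting = "uniform")
  set.seed(8)
  X <- scale(cbind(a = rnorm(nrow(q)), b = rnorm(nrow(q)),
                   c = rnorm(nrow(q))))
  pen <- 5
  mine <- dwpr_fit(X, q, penalty = pen)
  gn <- glmnet::glmnet(X, q$presence / q$w, family = "poisson",
                       weights = q$w, lambda = pen / sum(q$w),
                       standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(mine$coef),
               unname(c(gn$a0, as.vector(gn$beta))), tolerance = 1e-4)
})

test_that("LASSO saturates at lambda_max and for huge penalties", {
  w <- small_world()
  nests <- w$points[w$points$stream == "nest", ]
  q <- build_quadrature(w$grid, nests, m = 1500, seed = 9)
  set.seed(10)
  X <- cbind(a = rnorm(nrow(q)), b = rnorm(nrow(q)))
  big <- dwpr_fit(X, q, penalty = 1e9)
  expect_equal(unname(big$coef[-1]), c(0, 0))
  lc <- lasso_cv(X, q, folds = 4, seed = 11, n_penalty = 6)
  # head of the path (lambda_max) has zero slopes
  head_fit <- dwpr_fit(standardize(X)$x, q, penalty = lc$path$penalty[1])
  expect_equal(unname(head_fit$coef[-1]), c(0, 0), tolerance = 1e-10)
  expect_true(all(diff(lc$path$penalty) < 0))
})

test_that("scale selection prefers the generating scale and breaks ties small", {
  w <- small_world()
  # truth generated from the r90-summarized water layer
  g <- w$grid
  sc90 <- moving_window(get_layer(w$layers, "percent_water", 2001), "r90")
  st <- standardize(matrix(raster_values_rowmajor(sc90), ncol = 1))
  eta <- -9.5 + 1.2 * st$x[, 1]
  lam <- exp(eta) * cell_area(g)
  set.seed(12)
  cnt <- rpois(length(lam), lam)
  cc <- cell_centers_xy(g)
  pres <- point_table(data.frame(x = rep(cc[, 1], cnt), y = rep(cc[, 2], cnt),
                                 year = 2001L, stream = "nest"))
  g1 <- grid_spec(g$x0, g$y0, g$dx, g$dy, g$nx, g$ny, 2001L)
  q <- build_quadrature(g1, pres, type = "grid")
  sel <- select_scale(w$layers, "percent_water",
                      c("pixel30", "r90", "r750"), q, folds = 5, seed = 13)
  expect_equal(sel$scale, "r90")
  # single candidate trivially returned
  expect_equal(select_scale(w$layers, "slope", "r150", q)$scale, "r150")
  # identical layers at all scales -> smallest scale wins the tie
  flat_layers <- list(static = list(
    slope = w$layers$static$slope))
  sel2 <- select_scale(flat_layers, "slope", c("pixel30", "neighbor"), q,
                       folds = 4, seed = 14)
  expect_true(sel2$scale %in% c("pixel30", "neighbor"))
})

test_that("CV LASSO zeroes noise covariates alongside a strong signal", {
  w <- small_world()
  g1 <- grid_spec(w$grid$x0, w$grid$y0, w$grid$dx, w$grid$dy, w$grid$nx,
                  w$grid$ny, 2001L)
  sig <- standardize(matrix(raster_values_rowmajor(
    moving_window(get_layer(w$layers, "percent_water", 2001), "r90")),
    ncol = 1))$x[, 1]
  eta <- -9.2 + 1.3 * sig
  lam <- exp(eta) * cell_area(g1)
  set.seed(15)
  cnt <- rpois(length(lam), lam)
  cc <- cell_centers_xy(g1)
  pres <- point_table(data.frame(x = rep(cc[, 1], cnt), y = rep(cc[, 2], cnt),
                                 year = 2001L, stream = "nest"))
  q <- build_quadrature(g1, pres, type = "grid")
  sig_rows <- sig[point_to_cell(g1, q$x, q$y)$j * g1$nx +
                    point_to_cell(g1, q$x, q$y)$i + 1]
  X <- cbind(signal = sig_rows,
             matrix(rnorm(nrow(q) * 3), ncol = 3,
                    dimnames = list(NULL, paste0("noise", 1:3))))
  lc <- lasso_cv(X, q, folds = 5, seed = 16, n_penalty = 20)
  expect_true(lc$fit$coef["signal"] > 0)
  expect_equal(unname(lc$fit$coef[paste0("noise", 1:3)]), rep(0, 3))
})

test_that("model comparison reuses folds and scores duplicates identically", {
  w <- small_world()
  nests <- w$points[w$points$stream == "nest", ]
  q <- build_quadrature(w$grid, nests, m = 1200, seed = 17)
  set.seed(18)
  X1 <- cbind(a = rnorm(nrow(q)))
  X2 <- cbind(a = X1[, "a"], b = rnorm(nrow(q)))
  cmp <- compare_models(list(m1 = X1, m1dup = X1, m2 = X2), q, folds = 4,
                        seed = 19)
  expect_equal(cmp$cv_rmse[cmp$model == "m1"],
               cmp$cv_rmse[cmp$model == "m1dup"])
  expect_equal(cmp$cv_auc[cmp$model == "m1"],
               cmp$cv_auc[cmp$model == "m1dup"])
  expect_true(attr(cmp, "winner") %in% cmp$model)
})
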