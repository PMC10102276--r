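world_spec <- function(w, coarsen = 8, ...) {
  model_spec(w$grid, w$truth$specs_eco, w$truth$specs_obs,
             field_coarsen = coarsen, sample_method = "nearest", ...)
}

test_that("joint likelihood reduces to closed forms", {
  g <- grid_spec(0, 10 * 30, 30, 30, 10, 10, years = 2001:2002)
  L <- make_landscape(g, seed = 11)
  set.seed(12)
  n <- 40
  pts <- point_table(data.frame(x = runif(n, 0, 300), y = runif(n, 0, 300),
                                year = rep(2001:2002, n / 2),
                                stream = "nest"))
  ms <- model_spec(g, list(cov_spec("slope")), list(),
                   effort_columns = character(0), field_coarsen = 5,
                   sample_method = "nearest")
  id <- prepare_integrated(ms, L, pts, seed = 13)
  # constant lambda = c: loglik = n log c - c |A| n_years
  cval <- 1e-4
  beta <- c(log(cval), 0)
  expect_equal(joint_loglik(id, beta),
               n * log(cval) - cval * 300^2 * 2, tolerance = 1e-6)
  # delta = 0 makes the thinned term a plain Poisson process likelihood:
  # evaluating the ebird stream with b == 1 equals merging both streams
  w <- small_world()
  ms2 <- world_spec(w)
  id2 <- prepare_integrated(ms2, w$layers, w$points, seed = 14)
  p <- ncol(id2$X)
  set.seed(15)
  beta2 <- c(-9.5, rnorm(p - 1, 0, 0.2))
  delta0 <- rep(0, ncol(id2$Z))
  ll_joint <- joint_loglik(id2, beta2, delta0)
  # manual: same rows, no observation design at all
  eta <- drop(id2$X %*% beta2)
  ll_manual <- sum(id2$rows$presence * eta - id2$rows$w * exp(eta))
  expect_equal(ll_joint, ll_manual, tolerance = 1e-9)
})

test_that("quadrature integral matches the analytic exponential integral", {
  # integral of exp(beta * x) over the unit square, x = easting coordinate
  g <- grid_spec(0, 1, 1 / 64, 1 / 64, 64, 64, years = 2001L)
  beta <- 1.7
  cc <- cell_centers_xy(g)
  sch <- build_quadrature(g, NULL, type = "grid")
  eta <- beta * sch$x
  quad_int <- sum(sch$w * exp(eta))
  exact <- (exp(beta) - 1) / beta
  expect_equal(quad_int, exact, tolerance = 0.01 * exact)
  # refinement: a 128-cell lattice halves nothing but must not degrade
  g2 <- grid_spec(0, 1, 1 / 128, 1 / 128, 128, 128, years = 2001L)
  sch2 <- build_quadrature(g2, NULL, type = "grid")
  quad2 <- sum(sch2$w * exp(beta * sch2$x))
  expect_lt(abs(quad2 - exact), abs(quad_int - exact))
})

test_that("field-free fits recover known coefficients within 3 SE", {
  g <- grid_spec(0, 32 * 30, 30, 30, 32, 32, years = 2001:2002)
  L <- make_landscape(g, seed = 21)
  tr <- truth_spec(g, L, field = field_params(240, 1e-6, 0),
                   target_nests = 900, target_ebird = 200)
  pts <- simulate_points(tr, L, zero_field(g), seed = 22)
  ms <- model_spec(g, tr$specs_eco, tr$specs_obs, field_coarsen = 8,
                   sample_method = "nearest")
  ft <- fit_integrated(ms, L, pts, seed = 23, hyper = "none")
  co <- ft$coef[ft$coef$group == "beta", ][-1, ]
  for (k in seq_len(nrow(co))) {
    truthv <- tr$beta[co$name[k]]
    expect_lt(abs(co$q50[k] - truthv), 3 * co$sd[k] + 1e-9,
              label = co$name[k])
  }
  # interval endpoints ordered; field arrays match coarse grid x years
  expect_true(all(ft$coef$q2.5 <= ft$coef$q50 & ft$coef$q50 <= ft$coef$q97.5))
  expect_equal(length(ft$field), 2L)
  expect_equal(dim(ft$field$y2001$values), c(4L, 4L))
})

test_that("stronger priors shrink coefficients monotonically", {
  w <- small_world()
  ests <- sapply(c(0.001, 10, 1e4, 1e7), function(pp) {
    ms <- world_spec(w, prior_prec = pp)
    ft <- fit_integrated(ms, w$layers, w$points, seed = 24, hyper = "none")
    max(abs(ft$coef$q50[-1][ft$coef$group[-1] == "beta"]))
  })
  expect_true(all(diff(ests) < 0))
  expect_lt(ests[4], 0.05)
})

test_that("hyperparameter estimation runs and lands in a sane region", {
  w <- small_world()
  ms <- world_spec(w, coarsen = 4)
  ft <- fit_integrated(ms, w$layers, w$points, seed = 25, hyper = "estimate")
  expect_true(ft$hyper$rho > 120 && ft$hyper$rho < 3000)
  expect_true(ft$hyper$sigma > 0.05 && ft$hyper$sigma < 3)
  expect_true(abs(ft$hyper$phi) < 1)
  expect_true(is.finite(ft$marginal_loglik))
  expect_true(ft$diagnostics$converged)
})

test_that("stream removal behaves structurally", {
  w <- small_world()
  ms <- world_spec(w)
  nest_only <- fit_without_stream(ms, w$layers, w$points, "ebird",
                                  seed = 26, hyper = "none")
  expect_false(any(nest_only$coef$group == "delta"))
  # dropping an ebird table with no rows equals the full fit on nests only
  nests <- w$points[w$points$stream == "nest", ]
  full_empty_eb <- fit_integrated(ms, w$layers, nests, seed = 26,
                                  hyper = "none")
  expect_equal(full_empty_eb$coef, nest_only$coef, tolerance = 1e-8)
})

test_that("relabeling years with phi = 0 permutes estimates", {
  g <- grid_spec(0, 16 * 30, 30, 30, 16, 16, years = 2001:2002)
  L <- make_landscape(g, seed = 27)
  tr <- truth_spec(g, L, field = field_params(200, 0.3, 0),
                   target_nests = 250, target_ebird = 60)
  fld <- sample_field(tr$field, g, seed = 28)
  pts <- simulate_points(tr, L, fld, seed = 29)
  ms <- model_spec(g, tr$specs_eco, tr$specs_obs, field_coarsen = 2,
                   sample_method = "nearest")
  ft1 <- fit_integrated(ms, L, pts, seed = 30,
                        hyper = field_params(200, 0.3, 0))
  # swap the two years in both points and dynamic layers
  pts2 <- pts
  pts2$year <- ifelse(pts$year == 2001L, 2002L, 2001L)
  pts2 <- point_table(pts2[order(seq_len(nrow(pts2))), ], grid = g)
  L2 <- L
  for (nm in names(L$dynamic))
    L2$dynamic[[nm]] <- list(y2001 = L$dynamic[[nm]]$y2002,
                             y2002 = L$dynamic[[nm]]$y2001)
  ft2 <- fit_integrated(ms, L2, pts2, seed = 30,
                        hyper = field_params(200, 0.3, 0))
  expect_equal(ft1$coef$q50, ft2$coef$q50, tolerance = 1e-4)
  expect_equal(ft1$field$y2001$values, ft2$field$y2002$values,
               tolerance = 1e-4)
})

test_that("doubling quadrature density barely moves the joint likelihood", {
  w <- small_world()
  ms_a <- model_spec(w$grid, w$truth$specs_eco, w$truth$specs_obs,
                     field_coarsen = 8, quad_type = "random",
                     quad_m = 12000, sample_method = "nearest")
  ms_b <- model_spec(w$grid, w$truth$specs_eco, w$truth$specs_obs,
                     field_coarsen = 8, quad_type = "random",
                     quad_m = 24000, sample_method = "nearest")
  fa <- fit_integrated(ms_a, w$layers, w$points, seed = 31, hyper = "none")
  fb <- fit_integrated(ms_b, w$layers, w$points, seed = 31, hyper = "none")
  expect_lt(abs(fa$diagnostics$data_loglik - fb$diagnostics$data_loglik) /
              abs(fb$diagnostics$data_loglik), 0.005)
})
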