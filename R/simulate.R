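#' Generate a seeded synthetic landscape
#'
#' Builds the full covariate stack the analysis consumes, with the spatial
#' structure the method assumes: smooth static layers (elevation-derived
#' slope, exact Euclidean distances to seeded lakes / roads / settlements /
#' trees, road density, a crop mask) and per-year dynamic layers (percent
#' surface water, vegetation index) that evolve with positive year-to-year
#' correlation. All randomness is governed by `seed`.
#'
#' @param grid `grid_spec` (square cells); its `years` drive the dynamic
#'   layers.
#' @param seed Integer seed.
#' @param recipe Optional overrides: `n_lakes`, `n_roads`,
#'   `n_settlements`, `dyn_phi` (year-to-year correlation of dynamic
#'   layers), `rho_frac` (spatial range of generated layers as a fraction
#'   of the domain diameter).
#' @return List with `static` (named `raster_layer`s: `slope`,
#'   `dist_lake`, `dist_trees`, `dist_roads`, `dist_settlements`,
#'   `road_density`, `crop`), `dynamic` (named lists of per-year layers:
#'   `percent_water`, `ndvi`), and `features` (`geo_features` for lakes,
#'   roads, settlements; binary tree raster).
#' @export
make_landscape <- function(grid, seed = 1L, recipe = list()) {
  rc <- utils::modifyList(list(n_lakes = 3L, n_roads = 4L, n_settlements = 3L,
                               dyn_phi = 0.7, rho_frac = 0.25), recipe)
  ext <- grid_extent(grid)
  W <- ext["xmax"] - ext["xmin"]; H <- ext["ymax"] - ext["ymin"]
  diam <- sqrt(W^2 + H^2)
  rho <- max(rc$rho_frac * diam, 2.5 * grid$dx)
  with_seed(seed, {
    g1 <- grid_spec(grid$x0, grid$y0, grid$dx, grid$dy, grid$nx, grid$ny, 0L)
    smooth <- function(sigma = 1) sample_field(field_params(rho, sigma, 0), g1)[[1]]

    elevation <- raster_layer(grid, 100 + 40 * smooth()$values)
    slope <- slope_degrees(elevation)

    circle_poly <- function(cx, cy, r, k = 24)
      list(cbind(cx + r * cos(seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]),
                 cy + r * sin(seq(0, 2 * pi, length.out = k + 1)[-(k + 1)])))
    lakes <- geo_features(polygons = lapply(seq_len(rc$n_lakes), function(k)
      circle_poly(stats::runif(1, ext["xmin"] + 0.1 * W, ext["xmax"] - 0.1 * W),
                  stats::runif(1, ext["ymin"] + 0.1 * H, ext["ymax"] - 0.1 * H),
                  stats::runif(1, 0.04, 0.09) * min(W, H))))

    roads <- geo_features(lines = lapply(seq_len(rc$n_roads), function(k) {
      if (stats::runif(1) < 0.5)
        cbind(c(ext["xmin"], ext["xmax"]),
              stats::runif(2, ext["ymin"], ext["ymax"]))
      else
        cbind(stats::runif(2, ext["xmin"], ext["xmax"]),
              c(ext["ymin"], ext["ymax"]))
    }))

    settlements <- geo_features(points = cbind(
      stats::runif(rc$n_settlements, ext["xmin"], ext["xmax"]),
      stats::runif(rc$n_settlements, ext["ymin"], ext["ymax"])))

    tree_field <- smooth()
    trees <- raster_layer(grid, ifelse(tree_field$values >
                                         stats::quantile(tree_field$values, 0.85), 1, 0))
    crop_field <- smooth()
    crop <- raster_layer(grid, ifelse(crop_field$values >
                                        stats::quantile(crop_field$values, 0.6), 1, 0))

    static <- list(
      slope = slope,
      dist_lake = distance_to(lakes, grid),
      dist_trees = distance_to(trees, grid),
      dist_roads = distance_to(roads, grid),
      dist_settlements = distance_to(settlements, grid),
      # the 5 km accessibility disc of the real analysis is wider than a toy
      # domain; cap it at ~15% of the domain diameter so the layer varies
      road_density = road_density(roads, grid, radius = min(5000, 0.15 * diam)),
      crop = crop)

    # dynamic layers: latent Gaussian with AR1 persistence, mapped through
    # probit-style transforms to the natural ranges
    nyr <- length(grid$years)
    gyr <- grid_spec(grid$x0, grid$y0, grid$dx, grid$dy, grid$nx, grid$ny,
                     grid$years)
    dyn_field <- function() sample_field(field_params(rho, 1, rc$dyn_phi), gyr)
    water_base <- smooth()
    wf <- dyn_field()
    percent_water <- lapply(wf, function(u)
      raster_layer(grid, 100 * stats::pnorm(0.8 * water_base$values +
                                              0.8 * u$values - 1)))
    nf <- dyn_field()
    ndvi_base <- smooth()
    ndvi <- lapply(nf, function(u)
      raster_layer(grid, stats::pnorm(0.9 * ndvi_base$values + 0.6 * u$values)))

    list(static = static,
         dynamic = list(percent_water = percent_water, ndvi = ndvi),
         features = list(lakes = lakes, roads = roads,
                         settlements = settlements, trees = trees))
  })
}

#' True generative model for recovery tests
#'
#' Couples the landscape with true ecological coefficients `beta` (on the
#' standardized design, log-intensity scale), observation coefficients
#' `delta` (thinning of the opportunistic stream: spatial accessibility
#' plus per-checklist effort marks), per-stream intercepts, and field
#' hyperparameters. Intercepts are calibrated so that the expected total
#' nest and ebird counts match the stated targets (the field's lognormal
#' mean factor `exp(sigma^2/2)` is accounted for analytically).
#'
#' Standardization constants are computed over all grid cells x years and
#' stored, so fitted designs can reuse the exact scaling of the truth.
#'
#' @param grid `grid_spec`.
#' @param layers A landscape from [make_landscape()].
#' @param beta Named vector of ecological coefficients; names must match
#'   the expanded ecological design columns.
#' @param delta Named vector: spatial observation coefficients (e.g.
#'   `road_density`) and effort-mark coefficients (`effort_distance`,
#'   `effort_duration`).
#' @param field `field_params` of the latent space-time field.
#' @param target_nests,target_ebird Expected total point counts over all
#'   years used to calibrate the intercepts.
#' @param specs_eco,specs_obs Covariate spec lists; defaults build the
#'   standard design.
#' @return Object of class `truth_spec`.
#' @export
truth_spec <- function(grid, layers,
                       beta = default_beta(),
                       delta = default_delta(),
                       field = field_params(rho = 8 * grid$dx, sigma = 0.5,
                                            phi = 0.9),
                       target_nests = 2000, target_ebird = 300,
                       specs_eco = NULL, specs_obs = NULL) {
  if (is.null(specs_eco)) {
    mu_lake <- mean(layers$static$dist_lake$values)
    specs_eco <- list(
      cov_spec("percent_water", scale = "r90", quadratic = TRUE),
      cov_spec("ndvi"),
      cov_spec("lake_exp", layer = "dist_lake", transform = "exp_distance",
               mu = mu_lake),
      cov_spec("slope"),
      cov_spec("crop", scale = "neighbor"))
  }
  if (is.null(specs_obs))
    specs_obs <- list(cov_spec("road_density", role = "observation"))
  # grid-cell designs, all years stacked (year-major), standardized jointly
  Xraw <- do.call(rbind, lapply(grid$years, function(yr)
    assemble_design(layers, specs_eco, yr)))
  stX <- standardize(Xraw)
  Zraw <- do.call(rbind, lapply(grid$years, function(yr)
    assemble_design(layers, specs_obs, yr)))
  stZ <- standardize(Zraw)
  eco_names <- colnames(stX$x)
  if (!setequal(names(beta), eco_names))
    stop("truth_spec: beta names must be ",
         paste(eco_names, collapse = ", "))
  beta <- beta[eco_names]
  spat_delta <- delta[names(delta) %in% colnames(stZ$x)]
  eff_delta <- delta[names(delta) %in% c("effort_distance", "effort_duration")]
  # intercept calibration: E[sum counts] = e^{b0} * sum exp(X beta) * area * E[e^u]
  area <- cell_area(grid)
  eta_x <- drop(stX$x %*% beta)
  M <- sum(exp(eta_x)) * area * exp(field$sigma^2 / 2)
  b0 <- log(target_nests / M)
  # thinning calibration at mean effort marks (intensity-weighted mean of the
  # spatial thinning shape)
  z_shape <- drop(stZ$x[, names(spat_delta), drop = FALSE] %*% spat_delta)
  mean_b <- sum(exp(eta_x) * exp(z_shape)) / sum(exp(eta_x))
  d0 <- log(target_ebird / target_nests) - log(mean_b)
  structure(list(grid = grid, beta = beta, delta_spatial = spat_delta,
                 delta_effort = eff_delta,
                 intercept_nest = b0, intercept_ebird = d0,
                 field = field,
                 specs_eco = specs_eco, specs_obs = specs_obs,
                 std_eco = stX[c("center", "scale")],
                 std_obs = stZ[c("center", "scale")],
                 target_nests = target_nests, target_ebird = target_ebird),
            class = "truth_spec")
}

#' @rdname truth_spec
#' @export
default_beta <- function() {
  # signs follow the published effect table; magnitudes moderated to the
  # synthetic landscape's covariate ranges (see the methods vignette)
  c(percent_water = 1.0, percent_water_sq = -0.4, ndvi = 0.4,
    lake_exp = -1.5, slope = -0.4, crop = -0.5)
}

#' @rdname truth_spec
#' @export
default_delta <- function() {
  c(road_density = 0.6, effort_distance = 0.3, effort_duration = 0.3)
}

# standardized ecological design on grid cells for one year
truth_design_eco <- function(truth, layers, year) {
  X <- assemble_design(layers, truth$specs_eco, year)
  apply_standardize(X, truth$std_eco$center, truth$std_eco$scale)
}

truth_design_obs <- function(truth, layers, year) {
  Z <- assemble_design(layers, truth$specs_obs, year)
  apply_standardize(Z, truth$std_obs$center, truth$std_obs$scale)
}

# per-cell log intensity (per m^2) for one year, given the sampled field
truth_log_intensity <- function(truth, layers, field, year) {
  X <- truth_design_eco(truth, layers, year)
  u <- raster_values_rowmajor(field[[paste0("y", year)]])
  truth$intercept_nest + drop(X %*% truth$beta) + u
}

#' Simulate both point streams from the truth
#'
#' Nest stream: per cell-year counts are Poisson with mean
#' `lambda(cell center, t) * cell area`, points placed uniformly within
#' their cell (exact for the piecewise-constant intensity the pipeline
#' operates on). Opportunistic stream: latent individuals are drawn the
#' same way and then thinned with probability
#' `min(1, exp(delta0 + Z delta + effort marks))`; retained rows carry
#' their effort metadata (log-normal distance/duration, small observer
#' counts, daytime start times).
#'
#' @param truth A `truth_spec`.
#' @param layers Landscape from [make_landscape()].
#' @param field Per-year field rasters from [sample_field()] (pass rasters
#'   of zeros for a field-free world).
#' @param seed Integer seed.
#' @param eta_cap Error guard: per-cell log intensity above this aborts
#'   with advice to rescale coefficients.
#' @return A `point_table` with both streams.
#' @export
simulate_points <- function(truth, layers, field, seed = NULL, eta_cap = 10) {
  grid <- truth$grid
  area <- cell_area(grid)
  cc <- cell_centers_xy(grid)
  with_seed(seed, {
    rows <- list()
    for (yr in grid$years) {
      eta <- truth_log_intensity(truth, layers, field, yr)
      if (any(eta + log(area) > eta_cap))
        stop("simulate_points: log cell intensity exceeds cap (",
             eta_cap, "); rescale coefficients or intercepts")
      lam_cell <- exp(eta) * area
      # nests
      n_nest <- stats::rpois(length(lam_cell), lam_cell)
      rows[[length(rows) + 1L]] <- jitter_points(grid, cc, n_nest, yr, "nest")
      # latent individuals for the opportunistic stream, then thinning
      n_lat <- stats::rpois(length(lam_cell), lam_cell)
      cand <- jitter_points(grid, cc, n_lat, yr, "ebird")
      if (nrow(cand)) {
        Z <- truth_design_obs(truth, layers, yr)
        cell <- rep(seq_along(n_lat), n_lat)
        logb <- truth$intercept_ebird +
          drop(Z[cell, , drop = FALSE] %*% truth$delta_spatial)
        eff <- draw_effort(nrow(cand))
        if ("effort_distance" %in% names(truth$delta_effort))
          logb <- logb + truth$delta_effort[["effort_distance"]] * eff$dist_std
        if ("effort_duration" %in% names(truth$delta_effort))
          logb <- logb + truth$delta_effort[["effort_duration"]] * eff$dur_std
        keep <- stats::runif(nrow(cand)) < pmin(exp(logb), 1)
        cand <- cand[keep, , drop = FALSE]
        if (nrow(cand)) {
          cand$effort_distance <- eff$distance[keep]
          cand$effort_duration <- eff$duration[keep]
          cand$n_observers <- eff$n_observers[keep]
          cand$start_time <- eff$start_time[keep]
          cand$complete <- eff$complete[keep]
          rows[[length(rows) + 1L]] <- cand
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    point_table(out, grid = grid)
  })
}

jitter_points <- function(grid, cc, counts, year, stream) {
  tot <- sum(counts)
  if (tot == 0)
    return(data.frame(x = numeric(0), y = numeric(0), year = integer(0),
                      stream = character(0), effort_distance = numeric(0),
                      effort_duration = numeric(0), n_observers = numeric(0),
                      start_time = character(0), complete = logical(0),
                      stringsAsFactors = FALSE))
  cell <- rep(seq_along(counts), counts)
  data.frame(
    x = cc[cell, 1] + stats::runif(tot, -grid$dx / 2, grid$dx / 2),
    y = cc[cell, 2] + stats::runif(tot, -grid$dy / 2, grid$dy / 2),
    year = year, stream = stream,
    effort_distance = NA_real_, effort_duration = NA_real_,
    n_observers = NA_real_, start_time = NA_character_, complete = NA,
    stringsAsFactors = FALSE)
}

# effort marks: log-normal distance/duration (standardized versions enter
# the thinning), small observer parties, daytime start times
draw_effort <- function(n) {
  ld <- stats::rnorm(n, log(1.2), 0.5)     # log km
  lt <- stats::rnorm(n, log(1.0), 0.5)     # log hours
  hrs <- stats::runif(n, 5, 20.5)
  list(distance = exp(ld), duration = exp(lt),
       dist_std = (ld - log(1.2)) / 0.5, dur_std = (lt - log(1.0)) / 0.5,
       n_observers = 1L + stats::rpois(n, 1.2),
       start_time = sprintf("%02d:%02d", floor(hrs), floor((hrs %% 1) * 60)),
       complete = stats::runif(n) < 0.8)
}

#' Build the default synthetic world
#'
#' The stated testing regime: a 64 x 64 grid of 30 m cells, 5 years, field
#' range 8 cells (240 m), sd 0.5, persistence 0.9, ~2000 nests and ~300
#' opportunistic sightings in expectation.
#'
#' @param seed Integer seed (landscape, field and points use derived
#'   sub-seeds).
#' @param nx,ny,n_years,dx World dimensions.
#' @param ... Passed to [truth_spec()] (e.g. `beta`, `field`, targets).
#' @return List with `grid`, `layers`, `truth`, `field`, `points`.
#' @export
default_world <- function(seed = 1L, nx = 64, ny = 64, n_years = 5, dx = 30,
                          ...) {
  grid <- grid_spec(0, ny * dx, dx, dx, nx, ny,
                    years = seq(2001L, length.out = n_years))
  layers <- make_landscape(grid, seed = seed)
  truth <- truth_spec(grid, layers, ...)
  field <- sample_field(truth$field, grid, seed = seed + 7L)
  pts <- simulate_points(truth, layers, field, seed = seed + 13L)
  list(grid = grid, layers = layers, truth = truth, field = field,
       points = pts)
}
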