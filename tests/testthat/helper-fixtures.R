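# shared small fixtures, built once per test run
.fx <- new.env(parent = emptyenv())

tiny_grid <- function(nx = 8, ny = 8, dx = 30, years = 2001L) {
  grid_spec(0, ny * dx, dx, dx, nx, ny, years = years)
}

# a modest synthetic world reused by several test files
small_world <- function() {
  if (is.null(.fx$world)) {
    g <- grid_spec(0, 32 * 30, 30, 30, 32, 32, years = 2001:2003)
    layers <- make_landscape(g, seed = 42)
    truth <- truth_spec(g, layers,
                        field = field_params(240, 0.4, 0.8),
                        target_nests = 600, target_ebird = 150)
    fld <- sample_field(truth$field, g, seed = 43)
    pts <- simulate_points(truth, layers, fld, seed = 44)
    .fx$world <- list(grid = g, layers = layers, truth = truth,
                      field = fld, points = pts)
  }
  .fx$world
}

zero_field <- function(grid) {
  out <- lapply(grid$years, function(y) raster_layer(grid, 0))
  names(out) <- paste0("y", grid$years)
  out
}

expect_raster_equal <- function(a, b, tol = 1e-12) {
  expect_true(same_geometry(a$grid, b$grid))
  expect_equal(a$values, b$values, tolerance = tol)
}
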