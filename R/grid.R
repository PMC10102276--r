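#' Grid geometry for raster layers
#'
#' A `grid_spec` describes a regular planar grid in projected meters with an
#' upper-left origin. Cell `(i, j)` (0-based, column `i`, row `j`) covers the
#' half-open box `[x0 + i*dx, x0 + (i+1)*dx) x (y0 - (j+1)*dy, y0 - j*dy]`:
#' a point on a shared edge belongs to the cell of higher index in x and y.
#' The grid's bottom edge is closed so every simulated point stays inside.
#' `years` is the inclusive range of modeled years.
#'
#' @param x0,y0 Easting/northing of the grid origin (upper-left corner), m.
#' @param dx,dy Cell size in m; must be positive.
#' @param nx,ny Number of columns / rows.
#' @param years Contiguous integer vector of modeled years.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(x0, y0, dx, dy, nx, ny, years = 0L) {
  if (!(dx > 0 && dy > 0)) stop("grid_spec: dx and dy must be > 0")
  if (!(nx >= 1 && ny >= 1)) stop("grid_spec: nx and ny must be >= 1")
  years <- as.integer(years)
  if (length(years) == 0L) stop("grid_spec: years must be non-empty")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("grid_spec: years must be a contiguous integer range")
  structure(
    list(x0 = x0, y0 = y0, dx = dx, dy = dy,
         nx = as.integer(nx), ny = as.integer(ny), years = years),
    class = "grid_spec")
}

#' @export
#' @method print grid_spec
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g x %g m, origin (%g, %g), years %d-%d\n",
              x$nx, x$ny, x$dx, x$dy, x$x0, x$y0, min(x$years), max(x$years)))
  invisible(x)
}

#' @rdname grid_spec
#' @param a,b Two `grid_spec` objects.
#' @export
same_geometry <- function(a, b) {
  isTRUE(all.equal(a$x0, b$x0)) && isTRUE(all.equal(a$y0, b$y0)) &&
    isTRUE(all.equal(a$dx, b$dx)) && isTRUE(all.equal(a$dy, b$dy)) &&
    a$nx == b$nx && a$ny == b$ny
}

#' Cell-center coordinates
#'
#' @param grid A `grid_spec`.
#' @return `cell_centers()` returns a list with `x` (length nx) and `y`
#'   (length ny, top row first); `cell_centers_xy()` returns an
#'   `(nx*ny) x 2` matrix in row-major (row by row from the top) order.
#' @export
cell_centers <- function(grid) {
  list(x = grid$x0 + (seq_len(grid$nx) - 0.5) * grid$dx,
       y = grid$y0 - (seq_len(grid$ny) - 0.5) * grid$dy)
}

#' @rdname cell_centers
#' @export
cell_centers_xy <- function(grid) {
  cc <- cell_centers(grid)
  cbind(x = rep(cc$x, times = grid$ny), y = rep(cc$y, each = grid$nx))
}

#' @rdname cell_centers
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$x0, xmax = grid$x0 + grid$nx * grid$dx,
    ymin = grid$y0 - grid$ny * grid$dy, ymax = grid$y0)
}

#' @rdname cell_centers
#' @export
cell_area <- function(grid) grid$dx * grid$dy

#' Locate points on the grid
#'
#' Maps planar coordinates to 0-based cell indices under the half-open cell
#' convention: a point on a shared edge belongs to the cell of higher index
#' in x and y; the grid's right edge is outside, its bottom edge inside.
#'
#' @param grid A `grid_spec`.
#' @param x,y Coordinate vectors, m.
#' @return A list with integer vectors `i` (column), `j` (row), both 0-based,
#'   and logical `inside`. Outside points get `NA` indices.
#' @export
point_to_cell <- function(grid, x, y) {
  i <- floor((x - grid$x0) / grid$dx)
  j <- floor((grid$y0 - y) / grid$dy)
  # bottom-inclusive in y: a point exactly on the grid bottom belongs to the
  # last row, consistent with the half-open [lower, upper) box in northing
  j[y == grid$y0 - grid$ny * grid$dy] <- grid$ny - 1
  inside <- i >= 0 & i < grid$nx & j >= 0 & j < grid$ny
  i[!inside] <- NA_integer_
  j[!inside] <- NA_integer_
  list(i = as.integer(i), j = as.integer(j), inside = inside)
}

#' @rdname point_to_cell
#' @export
points_inside <- function(grid, x, y) point_to_cell(grid, x, y)$inside

#' Raster layer on a grid
#'
#' A `raster_layer` couples a `grid_spec` with an `ny x nx` value matrix
#' (row 1 = northernmost row). Missing cells are `NA`; every non-missing
#' value must be finite.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric `ny x nx` matrix, or a vector of length `nx*ny` in
#'   row-major (top row first) order, or a single value to fill.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values) {
  if (length(values) == 1L) values <- rep(as.numeric(values), grid$nx * grid$ny)
  if (is.matrix(values)) {
    if (nrow(values) != grid$ny || ncol(values) != grid$nx)
      stop(sprintf("raster_layer: values must be %d x %d (ny x nx), got %d x %d",
                   grid$ny, grid$nx, nrow(values), ncol(values)))
  } else {
    if (length(values) != grid$nx * grid$ny)
      stop(sprintf("raster_layer: values length %d != nx*ny = %d",
                   length(values), grid$nx * grid$ny))
    values <- matrix(values, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  }
  storage.mode(values) <- "double"
  if (any(!is.finite(values) & !is.na(values)))
    stop("raster_layer: non-missing values must be finite")
  structure(list(grid = grid, values = values), class = "raster_layer")
}

#' @export
#' @method print raster_layer
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer> %d x %d; range [%g, %g]; %d missing\n",
              x$grid$nx, x$grid$ny,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

#' Extract raster values at cells or points
#'
#' `raster_at_cells` indexes by 0-based (i, j); `raster_at_points` samples at
#' arbitrary coordinates by bilinear interpolation of cell-center values
#' (clamped at the boundary half-cell), or by the containing cell when
#' `method = "nearest"`.
#'
#' @param r A `raster_layer`.
#' @param i,j 0-based column/row indices.
#' @export
raster_at_cells <- function(r, i, j) {
  r$values[cbind(j + 1L, i + 1L)]
}

#' @rdname raster_at_cells
#' @param x,y Point coordinates (m).
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @export
raster_at_points <- function(r, x, y, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  g <- r$grid
  if (method == "nearest") {
    pc <- point_to_cell(g, x, y)
    out <- rep(NA_real_, length(x))
    ok <- pc$inside
    out[ok] <- raster_at_cells(r, pc$i[ok], pc$j[ok])
    return(out)
  }
  cc <- cell_centers(g)
  # fractional position in cell-center coordinates, clamped to the center hull
  fx <- (x - cc$x[1]) / g$dx
  fy <- (cc$y[1] - y) / g$dy
  fx <- pmin(pmax(fx, 0), g$nx - 1)
  fy <- pmin(pmax(fy, 0), g$ny - 1)
  i0 <- pmin(floor(fx), g$nx - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), g$ny - 2); j0 <- pmax(j0, 0)
  if (g$nx == 1L) i0 <- rep(0, length(x))
  if (g$ny == 1L) j0 <- rep(0, length(y))
  tx <- fx - i0; ty <- fy - j0
  i1 <- pmin(i0 + 1, g$nx - 1); j1 <- pmin(j0 + 1, g$ny - 1)
  v00 <- raster_at_cells(r, i0, j0); v10 <- raster_at_cells(r, i1, j0)
  v01 <- raster_at_cells(r, i0, j1); v11 <- raster_at_cells(r, i1, j1)
  (1 - ty) * ((1 - tx) * v00 + tx * v10) + ty * ((1 - tx) * v01 + tx * v11)
}

#' @rdname raster_at_cells
#' @export
raster_values_rowmajor <- function(r) as.vector(t(r$values))
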