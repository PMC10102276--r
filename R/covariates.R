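#' Checklist effort filtering for the opportunistic stream
#'
#' Applies the standard best-practice effort filters to ebird-stream rows:
#' distance traveled < 5 km (strict), duration < 5 h (strict), at most 10
#' observers (inclusive), and a start time between 05:00 and 21:00
#' (inclusive at both ends). Rows of the nest stream pass through
#' untouched. Incomplete checklists are retained: every row in a point
#' table is a presence record, so completeness never removes a record.
#' Ebird rows with unparseable effort fields are dropped with a message.
#'
#' @param table A `point_table`.
#' @param max_distance,max_duration,max_observers,time_window Filter
#'   settings; defaults match the standard filters.
#' @return The filtered `point_table` (a subset of the input; idempotent).
#' @export
filter_checklists <- function(table, max_distance = 5, max_duration = 5,
                              max_observers = 10, time_window = c(5, 21)) {
  is_eb <- table$stream == "ebird"
  if (!any(is_eb)) return(table)
  hrs <- parse_clock_hours(table$start_time)
  bad_fields <- is_eb & (is.na(table$effort_distance) |
                           is.na(table$effort_duration) |
                           is.na(table$n_observers) | is.na(hrs))
  if (any(bad_fields))
    message("filter_checklists: dropped ", sum(bad_fields),
            " ebird row(s) with missing/unparseable effort fields")
  keep_eb <- !bad_fields &
    table$effort_distance < max_distance &
    table$effort_duration < max_duration &
    table$n_observers <= max_observers &
    hrs >= time_window[1] & hrs <= time_window[2]
  out <- table[!is_eb | keep_eb, , drop = FALSE]
  rownames(out) <- NULL
  out
}

parse_clock_hours <- function(s) {
  out <- rep(NA_real_, length(s))
  ok <- !is.na(s) & grepl("^\\s*\\d{1,2}:\\d{2}\\s*$", s)
  if (any(ok)) {
    parts <- do.call(rbind, strsplit(trimws(s[ok]), ":"))
    h <- as.numeric(parts[, 1]); m <- as.numeric(parts[, 2])
    val <- h + m / 60
    val[h > 23 | m > 59] <- NA_real_
    out[ok] <- val
  }
  out
}

#' Seasonal surface-water reclassification
#'
#' Collapses a sequence of per-acquisition surface-water classification
#' rasters (codes 0-4; 1 = high-confidence water) to a single binary layer:
#' a cell is 1 if any acquisition classified it as high-confidence water
#' (code exactly 1), otherwise 0; cells missing in every acquisition stay
#' missing.
#'
#' @param rasters List of co-registered `raster_layer` with values in
#'   `{0, 1, 2, 3, 4}` or `NA`.
#' @return Binary `raster_layer`.
#' @export
reclassify_dswe <- function(rasters) {
  stopifnot(length(rasters) >= 1)
  g <- rasters[[1]]$grid
  any_water <- matrix(FALSE, g$ny, g$nx)
  any_obs <- matrix(FALSE, g$ny, g$nx)
  for (r in rasters) {
    if (!same_geometry(r$grid, g)) stop("reclassify_dswe: grid mismatch")
    v <- r$values
    bad <- !is.na(v) & !(v %in% 0:4)
    if (any(bad))
      stop("reclassify_dswe: out-of-range classification code(s): ",
           paste(unique(v[bad]), collapse = ", "))
    any_water <- any_water | (!is.na(v) & v == 1)
    any_obs <- any_obs | !is.na(v)
  }
  out <- ifelse(any_water, 1, 0)
  out[!any_obs] <- NA_real_
  raster_layer(g, out)
}

#' Cellwise maximum composite
#'
#' The per-cell maximum over a sequence of co-registered rasters (e.g. a
#' growing-season maximum vegetation-index composite), ignoring missing
#' acquisitions; cells missing everywhere stay missing.
#'
#' @param rasters List of co-registered `raster_layer`.
#' @return `raster_layer` of cellwise maxima.
#' @export
max_composite <- function(rasters) {
  stopifnot(length(rasters) >= 1)
  g <- rasters[[1]]$grid
  out <- rasters[[1]]$values
  for (r in rasters[-1]) {
    if (!same_geometry(r$grid, g)) stop("max_composite: grid mismatch")
    out <- pmax(out, r$values, na.rm = TRUE)
  }
  raster_layer(g, out)
}

#' Terrain slope in degrees (Horn's method)
#'
#' Central-difference gradients from the 3x3 neighborhood with Horn's
#' weighting; edge cells use clamped (replicated) neighbors. Flat input
#' gives 0 everywhere.
#'
#' @param elevation `raster_layer` of elevations (m); square cells.
#' @return `raster_layer` of slope in degrees.
#' @export
slope_degrees <- function(elevation) {
  g <- elevation$grid
  if (g$nx < 2 || g$ny < 2)
    stop("slope_degrees: raster too small for gradients (need >= 2x2)")
  if (!isTRUE(all.equal(g$dx, g$dy))) stop("slope_degrees: square cells required")
  z <- elevation$values
  cl <- function(k, n) pmin(pmax(k, 1L), n)
  jj <- seq_len(g$ny); ii <- seq_len(g$nx)
  W <- z[, cl(ii - 1L, g$nx), drop = FALSE]; E <- z[, cl(ii + 1L, g$nx), drop = FALSE]
  N <- z[cl(jj - 1L, g$ny), , drop = FALSE]; S <- z[cl(jj + 1L, g$ny), , drop = FALSE]
  NW <- z[cl(jj - 1L, g$ny), cl(ii - 1L, g$nx), drop = FALSE]
  NE <- z[cl(jj - 1L, g$ny), cl(ii + 1L, g$nx), drop = FALSE]
  SW <- z[cl(jj + 1L, g$ny), cl(ii - 1L, g$nx), drop = FALSE]
  SE <- z[cl(jj + 1L, g$ny), cl(ii + 1L, g$nx), drop = FALSE]
  gx <- ((NE + 2 * E + SE) - (NW + 2 * W + SW)) / (8 * g$dx)
  gy <- ((SW + 2 * S + SE) - (NW + 2 * N + NE)) / (8 * g$dy)
  raster_layer(g, atan(sqrt(gx^2 + gy^2)) * 180 / pi)
}

#' Euclidean distance to features
#'
#' Exact planar distance from every cell center to the nearest feature.
#' Features are either a binary `raster_layer` (cells equal to 1 are
#' features; distances are center-to-center) or a `geo_features` object
#' (points, polylines, polygons; cells inside a polygon get 0).
#'
#' @param features Binary `raster_layer` or `geo_features`.
#' @param grid Target `grid_spec`.
#' @return `raster_layer` of distances in m.
#' @export
distance_to <- function(features, grid) {
  cc <- cell_centers_xy(grid)
  if (inherits(features, "raster_layer")) {
    if (!same_geometry(features$grid, grid))
      stop("distance_to: feature raster grid mismatch")
    fc <- cell_centers_xy(features$grid)
    sel <- !is.na(raster_values_rowmajor(features)) &
      raster_values_rowmajor(features) == 1
    if (!any(sel)) stop("distance_to: empty feature set")
    d <- min_point_distance(cc, fc[sel, , drop = FALSE])
  } else if (inherits(features, "geo_features")) {
    d <- rep(Inf, nrow(cc))
    any_feat <- FALSE
    if (!is.null(features$points) && nrow(features$points)) {
      d <- pmin(d, min_point_distance(cc, features$points)); any_feat <- TRUE
    }
    for (ln in features$lines) {
      d <- pmin(d, min_segment_distance(cc, ln)); any_feat <- TRUE
    }
    for (pg in features$polygons) {
      for (ring in pg) {
        ringc <- rbind(ring, ring[1, , drop = FALSE])
        d <- pmin(d, min_segment_distance(cc, ringc))
      }
      inside <- point_in_polygon(cc, pg)
      d[inside] <- 0
      any_feat <- TRUE
    }
    if (!any_feat) stop("distance_to: empty feature set")
  } else stop("distance_to: features must be a raster_layer or geo_features")
  raster_layer(grid, matrix(d, grid$ny, grid$nx, byrow = TRUE))
}

# min distance from each row of pts (n x 2) to the nearest row of feat (m x 2)
min_point_distance <- function(pts, feat) {
  n <- nrow(pts); d <- rep(Inf, n)
  step <- max(1L, floor(2e6 / n))
  for (k0 in seq(1L, nrow(feat), by = step)) {
    k1 <- min(k0 + step - 1L, nrow(feat))
    blk <- feat[k0:k1, , drop = FALSE]
    dd <- sqrt(outer(pts[, 1], blk[, 1], "-")^2 + outer(pts[, 2], blk[, 2], "-")^2)
    d <- pmin(d, apply(dd, 1, min))
  }
  d
}

# min distance from each point to a polyline given as vertex matrix
min_segment_distance <- function(pts, verts) {
  d <- rep(Inf, nrow(pts))
  if (nrow(verts) == 1L) return(min_point_distance(pts, verts))
  for (k in seq_len(nrow(verts) - 1L)) {
    p1 <- verts[k, ]; p2 <- verts[k + 1L, ]
    vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
    L2 <- vx^2 + vy^2
    if (L2 == 0) { d <- pmin(d, sqrt((pts[, 1] - p1[1])^2 + (pts[, 2] - p1[2])^2)); next }
    t <- ((pts[, 1] - p1[1]) * vx + (pts[, 2] - p1[2]) * vy) / L2
    t <- pmin(pmax(t, 0), 1)
    d <- pmin(d, sqrt((pts[, 1] - (p1[1] + t * vx))^2 +
                        (pts[, 2] - (p1[2] + t * vy))^2))
  }
  d
}

# even-odd test against the polygon's rings (holes flip parity)
point_in_polygon <- function(pts, rings) {
  inside <- rep(FALSE, nrow(pts))
  for (ring in rings) {
    n <- nrow(ring)
    xs <- ring[, 1]; ys <- ring[, 2]
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      kk <- j[k]
      cond <- ((ys[k] > pts[, 2]) != (ys[kk] > pts[, 2]))
      if (any(cond)) {
        xint <- xs[k] + (pts[cond, 2] - ys[k]) * (xs[kk] - xs[k]) / (ys[kk] - ys[k])
        flip <- rep(FALSE, nrow(pts)); flip[cond] <- pts[cond, 1] < xint
        inside <- xor(inside, flip)
      }
    }
  }
  inside
}

#' Saturating exponential distance transform
#'
#' `1 - exp(-d / mu)`: 0 at the feature, saturating toward 1 with
#' characteristic scale `mu` (conventionally the mean observed distance of
#' the presence points to the feature).
#'
#' @param d `raster_layer` of nonnegative distances (m), or numeric vector.
#' @param mu Scale, m; > 0.
#' @return Same shape as `d`, values in `[0, 1)`.
#' @export
exp_distance <- function(d, mu) {
  if (!(mu > 0)) stop("exp_distance: mu must be > 0")
  f <- function(v) {
    if (any(v < 0, na.rm = TRUE)) stop("exp_distance: distances must be >= 0")
    1 - exp(-v / mu)
  }
  if (inherits(d, "raster_layer")) raster_layer(d$grid, f(d$values)) else f(d)
}

#' Binary distance classification
#'
#' 1 where distance exceeds the threshold, 0 below; a distance exactly at
#' the threshold maps to 1 (fixed tie rule for the measure-zero case).
#'
#' @param d `raster_layer` of distances (m) or numeric vector.
#' @param threshold Threshold in m; > 0.
#' @return Binary layer/vector.
#' @export
binarize_distance <- function(d, threshold) {
  if (!(threshold > 0)) stop("binarize_distance: threshold must be > 0")
  f <- function(v) ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  if (inherits(d, "raster_layer")) raster_layer(d$grid, f(d$values)) else f(d)
}

MW_SCALES <- c(pixel30 = 0, neighbor = -1, r90 = 90, r150 = 150, r300 = 300,
               r750 = 750)

#' Moving-window scale summaries
#'
#' Summarizes a layer at a coarser spatial scale: `"pixel30"` is the
#' identity, `"neighbor"` averages the 8 cells adjacent to the focal cell
#' (focal excluded), and `"r<radius>"` summarizes all cells whose centers
#' lie within the given radius in meters of the focal center (inclusive,
#' focal included). `stat` is `"mean"` or `"sd"` (sample sd; used for
#' terrain roughness). Missing cells are excluded from the statistic; a
#' window with no usable cell yields missing.
#'
#' @param r `raster_layer`.
#' @param scale One of `"pixel30"`, `"neighbor"`, `"r90"`, `"r150"`,
#'   `"r300"`, `"r750"`, or a numeric radius in m.
#' @param stat `"mean"` or `"sd"`.
#' @return `raster_layer` at the same resolution.
#' @export
moving_window <- function(r, scale, stat = c("mean", "sd")) {
  stat <- match.arg(stat)
  g <- r$grid
  if (is.character(scale)) {
    if (!scale %in% names(MW_SCALES)) stop("moving_window: unknown scale ", scale)
    radius <- MW_SCALES[[scale]]
  } else radius <- as.numeric(scale)
  if (radius == 0) {
    if (stat == "sd") return(raster_layer(g, ifelse(is.na(r$values), NA_real_, 0)))
    return(r)
  }
  if (radius < 0) {  # neighbor: 8 adjacent, focal excluded
    offs <- expand.grid(di = -1:1, dj = -1:1)
    offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  } else {
    m <- floor(radius / min(g$dx, g$dy))
    offs <- expand.grid(di = -m:m, dj = -m:m)
    offs <- offs[sqrt((offs$di * g$dx)^2 + (offs$dj * g$dy)^2) <= radius, ]
  }
  z <- r$values
  s <- matrix(0, g$ny, g$nx); s2 <- matrix(0, g$ny, g$nx)
  cnt <- matrix(0, g$ny, g$nx)
  for (k in seq_len(nrow(offs))) {
    zs <- shift_matrix(z, offs$di[k], offs$dj[k])
    ok <- !is.na(zs)
    s[ok] <- s[ok] + zs[ok]
    s2[ok] <- s2[ok] + zs[ok]^2
    cnt <- cnt + ok
  }
  if (stat == "mean") {
    out <- ifelse(cnt > 0, s / cnt, NA_real_)
  } else {
    out <- ifelse(cnt > 1, (s2 - s^2 / cnt) / (cnt - 1), NA_real_)
    out <- sqrt(pmax(out, 0))
  }
  raster_layer(g, out)
}

# value of the cell offset by (di, dj) from each focal cell; NA off-grid
shift_matrix <- function(z, di, dj) {
  ny <- nrow(z); nx <- ncol(z)
  out <- matrix(NA_real_, ny, nx)
  srow <- seq_len(ny) + dj; scol <- seq_len(nx) + di
  vr <- srow >= 1 & srow <= ny; vc <- scol >= 1 & scol <= nx
  out[vr, vc] <- z[srow[vr], scol[vc], drop = FALSE]
  out
}

#' Land-cover class masks
#'
#' `crop_binary` flags pasture/hay and cultivated-crop cells; `trees_mask`
#' flags deciduous, evergreen and mixed forest. The class-code table maps
#' class names to integer codes (e.g. the national land cover database
#' codes 81/82 and 41/42/43). Any raster code absent from the table raises
#' an error listing the known codes.
#'
#' @param landcover `raster_layer` of integer class codes.
#' @param codes Named integer vector: class name -> code. Default uses the
#'   standard land-cover code set.
#' @return Binary `raster_layer`.
#' @export
crop_binary <- function(landcover, codes = default_landcover_codes()) {
  landcover_mask(landcover, codes, c("pasture_hay", "cultivated_crops"))
}

#' @rdname crop_binary
#' @export
trees_mask <- function(landcover, codes = default_landcover_codes()) {
  landcover_mask(landcover, codes,
                 c("deciduous_forest", "evergreen_forest", "mixed_forest"))
}

#' @rdname crop_binary
#' @export
default_landcover_codes <- function() {
  c(open_water = 11L, developed = 21L, barren = 31L,
    deciduous_forest = 41L, evergreen_forest = 42L, mixed_forest = 43L,
    shrub = 52L, grassland = 71L, pasture_hay = 81L, cultivated_crops = 82L,
    wetlands = 90L)
}

landcover_mask <- function(landcover, codes, target_classes) {
  v <- landcover$values
  unknown <- setdiff(unique(v[!is.na(v)]), codes)
  if (length(unknown))
    stop("landcover: unknown class code(s) ", paste(unknown, collapse = ", "),
         "; known codes: ", paste(codes, collapse = ", "))
  tgt <- codes[intersect(target_classes, names(codes))]
  out <- ifelse(is.na(v), NA_real_, as.numeric(v %in% tgt))
  raster_layer(landcover$grid, out)
}

#' Road density within a radius
#'
#' Total road length (km) intersecting the disc of the given radius around
#' each cell center, divided by the disc area (km^2). Segment-disc
#' intersection lengths are computed in closed form, so the value is exact
#' for polyline roads.
#'
#' @param roads `geo_features` whose `lines` are road polylines.
#' @param grid `grid_spec`.
#' @param radius Disc radius in m (default 5000).
#' @return `raster_layer` of densities in km/km^2.
#' @export
road_density <- function(roads, grid, radius = 5000) {
  if (!(radius > 0)) stop("road_density: radius must be > 0")
  cc <- cell_centers_xy(grid)
  total <- rep(0, nrow(cc))
  for (ln in roads$lines) {
    for (k in seq_len(nrow(ln) - 1L)) {
      p1 <- ln[k, ]; p2 <- ln[k + 1L, ]
      dxs <- p2[1] - p1[1]; dys <- p2[2] - p1[2]
      L2 <- dxs^2 + dys^2
      if (L2 == 0) next
      # |p1 + t*d - c|^2 <= R^2  is a quadratic in t
      ex <- p1[1] - cc[, 1]; ey <- p1[2] - cc[, 2]
      b <- (ex * dxs + ey * dys) / L2
      c0 <- (ex^2 + ey^2 - radius^2) / L2
      disc <- b^2 - c0
      hit <- disc > 0
      if (any(hit)) {
        sq <- sqrt(disc[hit])
        t1 <- pmin(pmax(-b[hit] - sq, 0), 1)
        t2 <- pmin(pmax(-b[hit] + sq, 0), 1)
        total[hit] <- total[hit] + (t2 - t1) * sqrt(L2)
      }
    }
  }
  dens <- (total / 1000) / (pi * (radius / 1000)^2)
  raster_layer(grid, matrix(dens, grid$ny, grid$nx, byrow = TRUE))
}

#' Column standardization with persisted constants
#'
#' Scales each design column to mean 0 and sd 1 (sample sd, n-1) over the
#' reference rows, storing `(mean, sd)` so prediction-time designs reuse
#' identical scaling.
#'
#' @param x Numeric matrix (rows = reference point set).
#' @return List with `x` (scaled matrix), `center`, `scale` (named by
#'   column).
#' @export
standardize <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- which(scl == 0 | !is.finite(scl))
  if (length(zero))
    stop("standardize: zero-variance column(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' @rdname standardize
#' @param center,scale Constants from a previous [standardize()] call.
#' @export
apply_standardize <- function(x, center, scale) {
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Collinearity screen
#'
#' Pearson correlations for all column pairs; pairs with `|r|` above the
#' threshold are flagged, except declared quadratic partners (a column and
#' its square are definitionally related). Partners are auto-detected by
#' the `<name>` / `<name>_sq` convention and may be supplemented.
#'
#' @param x Numeric design matrix with >= 2 columns.
#' @param threshold Flagging threshold on `|r|` (default 0.70).
#' @param exempt Optional list of length-2 character vectors naming exempt
#'   pairs.
#' @return data.frame with columns `a`, `b`, `r`, `flagged`.
#' @export
correlation_screen <- function(x, threshold = 0.70, exempt = list()) {
  if (ncol(x) < 2) stop("correlation_screen: need >= 2 columns")
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
  for (k in seq_along(nm))
    if (paste0(nm[k], "_sq") %in% nm)
      exempt <- c(exempt, list(c(nm[k], paste0(nm[k], "_sq"))))
  cm <- stats::cor(x)
  pr <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(a = nm[pr[, 1]], b = nm[pr[, 2]],
                    r = cm[pr], stringsAsFactors = FALSE)
  ex <- vapply(seq_len(nrow(out)), function(k)
    any(vapply(exempt, function(p) setequal(p, c(out$a[k], out$b[k])), TRUE)),
    TRUE)
  out$flagged <- abs(out$r) > threshold & !ex
  out
}

#' Covariate specification
#'
#' Describes one design column (or quadratic pair) built from a named
#' layer: the spatial summarization scale, the summary statistic, an
#' optional transform, and its role (ecological `X(s)` vs observation
#' `Z(s)`).
#'
#' @param name Column base name.
#' @param layer Name of the source layer in the layer registry.
#' @param scale Moving-window scale (see [moving_window()]).
#' @param stat `"mean"` or `"sd"` (sd only for slope-type roughness).
#' @param transform `"identity"`, `"exp_distance"`, or `"binary"`.
#' @param mu Scale for `exp_distance` (m).
#' @param threshold Threshold for `binary` (m).
#' @param quadratic If TRUE the spec expands to columns `name`, `name_sq`.
#' @param role `"ecological"` or `"observation"`.
#' @export
cov_spec <- function(name, layer = name, scale = "pixel30", stat = "mean",
                     transform = "identity", mu = NULL, threshold = NULL,
                     quadratic = FALSE, role = "ecological") {
  if (stat == "sd" && !grepl("slope", layer))
    stop("cov_spec: stat 'sd' is only used for slope-type layers")
  structure(list(name = name, layer = layer, scale = scale, stat = stat,
                 transform = transform, mu = mu, threshold = threshold,
                 quadratic = quadratic, role = role), class = "cov_spec")
}

# fetch a layer (static or per-year dynamic) from a layer registry:
# layers$static[[name]] or layers$dynamic[[name]][[paste0("y", year)]]
get_layer <- function(layers, name, year) {
  if (!is.null(layers$static[[name]])) return(layers$static[[name]])
  dyn <- layers$dynamic[[name]]
  if (!is.null(dyn)) {
    key <- paste0("y", year)
    if (is.null(dyn[[key]]))
      stop("assemble_design: dynamic layer '", name, "' has no year ", year)
    return(dyn[[key]])
  }
  stop("assemble_design: layer '", name, "' not found")
}

build_cov_layer <- function(layers, spec, year) {
  r <- get_layer(layers, spec$layer, year)
  r <- moving_window(r, spec$scale, spec$stat)
  switch(spec$transform,
         identity = r,
         exp_distance = exp_distance(r, spec$mu),
         binary = binarize_distance(r, spec$threshold),
         stop("assemble_design: unknown transform ", spec$transform))
}

#' Assemble a design matrix
#'
#' Builds one column per expanded covariate spec (quadratic specs expand to
#' the pair `name`, `name_sq`), sampling layers at point locations by
#' bilinear interpolation, or per cell (row-major) when `at` is omitted.
#' Column order follows the spec list deterministically.
#'
#' @param layers Layer registry: `list(static = ..., dynamic = ...)`.
#' @param specs List of `cov_spec`.
#' @param year Year for dynamic layers.
#' @param at Optional data.frame/matrix with columns `x`, `y`; default all
#'   grid cells.
#' @param grid Required when `at` is NULL.
#' @param method Point sampling rule: `"bilinear"` (default; GPS-grade
#'   point data on coarser rasters) or `"nearest"` (value of the containing
#'   cell; consistent with a piecewise-constant intensity at the analysis
#'   resolution).
#' @return Numeric matrix with named columns.
#' @export
assemble_design <- function(layers, specs, year, at = NULL, grid = NULL,
                            method = "bilinear") {
  cols <- list()
  for (sp in specs) {
    r <- build_cov_layer(layers, sp, year)
    v <- if (is.null(at)) raster_values_rowmajor(r)
         else raster_at_points(r, at[["x"]], at[["y"]], method = method)
    cols[[sp$name]] <- v
    if (isTRUE(sp$quadratic)) cols[[paste0(sp$name, "_sq")]] <- v^2
  }
  do.call(cbind, cols)
}
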