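#' Read and write raster layers
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`): a 5-6 line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, optional
#' `NODATA_value`) followed by `nrows` lines of values, northernmost row
#' first. The format stores square cells only. GeoTIFF is not supported in
#' this build (no GDAL-backed reader is available); `.tif` paths raise an
#' informative error.
#'
#' @param path File path ending in `.asc` (or `.txt`/`.grd` treated as ASCII).
#' @param years Optional years to attach to the returned grid (ASCII grids
#'   carry no time metadata).
#' @return `read_raster` returns a `raster_layer`; `write_raster` returns
#'   `path` invisibly. A round trip preserves geometry exactly and values to
#'   17 significant digits; NODATA cells map to `NA` and back.
#' @export
read_raster <- function(path, years = 0L) {
  if (!file.exists(path)) stop("read_raster: file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("read_raster: GeoTIFF is not supported in this build; ",
         "convert to ESRI ASCII grid (.asc)")
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      nhdr <- nhdr + 1L
    } else break
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(req, names(hdr))
  if (length(miss))
    stop("read_raster: malformed ASCII grid header, missing field: ",
         paste(miss, collapse = ", "))
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  vals <- scan(path, what = double(), skip = nhdr, quiet = TRUE,
               na.strings = "NA")
  if (length(vals) != nx * ny)
    stop(sprintf("read_raster: value count %d != ncols*nrows = %d (field ncols/nrows)",
                 length(vals), nx * ny))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  g <- grid_spec(x0 = hdr$xllcorner, y0 = hdr$yllcorner + ny * hdr$cellsize,
                 dx = hdr$cellsize, dy = hdr$cellsize, nx = nx, ny = ny,
                 years = years)
  raster_layer(g, vals)
}

#' @rdname read_raster
#' @param r A `raster_layer` to write.
#' @param nodata Sentinel written for missing cells.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("write_raster: GeoTIFF is not supported in this build; use .asc")
  if (!dir.exists(dirname(path)))
    stop("write_raster: parent directory does not exist: ", dirname(path))
  g <- r$grid
  if (!isTRUE(all.equal(g$dx, g$dy)))
    stop("write_raster: ASCII grid requires square cells (dx == dy); field dx/dy")
  v <- r$values
  if (any(v == nodata, na.rm = TRUE))
    stop("write_raster: data contain the nodata sentinel ", nodata)
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$nx),
    sprintf("nrows %d", g$ny),
    sprintf("xllcorner %.17g", g$x0),
    sprintf("yllcorner %.17g", g$y0 - g$ny * g$dy),
    sprintf("cellsize %.17g", g$dx),
    sprintf("NODATA_value %.17g", nodata)), con)
  for (jj in seq_len(g$ny))
    writeLines(paste(sprintf("%.17g", v[jj, ]), collapse = " "), con)
  invisible(path)
}

POINT_COLUMNS <- c("x", "y", "year", "stream", "effort_distance",
                   "effort_duration", "n_observers", "start_time", "complete")
EFFORT_COLUMNS <- c("effort_distance", "effort_duration", "n_observers",
                    "start_time")

#' Presence point tables
#'
#' A point table is a data.frame of presence records with columns `x`, `y`
#' (m), `year`, `stream` (`"nest"` or `"ebird"`), and — for the ebird stream
#' only — effort metadata: `effort_distance` (km), `effort_duration` (h),
#' `n_observers`, `start_time` (`"HH:MM"`), `complete` (logical). Nest rows
#' must have all effort fields `NA`; ebird rows must have them populated.
#'
#' @param df A data.frame with at least `x`, `y`, `year`, `stream`.
#' @param grid Optional `grid_spec`; points are checked against its extent.
#' @param allow_holdout_years Allow years outside `grid$years` (used for
#'   out-of-sample evaluation data).
#' @return A validated data.frame of class `point_table`.
#' @export
point_table <- function(df, grid = NULL, allow_holdout_years = TRUE) {
  mandatory <- c("x", "y", "year", "stream")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("point_table: missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (cn in setdiff(POINT_COLUMNS, names(df))) {
    df[[cn]] <- if (cn == "complete") NA else
      if (cn == "start_time") NA_character_ else NA_real_
  }
  df <- df[, POINT_COLUMNS, drop = FALSE]
  df$year <- as.integer(df$year)
  df$stream <- as.character(df$stream)
  bad <- which(!df$stream %in% c("nest", "ebird"))
  if (length(bad))
    stop("point_table: invalid stream value in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  is_eb <- df$stream == "ebird"
  for (cn in EFFORT_COLUMNS) {
    bad <- which(!is_eb & !is.na(df[[cn]]))
    if (length(bad))
      stop("point_table: nest row(s) carry effort field ", cn, ": row ",
           paste(utils::head(bad, 5), collapse = ", "))
    bad <- which(is_eb & is.na(df[[cn]]))
    if (length(bad))
      stop("point_table: ebird row(s) missing effort field ", cn, ": row ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(grid)) {
    out <- which(!points_inside(grid, df$x, df$y))
    if (length(out))
      stop("point_table: point(s) outside grid extent in row(s) ",
           paste(utils::head(out, 5), collapse = ", "))
    if (!allow_holdout_years) {
      out <- which(!df$year %in% grid$years)
      if (length(out))
        stop("point_table: year outside grid years in row(s) ",
             paste(utils::head(out, 5), collapse = ", "))
    }
  }
  class(df) <- c("point_table", "data.frame")
  df
}

#' @rdname point_table
#' @param path CSV file path.
#' @export
read_points <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("read_points: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if ("complete" %in% names(df)) df$complete <- as.logical(df$complete)
  point_table(df, grid = grid)
}

#' @rdname point_table
#' @param table A `point_table`.
#' @export
write_points <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read vector features from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection (or bare geometry) into a flat
#' `geo_features` structure: a matrix of points, a list of line coordinate
#' matrices, and a list of polygons (each a list of rings, outer ring
#' first). Coordinates are planar meters; no CRS handling is performed and
#' any `crs` member is carried through opaquely.
#'
#' @param path GeoJSON file path.
#' @return A list of class `geo_features` with elements `points` (n x 2
#'   matrix), `lines` (list of m x 2 matrices), `polygons` (list of lists of
#'   rings), `crs` (opaque, possibly NULL).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- geo_features()
  feats$crs <- gj$crs
  add_geom <- function(f, geom) {
    if (is.null(geom) || is.null(geom$type)) return(f)
    cm <- function(c2) matrix(unlist(c2), ncol = 2, byrow = TRUE)
    switch(geom$type,
      Point = { f$points <- rbind(f$points, unlist(geom$coordinates)[1:2]) },
      MultiPoint = { f$points <- rbind(f$points, cm(geom$coordinates)) },
      LineString = { f$lines <- c(f$lines, list(cm(geom$coordinates))) },
      MultiLineString = {
        f$lines <- c(f$lines, lapply(geom$coordinates, cm)) },
      Polygon = { f$polygons <- c(f$polygons, list(lapply(geom$coordinates, cm))) },
      MultiPolygon = {
        f$polygons <- c(f$polygons,
                        lapply(geom$coordinates, function(p) lapply(p, cm))) },
      GeometryCollection = {
        for (g2 in geom$geometries) f <- add_geom(f, g2) },
      stop("read_geojson: unsupported geometry type: ", geom$type))
    f
  }
  if (identical(gj$type, "FeatureCollection")) {
    for (ft in gj$features) feats <- add_geom(feats, ft$geometry)
  } else if (identical(gj$type, "Feature")) {
    feats <- add_geom(feats, gj$geometry)
  } else {
    feats <- add_geom(feats, gj)
  }
  feats
}

#' @rdname read_geojson
#' @param points Optional n x 2 matrix of point features.
#' @param lines Optional list of m x 2 line coordinate matrices.
#' @param polygons Optional list of polygons (lists of ring matrices).
#' @export
geo_features <- function(points = NULL, lines = list(), polygons = list()) {
  structure(list(points = points, lines = lines, polygons = polygons,
                 crs = NULL),
            class = "geo_features")
}

#' @rdname read_geojson
#' @param feats A `geo_features` object to serialize.
#' @export
write_geojson <- function(feats, path) {
  geom <- list()
  if (!is.null(feats$points) && nrow(feats$points))
    geom <- c(geom, lapply(seq_len(nrow(feats$points)), function(k)
      list(type = "Point", coordinates = as.numeric(feats$points[k, ]))))
  geom <- c(geom, lapply(feats$lines, function(m)
    list(type = "LineString",
         coordinates = lapply(seq_len(nrow(m)), function(k) as.numeric(m[k, ])))))
  geom <- c(geom, lapply(feats$polygons, function(p)
    list(type = "Polygon",
         coordinates = lapply(p, function(m)
           lapply(seq_len(nrow(m)), function(k) as.numeric(m[k, ]))))))
  fc <- list(type = "FeatureCollection",
             features = lapply(geom, function(g)
               list(type = "Feature", properties = NULL, geometry = g)))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
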