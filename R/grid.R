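#' Regular longitude/latitude grid
#'
#' All rasters in the package live on regular WGS84 grids with square cells
#' and the half-open cell convention: cell (i, j) covers
#' \code{[west + (i-1)*d, west + i*d)} in longitude and
#' \code{[south + (j-1)*d, south + j*d)} in latitude, with row \code{j = 1}
#' at the south. The default analysis resolution is 0.25 degrees.
#'
#' @param lon_min,lon_max,lat_min,lat_max extent in decimal degrees.
#' @param cell_size_deg cell edge in degrees; must divide both extents exactly.
#' @return a \code{dg_grid} object.
#' @export
dg_grid <- function(lon_min, lon_max, lat_min, lat_max, cell_size_deg = 0.25) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, cell_size_deg > 0)
  nx <- (lon_max - lon_min) / cell_size_deg
  ny <- (lat_max - lat_min) / cell_size_deg
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8) {
    stop("cell_size_deg must divide the extent into a whole number of cells")
  }
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         cell_size_deg = cell_size_deg,
         nx = as.integer(round(nx)), ny = as.integer(round(ny))),
    class = "dg_grid")
}

#' @export
print.dg_grid <- function(x, ...) {
  cat(sprintf("<dg_grid %dx%d cells of %g deg, lon [%g, %g), lat [%g, %g)>\n",
              x$nx, x$ny, x$cell_size_deg,
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Raster on a dg_grid
#'
#' A thin wrapper around a numeric matrix: \code{values[j, i]} is the value
#' of cell column \code{i} (west to east), row \code{j} (south to north).
#' Missing cells are \code{NA}.
#'
#' @param grid a \code{dg_grid}.
#' @param values numeric matrix (\code{ny} rows by \code{nx} cols), or a
#'   single number recycled to a constant field.
#' @return a \code{dg_raster}.
#' @export
dg_raster <- function(grid, values = NA_real_) {
  stopifnot(inherits(grid, "dg_grid"))
  if (length(values) == 1) values <- matrix(values, grid$ny, grid$nx)
  stopifnot(is.matrix(values), nrow(values) == grid$ny, ncol(values) == grid$nx)
  structure(list(grid = grid, values = values), class = "dg_raster")
}

#' @export
print.dg_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<dg_raster %dx%d, %d non-missing, range [%s, %s]>\n",
              x$grid$nx, x$grid$ny, length(v),
              if (length(v)) signif(min(v), 4) else "NA",
              if (length(v)) signif(max(v), 4) else "NA"))
  invisible(x)
}

same_geometry <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  isTRUE(all.equal(unclass(ga)[c("lon_min", "lat_min", "cell_size_deg")],
                   unclass(gb)[c("lon_min", "lat_min", "cell_size_deg")],
                   tolerance = 1e-9)) && ga$nx == gb$nx && ga$ny == gb$ny
}

#' Cell indices of points
#'
#' Half-open convention: a point exactly on a cell's west or south edge
#' belongs to that cell; points on the east/north extent edge are outside.
#'
#' @param grid a \code{dg_grid}.
#' @param lon,lat coordinate vectors (degrees).
#' @param strict error if any point falls outside the extent (default TRUE);
#'   otherwise outside points get NA indices.
#' @return data.frame with integer columns \code{ix}, \code{iy} and the
#'   linearised \code{cell} id \code{(iy - 1) * nx + ix}.
#' @export
cell_of <- function(grid, lon, lat, strict = TRUE) {
  d <- grid$cell_size_deg
  ix <- floor((lon - grid$lon_min) / d) + 1L
  iy <- floor((lat - grid$lat_min) / d) + 1L
  bad <- ix < 1L | ix > grid$nx | iy < 1L | iy > grid$ny
  if (any(bad, na.rm = TRUE)) {
    if (strict) {
      i <- which(bad)[1]
      stop(sprintf("point (%g, %g) outside grid extent", lon[i], lat[i]))
    }
    ix[bad] <- NA_integer_; iy[bad] <- NA_integer_
  }
  data.frame(ix = as.integer(ix), iy = as.integer(iy),
             cell = (as.integer(iy) - 1L) * grid$nx + as.integer(ix))
}

#' Cell-centre coordinates
#'
#' @param grid a \code{dg_grid}.
#' @param ix,iy column/row indices; defaults give every cell (column-major:
#'   ix varies fastest).
#' @return data.frame with \code{lon}, \code{lat} of centres.
#' @export
cell_centers <- function(grid, ix = NULL, iy = NULL) {
  if (is.null(ix)) {
    ix <- rep(seq_len(grid$nx), times = grid$ny)
    iy <- rep(seq_len(grid$ny), each = grid$nx)
  }
  d <- grid$cell_size_deg
  data.frame(lon = grid$lon_min + (ix - 0.5) * d,
             lat = grid$lat_min + (iy - 0.5) * d)
}

#' Look up raster values at points (no resampling)
#' @param r a \code{dg_raster}.
#' @param lon,lat coordinates.
#' @return value of the containing cell; NA for missing cells. Errors for
#'   points outside the extent.
#' @export
raster_at <- function(r, lon, lat) {
  idx <- cell_of(r$grid, lon, lat)
  r$values[cbind(idx$iy, idx$ix)]
}

#' Read/write rasters as ESRI ASCII grid
#'
#' Plain-text single-band raster format (north-up, square cells, EPSG:4326
#' by package convention). Used for every raster the pipeline writes so all
#' artefacts stay human-readable text.
#'
#' @param r a \code{dg_raster}.
#' @param path file path (conventionally \code{.asc}).
#' @param nodata value standing for missing cells on disk.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  g <- r$grid
  hdr <- c(sprintf("ncols %d", g$nx),
           sprintf("nrows %d", g$ny),
           sprintf("xllcorner %.10g", g$lon_min),
           sprintf("yllcorner %.10g", g$lat_min),
           sprintf("cellsize %.10g", g$cell_size_deg),
           sprintf("NODATA_value %g", nodata))
  v <- r$values
  v[is.na(v)] <- nodata
  rows <- apply(v[rev(seq_len(g$ny)), , drop = FALSE], 1,
                function(x) paste(format(x, digits = 15, trim = TRUE,
                                         scientific = FALSE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- tolower(key)
  nx <- as.integer(val[["ncols"]]); ny <- as.integer(val[["nrows"]])
  g <- dg_grid(val[["xllcorner"]], val[["xllcorner"]] + nx * val[["cellsize"]],
               val[["yllcorner"]], val[["yllcorner"]] + ny * val[["cellsize"]],
               val[["cellsize"]])
  num <- scan(text = paste(ln[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(num) == nx * ny)
  m <- matrix(num, nrow = ny, ncol = nx, byrow = TRUE)[rev(seq_len(ny)), , drop = FALSE]
  m[m == val[["nodata_value"]]] <- NA_real_
  dg_raster(g, m)
}
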