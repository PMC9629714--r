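# Satellite reception quality: observed positions/vessel/day per grid cell
# and device class, and a finer predicted surface interpolated with a
# thin-plate-spline radial basis function (exact interpolation, smoothing 0).

#' Observed reception quality per grid cell
#'
#' Reception quality is the average number of AIS positions received per
#' vessel per day. Each vessel-day is attributed to the cell containing that
#' vessel's daily mean position; the cell value is total messages divided by
#' total vessel-days. Cells with zero vessel-days are missing, not zero.
#'
#' @param messages message table (vessel_id, timestamp, lon, lat,
#'   device_class, ...).
#' @param cell_size_deg observed-map resolution (default 1 degree).
#' @param device_class "A" or "B"; only that class's messages enter the
#'   numerator and denominator.
#' @param extent optional c(lon_min, lon_max, lat_min, lat_max); defaults to
#'   the message bounding box snapped outward to whole cells.
#' @return a \code{reception_grid}: \code{dg_raster} plus a \code{support}
#'   raster of vessel-days and fields \code{device_class}, \code{kind}.
#' @export
observed_reception <- function(messages, cell_size_deg = 1,
                               device_class = c("A", "B"),
                               extent = NULL) {
  dc <- match.arg(device_class)
  keep <- messages$device_class == dc
  m <- data.table::as.data.table(messages)[which(keep)]
  if (nrow(m) == 0) stop("no messages for device class ", dc)
  m[, day := as.integer(floor(as.numeric(timestamp) / 86400))]
  vd <- m[, .(n_msg = .N, lon = mean(lon), lat = mean(lat)),
          by = .(vessel_id, day)]
  if (is.null(extent)) {
    extent <- c(floor(min(vd$lon) / cell_size_deg) * cell_size_deg,
                ceiling((max(vd$lon) + 1e-9) / cell_size_deg) * cell_size_deg,
                floor(min(vd$lat) / cell_size_deg) * cell_size_deg,
                ceiling((max(vd$lat) + 1e-9) / cell_size_deg) * cell_size_deg)
  }
  grid <- dg_grid(extent[1], extent[2], extent[3], extent[4], cell_size_deg)
  idx <- cell_of(grid, vd$lon, vd$lat)
  vd[, c("ix", "iy") := list(idx$ix, idx$iy)]
  agg <- vd[, .(msgs = sum(n_msg), vdays = .N), by = .(ix, iy)]
  vals <- matrix(NA_real_, grid$ny, grid$nx)
  supp <- matrix(0, grid$ny, grid$nx)
  vals[cbind(agg$iy, agg$ix)] <- agg$msgs / agg$vdays
  supp[cbind(agg$iy, agg$ix)] <- agg$vdays
  structure(list(grid = grid, values = vals, support = supp,
                 device_class = dc, kind = "observed"),
            class = c("reception_grid", "dg_raster"))
}

#' Evaluate the reception interpolant at arbitrary points
#'
#' Fits the same exact thin-plate-spline surface as
#' \code{predict_reception} and evaluates it at the given coordinates,
#' without rasterisation or clamping — at an observed cell centre the
#' result equals the observed value (smoothing 0).
#'
#' @param observed a \code{reception_grid} of kind "observed".
#' @param lon,lat evaluation points (degrees).
#' @return interpolated positions/day at the points.
#' @export
interpolate_reception <- function(observed, lon, lat) {
  stopifnot(inherits(observed, "reception_grid"), observed$kind == "observed")
  ok <- which(!is.na(observed$values), arr.ind = TRUE)
  if (nrow(ok) < 4) stop("need >= 4 non-missing observed cells, have ", nrow(ok))
  cc <- cell_centers(observed$grid, ix = ok[, 2], iy = ok[, 1])
  fit <- tps_fit(cc$lon, cc$lat, observed$values[ok])
  tps_predict(fit, lon, lat)
}

# Thin-plate-spline RBF with appended linear polynomial, smoothing 0.
# Kernel phi(r) = r^2 log r (phi(0) = 0); exact at the data sites and
# reproduces affine functions, so adding a constant to the data adds the
# same constant to the surface.
tps_fit <- function(x, y, v) {
  n <- length(v)
  if (n < 4) stop("thin-plate interpolation needs at least 4 observed cells")
  if (any(!is.finite(v))) stop("non-finite observed reception values")
  r <- sqrt(outer(x, x, `-`)^2 + outer(y, y, `-`)^2)
  K <- ifelse(r > 0, r^2 * log(r), 0)
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(v, rep(0, 3)))
  list(x = x, y = y, w = sol[seq_len(n)], a = sol[n + 1:3])
}

tps_predict <- function(fit, px, py) {
  r <- sqrt(outer(px, fit$x, `-`)^2 + outer(py, fit$y, `-`)^2)
  K <- ifelse(r > 0, r^2 * log(r), 0)
  as.vector(K %*% fit$w) + fit$a[1] + fit$a[2] * px + fit$a[3] * py
}

#' Predict reception on a finer grid by RBF interpolation
#'
#' Fits an exact (smoothing 0) thin-plate-spline radial basis function with
#' a linear polynomial term through the non-missing observed cell-centre
#' values and evaluates it at the target cell centres. Negative interpolants
#' are clamped to 0.
#'
#' @param observed a \code{reception_grid} from \code{observed_reception}.
#' @param target_cell_size_deg predicted-map resolution (default 0.25).
#' @return a \code{reception_grid} with \code{kind = "predicted"} on the
#'   same extent at the target resolution.
#' @export
predict_reception <- function(observed, target_cell_size_deg = 0.25) {
  stopifnot(inherits(observed, "reception_grid"), observed$kind == "observed")
  g <- observed$grid
  ok <- which(!is.na(observed$values), arr.ind = TRUE)
  if (nrow(ok) < 4) stop("need >= 4 non-missing observed cells, have ", nrow(ok))
  cc <- cell_centers(g, ix = ok[, 2], iy = ok[, 1])
  fit <- tps_fit(cc$lon, cc$lat, observed$values[ok])
  tg <- dg_grid(g$lon_min, g$lon_max, g$lat_min, g$lat_max,
                target_cell_size_deg)
  tc <- cell_centers(tg)
  pred <- pmax(tps_predict(fit, tc$lon, tc$lat), 0)
  structure(list(grid = tg,
                 values = matrix(pred, tg$ny, tg$nx, byrow = TRUE),
                 support = NULL, device_class = observed$device_class,
                 kind = "predicted"),
            class = c("reception_grid", "dg_raster"))
}

#' Reception at a point
#'
#' Value of the cell containing the point (half-open cell convention, no
#' resampling). Errors for points outside the extent; missing cells return
#' NA.
#'
#' @param grid a \code{reception_grid} (or any \code{dg_raster}).
#' @param lon,lat coordinates (degrees).
#' @return positions/day.
#' @export
reception_at <- function(grid, lon, lat) {
  raster_at(grid, lon, lat)
}
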