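# Spatial allocation of hidden time: distribute each suspected disabling
# event's duration (capped at 2 weeks = 336 h for the lower bound) onto the
# quarter-degree grid, by linear great-circle interpolation or by a
# rasterized-probability method (speed-feasibility ellipse weighted by an
# activity prior), plus broadcast-activity rasters and the fraction of
# activity obscured.

#' Allocate a gap's hidden time along the great-circle track
#'
#' The segment from start to end position is traversed at constant speed;
#' \code{min(duration_h, cap_h)} hours are distributed to cells in
#' proportion to the arc length falling in each cell (computed by sampling
#' the arc at \code{step_deg} spacing and binning). Identical endpoints put
#' all time in the containing cell; near-antipodal endpoints (undefined
#' great circle) fall back to the start cell with a warning.
#'
#' @param gap one gap event (list/row with start_lon/lat, end_lon/lat,
#'   duration_h).
#' @param grid target \code{dg_grid}.
#' @param cap_h cap on attributed hours (default 336 = 2 weeks; Inf for
#'   uncapped).
#' @param step_deg arc sampling step (default 0.01 degrees).
#' @return data.frame with columns \code{cell} (linear index) and
#'   \code{hours}; hours sum to min(duration_h, cap_h).
#' @export
allocate_linear <- function(gap, grid, cap_h = 336, step_deg = 0.01) {
  tt <- min(gap$duration_h, cap_h)
  same_pt <- abs(gap$start_lon - gap$end_lon) < 1e-12 &&
    abs(gap$start_lat - gap$end_lat) < 1e-12
  ang_deg <- gc_dist_km(gap$start_lon, gap$start_lat, gap$end_lon,
                        gap$end_lat) / (EARTH_RADIUS_KM * pi / 180)
  if (!same_pt && ang_deg > 179.5) {
    warning("near-antipodal gap endpoints; allocating all time to start cell")
    same_pt <- TRUE
  }
  if (same_pt) {
    cl <- cell_of(grid, gap$start_lon, gap$start_lat)$cell
    return(data.frame(cell = cl, hours = tt))
  }
  p <- gc_sample(gap$start_lon, gap$start_lat, gap$end_lon, gap$end_lat,
                 step_deg = step_deg)
  # bin equal-arc segments by their midpoints (2nd-order accurate)
  n <- nrow(p)
  mid_lon <- (p[-n, "lon"] + p[-1, "lon"]) / 2
  mid_lat <- (p[-n, "lat"] + p[-1, "lat"]) / 2
  cl <- cell_of(grid, mid_lon, mid_lat)$cell
  cnt <- table(cl)
  data.frame(cell = as.integer(names(cnt)),
             hours = tt * as.numeric(cnt) / length(cl))
}

#' Allocation configuration
#' @param cap_h hours cap per event (336 = 2 weeks; Inf = uncapped).
#' @param max_speed_knots vessel speed bound for the probabilistic method.
#' @param prior optional activity \code{dg_raster} used as the probability
#'   weight (uniform when NULL).
#' @param bridge_scale_nmi e-folding scale (nautical miles) of the detour
#'   decay in the probabilistic method: a cell requiring detour D beyond the
#'   direct start-end distance is down-weighted by exp(-D / scale), the
#'   discrete analogue of a movement bridge between known endpoints. Inf
#'   gives uniform weight over the whole feasibility ellipse.
#' @export
allocation_config <- function(cap_h = 336, max_speed_knots = 10, prior = NULL,
                              bridge_scale_nmi = 30) {
  stopifnot(cap_h > 0, max_speed_knots > 0, bridge_scale_nmi > 0)
  list(cap_h = cap_h, max_speed_knots = max_speed_knots, prior = prior,
       bridge_scale_nmi = bridge_scale_nmi)
}

#' Allocate a gap's hidden time by the rasterized-probability method
#'
#' The feasible set is every cell whose centre c satisfies
#' d(start, c) + d(c, end) <= max_speed_knots x duration_h (great-circle
#' nautical miles) -- the spatial ellipse a vessel bounded by that speed
#' could have visited. Attributed time \code{min(duration_h, cap_h)} is
#' split over the feasible set proportionally to
#' \code{(prior + 1e-9) * exp(-detour / bridge_scale_nmi)}, where detour is
#' the extra distance d(start, c) + d(c, end) - d(start, end): a bridge
#' between the known endpoints that concentrates probability near the
#' direct route while never leaving the speed-feasible set (uniform prior
#' when none is supplied). An empty feasible set reduces to the start cell.
#'
#' @inheritParams allocate_linear
#' @param config an \code{allocation_config}.
#' @return data.frame with \code{cell}, \code{hours}.
#' @export
allocate_probabilistic <- function(gap, grid, config = allocation_config()) {
  tt <- min(gap$duration_h, config$cap_h)
  cc <- cell_centers(grid)
  reach_nmi <- config$max_speed_knots * gap$duration_h
  d_tot <- gc_dist_nmi(gap$start_lon, gap$start_lat, cc$lon, cc$lat) +
    gc_dist_nmi(cc$lon, cc$lat, gap$end_lon, gap$end_lat)
  feas <- which(d_tot <= reach_nmi)
  if (!length(feas)) {
    cl <- cell_of(grid, gap$start_lon, gap$start_lat)$cell
    return(data.frame(cell = cl, hours = tt))
  }
  if (is.null(config$prior)) {
    w <- rep(1, length(feas))
  } else {
    if (!same_geometry(config$prior, list(grid = grid))) {
      stop("prior raster geometry does not match the allocation grid")
    }
    pv <- as.vector(t(config$prior$values))[feas]  # linear index order
    pv[is.na(pv)] <- 0
    w <- pv + 1e-9
  }
  d_direct <- gc_dist_nmi(gap$start_lon, gap$start_lat, gap$end_lon,
                          gap$end_lat)
  if (is.finite(config$bridge_scale_nmi)) {
    w <- w * exp(-(d_tot[feas] - d_direct) / config$bridge_scale_nmi)
  }
  data.frame(cell = feas, hours = tt * w / sum(w))
}

#' Allocate many gaps onto a raster
#'
#' @param gaps classified gap table; only rows with classification
#'   \code{suspected_disabling} are allocated.
#' @param grid target grid.
#' @param method "linear" or "probabilistic".
#' @param config an \code{allocation_config}.
#' @return a \code{dg_raster} of hours (0 where nothing allocated).
#' @export
allocate_gaps <- function(gaps, grid, method = c("linear", "probabilistic"),
                          config = allocation_config()) {
  method <- match.arg(method)
  g <- data.table::as.data.table(gaps)
  g <- g[g$classification == "suspected_disabling"]
  acc <- numeric(grid$nx * grid$ny)
  for (i in seq_len(nrow(g))) {
    inc <- if (method == "linear") {
      allocate_linear(g[i], grid, cap_h = config$cap_h)
    } else {
      allocate_probabilistic(g[i], grid, config)
    }
    acc[inc$cell] <- acc[inc$cell] + inc$hours
  }
  dg_raster(grid, matrix(acc, grid$ny, grid$nx, byrow = TRUE))
}

#' Suspected-disabling event counts per cell
#'
#' Counts suspected disabling events by the grid cell of their start
#' position. This is the presence layer for the driver models: a presence
#' is a cell with at least one event, not a cell merely crossed by an
#' allocated track.
#'
#' @param gaps classified gap table.
#' @param grid target grid.
#' @return \code{dg_raster} of event counts.
#' @export
event_raster <- function(gaps, grid) {
  g <- data.table::as.data.table(gaps)
  g <- g[g$classification == "suspected_disabling"]
  acc <- numeric(grid$nx * grid$ny)
  if (nrow(g)) {
    cl <- cell_of(grid, g$start_lon, g$start_lat, strict = FALSE)$cell
    tb <- table(cl[!is.na(cl)])
    acc[as.integer(names(tb))] <- as.numeric(tb)
  }
  dg_raster(grid, matrix(acc, grid$ny, grid$nx, byrow = TRUE))
}

#' Broadcast-activity hours per cell
#'
#' Time between consecutive pings of one vessel is split half/half between
#' the two ping cells when the interval is shorter than \code{max_interval_h}
#' (default 12 h); longer intervals are gap candidates and contribute
#' nothing.
#'
#' @param messages message table.
#' @param grid target grid.
#' @param stratum optional column name ("gear" or "flag"); when given, a
#'   named list of rasters per stratum value is returned.
#' @param fishing_only keep only messages labelled is_fishing.
#' @param max_interval_h interval ceiling in hours.
#' @return a \code{dg_raster}, or a named list of them when stratified.
#' @export
activity_hours <- function(messages, grid, stratum = NULL,
                           fishing_only = FALSE, max_interval_h = 12) {
  m <- data.table::as.data.table(messages)
  if (fishing_only) m <- m[m$is_fishing == TRUE]
  if (!is.null(stratum)) {
    vals <- unique(m[[stratum]])
    out <- lapply(vals, function(s) {
      activity_hours(m[m[[stratum]] == s], grid, NULL, FALSE, max_interval_h)
    })
    names(out) <- vals
    return(out)
  }
  data.table::setorderv(m, c("vessel_id", "timestamp"))
  m[, t_num := as.numeric(timestamp)]
  acc <- numeric(grid$nx * grid$ny)
  if (nrow(m) >= 2) {
    same_v <- m$vessel_id[-1] == m$vessel_id[-nrow(m)]
    dt_h <- diff(m$t_num) / 3600
    ok <- same_v & dt_h < max_interval_h
    i1 <- which(ok); i2 <- i1 + 1L
    c1 <- cell_of(grid, m$lon[i1], m$lat[i1], strict = FALSE)$cell
    c2 <- cell_of(grid, m$lon[i2], m$lat[i2], strict = FALSE)$cell
    half <- dt_h[ok] / 2
    keep1 <- !is.na(c1); keep2 <- !is.na(c2)
    t1 <- tapply(half[keep1], c1[keep1], sum)
    t2 <- tapply(half[keep2], c2[keep2], sum)
    acc[as.integer(names(t1))] <- acc[as.integer(names(t1))] + as.numeric(t1)
    acc[as.integer(names(t2))] <- acc[as.integer(names(t2))] + as.numeric(t2)
  }
  dg_raster(grid, matrix(acc, grid$ny, grid$nx, byrow = TRUE))
}

#' Fraction of activity obscured by disabling
#'
#' Per cell, disabling hours / (activity hours + disabling hours): the
#' denominator is total time at sea including the hidden time. Missing
#' where the denominator is zero.
#'
#' @param disabling,activity \code{dg_raster}s of hours on one geometry.
#' @return \code{dg_raster} with values in [0, 1].
#' @export
fraction_obscured <- function(disabling, activity) {
  if (!same_geometry(disabling, activity)) stop("raster geometry mismatch")
  den <- activity$values + disabling$values
  f <- ifelse(den > 0, disabling$values / den, NA_real_)
  dg_raster(disabling$grid, f)
}

#' Disabling hot spots
#'
#' Cells with both high activity and a high obscured fraction, labelled by
#' rook-adjacent (edge-sharing, not corner-sharing) connected components.
#'
#' @param fraction,activity \code{dg_raster}s on one geometry.
#' @param f_min,a_min inclusive thresholds on fraction and activity hours.
#' @return data.frame: ix, iy, cell, fraction, activity, component.
#' @export
hotspots <- function(fraction, activity, f_min, a_min) {
  if (!same_geometry(fraction, activity)) stop("raster geometry mismatch")
  g <- fraction$grid
  sel <- !is.na(fraction$values) & fraction$values >= f_min &
    !is.na(activity$values) & activity$values >= a_min
  idx <- which(sel, arr.ind = TRUE)   # rows: iy, ix
  if (!nrow(idx)) {
    return(data.frame(ix = integer(), iy = integer(), cell = integer(),
                      fraction = numeric(), activity = numeric(),
                      component = integer()))
  }
  comp <- matrix(0L, g$ny, g$nx)
  next_id <- 0L
  for (r in seq_len(nrow(idx))) {
    if (comp[idx[r, 1], idx[r, 2]] > 0L) next
    next_id <- next_id + 1L
    queue <- list(idx[r, ])
    comp[idx[r, 1], idx[r, 2]] <- next_id
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (dd in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        ny_ <- cur[1] + dd[1]; nx_ <- cur[2] + dd[2]
        if (ny_ >= 1L && ny_ <= g$ny && nx_ >= 1L && nx_ <= g$nx &&
            sel[ny_, nx_] && comp[ny_, nx_] == 0L) {
          comp[ny_, nx_] <- next_id
          queue[[length(queue) + 1L]] <- c(ny_, nx_)
        }
      }
    }
  }
  data.frame(ix = idx[, 2], iy = idx[, 1],
             cell = (idx[, 1] - 1L) * g$nx + idx[, 2],
             fraction = fraction$values[idx],
             activity = activity$values[idx],
             component = comp[idx])
}

#' Summary of the disabling dataset by gear and flag
#'
#' Event counts, total time lost (lower bound = durations capped at
#' \code{cap_h}, upper = uncapped) and the fraction of time lost (time lost
#' over activity + time lost) per gear type and per flag state.
#'
#' @param gaps classified gap table.
#' @param messages message table (for the activity denominator).
#' @param cap_h cap in hours (default 336).
#' @return data.table: stratum_type, stratum, n_events, hours_lower,
#'   hours_upper, fraction_lower, fraction_upper.
#' @export
disabling_summary <- function(gaps, messages, cap_h = 336) {
  g <- data.table::as.data.table(gaps)
  g <- g[g$classification == "suspected_disabling"]
  m <- data.table::as.data.table(messages)
  data.table::setorderv(m, c("vessel_id", "timestamp"))
  m[, t_num := as.numeric(timestamp)]
  act <- m[, {
    if (.N < 2) list(gear = gear[0], flag = flag[0], hrs = numeric(0)) else {
      dt_h <- diff(t_num) / 3600
      ok <- dt_h < 12
      list(gear = gear[which(ok)], flag = flag[which(ok)], hrs = dt_h[ok])
    }
  }, by = vessel_id]
  one <- function(col) {
    a <- act[, .(activity_h = sum(hrs)), by = c(col)]
    d <- g[, .(n_events = .N, hours_lower = sum(pmin(duration_h, cap_h)),
               hours_upper = sum(duration_h)), by = c(col)]
    out <- merge(a, d, by = col, all = TRUE)
    for (cc in c("n_events", "hours_lower", "hours_upper", "activity_h")) {
      data.table::set(out, which(is.na(out[[cc]])), cc, 0)
    }
    out[, fraction_lower := hours_lower / (activity_h + hours_lower)]
    out[, fraction_upper := hours_upper / (activity_h + hours_upper)]
    data.table::setnames(out, col, "stratum")
    out[, stratum_type := col]
    out
  }
  res <- data.table::rbindlist(list(one("gear"), one("flag")), use.names = TRUE)
  data.table::setcolorder(res, c("stratum_type", "stratum", "n_events",
                                 "hours_lower", "hours_upper",
                                 "activity_h", "fraction_lower",
                                 "fraction_upper"))
  res[]
}
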