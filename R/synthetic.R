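# Synthetic AIS world: a reception field, a shoreline, driver rasters, and a
# fleet of vessels moving as correlated random walks whose pings are an
# inhomogeneous Poisson process thinned by satellite reception. Intentional
# disabling events are planted with a covariate-dependent daily probability
# and logged to a truth table, so the downstream gap classifier can be scored
# against known labels.

T0 <- as.POSIXct("2017-01-01 00:00:00", tz = "UTC")

GEARS <- c("drifting_longlines", "squid_jigger", "tuna_purse_seine",
           "trawler", "other")
FLAGS <- c("CHN", "TWN", "ESP", "USA", "KOR", "JPN", "ARG", "OTH")

#' World configuration
#'
#' Describes the synthetic ocean: extent, grid resolution, the true satellite
#' reception field (positions per vessel per day, a constant background plus
#' Gaussian bumps), the shoreline (by default the western extent edge), and
#' the spatial driver fields. Defaults are the package's reference study
#' conditions; they are assumptions, not values calibrated to any dataset.
#'
#' @param lon_min,lon_max,lat_min,lat_max extent (degrees).
#' @param cell_size_deg analysis resolution (default 0.25).
#' @param reception list: \code{background} (positions/day), \code{bumps}
#'   (data.frame lon, lat, amplitude, sigma_deg), \code{class_b_factor}
#'   (class B reception relative to class A).
#' @param shore either "west" (shoreline is the western extent edge) or a
#'   data.frame of polyline vertices (lon, lat).
#' @param n_mpa,n_piracy number of random point sources for the
#'   distance-to-MPA and distance-to-piracy drivers.
#' @param driver_specs named list of field parameters for the four smooth
#'   environmental drivers (loitering, chl, eke, sst_sd; sst additionally
#'   carries a latitudinal ramp): each a list(mean, amplitude, scale_deg,
#'   n_bumps, floor). NULL keeps the package defaults.
#' @param seed integer RNG seed; fixes every byte of generator output.
#' @return a \code{world_config} list.
#' @export
world_config <- function(lon_min = 0, lon_max = 15, lat_min = -10, lat_max = 10,
                         cell_size_deg = 0.25,
                         reception = list(
                           background = 5,
                           bumps = data.frame(
                             lon = c(4, 10, 7, 6, 10.5, 3.2),
                             lat = c(4, -4, -8, 1.5, -7, -3),
                             amplitude = c(35, 30, 18, -40, -36, -30),
                             sigma_deg = c(4.5, 4.5, 3.5, 2.1, 2.1, 1.7)),
                           class_b_factor = 0.6),
                         shore = "west",
                         n_mpa = 4, n_piracy = 3,
                         driver_specs = NULL,
                         seed = 1L) {
  defaults <- list(
    loitering = list(mean = 20, amplitude = 400, scale_deg = 2.5,
                     n_bumps = 8, floor = 0),
    chl = list(mean = 0.3, amplitude = 0.35, scale_deg = 4, n_bumps = 12,
               floor = 0.01),
    eke = list(mean = 0.02, amplitude = 0.04, scale_deg = 3, n_bumps = 12,
               floor = 0.001),
    sst = list(mean = 0, amplitude = 2, scale_deg = 6, n_bumps = 12,
               floor = -Inf, lat_ramp = 0.5),
    sst_sd = list(mean = 1, amplitude = 1, scale_deg = 4, n_bumps = 12,
                  floor = 0.05))
  driver_specs <- utils::modifyList(defaults, driver_specs %||% list())
  cfg <- list(lon_min = lon_min, lon_max = lon_max, lat_min = lat_min,
              lat_max = lat_max, cell_size_deg = cell_size_deg,
              reception = reception, shore = shore,
              n_mpa = n_mpa, n_piracy = n_piracy,
              driver_specs = driver_specs, seed = as.integer(seed))
  stopifnot(reception$background >= 0)
  class(cfg) <- "world_config"
  cfg
}

# Gaussian-bump field evaluated at cell centres (planar degrees; adequate at
# the synthetic domain's scale). Negative amplitudes carve reception holes;
# the field is floored at 0 so reception stays non-negative.
bump_field <- function(grid, background, bumps) {
  cc <- cell_centers(grid)
  v <- rep(background, nrow(cc))
  if (!is.null(bumps) && nrow(bumps)) {
    for (b in seq_len(nrow(bumps))) {
      d2 <- (cc$lon - bumps$lon[b])^2 + (cc$lat - bumps$lat[b])^2
      v <- v + bumps$amplitude[b] * exp(-d2 / (2 * bumps$sigma_deg[b]^2))
    }
  }
  dg_raster(grid, matrix(pmax(v, 0), grid$ny, grid$nx, byrow = TRUE))
}

# Random smooth positive field: mean + signed Gaussian bumps, floored.
smooth_field <- function(grid, mean, amplitude, scale_deg, n_bumps = 12,
                         floor = 0) {
  cc <- cell_centers(grid)
  v <- rep(mean, nrow(cc))
  for (b in seq_len(n_bumps)) {
    x0 <- stats::runif(1, grid$lon_min, grid$lon_max)
    y0 <- stats::runif(1, grid$lat_min, grid$lat_max)
    a <- stats::runif(1, -1, 1) * amplitude
    s <- scale_deg * stats::runif(1, 0.6, 1.6)
    v <- v + a * exp(-((cc$lon - x0)^2 + (cc$lat - y0)^2) / (2 * s^2))
  }
  dg_raster(grid, matrix(pmax(v, floor), grid$ny, grid$nx, byrow = TRUE))
}

shore_vertices <- function(cfg, grid) {
  if (identical(cfg$shore, "west")) {
    data.frame(lon = cfg$lon_min,
               lat = seq(cfg$lat_min, cfg$lat_max, by = grid$cell_size_deg))
  } else {
    stopifnot(is.data.frame(cfg$shore), all(c("lon", "lat") %in% names(cfg$shore)))
    cfg$shore
  }
}

# Min great-circle distance (km) from each cell centre to a set of vertices.
min_dist_field <- function(grid, pts, clip_km = Inf) {
  cc <- cell_centers(grid)
  d <- rep(Inf, nrow(cc))
  for (k in seq_len(nrow(pts))) {
    d <- pmin(d, gc_dist_km(cc$lon, cc$lat, pts$lon[k], pts$lat[k]))
  }
  dg_raster(grid, matrix(pmin(d, clip_km), grid$ny, grid$nx, byrow = TRUE))
}

#' Build the synthetic world
#'
#' Evaluates the true reception fields (class A and B), the shore-distance
#' raster, and the eight driver rasters (dist_shore, dist_mpa, loitering,
#' dist_piracy, chl, eke, sst, sst_sd) on the analysis grid. Distance drivers
#' are clipped at 400 km to focus the driver models on proximal effects; the
#' unclipped shore distance is kept separately for the gap filters.
#' Deterministic for a fixed \code{config$seed}.
#'
#' @param config a \code{world_config}.
#' @return a \code{dg_world} list: \code{grid}, \code{reception} (truth
#'   rasters \code{$A}, \code{$B}), \code{shore} (vertex data.frame),
#'   \code{shore_dist_km} (unclipped), \code{drivers} (named list of 8
#'   rasters), \code{config}.
#' @export
build_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  grid <- dg_grid(config$lon_min, config$lon_max, config$lat_min,
                  config$lat_max, config$cell_size_deg)
  set.seed(config$seed)
  recA <- bump_field(grid, config$reception$background, config$reception$bumps)
  recB <- dg_raster(grid, recA$values * config$reception$class_b_factor)
  shore <- shore_vertices(config, grid)
  shore_dist <- min_dist_field(grid, shore)
  mpa_pts <- data.frame(lon = stats::runif(config$n_mpa, config$lon_min, config$lon_max),
                        lat = stats::runif(config$n_mpa, config$lat_min, config$lat_max))
  pir_pts <- data.frame(lon = stats::runif(config$n_piracy, config$lon_min, config$lon_max),
                        lat = stats::runif(config$n_piracy, config$lat_min, config$lat_max))
  cc <- cell_centers(grid)
  sf <- function(nm) {
    s <- config$driver_specs[[nm]]
    smooth_field(grid, s$mean, s$amplitude, s$scale_deg, n_bumps = s$n_bumps,
                 floor = s$floor)
  }
  drivers <- list(
    dist_shore = dg_raster(grid, pmin(shore_dist$values, 400)),
    dist_mpa   = min_dist_field(grid, mpa_pts, clip_km = 400),
    loitering  = sf("loitering"),
    dist_piracy = min_dist_field(grid, pir_pts, clip_km = 400),
    chl  = sf("chl"),
    eke  = sf("eke"),
    sst  = dg_raster(grid, sf("sst")$values +
                       matrix(15 + (config$driver_specs$sst$lat_ramp %||% 0.5) *
                                cc$lat, grid$ny, grid$nx, byrow = TRUE)),
    sst_sd = sf("sst_sd"))
  structure(list(grid = grid, reception = list(A = recA, B = recB),
                 shore = shore, shore_dist_km = shore_dist,
                 drivers = drivers, config = config),
            class = "dg_world")
}

#' Fleet configuration
#'
#' Vessel counts, gear/flag/device-class mixtures, the ping process, the
#' movement model, and the intentional-disabling model. The disabling model
#' is logistic on a per-day basis in two per-cell covariates: log10 loitering
#' hours and an exclusive-economic-zone-boundary band indicator
#' (shore distance within \code{band_nmi} of 200 nautical miles); disabling
#' durations are log-normal (hours).
#'
#' @param n_vessels vessel count.
#' @param gear_mix,flag_mix,device_class_mix named proportion vectors; each
#'   must sum to 1 within 1e-9.
#' @param base_ping_rate named vector, expected broadcasts/day at perfect
#'   reception per device class.
#' @param reference_reception positions/day at which thinning saturates.
#' @param movement list: \code{speed_kmh_mean}, \code{turn_sd_rad},
#'   \code{attract_strength}, \code{ground_sd_deg} (vessel spread around its
#'   gear's fishing-ground centre).
#' @param disabling list: \code{intercept}, \code{b_loiter} (per log10 hour),
#'   \code{b_eez_band}, \code{band_nmi}, \code{band_center_nmi} (default 200,
#'   the EEZ boundary), \code{rec_power}, \code{dur_meanlog},
#'   \code{dur_sdlog} (log-hours). The logistic probability is multiplied by
#'   \code{min(1, reception/reference_reception)^rec_power}: in the generator
#'   vessels disable mainly where tracking is effective, so little is gained
#'   by switching off in waters where reception already hides them. Set
#'   \code{rec_power = 0} for a purely logistic model in loitering and shore
#'   distance, and \code{intercept = -Inf} to disable planting.
#' @param seed integer RNG seed.
#' @return a \code{fleet_config} list.
#' @export
fleet_config <- function(n_vessels = 50,
                         gear_mix = c(drifting_longlines = 0.3,
                                      squid_jigger = 0.25,
                                      tuna_purse_seine = 0.15,
                                      trawler = 0.2, other = 0.1),
                         flag_mix = c(CHN = 0.3, TWN = 0.15, ESP = 0.15,
                                      USA = 0.1, KOR = 0.1, JPN = 0.1,
                                      ARG = 0.05, OTH = 0.05),
                         device_class_mix = c(A = 0.75, B = 0.25),
                         base_ping_rate = c(A = 72, B = 60),
                         reference_reception = 30,
                         movement = list(speed_kmh_mean = 6, turn_sd_rad = 0.6,
                                         attract_strength = 0.15,
                                         ground_sd_deg = 2,
                                         excursion_prob = 0.4),
                         disabling = list(intercept = -3.4, b_loiter = 0.55,
                                          b_eez_band = 1.2, band_nmi = 50,
                                          rec_power = 2,
                                          dur_meanlog = log(30),
                                          dur_sdlog = 0.7),
                         seed = 1L) {
  for (mx in list(gear_mix, flag_mix, device_class_mix)) {
    if (abs(sum(mx) - 1) > 1e-9) stop("mixture proportions must sum to 1")
  }
  structure(list(n_vessels = as.integer(n_vessels), gear_mix = gear_mix,
                 flag_mix = flag_mix, device_class_mix = device_class_mix,
                 base_ping_rate = base_ping_rate,
                 reference_reception = reference_reception,
                 movement = movement, disabling = disabling,
                 seed = as.integer(seed)),
            class = "fleet_config")
}

# Hourly correlated-random-walk trajectories for all vessels at once.
# Returns lon/lat matrices [n_hours + 1, n_vessels].
simulate_tracks <- function(world, fleet, n_hours) {
  g <- world$grid
  n <- fleet$n_vessels
  mv <- fleet$movement
  # gear-specific fishing-ground centres, biased offshore
  gear_of <- sample(names(fleet$gear_mix), n, replace = TRUE,
                    prob = fleet$gear_mix)
  centers <- data.frame(
    gear = names(fleet$gear_mix),
    lon = stats::runif(length(fleet$gear_mix),
                       g$lon_min + 0.1 * (g$lon_max - g$lon_min),
                       g$lon_max - 0.35 * (g$lon_max - g$lon_min)),
    lat = stats::runif(length(fleet$gear_mix),
                       g$lat_min + 0.15 * (g$lat_max - g$lat_min),
                       g$lat_max - 0.15 * (g$lat_max - g$lat_min)))
  ci <- match(gear_of, centers$gear)
  cx <- centers$lon[ci]; cy <- centers$lat[ci]
  # per 72-h block a vessel either works its ground or makes an excursion
  # to a random waypoint, so tracks cross the whole domain (incl. any
  # reception holes) rather than sitting on one ground
  n_blocks <- ceiling(n_hours / 72)
  exc <- matrix(stats::runif(n_blocks * n) < (mv$excursion_prob %||% 0.3),
                n_blocks, n)
  wx <- matrix(stats::runif(n_blocks * n, g$lon_min + 1, g$lon_max - 1),
               n_blocks, n)
  wy <- matrix(stats::runif(n_blocks * n, g$lat_min + 1, g$lat_max - 1),
               n_blocks, n)
  tx <- ifelse(exc, wx, matrix(cx, n_blocks, n, byrow = TRUE))
  ty <- ifelse(exc, wy, matrix(cy, n_blocks, n, byrow = TRUE))
  lon <- matrix(NA_real_, n_hours + 1, n)
  lat <- matrix(NA_real_, n_hours + 1, n)
  lon[1, ] <- pmin(pmax(cx + stats::rnorm(n, 0, mv$ground_sd_deg), g$lon_min),
                   g$lon_max - 1e-6)
  lat[1, ] <- pmin(pmax(cy + stats::rnorm(n, 0, mv$ground_sd_deg), g$lat_min),
                   g$lat_max - 1e-6)
  heading <- stats::runif(n, 0, 2 * pi)
  for (h in seq_len(n_hours)) {
    b <- (h - 1) %/% 72 + 1
    heading <- heading + stats::rnorm(n, 0, mv$turn_sd_rad)
    to_center <- atan2(tx[b, ] - lon[h, ], ty[b, ] - lat[h, ])
    dh <- ((to_center - heading + pi) %% (2 * pi)) - pi
    heading <- heading + mv$attract_strength * dh
    step_km <- stats::rgamma(n, shape = 2, scale = mv$speed_kmh_mean / 2)
    dlat <- step_km / 111.2 * cos(heading)
    dlon <- step_km / (111.2 * pmax(cos(lat[h, ] * pi / 180), 0.2)) * sin(heading)
    nlon <- lon[h, ] + dlon
    nlat <- lat[h, ] + dlat
    # reflective boundary
    nlon <- ifelse(nlon < g$lon_min, 2 * g$lon_min - nlon, nlon)
    nlon <- ifelse(nlon >= g$lon_max, 2 * g$lon_max - nlon - 1e-9, nlon)
    nlat <- ifelse(nlat < g$lat_min, 2 * g$lat_min - nlat, nlat)
    nlat <- ifelse(nlat >= g$lat_max, 2 * g$lat_max - nlat - 1e-9, nlat)
    lon[h + 1, ] <- pmin(pmax(nlon, g$lon_min), g$lon_max - 1e-9)
    lat[h + 1, ] <- pmin(pmax(nlat, g$lat_min), g$lat_max - 1e-9)
  }
  list(lon = lon, lat = lat, gear = gear_of,
       center_lon = cx, center_lat = cy)
}

#' Simulate an AIS message stream with planted disabling events
#'
#' Vessels follow hourly correlated random walks attracted to gear-specific
#' fishing grounds. Within each hour a vessel emits a Poisson number of pings
#' with mean \code{base_ping_rate/24 * min(1, reception/reference_reception)}
#' evaluated at the vessel's position on the true reception field of its
#' device class, so unintentional gaps arise naturally in poor-reception
#' waters. Intentional disabling is planted per vessel-day with logistic
#' probability in the loitering and shore-distance covariates at the vessel's
#' position; all pings strictly inside a planted window are deleted and the
#' truth log records the window anchored at the last ping before and the
#' first ping after.
#'
#' @param world a \code{dg_world}.
#' @param fleet a \code{fleet_config}.
#' @param days simulation length in days (>= 1).
#' @return list with \code{messages} (data.table: vessel_id, timestamp,
#'   lon, lat, device_class, is_fishing, gear, flag) and \code{truth}
#'   (data.table: vessel_id, start, end, start_lon, start_lat, end_lon,
#'   end_lat, cause).
#' @export
simulate_fleet <- function(world, fleet, days) {
  stopifnot(inherits(world, "dg_world"), inherits(fleet, "fleet_config"),
            days >= 1)
  if (fleet$n_vessels < 1) stop("empty fleet")
  if (all(world$reception$A$values <= 0, na.rm = TRUE)) {
    stop("reception field is zero everywhere: no observable vessels")
  }
  set.seed(fleet$seed)
  n <- fleet$n_vessels
  n_hours <- as.integer(days) * 24L
  tr <- simulate_tracks(world, fleet, n_hours)
  vid <- sprintf("V%06d", 100000 + seq_len(n))
  flag_v <- sample(names(fleet$flag_mix), n, replace = TRUE, prob = fleet$flag_mix)
  dev <- sample(names(fleet$device_class_mix), n, replace = TRUE,
                prob = fleet$device_class_mix)

  # per vessel-hour expected ping count, thinned by true reception
  recA <- world$reception$A; recB <- world$reception$B
  lon_h <- tr$lon[seq_len(n_hours), , drop = FALSE]
  lat_h <- tr$lat[seq_len(n_hours), , drop = FALSE]
  rec_v <- matrix(NA_real_, n_hours, n)
  for (v in seq_len(n)) {
    r <- if (dev[v] == "A") recA else recB
    rec_v[, v] <- raster_at(r, lon_h[, v], lat_h[, v])
  }
  rate <- sweep(pmin(rec_v / fleet$reference_reception, 1), 2,
                fleet$base_ping_rate[dev] / 24, `*`)
  n_ping <- matrix(stats::rpois(length(rate), rate), n_hours, n)

  # expand to individual pings, positions linearly interpolated within hour
  tot <- sum(n_ping)
  if (tot == 0) stop("simulation produced no messages; check reception/ping rates")
  v_idx <- rep(rep(seq_len(n), each = n_hours), times = as.vector(n_ping))
  h_idx <- rep(rep(seq_len(n_hours), times = n), times = as.vector(n_ping))
  frac <- stats::runif(tot)
  i1 <- cbind(h_idx, v_idx); i2 <- cbind(h_idx + 1L, v_idx)
  msg <- data.table::data.table(
    vessel_id = vid[v_idx],
    t_sec = (h_idx - 1) * 3600 + frac * 3600,
    lon = tr$lon[i1] + frac * (tr$lon[i2] - tr$lon[i1]),
    lat = tr$lat[i1] + frac * (tr$lat[i2] - tr$lat[i1]),
    device_class = dev[v_idx])
  msg[, t_sec := floor(t_sec)]
  data.table::setorderv(msg, c("vessel_id", "t_sec"))
  msg <- unique(msg, by = c("vessel_id", "t_sec"))

  # fishing label: within 3 degrees of the vessel's fishing-ground centre
  msg[, is_fishing := sqrt((lon - tr$center_lon[match(vessel_id, vid)])^2 +
                           (lat - tr$center_lat[match(vessel_id, vid)])^2) < 3]
  msg[, gear := tr$gear[match(vessel_id, vid)]]
  msg[, flag := flag_v[match(vessel_id, vid)]]

  truth <- plant_disabling(msg, world, fleet, tr, vid, days)
  msg <- truth$messages
  msg[, timestamp := T0 + t_sec]
  msg[, t_sec := NULL]
  data.table::setcolorder(msg, c("vessel_id", "timestamp", "lon", "lat",
                                 "device_class", "is_fishing", "gear", "flag"))
  list(messages = msg[], truth = truth$truth)
}

# Plant intentional disabling windows and delete the pings inside them.
plant_disabling <- function(msg, world, fleet, tr, vid, days) {
  db <- fleet$disabling
  empty <- data.table::data.table(
    vessel_id = character(), start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    start_lon = numeric(), start_lat = numeric(),
    end_lon = numeric(), end_lat = numeric(), cause = character())
  if (!is.finite(db$intercept) && db$intercept < 0) {
    return(list(messages = msg, truth = empty))
  }
  n <- fleet$n_vessels
  loit <- world$drivers$loitering
  shore_nmi_r <- dg_raster(world$grid, world$shore_dist_km$values / KM_PER_NMI)
  dev <- msg$device_class[match(vid, msg$vessel_id)]
  drop_keys <- vector("list", n * days)
  rows <- vector("list", n * days)
  k <- 0L
  msg_by_v <- split(msg[, .(t_sec, lon, lat)], msg$vessel_id)
  rp <- db$rec_power %||% 0
  for (v in seq_len(n)) {
    vt <- msg_by_v[[vid[v]]]
    if (is.null(vt) || nrow(vt) < 2) next
    rfield <- if (!is.na(dev[v]) && dev[v] == "B") world$reception$B else world$reception$A
    prev_end <- -Inf
    for (d in seq_len(days)) {
      # draw one candidate anchor ping this day; accept with the logistic
      # disabling probability evaluated at the anchor's cell, so the planted
      # event location carries exactly the covariates that caused it
      cand <- which(vt$t_sec >= (d - 1) * 86400 & vt$t_sec < d * 86400 &
                    vt$t_sec > prev_end)
      if (!length(cand)) next
      a <- cand[sample.int(length(cand), 1)]
      lv <- raster_at(loit, vt$lon[a], vt$lat[a])
      sv <- raster_at(shore_nmi_r, vt$lon[a], vt$lat[a])
      band <- as.numeric(abs(sv - (db$band_center_nmi %||% 200)) <= db$band_nmi)
      p <- stats::plogis(db$intercept + db$b_loiter * log10(lv + 1) +
                         db$b_eez_band * band)
      if (rp > 0) {
        rv <- raster_at(rfield, vt$lon[a], vt$lat[a])
        p <- p * pmin(1, rv / fleet$reference_reception)^rp
      }
      if (stats::runif(1) >= p) next
      dur_s <- stats::rlnorm(1, db$dur_meanlog, db$dur_sdlog) * 3600
      t_start <- vt$t_sec[a]
      after <- which(vt$t_sec > t_start + dur_s)
      if (!length(after)) next
      b <- after[1]
      k <- k + 1L
      rows[[k]] <- data.table::data.table(
        vessel_id = vid[v], start_sec = t_start, end_sec = vt$t_sec[b],
        start_lon = vt$lon[a], start_lat = vt$lat[a],
        end_lon = vt$lon[b], end_lat = vt$lat[b])
      drop_keys[[k]] <- data.table::data.table(
        vessel_id = vid[v], lo = t_start, hi = vt$t_sec[b])
      prev_end <- vt$t_sec[b]
    }
  }
  if (k == 0L) return(list(messages = msg, truth = empty))
  tw <- data.table::rbindlist(rows[seq_len(k)])
  dk <- data.table::rbindlist(drop_keys[seq_len(k)])
  keep <- rep(TRUE, nrow(msg))
  for (i in seq_len(nrow(dk))) {
    keep <- keep & !(msg$vessel_id == dk$vessel_id[i] &
                     msg$t_sec > dk$lo[i] & msg$t_sec < dk$hi[i])
  }
  truth <- data.table::data.table(
    vessel_id = tw$vessel_id,
    start = T0 + tw$start_sec, end = T0 + tw$end_sec,
    start_lon = tw$start_lon, start_lat = tw$start_lat,
    end_lon = tw$end_lon, end_lat = tw$end_lat,
    cause = "intentional")
  list(messages = msg[keep], truth = truth)
}

#' Write / read AIS fixtures as CSV
#'
#' Timestamps are written as ISO-8601 UTC (\code{YYYY-MM-DDTHH:MM:SSZ}) and
#' round-trip losslessly to the second.
#'
#' @param messages message table as from \code{simulate_fleet}.
#' @param truth truth log as from \code{simulate_fleet} (optional).
#' @param dir output directory; files \code{messages.csv} and
#'   \code{truth.csv} are created.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(messages, truth = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, "messages.csv")
  m <- data.table::copy(data.table::as.data.table(messages))
  m[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  data.table::fwrite(m, mp)
  paths <- mp
  if (!is.null(truth)) {
    tp <- file.path(dir, "truth.csv")
    tt <- data.table::copy(data.table::as.data.table(truth))
    for (cl in c("start", "end")) {
      data.table::set(tt, j = cl,
                      value = format(tt[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
    }
    data.table::fwrite(tt, tp)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' @rdname write_fixture
#' @param path a \code{messages.csv} path.
#' @export
read_messages <- function(path) {
  m <- data.table::fread(path, colClasses = list(character = "timestamp"))
  m[, timestamp := as.POSIXct(timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")]
  m[]
}

#' @rdname write_fixture
#' @export
read_truth <- function(path) {
  tt <- data.table::fread(path, colClasses = list(character = c("start", "end")))
  for (cl in c("start", "end")) {
    data.table::set(tt, j = cl,
                    value = as.POSIXct(tt[[cl]], format = "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC"))
  }
  tt[]
}
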