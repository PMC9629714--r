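# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# The reference study fixture: 100 vessels, 90 days, fixed seeds, with
# reception maps, filtered + truth-labelled gaps.
study_fixture <- function() {
  if (!is.null(.fixture_cache$study)) return(.fixture_cache$study)
  world <- build_world(world_config(seed = 7))
  sim <- simulate_fleet(world, fleet_config(n_vessels = 100, seed = 11),
                        days = 90)
  ext <- c(world$config$lon_min, world$config$lon_max,
           world$config$lat_min, world$config$lat_max)
  pred <- lapply(c(A = "A", B = "B"), function(cl) {
    predict_reception(observed_reception(sim$messages, 1, cl, extent = ext))
  })
  gaps <- detect_gaps(sim$messages)
  gaps <- filter_gaps(gaps, world$shore_dist_km, pred)
  gaps <- label_gaps(gaps, sim$truth)
  .fixture_cache$study <- list(world = world, messages = sim$messages,
                               truth = sim$truth, pred = pred, gaps = gaps)
  .fixture_cache$study
}

# A small world + fleet for fast unit tests.
small_sim <- function(n_vessels = 20, days = 15, world_seed = 3,
                      fleet_seed = 4, ...) {
  world <- build_world(world_config(seed = world_seed))
  sim <- simulate_fleet(world,
                        fleet_config(n_vessels = n_vessels, seed = fleet_seed,
                                     ...),
                        days = days)
  c(sim, list(world = world))
}

# Hand-built message table: one vessel pinging at given hour offsets.
msg_at_hours <- function(hours, vessel = "V1", lon = 5, lat = 0,
                         device_class = "A") {
  data.table::data.table(
    vessel_id = vessel,
    timestamp = as.POSIXct("2017-01-01", tz = "UTC") + hours * 3600,
    lon = lon, lat = lat, device_class = device_class,
    is_fishing = TRUE, gear = "trawler", flag = "CHN")
}

# Constant-value predicted reception grids for both device classes.
const_reception <- function(grid, value) {
  r <- structure(list(grid = grid,
                      values = matrix(value, grid$ny, grid$nx),
                      support = NULL, device_class = "A", kind = "predicted"),
                 class = c("reception_grid", "dg_raster"))
  list(A = r, B = r)
}

# Random driver stack on a grid, for driver-model tests.
drivers_for <- function(grid, seed = 1) {
  set.seed(seed)
  nm <- c("dist_shore", "dist_mpa", "loitering", "dist_piracy", "chl", "eke",
          "sst", "sst_sd")
  out <- lapply(nm, function(d) {
    dg_raster(grid, matrix(stats::runif(grid$nx * grid$ny, 0,
                                        if (grepl("dist", d)) 400 else 10),
                           grid$ny, grid$nx))
  })
  names(out) <- nm
  out
}

# Presence/absence table with a synthetic absence pool, for driver-model
# tests that do not need a simulated world.
synthetic_pa_table <- function(n_per_class = 150, pool_size = 800, seed = 1,
                               label_fun = NULL) {
  set.seed(seed)
  drivers <- c("dist_shore", "dist_mpa", "loitering", "dist_piracy",
               "chl", "eke", "sst", "sst_sd")
  X <- matrix(stats::runif(pool_size * 8), pool_size, 8,
              dimnames = list(NULL, drivers))
  X[, "dist_shore"] <- X[, "dist_shore"] * 400
  X[, "loitering"] <- X[, "loitering"] * 1000
  pool <- data.table::data.table(cell = seq_len(pool_size))
  pool <- cbind(pool, data.table::as.data.table(X))
  if (is.null(label_fun)) label_fun <- function(X) X[, "loitering"] > 500
  y_pool <- as.integer(label_fun(X))
  pres <- which(y_pool == 1)[seq_len(n_per_class)]
  abs_ <- which(y_pool == 0)[seq_len(n_per_class)]
  tab <- rbind(pool[pres], pool[abs_])
  tab[, label := rep(c(1L, 0L), each = n_per_class)]
  data.table::setcolorder(tab, c("cell", "label"))
  data.table::setattr(tab, "absence_pool", pool[y_pool == 0])
  data.table::setattr(tab, "gear", NULL)
  tab[]
}
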