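test_that("observed reception is messages per vessel-day in the daily-mean cell", {
  # one vessel, one day, 30 messages in one cell -> that cell = 30
  m1 <- msg_at_hours(seq(0, 23, length.out = 30), lon = 5.2, lat = 0.3)
  obs <- observed_reception(m1, 1, "A", extent = c(0, 10, -5, 5))
  expect_equal(obs$values[cell_of(obs$grid, 5.2, 0.3)$iy,
                          cell_of(obs$grid, 5.2, 0.3)$ix], 30)
  expect_equal(sum(!is.na(obs$values)), 1)

  # two vessels sharing the cell with 30 and 10 messages -> (30+10)/2 = 20
  m2 <- rbind(m1, msg_at_hours(seq(1, 22, length.out = 10), vessel = "V2",
                               lon = 5.3, lat = 0.4))
  obs2 <- observed_reception(m2, 1, "A", extent = c(0, 10, -5, 5))
  expect_equal(obs2$values[cell_of(obs2$grid, 5.2, 0.3)$iy,
                           cell_of(obs2$grid, 5.2, 0.3)$ix], 20)
  expect_equal(obs2$support[cell_of(obs2$grid, 5.2, 0.3)$iy,
                            cell_of(obs2$grid, 5.2, 0.3)$ix], 2)
})

test_that("device classes partition the observed map", {
  mA <- msg_at_hours(0:19, lon = 5.2)
  mB <- msg_at_hours(0:9, vessel = "V2", lon = 5.3, device_class = "B")
  m <- rbind(mA, mB)
  obsA <- observed_reception(m, 1, "A", extent = c(0, 10, -5, 5))
  obsB <- observed_reception(m, 1, "B", extent = c(0, 10, -5, 5))
  i <- cell_of(obsA$grid, 5.2, 0)
  expect_equal(obsA$values[i$iy, i$ix], 20)
  expect_equal(obsB$values[i$iy, i$ix], 10)
})

test_that("observed reception is invariant to row order and linear in counts", {
  sim <- small_sim(n_vessels = 8, days = 8)
  m <- sim$messages
  ext <- c(0, 15, -10, 10)
  obs <- observed_reception(m, 1, "A", extent = ext)
  shuffled <- m[sample(nrow(m))]
  expect_equal(observed_reception(shuffled, 1, "A", extent = ext)$values,
               obs$values)
  # doubling every message (distinct duplicate timestamps) doubles values
  m2 <- data.table::copy(m)
  m2[, timestamp := timestamp + 0.5]
  doubled <- observed_reception(rbind(m, m2), 1, "A", extent = ext)
  expect_equal(doubled$values, 2 * obs$values, tolerance = 1e-9)
})

test_that("thin-plate interpolation is exact and reproduces constants", {
  g <- dg_grid(0, 10, 0, 10, 1)
  vals <- matrix(NA_real_, 10, 10)
  set.seed(2)
  idx <- cbind(sample(10, 30, TRUE), sample(10, 30, TRUE))
  idx <- unique(idx)
  vals[idx] <- runif(nrow(idx), 5, 40)
  obs <- structure(list(grid = g, values = vals, support = NULL,
                        device_class = "A", kind = "observed"),
                   class = c("reception_grid", "dg_raster"))
  cc <- cell_centers(g, ix = idx[, 2], iy = idx[, 1])
  expect_equal(interpolate_reception(obs, cc$lon, cc$lat), vals[idx],
               tolerance = 1e-6)

  # constant observed field c -> predicted c everywhere
  vc <- vals; vc[idx] <- 17.5
  obs_c <- obs; obs_c$values <- vc
  pred_c <- predict_reception(obs_c, 0.25)
  expect_true(all(abs(pred_c$values - 17.5) < 1e-6))

  # adding a constant shifts the whole surface by that constant
  obs_s <- obs; obs_s$values <- vals + 3
  set.seed(5)
  px <- runif(50, 0, 10); py <- runif(50, 0, 10)
  expect_equal(interpolate_reception(obs_s, px, py),
               interpolate_reception(obs, px, py) + 3, tolerance = 1e-6)
})

test_that("interpolation rejects degenerate inputs", {
  g <- dg_grid(0, 5, 0, 5, 1)
  vals <- matrix(NA_real_, 5, 5)
  vals[1, 1] <- 1; vals[2, 2] <- 2; vals[3, 3] <- 3
  obs <- structure(list(grid = g, values = vals, support = NULL,
                        device_class = "A", kind = "observed"),
                   class = c("reception_grid", "dg_raster"))
  expect_error(predict_reception(obs), ">= 4")
  vals[4, 4] <- Inf
  obs$values <- vals
  expect_error(predict_reception(obs), "non-finite")
})

test_that("negative interpolants are clamped to zero", {
  g <- dg_grid(0, 6, 0, 6, 1)
  vals <- matrix(NA_real_, 6, 6)
  # steep gradient forcing undershoot between sites
  vals[1, 1] <- 100; vals[1, 6] <- 0.1; vals[6, 1] <- 0.1; vals[6, 6] <- 100
  vals[3, 3] <- 0.1; vals[4, 4] <- 0.1
  obs <- structure(list(grid = g, values = vals, support = NULL,
                        device_class = "A", kind = "observed"),
                   class = c("reception_grid", "dg_raster"))
  pred <- predict_reception(obs, 0.25)
  expect_true(all(pred$values >= 0))
})

test_that("prediction beats a nearest-neighbour baseline on synthetic worlds", {
  wins <- 0L
  for (s in 1:10) {
    sim <- small_sim(n_vessels = 25, days = 12, world_seed = 50 + s,
                     fleet_seed = 60 + s)
    w <- sim$world
    ext <- c(w$config$lon_min, w$config$lon_max, w$config$lat_min,
             w$config$lat_max)
    obs <- observed_reception(sim$messages, 1, "A", extent = ext)
    pred <- predict_reception(obs, 0.25)
    # truth at the analysis resolution, on the observed-message scale
    fl <- fleet_config()
    cc <- cell_centers(pred$grid)
    truth <- fl$base_ping_rate[["A"]] *
      pmin(1, reception_at(w$reception$A, cc$lon, cc$lat) /
             fl$reference_reception)
    # evaluate only where the parent observed cell exists
    parent <- cell_of(obs$grid, cc$lon, cc$lat)
    known <- !is.na(obs$values[cbind(parent$iy, parent$ix)])
    # nearest-neighbour baseline: value of nearest observed cell centre
    ok <- which(!is.na(obs$values), arr.ind = TRUE)
    oc <- cell_centers(obs$grid, ix = ok[, 2], iy = ok[, 1])
    nn <- apply(outer(cc$lon[known], oc$lon, `-`)^2 +
                  outer(cc$lat[known], oc$lat, `-`)^2, 1, which.min)
    nn_pred <- obs$values[ok][nn]
    rmse_tps <- sqrt(mean((as.vector(t(pred$values))[known] - truth[known])^2))
    rmse_nn <- sqrt(mean((nn_pred - truth[known])^2))
    if (rmse_tps < rmse_nn) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("point lookup respects extent and conventions", {
  g <- dg_grid(0, 10, 0, 10, 0.25)
  r <- structure(list(grid = g, values = matrix(7, g$ny, g$nx),
                      support = NULL, device_class = "A", kind = "predicted"),
                 class = c("reception_grid", "dg_raster"))
  expect_equal(reception_at(r, 0, 0), 7)          # west/south edge in-grid
  expect_equal(reception_at(r, 9.999, 9.999), 7)
  expect_error(reception_at(r, 10, 5), "outside")
})
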