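grid25 <- dg_grid(0, 10, -5, 5, 0.25)

gap_row <- function(slon, slat, elon, elat, dur) {
  list(start_lon = slon, start_lat = slat, end_lon = elon, end_lat = elat,
       duration_h = dur)
}

test_that("linear allocation handles point gaps, caps, and equal spans", {
  # start = end: all time in the containing cell
  a <- allocate_linear(gap_row(5.1, 0.1, 5.1, 0.1, 24), grid25, cap_h = Inf)
  expect_equal(nrow(a), 1)
  expect_equal(a$hours, 24)
  expect_equal(a$cell, cell_of(grid25, 5.1, 0.1)$cell)

  # 400 h capped at 336
  a2 <- allocate_linear(gap_row(5.1, 0.1, 6.3, 0.4, 400), grid25, cap_h = 336)
  expect_equal(sum(a2$hours), 336)

  # segment crossing two equal-length cell spans: 5 h + 5 h, against a
  # brute-force fine-step integration of the same arc
  a3 <- allocate_linear(gap_row(5.05, 0.05, 5.45, 0.05, 10), grid25,
                        cap_h = Inf)
  expect_equal(nrow(a3), 2)
  expect_equal(sort(a3$hours), c(5, 5), tolerance = 0.02)
  fine <- gc_sample(5.05, 0.05, 5.45, 0.05, step_deg = 1e-4)
  cl <- cell_of(grid25, fine[, "lon"], fine[, "lat"])$cell
  brute <- 10 * as.numeric(table(cl)) / length(cl)
  expect_equal(sort(a3$hours), sort(brute), tolerance = 0.01)
})

test_that("probabilistic allocation respects feasibility and symmetry", {
  cfg <- allocation_config(max_speed_knots = 1e-6)
  a <- allocate_probabilistic(gap_row(5.1, 0.1, 5.1, 0.1, 24), grid25, cfg)
  expect_equal(sum(a$hours), 24)
  expect_lte(nrow(a), 2)   # degenerate ellipse: start/end cell only

  # symmetric about the start-end axis (here the equator, so reflection is
  # an isometry of the sphere) for a uniform prior
  cfg2 <- allocation_config(max_speed_knots = 10)
  a2 <- allocate_probabilistic(gap_row(4, 0, 6, 0, 30), grid25, cfg2)
  ix <- (a2$cell - 1) %% grid25$nx + 1
  iy <- (a2$cell - 1) %/% grid25$nx + 1
  lat_c <- grid25$lat_min + (iy - 0.5) * 0.25
  up <- a2[lat_c > 0, ]
  dn <- a2[lat_c < 0, ]
  up_key <- paste(ix[lat_c > 0], round(lat_c[lat_c > 0], 6))
  dn_key <- paste(ix[lat_c < 0], round(-lat_c[lat_c < 0], 6))
  expect_equal(sum(up$hours), sum(dn$hours), tolerance = 1e-9)
  m <- match(up_key, dn_key)
  expect_true(all(!is.na(m)))
  expect_equal(up$hours, dn$hours[m], tolerance = 1e-9)
})

test_that("both methods conserve capped duration over random gaps", {
  set.seed(42)
  total_lin <- total_prob <- 0
  expected <- 0
  for (i in 1:100) {
    dur <- runif(1, 12, 500)
    g <- gap_row(runif(1, 1, 9), runif(1, -4, 4),
                 runif(1, 1, 9), runif(1, -4, 4), dur)
    la <- allocate_linear(g, grid25, cap_h = 336)
    pa <- allocate_probabilistic(g, grid25, allocation_config())
    expect_equal(sum(la$hours), min(dur, 336), tolerance = 1e-6 * dur)
    expect_equal(sum(pa$hours), min(dur, 336), tolerance = 1e-6 * dur)
    total_lin <- total_lin + sum(la$hours)
    total_prob <- total_prob + sum(pa$hours)
    expected <- expected + min(dur, 336)
  }
  expect_equal(total_lin, expected, tolerance = 1e-9)
  expect_equal(total_prob, expected, tolerance = 1e-9)
})

test_that("capped totals never exceed uncapped, equal iff nothing exceeds cap", {
  g <- data.table::data.table(
    start_lon = c(3, 5), start_lat = c(0, 1), end_lon = c(3.5, 5.2),
    end_lat = c(0.2, 1.1), duration_h = c(100, 200),
    classification = "suspected_disabling")
  capped <- allocate_gaps(g, grid25, "linear", allocation_config(cap_h = 336))
  uncapped <- allocate_gaps(g, grid25, "linear", allocation_config(cap_h = Inf))
  expect_equal(sum(capped$values), sum(uncapped$values))
  g$duration_h[2] <- 400
  capped2 <- allocate_gaps(g, grid25, "linear", allocation_config(cap_h = 336))
  uncapped2 <- allocate_gaps(g, grid25, "linear", allocation_config(cap_h = Inf))
  expect_lt(sum(capped2$values), sum(uncapped2$values))
  expect_equal(sum(uncapped2$values) - sum(capped2$values), 400 - 336,
               tolerance = 1e-6)
})

test_that("activity hours split intervals and skip gap candidates", {
  m <- rbind(msg_at_hours(c(0, 4), lon = 5.1, lat = 0.1),
             msg_at_hours(c(10, 14), vessel = "V2", lon = 5.1, lat = 0.35),
             msg_at_hours(c(20, 40), vessel = "V3", lon = 5.1, lat = 0.1))
  m$lat[4] <- 0.1    # V2's second ping in the adjacent cell southward
  act <- activity_hours(m, grid25)
  c1 <- cell_of(grid25, 5.1, 0.1); c2 <- cell_of(grid25, 5.1, 0.35)
  # V1: 4 h within one cell; V2: 2 h to each of two cells; V3: 20 h dropped
  expect_equal(act$values[c1$iy, c1$ix], 4 + 2)
  expect_equal(act$values[c2$iy, c2$ix], 2)
  expect_equal(sum(act$values), 8)
})

test_that("gear strata partition activity hours exactly", {
  sim <- small_sim(n_vessels = 15, days = 10)
  total <- activity_hours(sim$messages, sim$world$grid)
  strata <- activity_hours(sim$messages, sim$world$grid, stratum = "gear")
  expect_equal(Reduce(`+`, lapply(strata, `[[`, "values")), total$values,
               tolerance = 1e-9)
})

test_that("fraction obscured follows the inclusive-denominator definition", {
  g <- dg_grid(0, 1, 0, 1, 0.5)
  act <- dg_raster(g, matrix(c(90, 10, 0, 0), 2, 2))
  dis <- dg_raster(g, matrix(c(10, 0, 5, 0), 2, 2))
  fr <- fraction_obscured(dis, act)
  expect_equal(fr$values[1, 1], 0.1)    # 10 / (90 + 10)
  expect_equal(fr$values[2, 1], 0)      # no disabling, activity present
  expect_equal(fr$values[1, 2], 1)      # all-disabling cell
  expect_true(is.na(fr$values[2, 2]))   # empty cell is missing, not 0
  expect_error(fraction_obscured(dis, dg_raster(dg_grid(0, 2, 0, 2, 0.5), 1)),
               "mismatch")
})

test_that("hotspots threshold and label rook-adjacent components", {
  g <- dg_grid(0, 2, 0, 2, 0.5)
  fr <- dg_raster(g, matrix(0.5, 4, 4))
  act <- dg_raster(g, matrix(100, 4, 4))
  all_cells <- hotspots(fr, act, 0, 0)
  expect_equal(nrow(all_cells), 16)
  expect_equal(unique(all_cells$component), 1L)
  # empty selection
  expect_equal(nrow(hotspots(fr, act, 0.9, 0)), 0)
  # two cells sharing only a corner are two components (rook, not queen)
  sel <- dg_raster(g, matrix(0, 4, 4))
  sel$values[1, 1] <- 0.9; sel$values[2, 2] <- 0.9
  hs <- hotspots(sel, act, 0.8, 0)
  expect_equal(nrow(hs), 2)
  expect_equal(length(unique(hs$component)), 2)
})

test_that("gear and flag summaries account for every suspected hour", {
  sim <- small_sim(n_vessels = 20, days = 15)
  gaps <- detect_gaps(sim$messages)
  gaps[, classification := "suspected_disabling"]
  summ <- disabling_summary(gaps, sim$messages)
  by_gear <- summ[summ$stratum_type == "gear"]
  expect_equal(sum(by_gear$n_events), nrow(gaps))
  expect_equal(sum(by_gear$hours_upper), sum(gaps$duration_h), tolerance = 1e-9)
  expect_equal(sum(by_gear$hours_lower), sum(pmin(gaps$duration_h, 336)),
               tolerance = 1e-9)
  expect_true(all(summ$fraction_lower <= summ$fraction_upper + 1e-12))
  expect_true(all(summ$fraction_lower >= 0 & summ$fraction_upper <= 1))
})
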