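test_that("gap detection applies the 12-hour threshold and lookback counts", {
  # pings at 0 and 11 h only: below threshold, no gap
  expect_equal(nrow(detect_gaps(msg_at_hours(c(0, 11)))), 0)

  # hourly pings to 12 h then silence to 36 h: one 24-h gap; the half-open
  # lookback window (start-12h, start] holds the pings at 1..12 h
  g <- detect_gaps(msg_at_hours(c(0:12, 36)))
  expect_equal(nrow(g), 1)
  expect_equal(g$duration_h, 24)
  expect_equal(g$pb_12, 12L)
  expect_equal(g$pb_24, 13L)
  expect_equal(g$pb_6, 6L)

  # a ping exactly on the window's open boundary is excluded
  g2 <- detect_gaps(msg_at_hours(c(0, 6, 12, 40)))
  expect_equal(nrow(g2), 1)
  expect_equal(g2$pb_12[1], 2L)   # pings at 6 and 12; the one at 0 is outside
})

test_that("exact 12-hour spacing is a gap, 11.99 hours is not", {
  expect_equal(nrow(detect_gaps(msg_at_hours(c(0, 11.99)))), 0)
  g <- detect_gaps(msg_at_hours(c(0, 12)))
  expect_equal(nrow(g), 1)
  expect_equal(g$duration_h, 12)
})

test_that("gap detection is independent across vessels", {
  m1 <- msg_at_hours(c(0:5, 30, 31), vessel = "VA")
  m2 <- msg_at_hours(c(0, 2, 50), vessel = "VB", lon = 8)
  joint <- detect_gaps(rbind(m2, m1))   # deliberately unsorted input
  solo <- rbind(detect_gaps(m1), detect_gaps(m2))
  data.table::setorderv(solo, c("vessel_id", "start"))
  expect_equal(joint, solo)
})

test_that("planted truth intervals are recovered with matching endpoints", {
  sim <- small_sim(n_vessels = 25, days = 20)
  gaps <- detect_gaps(sim$messages)
  gaps <- label_gaps(gaps, sim$truth)
  long_truth <- sim$truth[as.numeric(sim$truth$end - sim$truth$start,
                                     units = "hours") >= 12]
  found <- merge(long_truth, gaps,
                 by.x = c("vessel_id", "start"), by.y = c("vessel_id", "start"))
  expect_equal(nrow(found), nrow(long_truth))
  expect_equal(found$end.x, found$end.y)
  expect_equal(found$start_lon.x, found$start_lon.y)
})

test_that("filters use strict thresholds at the documented boundaries", {
  g <- dg_grid(0, 10, -5, 5, 0.25)
  base <- detect_gaps(msg_at_hours(c(0:12, 42), lon = 5, lat = 0))
  run_filter <- function(shore_nmi, rec) {
    shore <- dg_raster(g, shore_nmi * 1.852)
    filter_gaps(base, shore, const_reception(g, rec))
  }
  expect_equal(run_filter(49.9, 25)$retained, FALSE)  # inshore of 50 nmi
  expect_equal(run_filter(50, 25)$retained, FALSE)    # exactly 50: excluded
  expect_equal(run_filter(120, 10)$retained, FALSE)   # reception exactly 10
  expect_equal(run_filter(120, 10.01)$retained, TRUE)
  expect_equal(run_filter(120, 25)$retained, TRUE)
  f <- run_filter(49.9, 25)
  expect_equal(f$classification, "excluded")
  expect_equal(f$dist_shore_nmi, 49.9, tolerance = 1e-9)
  expect_error(
    filter_gaps(base, dg_raster(dg_grid(6, 10, -5, 5, 0.25), 200),
                const_reception(g, 25)),
    "outside")
})

test_that("rule classification thresholds on lookback count and reception", {
  g <- dg_grid(0, 10, -5, 5, 0.25)
  mk <- function(pb) {
    # pb pings in the final 12 h before a 30-h gap
    hrs <- c(seq(12 - 11.5, 12, length.out = pb), 42)
    detect_gaps(msg_at_hours(c(0, hrs)), lookback_h = c(6, 12, 18, 24))
  }
  shore <- dg_raster(g, 400)
  f20 <- filter_gaps(mk(20), shore, const_reception(g, 15))
  expect_equal(classify_gaps(f20, rule_model(12, 14, 10))$classification[1],
               "suspected_disabling")
  f13 <- filter_gaps(mk(13), shore, const_reception(g, 15))
  expect_equal(classify_gaps(f13, rule_model(12, 14, 10))$classification[1],
               "not_suspected")
  # degenerate threshold k = 1: any retained gap is suspected
  expect_equal(classify_gaps(f13, rule_model(12, 1, 10))$classification[1],
               "suspected_disabling")
  # missing lookback column
  expect_error(classify_gaps(f13, rule_model(3, 5, 10)), "pb_3")
})

test_that("classification is monotone in k", {
  fx <- study_fixture()
  sets <- lapply(c(5, 6, 10, 14, 20), function(k) {
    cg <- classify_gaps(fx$gaps, rule_model(12, k, 10))
    which(cg$classification == "suspected_disabling")
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("f_beta matches hand-computed and degenerate cases", {
  expect_equal(f_beta(10, 0, 0), 1)
  expect_equal(f_beta(0, 5, 5), 0)
  # P = 0.8, R = 0.5 -> 1.25 * 0.8 * 0.5 / (0.25 * 0.8 + 0.5) = 0.714286
  expect_equal(f_beta(40, 10, 40), 0.714286, tolerance = 1e-6)
  expect_error(f_beta(0, 0, 0), "undefined")
})

test_that("f_beta equals brute-force per-item computation", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    if (tp + fp + fn == 0) next
    beta <- sample(c(0.5, 1, 2), 1)
    brute <- if (tp == 0) 0 else {
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      (1 + beta^2) * p * r / (beta^2 * p + r)
    }
    expect_equal(f_beta(tp, fp, fn, beta), brute, tolerance = 1e-12)
  }
})

test_that("evaluation reports the documented confusion-derived rates", {
  # build a labelled gap set producing tp=86, fp=14, fn=50, tn=350
  n <- c(tp = 86, fp = 14, fn = 50, tn = 350)
  g <- data.table::data.table(
    vessel_id = "V", retained = TRUE,
    pb_12 = rep(c(20, 20, 1, 1), n),
    reception_pred = 30,
    truth = rep(c("intentional", "reception", "intentional", "reception"), n))
  ev <- evaluate_rule(g, rule_model(12, 14, 10))
  expect_equal(ev$precision, 0.86)
  expect_equal(ev$fpr, 14 / 364)
  expect_equal(round(ev$fpr, 4), 0.0385)
  # a model that labels nothing positive has undefined precision, not 0
  ev2 <- evaluate_rule(g, rule_model(12, 25, 10))
  expect_true(is.na(ev2$precision))
  expect_equal(ev2$fpr, 0)
})

test_that("model selection honours score, tie-breaks and reproducibility", {
  # separable synthetic truth: intentional gaps have pb_12 >= 10
  set.seed(1)
  n_pos <- 60; n_neg <- 40
  g <- data.table::data.table(
    vessel_id = "V", retained = TRUE,
    pb_12 = c(sample(10:30, n_pos, TRUE), sample(1:5, n_neg, TRUE)),
    pb_6 = c(sample(10:30, n_pos, TRUE), sample(1:5, n_neg, TRUE)),
    reception_pred = 30,
    truth = rep(c("intentional", "reception"), c(n_pos, n_neg)))
  # single candidate: returned regardless of score
  only <- list(rule_model(12, 29, 10))
  expect_identical(select_model(g, only, seed = 5)$best, only[[1]])
  # a perfect separator in the grid is selected with mean F0.5 = 1
  cands <- list(rule_model(12, 29, 10), rule_model(12, 8, 10),
                rule_model(12, 6, 10))
  sel <- select_model(g, cands, seed = 5)
  expect_equal(sel$best$k, 6L)   # tie between k = 6 and k = 8 -> smaller k
  expect_equal(max(sel$scores$mean_f05), 1)
  expect_equal(sel$eval$precision, 1)
  # reproducible from seed
  sel2 <- select_model(g, cands, seed = 5)
  expect_identical(sel$scores, sel2$scores)
})
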