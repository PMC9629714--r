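# Gap events: detection of AIS transmission gaps, the spatial/temporal
# filters (>= 12 h, > 50 nmi from shore, > 10 positions/day predicted
# reception), the rule-based disabling classifier, and its selection by
# F0.5 under repeated stratified k-fold cross-validation.

#' Detect AIS transmission gaps
#'
#' One gap event per consecutive message pair of the same vessel spaced by
#' at least \code{min_gap_h} hours. For every lookback window L the count of
#' positions in the half-open window (start - L, start] is recorded (the
#' gap's own starting ping counts once).
#'
#' @param messages message table; sorted defensively per vessel.
#' @param min_gap_h minimum gap duration in hours (default 12).
#' @param lookback_h lookback windows (hours) for which ping counts are
#'   computed (default c(6, 12, 18, 24)).
#' @return data.table of gap events ordered by vessel then start time, with
#'   columns vessel_id, start, end, duration_h, start_lon/lat, end_lon/lat,
#'   pb_<L> per lookback window, device_class, gear, flag.
#' @export
detect_gaps <- function(messages, min_gap_h = 12, lookback_h = c(6, 12, 18, 24)) {
  m <- data.table::as.data.table(messages)
  data.table::setorderv(m, c("vessel_id", "timestamp"))
  m[, t_num := as.numeric(timestamp)]
  res <- m[, {
    n <- .N
    if (n < 2) NULL else {
      dt_h <- diff(t_num) / 3600
      gi <- which(dt_h >= min_gap_h)
      if (!length(gi)) NULL else {
        out <- list(start = timestamp[gi], end = timestamp[gi + 1],
                    duration_h = dt_h[gi],
                    start_lon = lon[gi], start_lat = lat[gi],
                    end_lon = lon[gi + 1], end_lat = lat[gi + 1],
                    device_class = device_class[gi], gear = gear[gi],
                    flag = flag[gi])
        for (L in lookback_h) {
          # count pings in the half-open window (start - L, start]:
          # (# t <= start) - (# t <= start - L); a ping exactly at
          # start - L is outside, the gap's own starting ping counts once
          n_le_lo <- findInterval(t_num[gi] - L * 3600, t_num)
          out[[paste0("pb_", L)]] <- gi - n_le_lo
        }
        out
      }
    }
  }, by = vessel_id]
  if (nrow(res) == 0) {
    cols <- c("vessel_id", "start", "end", "duration_h", "start_lon",
              "start_lat", "end_lon", "end_lat", "device_class", "gear",
              "flag", paste0("pb_", lookback_h))
    res <- data.table::as.data.table(
      stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  data.table::setorderv(res, c("vessel_id", "start"))
  res[]
}

#' Apply the spatial and reception filters to gap events
#'
#' A gap is retained iff its start position is strictly more than
#' \code{min_shore_nmi} nautical miles from shore AND the class-matched
#' predicted reception there strictly exceeds \code{min_reception}
#' positions/day AND duration >= \code{min_gap_h} hours. The covariates are
#' stored on every event regardless of outcome; excluded events get
#' classification "excluded".
#'
#' @param gaps from \code{detect_gaps}.
#' @param shore_dist_km shore-distance raster (km, unclipped).
#' @param reception named list of predicted \code{reception_grid}s by device
#'   class (e.g. \code{list(A = ..., B = ...)}).
#' @param min_shore_nmi shore filter (default 50 nautical miles, strict >).
#' @param min_reception reception filter (default 10 positions/day, strict >).
#' @param min_gap_h duration filter (default 12 h, inclusive >=).
#' @return gaps with columns dist_shore_nmi, reception_pred, retained,
#'   classification added.
#' @export
filter_gaps <- function(gaps, shore_dist_km, reception,
                        min_shore_nmi = 50, min_reception = 10,
                        min_gap_h = 12) {
  g <- data.table::as.data.table(gaps)
  if (nrow(g) == 0) {
    g[, c("dist_shore_nmi", "reception_pred", "retained", "classification") :=
        list(numeric(0), numeric(0), logical(0), character(0))]
    return(g[])
  }
  ds <- tryCatch(raster_at(shore_dist_km, g$start_lon, g$start_lat) / KM_PER_NMI,
                 error = function(e) stop("gap start position outside raster extent (",
                                          conditionMessage(e), ")"))
  rp <- numeric(nrow(g))
  for (cl in unique(g$device_class)) {
    grd <- reception[[cl]]
    if (is.null(grd)) stop("no predicted reception grid for device class ", cl)
    sel <- which(g$device_class == cl)
    rp[sel] <- tryCatch(reception_at(grd, g$start_lon[sel], g$start_lat[sel]),
                        error = function(e) {
                          i <- sel[1]
                          stop(sprintf("gap start outside reception extent (vessel %s at %s)",
                                       g$vessel_id[i], format(g$start[i])))
                        })
  }
  g[, dist_shore_nmi := ds]
  g[, reception_pred := rp]
  g[, retained := dist_shore_nmi > min_shore_nmi &
        !is.na(reception_pred) & reception_pred > min_reception &
        duration_h >= min_gap_h]
  g[, classification := ifelse(retained, NA_character_, "excluded")]
  g[]
}

#' Rule model for suspected disabling
#'
#' A retained gap is classified \code{suspected_disabling} iff the ping
#' count in the \code{lookback_h}-hour window before the gap is at least
#' \code{k} AND predicted reception at the start strictly exceeds
#' \code{reception_min}. The default is the selected headline model:
#' 12-hour lookback with k = 14.
#'
#' @param lookback_h lookback window, hours.
#' @param k minimum position count in the window (>= 1).
#' @param reception_min positions/day threshold inside the rule (strict >).
#' @return a \code{rule_model}.
#' @export
rule_model <- function(lookback_h = 12, k = 14, reception_min = 10) {
  stopifnot(lookback_h > 0, k >= 1)
  structure(list(lookback_h = lookback_h, k = as.integer(k),
                 reception_min = reception_min), class = "rule_model")
}

#' @export
print.rule_model <- function(x, ...) {
  cat(sprintf("<rule_model: >=%d pings in %gh lookback, reception > %g/day>\n",
              x$k, x$lookback_h, x$reception_min))
  invisible(x)
}

#' Classify retained gaps with a rule model
#'
#' @param gaps filtered gaps (from \code{filter_gaps}).
#' @param model a \code{rule_model}.
#' @return gaps with \code{classification} set to \code{suspected_disabling}
#'   or \code{not_suspected} on retained rows ("excluded" rows untouched).
#' @export
classify_gaps <- function(gaps, model = rule_model()) {
  g <- data.table::copy(data.table::as.data.table(gaps))
  pb_col <- paste0("pb_", model$lookback_h)
  if (!pb_col %in% names(g)) {
    stop("gaps lack lookback window pb_", model$lookback_h,
         "; re-run detect_gaps with it")
  }
  sus <- g[[pb_col]] >= model$k & g$reception_pred > model$reception_min
  idx <- which(g$retained)
  data.table::set(g, idx, "classification",
                  ifelse(sus[idx], "suspected_disabling", "not_suspected"))
  g[]
}

#' F-beta score from confusion counts
#'
#' \eqn{(1+\beta^2) P R / (\beta^2 P + R)} with precision P = tp/(tp+fp) and
#' recall R = tp/(tp+fn); 0 when tp = 0. The default beta = 0.5 weights
#' precision above recall.
#'
#' @param tp,fp,fn confusion counts (>= 0, not all zero).
#' @param beta precision/recall trade-off.
#' @return score in [0, 1].
#' @export
f_beta <- function(tp, fp, fn, beta = 0.5) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) stop("F-beta undefined: all counts zero")
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  (1 + beta^2) * p * r / (beta^2 * p + r)
}

#' Attach ground-truth causes to gap events
#'
#' A gap is labelled \code{intentional} iff it overlaps a truth-log
#' intentional interval of the same vessel, else \code{reception}.
#'
#' @param gaps gap table.
#' @param truth truth log (vessel_id, start, end, cause).
#' @return gaps with a \code{truth} column.
#' @export
label_gaps <- function(gaps, truth) {
  g <- data.table::copy(data.table::as.data.table(gaps))
  tt <- data.table::as.data.table(truth)
  tt <- tt[tt$cause == "intentional"]
  g[, truth := "reception"]
  if (nrow(tt) && nrow(g)) {
    for (i in seq_len(nrow(tt))) {
      g[vessel_id == tt$vessel_id[i] & start < tt$end[i] & end > tt$start[i],
        truth := "intentional"]
    }
  }
  g[]
}

confusion_counts <- function(g) {
  sus <- g$classification == "suspected_disabling"
  pos <- g$truth == "intentional"
  list(tp = sum(sus & pos), fp = sum(sus & !pos),
       fn = sum(!sus & pos), tn = sum(!sus & !pos))
}

#' Evaluate a rule model against truth labels
#'
#' Confusion counts over retained gaps only, with precision, recall,
#' false-positive rate and F0.5. Precision is NA (not 0) when the model
#' labels nothing positive.
#'
#' @param gaps filtered + labelled gaps.
#' @param model a \code{rule_model}.
#' @param beta F-beta weight (default 0.5).
#' @return a \code{classifier_eval} list: tp, fp, fn, tn, precision, recall,
#'   fpr, f_beta.
#' @export
evaluate_rule <- function(gaps, model, beta = 0.5) {
  g <- classify_gaps(gaps, model)
  g <- g[g$retained == TRUE]
  cc <- confusion_counts(g)
  precision <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_
  recall <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
  fpr <- if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else NA_real_
  fb <- if (cc$tp + cc$fp + cc$fn > 0) f_beta(cc$tp, cc$fp, cc$fn, beta) else NA_real_
  structure(c(cc, list(precision = precision, recall = recall, fpr = fpr,
                       f_beta = fb, beta = beta)),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("<classifier_eval tp=%d fp=%d fn=%d tn=%d | P=%.3f R=%.3f FPR=%.4f F%.1f=%.3f>\n",
              x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$fpr, x$beta,
              x$f_beta))
  invisible(x)
}

#' Default candidate grid of rule models
#'
#' @param lookback_h,k,reception_min vectors crossed into candidates.
#' @return list of \code{rule_model}s.
#' @export
candidate_grid <- function(lookback_h = c(6, 12, 18, 24), k = 2:30,
                           reception_min = c(10, 15, 20)) {
  gr <- expand.grid(lookback_h = lookback_h, k = k,
                    reception_min = reception_min)
  lapply(seq_len(nrow(gr)), function(i) {
    rule_model(gr$lookback_h[i], gr$k[i], gr$reception_min[i])
  })
}

# Stratified fold ids: within each class, shuffled round-robin assignment.
stratified_folds <- function(labels, k_folds) {
  if (min(table(labels)) < k_folds) {
    stop("cannot stratify: a class has fewer members than folds")
  }
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

#' Select a rule model by F0.5 under repeated k-fold cross-validation
#'
#' For every candidate the F0.5 score is computed on each held-out fold
#' (folds stratified by truth label, redrawn each repeat) and averaged over
#' folds x repeats. The best candidate maximises mean F0.5; ties break by
#' higher precision on the full retained set, then smaller k, then shorter
#' lookback. Fold assignment is reproducible from \code{seed}.
#'
#' @param gaps filtered + labelled gaps (truth present on retained rows).
#' @param candidates list of \code{rule_model}s (default \code{candidate_grid()}).
#' @param k_folds,n_repeats cross-validation design (defaults 5 and 10).
#' @param seed integer seed.
#' @return list: \code{best} (rule_model), \code{scores} (data.table:
#'   candidate parameters, mean and sd of F0.5), \code{eval}
#'   (\code{classifier_eval} of the best model on all retained gaps).
#' @export
select_model <- function(gaps, candidates = candidate_grid(), k_folds = 5,
                         n_repeats = 10, seed = 1L) {
  stopifnot(length(candidates) > 0)
  g <- data.table::as.data.table(gaps)
  g <- g[g$retained == TRUE]
  if (!nrow(g)) stop("no retained gaps to select on")
  if (any(is.na(g$truth))) stop("truth labels required on every retained gap")
  set.seed(seed)
  n_cand <- length(candidates)
  pos <- g$truth == "intentional"
  # precompute the rule decision per candidate once; folds only re-slice it
  sus <- matrix(FALSE, nrow(g), n_cand)
  for (j in seq_len(n_cand)) {
    m <- candidates[[j]]
    pb <- g[[paste0("pb_", m$lookback_h)]]
    if (is.null(pb)) stop("gaps lack lookback window pb_", m$lookback_h)
    sus[, j] <- pb >= m$k & g$reception_pred > m$reception_min
  }
  scores <- matrix(NA_real_, k_folds * n_repeats, n_cand)
  row <- 0L
  for (rep_i in seq_len(n_repeats)) {
    fold <- stratified_folds(ifelse(pos, "pos", "neg"), k_folds)
    for (f in seq_len(k_folds)) {
      row <- row + 1L
      held <- fold == f
      for (j in seq_len(n_cand)) {
        s <- sus[held, j]; p <- pos[held]
        tp <- sum(s & p); fp <- sum(s & !p); fn <- sum(!s & p)
        scores[row, j] <- if (tp + fp + fn == 0) NA_real_ else f_beta(tp, fp, fn)
      }
    }
  }
  mean_f <- colMeans(scores, na.rm = TRUE)
  sd_f <- apply(scores, 2, stats::sd, na.rm = TRUE)
  # tie-breaks: precision on the full set, then smaller k, then shorter lookback
  prec_all <- vapply(seq_len(n_cand), function(j) {
    tp <- sum(sus[, j] & pos); fp <- sum(sus[, j] & !pos)
    if (tp + fp > 0) tp / (tp + fp) else -1
  }, 0)
  kv <- vapply(candidates, `[[`, 0L, "k")
  lb <- vapply(candidates, function(m) m$lookback_h, 0)
  ord <- order(-mean_f, -prec_all, kv, lb)
  best <- candidates[[ord[1]]]
  tab <- data.table::data.table(
    lookback_h = lb, k = kv,
    reception_min = vapply(candidates, `[[`, 0, "reception_min"),
    mean_f05 = mean_f, sd_f05 = sd_f)
  data.table::setorderv(tab, "mean_f05", order = -1L)
  list(best = best, scores = tab[], eval = evaluate_rule(gaps, best))
}
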