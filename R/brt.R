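# Drivers of suspected disabling: presence / pseudo-absence dataset over
# grid cells, boosted regression trees (binomial deviance, stagewise
# gradient boosting via xgboost), relative importance (normalised split
# gain, summing to 100%), partial dependence, and evaluation by explained
# deviance, AUC and true skill statistic under repeated 75/25 splits with
# per-iteration absence redraws.

DRIVER_NAMES <- c("dist_shore", "dist_mpa", "loitering", "dist_piracy",
                  "chl", "eke", "sst", "sst_sd")

#' Minimum-distance raster to a set of source points
#'
#' Per cell centre, the minimum great-circle distance to any source,
#' clipped at \code{clip_km} to constrain driver models to proximal
#' effects.
#'
#' @param points data.frame with lon, lat (>= 1 row).
#' @param grid target \code{dg_grid}.
#' @param clip_km clip distance (default 400 km).
#' @return \code{dg_raster} in km.
#' @export
distance_raster <- function(points, grid, clip_km = 400) {
  if (is.null(points) || nrow(points) == 0) stop("empty source geometry set")
  min_dist_field(grid, points, clip_km = clip_km)
}

raster_vec <- function(r) as.vector(t(r$values))  # linear cell order

#' Build the presence / pseudo-absence driver table
#'
#' Presences are grid cells with at least one suspected disabling event
#' (positive \code{disabling} raster value); eligible absences are cells
#' with fishing activity and no disabling. Cells with any missing driver
#' are dropped (count reported via message). Absences are sampled uniformly
#' without replacement to a 1:1 ratio, reproducibly from \code{seed}. The
#' eligible absence pool is kept as an attribute so evaluation can redraw
#' absences per iteration.
#'
#' @param disabling \code{dg_raster}: disabling events or hours per cell.
#' @param fishing \code{dg_raster}: fishing activity hours per cell.
#' @param drivers named list of 8 driver \code{dg_raster}s (DRIVER_NAMES).
#' @param gear optional label stored on the table.
#' @param seed integer seed for the absence draw.
#' @return data.table: cell, label (1 presence / 0 absence), 8 driver
#'   columns; attributes \code{absence_pool} (data.table of all eligible
#'   absences) and \code{gear}.
#' @export
build_dataset <- function(disabling, fishing, drivers, gear = NULL, seed = 1L) {
  stopifnot(all(DRIVER_NAMES %in% names(drivers)))
  for (d in drivers) {
    if (!same_geometry(d, disabling)) stop("driver/disabling geometry mismatch")
  }
  if (!same_geometry(fishing, disabling)) stop("fishing/disabling geometry mismatch")
  dis <- raster_vec(disabling); fis <- raster_vec(fishing)
  dis[is.na(dis)] <- 0; fis[is.na(fis)] <- 0
  X <- do.call(cbind, lapply(drivers[DRIVER_NAMES], raster_vec))
  colnames(X) <- DRIVER_NAMES
  complete <- stats::complete.cases(X)
  n_dropped <- sum(!complete & (dis > 0 | fis > 0))
  if (n_dropped > 0) message(n_dropped, " cells dropped for missing drivers")
  pres_cells <- which(dis > 0 & complete)
  elig_cells <- which(fis > 0 & dis == 0 & complete)
  if (length(pres_cells) == 0) stop("zero presence cells: no model possible")
  if (length(elig_cells) < length(pres_cells)) {
    stop("eligible absence cells (", length(elig_cells),
         ") fewer than presences (", length(pres_cells),
         "); use a larger fixture or relax eligibility")
  }
  set.seed(seed)
  abs_cells <- sample(elig_cells, length(pres_cells))
  tab <- data.table::data.table(
    cell = c(pres_cells, abs_cells),
    label = rep(c(1L, 0L), c(length(pres_cells), length(abs_cells))))
  tab <- cbind(tab, data.table::as.data.table(X[tab$cell, , drop = FALSE]))
  pool <- data.table::data.table(cell = elig_cells)
  pool <- cbind(pool, data.table::as.data.table(X[elig_cells, , drop = FALSE]))
  data.table::setattr(tab, "absence_pool", pool)
  data.table::setattr(tab, "gear", gear)
  tab[]
}

#' BRT hyperparameters
#' @param tree_complexity maximum tree depth (interaction depth).
#' @param learning_rate shrinkage per tree.
#' @param bag_fraction row subsample per tree.
#' @param max_trees ceiling on ensemble size.
#' @param min_trees floor on ensemble size: ensembles of only a handful of
#'   trees give erratic split-gain importances, so the internal
#'   cross-validation never chooses fewer than this many.
#' @param cv_folds internal folds used to choose the ensemble size.
#' @export
brt_hyper <- function(tree_complexity = 3, learning_rate = 0.01,
                      bag_fraction = 0.5, max_trees = 10000, min_trees = 50,
                      cv_folds = 5) {
  list(tree_complexity = tree_complexity, learning_rate = learning_rate,
       bag_fraction = bag_fraction, max_trees = max_trees,
       min_trees = min_trees, cv_folds = cv_folds)
}

xgb_params <- function(hyper) {
  list(objective = "binary:logistic", eval_metric = "logloss",
       max_depth = hyper$tree_complexity, eta = hyper$learning_rate,
       subsample = hyper$bag_fraction, nthread = 1)
}

train_booster <- function(X, y, hyper, nrounds, seed) {
  set.seed(seed)
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  xgboost::xgb.train(params = xgb_params(hyper), data = dm, nrounds = nrounds,
                     verbose = 0)
}

choose_nrounds <- function(X, y, hyper, seed) {
  set.seed(seed)
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  cv <- xgboost::xgb.cv(params = xgb_params(hyper), data = dm,
                        nrounds = hyper$max_trees, nfold = hyper$cv_folds,
                        early_stopping_rounds = 50, verbose = 0)
  best <- cv$early_stop$best_iteration
  if (is.null(best) || !length(best)) best <- cv$niter
  max(best, hyper$min_trees %||% 50)
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit a boosted regression tree model
#'
#' Binomial-deviance gradient boosting (depth = tree complexity, shrinkage,
#' bagging); the ensemble size is chosen by internal cross-validation up to
#' \code{max_trees}. Relative importance is each driver's share of total
#' split gain, normalised to sum to 100; constant drivers are retained with
#' zero importance (with a warning). Partial dependence is the mean
#' predicted probability over the table with one driver swept along a
#' 100-point grid spanning its observed range. Explained deviance is
#' 1 - residual/null deviance on the training data.
#'
#' @param table from \code{build_dataset}.
#' @param hyper from \code{brt_hyper}.
#' @param seed integer seed.
#' @return a \code{brt_fit}: booster, nrounds, importance (named %,
#'   sums to 100), pdp (data.table: driver, x, yhat), explained_deviance,
#'   hyper.
#' @export
fit_brt <- function(table, hyper = brt_hyper(), seed = 1L) {
  stopifnot(sum(table$label == 1) >= 20, sum(table$label == 0) >= 20)
  X <- as.matrix(table[, DRIVER_NAMES, with = FALSE])
  y <- table$label
  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    warning("constant driver(s) retained with zero importance: ",
            paste(DRIVER_NAMES[const], collapse = ", "))
  }
  nrounds <- choose_nrounds(X, y, hyper, seed)
  booster <- train_booster(X, y, hyper, nrounds, seed)
  imp_raw <- xgboost::xgb.importance(model = booster)
  imp <- stats::setNames(rep(0, length(DRIVER_NAMES)), DRIVER_NAMES)
  imp[imp_raw$Feature] <- imp_raw$Gain
  imp <- 100 * imp / sum(imp)
  pdp <- data.table::rbindlist(lapply(DRIVER_NAMES, function(d) {
    xs <- seq(min(X[, d]), max(X[, d]), length.out = 100)
    Xp <- X
    yhat <- vapply(xs, function(x0) {
      Xp[, d] <- x0
      mean(stats::predict(booster, xgboost::xgb.DMatrix(Xp)))
    }, 0)
    data.table::data.table(driver = d, x = xs, yhat = yhat)
  }))
  p_hat <- stats::predict(booster, xgboost::xgb.DMatrix(X))
  ed <- 1 - binomial_deviance(y, p_hat) / binomial_deviance(y, mean(y))
  structure(list(booster = booster, nrounds = nrounds, importance = imp,
                 pdp = pdp, explained_deviance = ed, hyper = hyper,
                 gear = attr(table, "gear")),
            class = "brt_fit")
}

#' @export
print.brt_fit <- function(x, ...) {
  top <- sort(x$importance, decreasing = TRUE)[1:3]
  cat(sprintf("<brt_fit %d trees, explained deviance %.1f%%, top drivers: %s>\n",
              x$nrounds, 100 * x$explained_deviance,
              paste(sprintf("%s %.0f%%", names(top), top), collapse = ", ")))
  invisible(x)
}

auc_score <- function(y, p) {
  as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<",
                                 levels = c(0, 1))))
}

max_tss <- function(y, p) {
  # sensitivity + specificity - 1 at the threshold maximising it
  thr <- sort(unique(p))
  best <- -1
  for (t in thr) {
    pred <- p >= t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

#' Evaluate a BRT model by repeated split cross-validation
#'
#' Runs exactly \code{n_iter} iterations. Each iteration redraws the
#' absences from the eligible pool (keeping the 1:1 ratio), splits the
#' rebuilt table into a stratified \code{train_frac} / (1 - train_frac)
#' partition, trains a booster on the training part (ensemble size fixed
#' by one internal cross-validation on the full input table) and scores
#' held-out AUC and max-threshold TSS. Explained deviance comes from the
#' final full-data fit.
#'
#' @param table from \code{build_dataset} (carries the absence pool).
#' @param hyper from \code{brt_hyper}.
#' @param n_iter iterations (default 50).
#' @param train_frac training fraction (default 0.75).
#' @param seed integer seed; the whole procedure is reproducible from it.
#' @return an \code{eval_report}: auc_mean/sd, tss_mean/sd,
#'   explained_deviance, n_iter, per_iter (data.table iter, auc, tss).
#' @export
evaluate_brt <- function(table, hyper = brt_hyper(), n_iter = 50,
                         train_frac = 0.75, seed = 1L) {
  pool <- attr(table, "absence_pool")
  if (is.null(pool)) stop("table lacks an absence pool; use build_dataset()")
  pres <- table[table$label == 1L]
  n_pres <- nrow(pres)
  X_full <- as.matrix(table[, DRIVER_NAMES, with = FALSE])
  nrounds <- choose_nrounds(X_full, table$label, hyper, seed)
  full_fit <- train_booster(X_full, table$label, hyper, nrounds, seed)
  p_full <- stats::predict(full_fit, xgboost::xgb.DMatrix(X_full))
  ed <- 1 - binomial_deviance(table$label, p_full) /
    binomial_deviance(table$label, mean(table$label))
  set.seed(seed + 1L)
  res <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    abs_idx <- sample.int(nrow(pool), n_pres)
    abs_rows <- pool[abs_idx]
    Xi <- rbind(as.matrix(pres[, DRIVER_NAMES, with = FALSE]),
                as.matrix(abs_rows[, DRIVER_NAMES, with = FALSE]))
    yi <- rep(c(1L, 0L), c(n_pres, n_pres))
    for (attempt in 1:10) {
      tr <- c(sample.int(n_pres, round(train_frac * n_pres)),
              n_pres + sample.int(n_pres, round(train_frac * n_pres)))
      te <- setdiff(seq_len(2 * n_pres), tr)
      if (length(unique(yi[te])) == 2 && length(unique(yi[tr])) == 2) break
      if (attempt == 10) stop("could not form a two-class test split")
    }
    fit <- train_booster(Xi[tr, , drop = FALSE], yi[tr], hyper, nrounds,
                         seed + it)
    p_te <- stats::predict(fit, xgboost::xgb.DMatrix(Xi[te, , drop = FALSE]))
    res[[it]] <- data.table::data.table(
      iter = it, auc = auc_score(yi[te], p_te), tss = max_tss(yi[te], p_te),
      n_train = length(tr), n_test = length(te),
      absence_sig = sum(abs_idx))
  }
  per <- data.table::rbindlist(res)
  structure(list(auc_mean = mean(per$auc), auc_sd = stats::sd(per$auc),
                 tss_mean = mean(per$tss), tss_sd = stats::sd(per$tss),
                 explained_deviance = ed, n_iter = n_iter, per_iter = per[]),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %d iters: AUC %.3f±%.3f, TSS %.3f±%.3f, expl. dev. %.1f%%>\n",
              x$n_iter, x$auc_mean, x$auc_sd, x$tss_mean, x$tss_sd,
              100 * x$explained_deviance))
  invisible(x)
}
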