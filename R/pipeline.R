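# One-command pipeline: simulate -> reception -> classify -> allocate ->
# drivers, with config validation, per-stage seeds derived deterministically
# from one global seed, and a JSON manifest of outputs.

#' Pipeline configuration
#'
#' Collects every stage parameter with the analysis defaults (12 h minimum
#' gap, 50 nmi shore filter, 10 positions/day reception filter, rule model
#' lookback 12 h with k = 14, 336 h cap, 1:1 presence:absence, 50
#' iterations of 75/25 evaluation splits, 400 km driver clip).
#'
#' @param world a \code{world_config}.
#' @param fleet a \code{fleet_config}.
#' @param days simulated days.
#' @param min_gap_h,min_shore_nmi,min_reception gap filters.
#' @param obs_cell_deg,pred_cell_deg reception map resolutions.
#' @param model a \code{rule_model}, or NULL to select one by repeated
#'   k-fold F0.5 (needs truth labels).
#' @param select list(k_folds, n_repeats) for model selection.
#' @param cap_h,max_speed_knots allocation parameters.
#' @param brt list(hyper = brt_hyper(), n_iter, train_frac).
#' @param seed global seed; per-stage seeds derive from it.
#' @return a \code{pipeline_config}.
#' @export
pipeline_config <- function(world = world_config(), fleet = fleet_config(),
                            days = 60, min_gap_h = 12, min_shore_nmi = 50,
                            min_reception = 10, obs_cell_deg = 1,
                            pred_cell_deg = 0.25, model = rule_model(),
                            select = list(k_folds = 5, n_repeats = 10),
                            cap_h = 336, max_speed_knots = 10,
                            brt = list(hyper = brt_hyper(), n_iter = 50,
                                       train_frac = 0.75),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a \code{pipeline_config}.
#' @return character vector of violations (empty when valid), each naming
#'   the offending field and constraint.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  chk(inherits(config$world, "world_config"), "world: not a world_config")
  chk(inherits(config$fleet, "fleet_config"), "fleet: not a fleet_config")
  if (inherits(config$fleet, "fleet_config")) {
    for (mx in c("gear_mix", "flag_mix", "device_class_mix")) {
      chk(abs(sum(config$fleet[[mx]]) - 1) <= 1e-9,
          paste0("fleet$", mx, ": proportions must sum to 1"))
    }
    chk(config$fleet$n_vessels >= 1, "fleet$n_vessels: must be >= 1")
  }
  chk(config$days >= 1, "days: must be >= 1")
  chk(config$min_gap_h > 0, "min_gap_h: must be > 0")
  chk(config$min_shore_nmi >= 0, "min_shore_nmi: must be >= 0")
  chk(config$min_reception >= 0, "min_reception: must be >= 0")
  chk(config$cap_h > 0, "cap_h: must be > 0")
  chk(config$max_speed_knots > 0, "max_speed_knots: must be > 0")
  if (!is.null(config$model)) {
    chk(inherits(config$model, "rule_model"), "model: not a rule_model")
  }
  chk(config$brt$n_iter >= 1, "brt$n_iter: must be >= 1")
  chk(config$brt$train_frac > 0 && config$brt$train_frac < 1,
      "brt$train_frac: must be in (0, 1)")
  v
}

#' Derive a per-stage seed from the global seed
#'
#' \code{(seed * 7919 + stage index * 10007) mod (2^31 - 1)}: documented,
#' deterministic, and keeps every derived seed a valid 32-bit integer so
#' stages are individually reproducible.
#'
#' @param seed global integer seed.
#' @param stage one of the pipeline stage names.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage = c("simulate", "reception", "classify",
                                       "allocate", "drivers")) {
  stage <- match.arg(stage)
  i <- match(stage, c("simulate", "reception", "classify", "allocate",
                      "drivers"))
  as.integer((as.numeric(seed) * 7919 + i * 10007) %% 2147483647)
}

#' Run the full pipeline
#'
#' Stages in order: simulate the world and fleet, build observed/predicted
#' reception maps per device class, detect + filter + classify gaps
#' (optionally selecting the rule model by repeated k-fold F0.5 against the
#' synthetic truth), allocate hidden time by both methods, and fit/evaluate
#' the driver BRT. Outputs (CSV tables, .asc rasters, JSON manifest with
#' file checksums) are written under \code{out_dir}.
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir output directory (created if needed).
#' @param run_brt fit the driver model stage (default TRUE).
#' @return invisibly, a result list: world, messages, truth, reception,
#'   gaps, model, eval, rasters, summary, brt, manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("darkgaps_"),
                         run_brt = TRUE) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    world <- build_world(config$world)
    fleet <- config$fleet
    fleet$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_fleet(world, fleet, config$days)
    write_fixture(sim$messages, sim$truth, out_dir)

    stage <- "reception"
    ext <- c(config$world$lon_min, config$world$lon_max,
             config$world$lat_min, config$world$lat_max)
    obs <- lapply(c(A = "A", B = "B"), function(cl) {
      observed_reception(sim$messages, config$obs_cell_deg, cl, extent = ext)
    })
    pred <- lapply(obs, predict_reception,
                   target_cell_size_deg = config$pred_cell_deg)
    for (cl in names(pred)) {
      write_asc(pred[[cl]], file.path(out_dir, paste0("reception_", cl, ".asc")))
    }
    write_asc(world$shore_dist_km, file.path(out_dir, "shore_dist_km.asc"))

    stage <- "classify"
    gaps <- detect_gaps(sim$messages, config$min_gap_h)
    gaps <- filter_gaps(gaps, world$shore_dist_km, pred,
                        config$min_shore_nmi, config$min_reception,
                        config$min_gap_h)
    gaps <- label_gaps(gaps, sim$truth)
    if (is.null(config$model)) {
      sel <- select_model(gaps, k_folds = config$select$k_folds,
                          n_repeats = config$select$n_repeats,
                          seed = stage_seed(config$seed, "classify"))
      model <- sel$best
      data.table::fwrite(sel$scores, file.path(out_dir, "model_selection.csv"))
    } else {
      sel <- NULL
      model <- config$model
    }
    gaps <- classify_gaps(gaps, model)
    eval <- evaluate_rule(gaps, model)
    gexp <- data.table::copy(gaps)
    gexp[, start := format(start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
    gexp[, end := format(end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
    data.table::fwrite(gexp, file.path(out_dir, "gaps.csv"))
    jsonlite::write_json(unclass(eval)[c("tp", "fp", "fn", "tn", "precision",
                                         "recall", "fpr", "f_beta")],
                         file.path(out_dir, "eval.json"), auto_unbox = TRUE,
                         digits = NA)

    stage <- "allocate"
    grid <- world$grid
    act <- activity_hours(sim$messages, grid)
    cfg_alloc <- allocation_config(config$cap_h, config$max_speed_knots,
                                   prior = act)
    dis_lin <- allocate_gaps(gaps, grid, "linear", cfg_alloc)
    dis_prob <- allocate_gaps(gaps, grid, "probabilistic", cfg_alloc)
    frac <- fraction_obscured(dis_lin, act)
    write_asc(act, file.path(out_dir, "activity_hours.asc"))
    write_asc(dis_lin, file.path(out_dir, "disabling_time_linear.asc"))
    write_asc(dis_prob, file.path(out_dir, "disabling_time_prob.asc"))
    write_asc(frac, file.path(out_dir, "fraction_obscured.asc"))
    summ <- disabling_summary(gaps, sim$messages, config$cap_h)
    data.table::fwrite(summ, file.path(out_dir, "table1_summary.csv"))

    brt <- NULL
    if (run_brt) {
      stage <- "drivers"
      fish <- activity_hours(sim$messages, grid, fishing_only = TRUE)
      ev_r <- event_raster(gaps, grid)
      tab <- build_dataset(ev_r, fish, world$drivers,
                           seed = stage_seed(config$seed, "drivers"))
      fit <- fit_brt(tab, config$brt$hyper,
                     seed = stage_seed(config$seed, "drivers"))
      ev <- evaluate_brt(tab, config$brt$hyper, config$brt$n_iter,
                         config$brt$train_frac,
                         seed = stage_seed(config$seed, "drivers"))
      data.table::fwrite(
        data.table::data.table(driver = names(fit$importance),
                               importance_pct = as.numeric(fit$importance)),
        file.path(out_dir, "importance.csv"))
      data.table::fwrite(fit$pdp, file.path(out_dir, "pdp.csv"))
      jsonlite::write_json(list(auc_mean = ev$auc_mean, auc_sd = ev$auc_sd,
                                tss_mean = ev$tss_mean, tss_sd = ev$tss_sd,
                                explained_deviance = ev$explained_deviance),
                           file.path(out_dir, "brt_eval.json"),
                           auto_unbox = TRUE, digits = NA)
      brt <- list(table = tab, fit = fit, eval = ev)
    }
    list(world = world, messages = sim$messages, truth = sim$truth,
         reception = list(observed = obs, predicted = pred),
         gaps = gaps, model = model, selection = sel, eval = eval,
         rasters = list(activity = act, disabling_linear = dis_lin,
                        disabling_prob = dis_prob, fraction = frac),
         summary = summ, brt = brt)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    package_version = as.character(utils::packageVersion("darkgaps")),
    seed = config$seed,
    stage_seeds = sapply(c("simulate", "reception", "classify", "allocate",
                           "drivers"), function(s) stage_seed(config$seed, s)),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror \code{world_config} / \code{fleet_config} /
#' \code{pipeline_config} arguments; omitted fields keep defaults.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  wc <- do.call(world_config, modifyList(list(), y$world %||% list()))
  fl <- y$fleet %||% list()
  for (nm in c("gear_mix", "flag_mix", "device_class_mix", "base_ping_rate")) {
    if (!is.null(fl[[nm]])) fl[[nm]] <- unlist(fl[[nm]])
  }
  fc <- do.call(fleet_config, fl)
  top <- y[setdiff(names(y), c("world", "fleet"))]
  do.call(pipeline_config, c(list(world = wc, fleet = fc), top))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
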