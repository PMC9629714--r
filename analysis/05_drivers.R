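#!/usr/bin/env Rscript
# Stage 5 — boosted-regression-tree models of disabling drivers.
#
# Presences are cells with at least one suspected disabling event; absences
# are sampled 1:1 from cells with fishing activity and no events. A model is
# fitted for all gears together and per gear type where the data allow,
# reporting relative importance (summing to 100%), partial dependence, and
# AUC / TSS over 50 iterations of 75/25 splits with per-iteration absence
# redraws.

library(darkgaps)

out <- "results"
messages <- read_messages(file.path(out, "messages.csv"))
gaps <- data.table::fread(file.path(out, "gaps.csv"))
world <- build_world(world_config(seed = stage_seed(1L, "simulate")))
grid <- world$grid
seed <- stage_seed(1L, "drivers")

fish <- activity_hours(messages, grid, fishing_only = TRUE)

fit_one <- function(gear_label) {
  if (is.null(gear_label)) {
    gg <- gaps; mm <- messages; fg <- fish
  } else {
    gg <- gaps[which(gaps[["gear"]] == gear_label)]
    mm <- messages[which(messages[["gear"]] == gear_label)]
    fg <- activity_hours(mm, grid, fishing_only = TRUE)
  }
  er <- event_raster(gg, grid)
  if (sum(er$values > 0) < 25 ||
      sum(fg$values > 0 & er$values == 0) <= sum(er$values > 0)) return(NULL)
  tab <- build_dataset(er, fg, world$drivers, gear = gear_label, seed = seed)
  if (min(table(tab$label)) < 20) return(NULL)
  list(gear = if (is.null(gear_label)) "all" else gear_label,
       fit = fit_brt(tab, seed = seed),
       eval = evaluate_brt(tab, n_iter = 50, seed = seed))
}

models <- Filter(Negate(is.null),
                 lapply(list(NULL, "drifting_longlines", "squid_jigger",
                             "tuna_purse_seine", "trawler"), fit_one))

imp <- data.table::rbindlist(lapply(models, function(m) {
  data.table::data.table(model = m$gear, driver = names(m$fit$importance),
                         importance_pct = as.numeric(m$fit$importance))
}))
pdp <- data.table::rbindlist(lapply(models, function(m) {
  cbind(model = m$gear, m$fit$pdp)
}))
evals <- data.table::rbindlist(lapply(models, function(m) {
  data.table::data.table(model = m$gear, auc_mean = m$eval$auc_mean,
                         auc_sd = m$eval$auc_sd, tss_mean = m$eval$tss_mean,
                         tss_sd = m$eval$tss_sd,
                         explained_deviance = m$eval$explained_deviance)
}))
data.table::fwrite(imp, file.path(out, "importance.csv"))
data.table::fwrite(pdp, file.path(out, "pdp.csv"))
data.table::fwrite(evals, file.path(out, "brt_eval.csv"))

for (m in models) {
  top <- sort(m$fit$importance, decreasing = TRUE)[1:3]
  cat(sprintf("%-20s AUC %.3f±%.3f  expl.dev %4.1f%%  top: %s\n",
              m$gear, m$eval$auc_mean, m$eval$auc_sd,
              100 * m$fit$explained_deviance,
              paste(sprintf("%s %.0f%%", names(top), top), collapse = ", ")))
}
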