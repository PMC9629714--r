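#!/usr/bin/env Rscript
# Stage 2 — satellite reception quality maps.
#
# Observed reception (positions per vessel per day) per device class on a
# 1-degree grid, then a 0.25-degree predicted surface by exact thin-plate-
# spline interpolation. The predicted maps feed the gap filters in stage 3.

library(darkgaps)

out <- "results"
messages <- read_messages(file.path(out, "messages.csv"))
world <- build_world(world_config(seed = stage_seed(1L, "simulate")))
ext <- c(world$config$lon_min, world$config$lon_max,
         world$config$lat_min, world$config$lat_max)

for (cl in c("A", "B")) {
  obs <- observed_reception(messages, 1, cl, extent = ext)
  pred <- predict_reception(obs, 0.25)
  write_asc(obs, file.path(out, paste0("reception_observed_", cl, ".asc")))
  write_asc(pred, file.path(out, paste0("reception_predicted_", cl, ".asc")))
  cat(sprintf(
    "class %s: %d observed 1-deg cells (median %.1f pos/day) -> %d predicted cells\n",
    cl, sum(!is.na(obs$values)),
    stats::median(obs$values, na.rm = TRUE),
    sum(!is.na(pred$values))))
}
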