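# Great-circle geometry. All distances are on a sphere of radius 6371 km;
# nautical mile = 1.852 km.

EARTH_RADIUS_KM <- 6371
KM_PER_NMI <- 1.852

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised; arguments
#' recycle as in \code{geosphere::distHaversine}.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distances in km.
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' @rdname gc_dist_km
#' @return distances in nautical miles.
#' @export
gc_dist_nmi <- function(lon1, lat1, lon2, lat2) {
  gc_dist_km(lon1, lat1, lon2, lat2) / KM_PER_NMI
}

#' Sample a great-circle arc at (near) equal arc-length spacing
#'
#' @param lon1,lat1,lon2,lat2 endpoints (degrees).
#' @param step_deg maximum angular spacing between samples, in degrees of
#'   arc (default 0.01).
#' @return matrix with columns lon, lat including both endpoints.
#' @export
gc_sample <- function(lon1, lat1, lon2, lat2, step_deg = 0.01) {
  ang <- gc_dist_km(lon1, lat1, lon2, lat2) / (EARTH_RADIUS_KM * pi / 180)
  n_mid <- max(1L, as.integer(ceiling(ang / step_deg)) - 1L)
  p <- geosphere::gcIntermediate(c(lon1, lat1), c(lon2, lat2), n = n_mid,
                                 addStartEnd = TRUE, sp = FALSE)
  colnames(p) <- c("lon", "lat")
  p
}
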