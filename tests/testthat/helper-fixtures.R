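# Shared fixtures: tiny coastlines, track tables and independent oracles.

# Straight meridian coastline at lon 90 from lat 20 to 22; land to the east.
meridian_coastline <- function(lat_from = 20, lat_to = 22, lon = 90) {
  coastline(cbind(c(lon, lon), c(lat_from, lat_to)),
            land = cbind(c(lon, lon + 6, lon + 6, lon),
                         c(lat_from - 2, lat_from - 2, lat_to + 2, lat_to + 2)))
}

# East-west coastline at lat 21.2 (off the lattice), land to the south.
zonal_coastline <- function(lon_from = 85.05, lon_to = 89.05, lat = 21.2) {
  coastline(cbind(c(lon_from, lon_to), c(lat, lat)),
            land = cbind(c(lon_from - 1, lon_to + 1, lon_to + 1, lon_from - 1),
                         c(lat, lat, 15, 15)))
}

# Independent haversine (R = 6371 km), written out so the oracles do not
# share code with the implementation under test.
oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad; dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

oracle_arc_deg <- function(lon1, lat1, lon2, lat2) {
  oracle_haversine_km(lon1, lat1, lon2, lat2) / 6371 * 180 / pi
}

# Brute-force incidence: for every (storm, cell) pair, count the storm once
# if any of its landfall events lies within the footprint of the cell centre.
oracle_incidence <- function(events, cells, halfwidth_deg = 1.0) {
  counts <- stats::setNames(integer(nrow(cells)), cells$cell_id)
  clon <- (cells$lon_min + cells$lon_max) / 2
  clat <- (cells$lat_min + cells$lat_max) / 2
  for (sid in unique(events$storm_id)) {
    ev <- events[events$storm_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      for (j in seq_len(nrow(ev))) {
        if (oracle_arc_deg(ev$lon[j], ev$lat[j], clon[i], clat[i]) <=
              halfwidth_deg) {
          counts[i] <- counts[i] + 1L
          break
        }
      }
    }
  }
  counts
}

# Minimal two-storm track table (three fixes each).
two_storm_tracks <- function() {
  data.frame(
    storm_id = rep(c("A", "B"), each = 3),
    timestamp = rep(sprintf("1950-01-0%d 00:00:00", 1:3), 2),
    lon = c(92, 91, 90.5, 93, 92.5, 92),
    lat = c(21, 21, 21, 19, 19.5, 20),
    category = c(2, 2, 2, NA, 3, 3),
    stringsAsFactors = FALSE
  )
}

# Fully attributed single test cell.
attrs_row <- function(elevation_m = 1, geomorph = "DELTA_PLAIN_RIVER_MOUTH",
                      cyclone_count = 12, sept_rainfall_mm = 140,
                      groundwater = "SALINE_SHALLOW_AND_DEEP",
                      pop_density = 1200) {
  data.frame(elevation_m = elevation_m, geomorph = geomorph,
             cyclone_count = cyclone_count,
             sept_rainfall_mm = sept_rainfall_mm, groundwater = groundwater,
             pop_density = pop_density, stringsAsFactors = FALSE)
}
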