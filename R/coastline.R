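#' Construct a coastline object
#'
#' A coastline is one or more ordered lon/lat polylines (WGS84 degrees)
#' together with closed land polygon ring(s) that distinguish land from sea.
#' The polylines trace the shore; the land rings are used for landfall
#' detection (sea-to-land transitions of cyclone tracks) and for land-area
#' fractions of grid cells.
#'
#' @param lines a two-column lon/lat matrix, or a list of such matrices
#'   (one per polyline). Each polyline needs at least 2 vertices.
#' @param land a two-column lon/lat matrix describing a closed ring, or a
#'   list of such rings. A ring may repeat its first vertex at the end but
#'   does not have to.
#' @return an object of class `coastline` with elements `lines` and `land`.
#' @examples
#' cl <- coastline(cbind(lon = c(90, 90), lat = c(20, 22)),
#'                 land = cbind(c(90, 92, 92, 90), c(19, 19, 23, 23)))
#' coastline_total_length(cl)
#' @export
coastline <- function(lines, land) {
  if (is.matrix(lines) || is.data.frame(lines)) lines <- list(lines)
  if (is.matrix(land) || is.data.frame(land)) land <- list(land)
  lines <- lapply(lines, as_lonlat_matrix)
  land <- lapply(land, as_lonlat_matrix)
  for (pl in lines) {
    if (nrow(pl) < 2L) stop("every coastline polyline needs >= 2 vertices")
  }
  for (rg in land) {
    if (nrow(rg) < 3L) stop("every land ring needs >= 3 vertices")
  }
  structure(list(lines = lines, land = lapply(land, close_ring)),
            class = "coastline")
}

as_lonlat_matrix <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("lon/lat input needs 2 columns")
  m <- unname(m[, 1:2, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite coordinates")
  if (any(m[, 1] < -180 | m[, 1] > 180)) stop("lon outside [-180, 180]")
  if (any(m[, 2] < -90 | m[, 2] > 90)) stop("lat outside [-90, 90]")
  colnames(m) <- c("lon", "lat")
  m
}

close_ring <- function(rg) {
  n <- nrow(rg)
  if (rg[1, 1] != rg[n, 1] || rg[1, 2] != rg[n, 2]) rg <- rbind(rg, rg[1, ])
  rg
}

#' @export
print.coastline <- function(x, ...) {
  cat("<coastline>", length(x$lines), "polyline(s),",
      length(x$land), "land ring(s);",
      "total length", format(round(coastline_total_length(x), 1)), "km\n")
  invisible(x)
}

# Great-circle length of a lon/lat matrix polyline, km (spherical Earth,
# R = 6371 km).
polyline_length_km <- function(m) {
  if (nrow(m) < 2L) return(0)
  sum(geosphere::distHaversine(m[-nrow(m), , drop = FALSE],
                               m[-1, , drop = FALSE], r = 6371))
}

#' Total great-circle length of a coastline in km
#' @param cl a [coastline()] object
#' @return length in km (spherical Earth, R = 6371 km)
#' @export
coastline_total_length <- function(cl) {
  sum(vapply(cl$lines, polyline_length_km, numeric(1)))
}

# Central angle between points, in degrees of arc (used for the cyclone
# impact footprint, which the source data express in degrees).
arc_distance_deg <- function(p, q) {
  geosphere::distHaversine(p, q, r = 1) * 180 / pi
}

# Ray-casting point-in-ring test, vectorised over points. Points exactly on
# the boundary are not guaranteed either way; callers keep test geometry off
# ring edges.
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring) - 1L       # ring is closed
  inside <- rep(FALSE, length(lon))
  x1 <- ring[1:n, 1]; y1 <- ring[1:n, 2]
  x2 <- ring[2:(n + 1L), 1]; y2 <- ring[2:(n + 1L), 2]
  for (k in seq_len(n)) {
    crosses <- ((y1[k] > lat) != (y2[k] > lat))
    if (any(crosses)) {
      xint <- x1[k] + (lat - y1[k]) / (y2[k] - y1[k]) * (x2[k] - x1[k])
      inside[crosses & (lon < xint)] <- !inside[crosses & (lon < xint)]
    }
  }
  inside
}

#' Test whether points are on land
#' @param lon,lat numeric vectors of coordinates (degrees)
#' @param cl a [coastline()] object
#' @return logical vector, `TRUE` where the point lies inside a land ring
#' @export
point_on_land <- function(lon, lat, cl) {
  res <- rep(FALSE, length(lon))
  for (rg in cl$land) res <- res | point_in_ring(lon, lat, rg)
  res
}

# Intersection of segments p1->p2 and q1->q2 in the lon/lat plane.
# Returns parameter t along p1->p2 in [0,1], or NA if disjoint/parallel.
segment_intersection_t <- function(p1, p2, q1, q2) {
  r <- p2 - p1; s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-15) return(NA_real_)
  qp <- q1 - p1
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (t < -1e-12 || t > 1 + 1e-12 || u < -1e-12 || u > 1 + 1e-12) {
    return(NA_real_)
  }
  min(max(t, 0), 1)
}

# Distance (km) from points to a polyline, using a local equirectangular
# projection per segment; adequate at the sub-degree scales of the grid.
points_to_polyline_km <- function(lon, lat, m) {
  best <- rep(Inf, length(lon))
  for (i in seq_len(nrow(m) - 1L)) {
    latref <- (m[i, 2] + m[i + 1, 2]) / 2
    cs <- cospi(latref / 180)
    ax <- m[i, 1] * cs;     ay <- m[i, 2]
    bx <- m[i + 1, 1] * cs; by <- m[i + 1, 2]
    px <- lon * cs;         py <- lat
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * dx + (py - ay) * dy) / L2, 0), 1)
    d <- sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2) * 111.195
    best <- pmin(best, d)
  }
  best
}

#' Distance from points to the coastline in km
#' @inheritParams point_on_land
#' @return numeric vector of distances (km)
#' @export
distance_to_coastline_km <- function(lon, lat, cl) {
  best <- rep(Inf, length(lon))
  for (pl in cl$lines) best <- pmin(best, points_to_polyline_km(lon, lat, pl))
  best
}

#' Read a coastline from GeoJSON
#'
#' Expects a FeatureCollection whose LineString/MultiLineString features are
#' the coastline polylines and whose Polygon/MultiPolygon features are the
#' land rings (outer rings only; holes are ignored).
#'
#' @param path path to a GeoJSON file
#' @return a [coastline()] object
#' @export
read_coastline_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  lines <- list(); land <- list()
  coords_mat <- function(cc) {
    do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
  }
  for (f in feats) {
    g <- if (!is.null(f$geometry)) f$geometry else f
    switch(g$type,
      LineString = { lines[[length(lines) + 1L]] <- coords_mat(g$coordinates) },
      MultiLineString = for (part in g$coordinates)
        lines[[length(lines) + 1L]] <- coords_mat(part),
      Polygon = { land[[length(land) + 1L]] <- coords_mat(g$coordinates[[1]]) },
      MultiPolygon = for (poly in g$coordinates)
        land[[length(land) + 1L]] <- coords_mat(poly[[1]]),
      stop("unsupported GeoJSON geometry type: ", g$type)
    )
  }
  if (length(lines) == 0L) stop("no LineString coastline features found")
  if (length(land) == 0L) stop("no Polygon land features found")
  coastline(lines, land)
}

#' Write a coastline to GeoJSON
#' @param cl a [coastline()] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_coastline_geojson <- function(cl, path) {
  mat_coords <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  feats <- c(
    lapply(cl$lines, function(m) list(
      type = "Feature", properties = list(role = "coastline"),
      geometry = list(type = "LineString", coordinates = mat_coords(m)))),
    lapply(cl$land, function(m) list(
      type = "Feature", properties = list(role = "land"),
      geometry = list(type = "Polygon", coordinates = list(mat_coords(m)))))
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
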