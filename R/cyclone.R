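#' Read cyclone tracks from CSV
#'
#' Expects columns `storm_id`, `timestamp`, `lon`, `lat`, `category`
#' (Saffir-Simpson 0-5; blank where the fix is uncategorised). Rows with
#' unparseable coordinates are rejected with a message giving the count.
#'
#' @param path CSV path, or a data frame already holding the same columns
#' @return a list of tracks of class `cyclone_tracks`; each track is a list
#'   with `storm_id` and a time-sorted data frame `points`
#'   (`time`, `lon`, `lat`, `category`)
#' @export
read_tracks <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(storm_id = "character"))
  need <- c("storm_id", "timestamp", "lon", "lat", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tracks input missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty tracks file")
    return(structure(list(), class = "cyclone_tracks"))
  }
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad <- !is.finite(lon) | !is.finite(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  if (any(bad)) {
    message(sum(bad), " track row(s) with unparseable coordinates rejected")
    df <- df[!bad, , drop = FALSE]
    lon <- lon[!bad]; lat <- lat[!bad]
  }
  cat_num <- suppressWarnings(as.integer(df$category))
  tracks <- lapply(split(seq_len(nrow(df)), df$storm_id), function(idx) {
    tm <- df$timestamp[idx]
    o <- order(tm)
    list(storm_id = df$storm_id[idx][1],
         points = data.frame(time = tm[o], lon = lon[idx][o],
                             lat = lat[idx][o], category = cat_num[idx][o],
                             stringsAsFactors = FALSE))
  })
  structure(unname(tracks), class = "cyclone_tracks")
}

#' @export
print.cyclone_tracks <- function(x, ...) {
  cat("<cyclone_tracks>", length(x), "storm(s),",
      sum(vapply(x, function(t) nrow(t$points), integer(1))), "fixes\n")
  invisible(x)
}

#' Keep storms at or above a Saffir-Simpson category
#'
#' A storm is kept if its maximum recorded category reaches `min_category`.
#' Storms whose category is missing on every fix (uncategorised) are
#' dropped.
#'
#' @param tracks a `cyclone_tracks` list from [read_tracks()]
#' @param min_category minimum peak category to retain (default 1,
#'   i.e. hurricane-strength and above; tropical storms and depressions
#'   are excluded)
#' @return filtered `cyclone_tracks`
#' @export
filter_category <- function(tracks, min_category = 1L) {
  keep <- vapply(tracks, function(t) {
    cats <- t$points$category
    if (all(is.na(cats))) return(FALSE)
    max(cats, na.rm = TRUE) >= min_category
  }, logical(1))
  structure(tracks[keep], class = "cyclone_tracks")
}

#' Detect coastline landfalls of one cyclone track
#'
#' A landfall is the first intersection of each sea-to-land transition of
#' the track polyline with a land-polygon boundary, located by linear
#' interpolation between the bracketing 6-hourly fixes. The category at
#' landfall is the category of the last at-sea fix (falling back to the
#' storm maximum where that fix is uncategorised). Successive landfalls of
#' the same storm closer than `merge_radius_deg` degrees of arc are merged
#' into the first, so a track skimming the coast is counted once.
#'
#' @param track one element of a `cyclone_tracks` list
#' @param cl a [coastline()] object
#' @param merge_radius_deg merge radius for near-duplicate landfalls
#'   (degrees of arc, default 1)
#' @return data frame with columns `storm_id`, `lon`, `lat`, `category`,
#'   `time` (zero rows if the track never reaches land)
#' @export
detect_landfall <- function(track, cl, merge_radius_deg = 1.0) {
  pts <- track$points
  empty <- data.frame(storm_id = character(0), lon = numeric(0),
                      lat = numeric(0), category = integer(0),
                      time = character(0), stringsAsFactors = FALSE)
  if (nrow(pts) < 2L) return(empty)
  on_land <- point_on_land(pts$lon, pts$lat, cl)
  storm_max <- suppressWarnings(max(pts$category, na.rm = TRUE))
  events <- empty
  for (i in seq_len(nrow(pts) - 1L)) {
    if (on_land[i] || !on_land[i + 1L]) next
    p1 <- c(pts$lon[i], pts$lat[i]); p2 <- c(pts$lon[i + 1L], pts$lat[i + 1L])
    tbest <- Inf
    for (rg in cl$land) {
      for (k in seq_len(nrow(rg) - 1L)) {
        tt <- segment_intersection_t(p1, p2, rg[k, ], rg[k + 1L, ])
        if (!is.na(tt) && tt < tbest) tbest <- tt
      }
    }
    if (!is.finite(tbest)) tbest <- 0.5  # land point inside ring, no edge hit
    hit <- p1 + tbest * (p2 - p1)
    cat_lf <- pts$category[i]
    if (is.na(cat_lf)) cat_lf <- if (is.finite(storm_max)) storm_max else NA_integer_
    events <- rbind(events, data.frame(
      storm_id = track$storm_id, lon = hit[1], lat = hit[2],
      category = as.integer(cat_lf), time = pts$time[i],
      stringsAsFactors = FALSE))
  }
  if (nrow(events) > 1L) {
    keep <- rep(TRUE, nrow(events))
    last <- 1L
    for (j in 2:nrow(events)) {
      d <- arc_distance_deg(c(events$lon[last], events$lat[last]),
                            c(events$lon[j], events$lat[j]))
      if (d < merge_radius_deg) keep[j] <- FALSE else last <- j
    }
    events <- events[keep, , drop = FALSE]
  }
  rownames(events) <- NULL
  events
}

#' Detect landfalls for every storm in a track set
#' @param tracks a `cyclone_tracks` list
#' @inheritParams detect_landfall
#' @return a single data frame of landfall events across storms
#' @export
detect_landfalls <- function(tracks, cl, merge_radius_deg = 1.0) {
  out <- lapply(tracks, detect_landfall, cl = cl,
                merge_radius_deg = merge_radius_deg)
  if (length(out) == 0L) {
    return(data.frame(storm_id = character(0), lon = numeric(0),
                      lat = numeric(0), category = integer(0),
                      time = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-cell cyclone landfall incidence
#'
#' Each landfall event increments the count of every coastal cell whose
#' centre lies within `impact_halfwidth_deg` degrees of arc (great circle)
#' of the landfall point — the roughly two-degree impact footprint, which
#' touches about four half-degree elements along a straight coast. A storm
#' increments a given cell at most once, however many landfalls it makes.
#'
#' @param events landfall event data frame from [detect_landfalls()]
#' @param cells a `coastal_cells` data frame
#' @param impact_halfwidth_deg footprint radius in degrees of arc
#'   (default 1)
#' @return integer vector of counts aligned with `cells` rows, named by
#'   `cell_id`
#' @export
count_incidence <- function(events, cells, impact_halfwidth_deg = 1.0) {
  counts <- stats::setNames(integer(nrow(cells)), cells$cell_id)
  if (is.null(events) || nrow(events) == 0L) return(counts)
  ctr <- cell_centres(cells)
  for (sid in unique(events$storm_id)) {
    ev <- events[events$storm_id == sid, , drop = FALSE]
    hit <- rep(FALSE, nrow(cells))
    for (j in seq_len(nrow(ev))) {
      d <- arc_distance_deg(cbind(ev$lon[j], ev$lat[j]), ctr)
      hit <- hit | (d <= impact_halfwidth_deg)
    }
    counts <- counts + hit
  }
  counts
}

#' Run the full cyclone incidence analysis
#'
#' Reads tracks, keeps storms at or above `min_category`, detects landfalls
#' and accumulates per-cell incidence counts.
#'
#' @inheritParams read_tracks
#' @inheritParams count_incidence
#' @inheritParams filter_category
#' @param cl a [coastline()] object
#' @return `cells` with a `cyclone_count` column filled in
#' @export
cyclone_incidence <- function(path, cl, cells, min_category = 1L,
                              impact_halfwidth_deg = 1.0) {
  tracks <- filter_category(read_tracks(path), min_category)
  events <- detect_landfalls(tracks, cl)
  cells$cyclone_count <- as.integer(count_incidence(events, cells,
                                                    impact_halfwidth_deg))
  cells
}
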