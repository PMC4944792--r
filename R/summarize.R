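#' Coastline length per vulnerability class
#'
#' Sums `coastline_length_km` over assessed cells by CVI class. The class
#' totals add up to the full coastline length across the assessed cells.
#'
#' @param assessment a `cvi_assessment` from [cvi_assess()]
#' @return named numeric vector with elements `LOW`, `MODERATE`, `HIGH`
#'   (km)
#' @export
coast_length_by_class <- function(assessment) {
  cells <- assessment$cells
  out <- c(LOW = 0, MODERATE = 0, HIGH = 0)
  if (nrow(cells)) {
    s <- tapply(cells$coastline_length_km, cells$cvi_class, sum)
    out[names(s)] <- s
  }
  out
}

#' Population living near the coast, per vulnerability class
#'
#' For each assessed cell, the exposed population is `pop_density` times
#' the land area of the cell lying within `buffer_km` of the coastline.
#' The land area is approximated as cell area x land fraction x buffer
#' fraction, where the buffer fraction is estimated by sampling the cell
#' on a regular sub-grid (default 0.05 degrees) against land membership
#' and distance to the coastline.
#'
#' @param assessment a `cvi_assessment`
#' @param cl the [coastline()] object the cells were built from
#' @param buffer_km coastal buffer distance in km (default 30)
#' @param sub_res_deg sub-grid sampling resolution in degrees
#'   (default 0.05)
#' @return named numeric vector of people per class (`LOW`, `MODERATE`,
#'   `HIGH`)
#' @export
exposed_population <- function(assessment, cl, buffer_km = 30,
                               sub_res_deg = 0.05) {
  if (buffer_km < 0) stop("buffer_km must be non-negative")
  cells <- assessment$cells
  out <- c(LOW = 0, MODERATE = 0, HIGH = 0)
  if (nrow(cells) == 0L || buffer_km == 0) return(out)
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    res <- max(2L, as.integer(round((cc$lon_max - cc$lon_min) / sub_res_deg)))
    g <- sub_sample_points(cc, res)
    land <- point_on_land(g$lon, g$lat, cl)
    if (!any(land)) next
    within <- distance_to_coastline_km(g$lon[land], g$lat[land], cl) <= buffer_km
    land_frac <- mean(land)
    buf_frac <- mean(within)
    people <- cc$pop_density * cell_area_km2(cc) * land_frac * buf_frac
    out[cc$cvi_class] <- out[cc$cvi_class] + people
  }
  out
}

#' Exposure summary report
#'
#' Per-class coastline lengths, exposed population, and cell counts in a
#' single JSON-serialisable list.
#'
#' @inheritParams exposed_population
#' @return a list with `n_cells`, `cell_counts`, `coastline_km`, and (when
#'   `cl` is supplied) `population_within_buffer` and `buffer_km`
#' @export
summary_report <- function(assessment, cl = NULL, buffer_km = 30) {
  cells <- assessment$cells
  counts <- table(factor(cells$cvi_class, c("LOW", "MODERATE", "HIGH")))
  rep <- list(
    n_cells = nrow(cells),
    cell_counts = as.list(stats::setNames(as.integer(counts), names(counts))),
    coastline_km = as.list(coast_length_by_class(assessment)),
    cvi_range = if (nrow(cells)) round(range(cells$cvi), 2) else NULL
  )
  if (!is.null(cl)) {
    rep$buffer_km <- buffer_km
    rep$population_within_buffer <-
      as.list(round(exposed_population(assessment, cl, buffer_km)))
  }
  rep
}

format_summary_report <- function(rep) {
  fmt_class <- function(x, unit = "") sprintf(
    "    LOW %s%s | MODERATE %s%s | HIGH %s%s",
    format(round(x$LOW, 1), big.mark = ","), unit,
    format(round(x$MODERATE, 1), big.mark = ","), unit,
    format(round(x$HIGH, 1), big.mark = ","), unit)
  out <- c(
    "Exposure summary",
    sprintf("  coastal cells assessed: %d", rep$n_cells),
    "  cells per class:",
    fmt_class(rep$cell_counts),
    "  coastline length per class:",
    fmt_class(rep$coastline_km, " km")
  )
  if (!is.null(rep$population_within_buffer)) {
    out <- c(out,
      sprintf("  population within %g km of the coast, per class:",
              rep$buffer_km),
      fmt_class(rep$population_within_buffer))
  }
  out
}

#' Write a summary report to JSON and text
#' @param rep list from [summary_report()]
#' @param path output path for the JSON file; a `.txt` sibling is written
#'   alongside it
#' @return `path`, invisibly
#' @export
write_summary_report <- function(rep, path) {
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  writeLines(format_summary_report(rep), sub("\\.json$", ".txt", path))
  invisible(path)
}
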