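#' @title Ordinal vulnerability classifiers
#' @description
#' Six classifiers map raw cell attributes to ordinal vulnerability scores
#' 1 (low), 2 (moderate), 3 (high). The interval conventions are fixed by
#' the classification table: elevation <= 2 m amsl is high and >= 5 m low;
#' 5-10 cyclone landfalls (closed band) is moderate; 100-500 people/km^2
#' (closed) moderate; 150-300 mm September rainfall (closed) moderate.
#' Geomorphology and groundwater are categorical maps. All classifiers are
#' vectorised and return integer scores in {1, 2, 3}.
#' @name classifiers
NULL

#' Geomorphology categories, ordered low to high vulnerability
#' @export
GEOMORPH_LEVELS <- c("BEACH_CLIFF", "BEACH_RIVER_MOUTH",
                     "DELTA_PLAIN_RIVER_MOUTH")

#' Groundwater salinity categories, ordered low to high vulnerability
#' @export
GROUNDWATER_LEVELS <- c("FRESH_SHALLOW", "SALINE_SHALLOW_FRESH_DEEP",
                        "SALINE_SHALLOW_AND_DEEP")

#' Default classification thresholds
#'
#' Returns the threshold block used by all interval classifiers, suitable
#' for echoing into a run manifest. Units: elevation m amsl, population
#' people/km^2, rainfall mm (September mean), cyclones landfall counts over
#' the record.
#' @return a named list of two-sided thresholds per variable
#' @export
default_thresholds <- function() {
  list(
    elevation = c(high_max = 2, low_min = 5),
    cyclone = c(moderate_min = 5, moderate_max = 10),
    population = c(moderate_min = 100, moderate_max = 500),
    rainfall = c(moderate_min = 150, moderate_max = 300)
  )
}

#' @describeIn classifiers cyclone landfall count: `<5` low, `5-10`
#'   moderate, `>10` high
#' @param count non-negative integer landfall count(s)
#' @param thresholds threshold block as from [default_thresholds()]
#' @export
classify_cyclone <- function(count, thresholds = default_thresholds()) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("cyclone count must be a non-negative number")
  th <- thresholds$cyclone
  ifelse(count > th[["moderate_max"]], 3L,
         ifelse(count >= th[["moderate_min"]], 2L, 1L))
}

#' @describeIn classifiers elevation (m amsl): `<=2` high, `>2 and <5`
#'   moderate, `>=5` low; negative values (subsided land) allowed
#' @param elev_m elevation(s) in metres amsl
#' @export
classify_elevation <- function(elev_m, thresholds = default_thresholds()) {
  if (any(!is.finite(elev_m))) stop("elevation must be finite")
  th <- thresholds$elevation
  ifelse(elev_m <= th[["high_max"]], 3L,
         ifelse(elev_m < th[["low_min"]], 2L, 1L))
}

#' @describeIn classifiers geomorphology category to score
#' @param geo character vector of [GEOMORPH_LEVELS] categories
#' @export
classify_geomorphology <- function(geo) {
  s <- match(as.character(geo), GEOMORPH_LEVELS)
  if (any(is.na(s))) stop("unknown geomorphology category: ",
                          paste(unique(geo[is.na(s)]), collapse = ", "))
  as.integer(s)
}

#' @describeIn classifiers population density (people/km^2): `<100` low,
#'   `100-500` moderate, `>500` high
#' @param density population density value(s)
#' @export
classify_population <- function(density, thresholds = default_thresholds()) {
  if (any(!is.finite(density)) || any(density < 0))
    stop("population density must be non-negative")
  th <- thresholds$population
  ifelse(density > th[["moderate_max"]], 3L,
         ifelse(density >= th[["moderate_min"]], 2L, 1L))
}

#' @describeIn classifiers mean September rainfall (mm): `>300` low,
#'   `150-300` moderate, `<150` high (less rain, less rainwater harvest,
#'   higher vulnerability)
#' @param sept_mm rainfall value(s) in mm
#' @export
classify_rainfall <- function(sept_mm, thresholds = default_thresholds()) {
  if (any(!is.finite(sept_mm)) || any(sept_mm < 0))
    stop("rainfall must be non-negative")
  th <- thresholds$rainfall
  ifelse(sept_mm < th[["moderate_min"]], 3L,
         ifelse(sept_mm <= th[["moderate_max"]], 2L, 1L))
}

#' @describeIn classifiers groundwater salinity category to score
#' @param gw character vector of [GROUNDWATER_LEVELS] categories
#' @export
classify_groundwater <- function(gw) {
  s <- match(as.character(gw), GROUNDWATER_LEVELS)
  if (any(is.na(s))) stop("unknown groundwater category: ",
                          paste(unique(gw[is.na(s)]), collapse = ", "))
  as.integer(s)
}

#' Score all six variables of one or more cells
#'
#' Applies the six classifiers componentwise. Score letters follow the
#' index definition: a = elevation, b = geomorphology, c = cyclone
#' frequency, d = rainfall, e = groundwater, f = population density.
#'
#' @param attrs a data frame (or one-row list) with columns `elevation_m`,
#'   `geomorph`, `cyclone_count`, `sept_rainfall_mm`, `groundwater`,
#'   `pop_density`
#' @param thresholds threshold block as from [default_thresholds()]
#' @return a data frame with integer columns `a`..`f`
#' @examples
#' score_cell(data.frame(elevation_m = 1, geomorph = "DELTA_PLAIN_RIVER_MOUTH",
#'   cyclone_count = 12, sept_rainfall_mm = 140,
#'   groundwater = "SALINE_SHALLOW_AND_DEEP", pop_density = 1200))
#' @export
score_cell <- function(attrs, thresholds = default_thresholds()) {
  attrs <- as.data.frame(attrs)
  need <- c("elevation_m", "geomorph", "cyclone_count", "sept_rainfall_mm",
            "groundwater", "pop_density")
  miss <- setdiff(need, names(attrs))
  if (length(miss)) stop("missing attribute(s): ", paste(miss, collapse = ", "))
  for (v in need) {
    if (any(is.na(attrs[[v]]))) stop("missing values in attribute: ", v)
  }
  data.frame(
    a = classify_elevation(attrs$elevation_m, thresholds),
    b = classify_geomorphology(attrs$geomorph),
    c = classify_cyclone(attrs$cyclone_count, thresholds),
    d = classify_rainfall(attrs$sept_rainfall_mm, thresholds),
    e = classify_groundwater(attrs$groundwater),
    f = classify_population(attrs$pop_density, thresholds)
  )
}

#' Rainwater harvest volume from roof catchment
#'
#' Volume in litres collectable from `rain_mm` of rainfall on a roof of
#' `roof_area_m2` square metres: 1 mm on 1 m^2 yields 1 litre, scaled by a
#' runoff coefficient. With the default unit coefficient, 300 mm on a
#' 20 m^2 roof yields 6000 l, about 4-6 months of drinking water for a
#' five-person household.
#'
#' @param rain_mm rainfall depth in mm (> 0)
#' @param roof_area_m2 roof catchment area in m^2 (> 0)
#' @param runoff_coeff collection efficiency in (0, 1]; default 1
#' @return volume in litres
#' @examples
#' harvest_volume(300, 20)        # 6000 l
#' harvest_volume(300, 15, 0.89)  # ~4000 l
#' @export
harvest_volume <- function(rain_mm, roof_area_m2, runoff_coeff = 1.0) {
  if (any(rain_mm <= 0) || any(roof_area_m2 <= 0) || any(runoff_coeff <= 0) ||
      any(runoff_coeff > 1))
    stop("rain_mm and roof_area_m2 must be positive; runoff_coeff in (0, 1]")
  rain_mm * roof_area_m2 * runoff_coeff
}
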