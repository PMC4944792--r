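#' Define a climate-change projection scenario
#'
#' A scenario adjusts three of the six variables: population density by a
#' multiplier, elevation by an additive offset in metres (negative values
#' are the effective land-height loss under sea-level rise), and September
#' rainfall by a multiplier. Cyclone incidence, geomorphology and
#' groundwater are left untouched, reflecting the assessment assumption
#' that these will not change materially over the projection horizon.
#'
#' @param label scenario name
#' @param pop_multiplier population-density multiplier (> 0)
#' @param elevation_offset_m additive elevation change in metres
#' @param rainfall_multiplier rainfall multiplier (> 0)
#' @return an object of class `scenario_spec`
#' @export
scenario_spec <- function(label, pop_multiplier = 1,
                          elevation_offset_m = 0, rainfall_multiplier = 1) {
  stopifnot(pop_multiplier > 0, rainfall_multiplier > 0)
  structure(list(label = label, pop_multiplier = pop_multiplier,
                 elevation_offset_m = elevation_offset_m,
                 rainfall_multiplier = rainfall_multiplier),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario %s> population x%.2f, elevation %+.1f m, rainfall x%.2f\n",
              x$label, x$pop_multiplier, x$elevation_offset_m,
              x$rainfall_multiplier))
  invisible(x)
}

#' Built-in 2050 and 2100 scenarios
#'
#' The mid-century and end-of-century projections relative to the 2010
#' baseline: 2050 — population density 40 % higher, elevation 0.2 m lower
#' (sea-level rise), rainfall 5 % higher; 2100 — population 35 % higher
#' (relative to 2010, not compounded on 2050), elevation 0.6 m lower,
#' rainfall 10 % higher.
#'
#' @return a named list of two [scenario_spec()] objects, `S2050` and
#'   `S2100`
#' @export
builtin_scenarios <- function() {
  list(
    S2050 = scenario_spec("2050", pop_multiplier = 1.40,
                          elevation_offset_m = -0.2,
                          rainfall_multiplier = 1.05),
    S2100 = scenario_spec("2100", pop_multiplier = 1.35,
                          elevation_offset_m = -0.6,
                          rainfall_multiplier = 1.10)
  )
}

#' Apply a scenario to cell attributes
#'
#' Returns a copy with `elevation_m` shifted by the offset, `pop_density`
#' and `sept_rainfall_mm` scaled by their multipliers, and every other
#' column unchanged. The input is not modified.
#'
#' @param attrs a data frame of cell attributes
#' @param spec a [scenario_spec()]
#' @return adjusted copy of `attrs`
#' @export
apply_scenario <- function(attrs, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  out <- attrs
  out$elevation_m <- attrs$elevation_m + spec$elevation_offset_m
  out$pop_density <- attrs$pop_density * spec$pop_multiplier
  out$sept_rainfall_mm <- attrs$sept_rainfall_mm * spec$rainfall_multiplier
  out
}

#' Re-assess cells under a scenario and tabulate class transitions
#'
#' Applies the scenario to the baseline assessment's cells, recomputes
#' scores and CVI, and reports per-cell class transitions.
#'
#' @param baseline a `cvi_assessment` from [cvi_assess()]
#' @param spec a [scenario_spec()]
#' @return a list with `assessment` (the re-assessed `cvi_assessment`) and
#'   `delta`, a data frame with `cell_id`, `baseline_class`,
#'   `scenario_class`, `transition` (`"unchanged"`, `"up"`, `"down"`) and
#'   `changed_components` (letters of the score components that moved)
#' @export
project_assessment <- function(baseline, spec) {
  stopifnot(inherits(baseline, "cvi_assessment"))
  adj <- apply_scenario(baseline$cells, spec)
  proj <- cvi_assess(adj, thresholds = baseline$thresholds)
  lev <- c(LOW = 1L, MODERATE = 2L, HIGH = 3L)
  b <- baseline$cells; p <- proj$cells
  comp <- c("a", "b", "c", "d", "e", "f")
  changed <- vapply(seq_len(nrow(b)), function(i)
    paste(comp[unlist(b[i, comp]) != unlist(p[i, comp])], collapse = ""),
    character(1))
  dirn <- sign(lev[p$cvi_class] - lev[b$cvi_class])
  delta <- data.frame(
    cell_id = b$cell_id,
    baseline_class = b$cvi_class,
    scenario_class = p$cvi_class,
    transition = c("down", "unchanged", "up")[dirn + 2L],
    changed_components = changed,
    stringsAsFactors = FALSE
  )
  list(assessment = proj, delta = delta)
}
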