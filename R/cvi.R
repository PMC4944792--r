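#' Coastal Vulnerability Index from a score vector
#'
#' The index combines the six ordinal scores with equal weight as the
#' square root of their product mean:
#' \deqn{CVI = \sqrt{(a \cdot b \cdot c \cdot d \cdot e \cdot f) / 6}}
#' where a = elevation, b = geomorphology, c = cyclone frequency,
#' d = rainfall, e = groundwater availability and f = population density,
#' each scored 1 (low), 2 (moderate) or 3 (high). CVI ranges from
#' sqrt(1/6) = 0.41 (all low) to sqrt(729/6) = 11.02 (all high).
#'
#' @param scores a length-6 integer vector, or a data frame / matrix with
#'   six score columns (rows are cells), values in \{1, 2, 3\}
#' @return a data frame with columns `product` (integer, in 1..729), `cvi`
#'   and `cvi_class` (`"LOW"`, `"MODERATE"`, `"HIGH"`)
#' @examples
#' compute_cvi(c(1, 1, 1, 2, 3, 3))   # the 1.73 low/moderate limit
#' compute_cvi(rep(2, 6))             # the 3.27 moderate/high limit
#' @export
compute_cvi <- function(scores) {
  m <- score_matrix(scores)
  product <- as.integer(apply(m, 1, prod))
  cvi <- sqrt(product / 6)
  data.frame(product = product, cvi = cvi,
             cvi_class = classify_cvi(product), stringsAsFactors = FALSE)
}

score_matrix <- function(scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != 6L) stop("a score vector has exactly 6 components")
  if (any(!(scores %in% c(1L, 2L, 3L))))
    stop("score components must be in {1, 2, 3}")
  storage.mode(scores) <- "integer"
  scores
}

#' Classify CVI values into LOW / MODERATE / HIGH
#'
#' The published limits are CVI 1.73 (three lows, one moderate, two highs)
#' and 3.27 (all moderate). Because every attainable CVI is sqrt(p/6) for
#' an integer product p, the rule is applied exactly on the product:
#' LOW for p <= 18, MODERATE for 18 < p <= 64, HIGH for p > 64 (18 and 64
#' are the products behind 1.73 and 3.27; both limits sit on the lower
#' class). This is identical to floating comparison against sqrt(18/6) and
#' sqrt(64/6) over the whole score space.
#'
#' @param product integer score product(s) in 1..729 (or a data frame with
#'   a `product` column, as returned by [compute_cvi()])
#' @return character vector of classes
#' @export
classify_cvi <- function(product) {
  if (is.data.frame(product)) product <- product$product
  ifelse(product > 64, "HIGH", ifelse(product > 18, "MODERATE", "LOW"))
}

#' Enumerate the complete six-variable score space
#'
#' All 3^6 = 729 combinations of the six scores, with product, CVI and
#' class for each. The returned table carries two attributes:
#' `class_counts` (cells per class) and `cvi_histogram` (counts of each
#' distinct CVI value).
#'
#' @return a 729-row data frame with columns `a`..`f`, `product`, `cvi`,
#'   `cvi_class`
#' @export
enumerate_score_space <- function() {
  tab <- expand.grid(a = 1:3, b = 1:3, c = 1:3, d = 1:3, e = 1:3, f = 1:3,
                     KEEP.OUT.ATTRS = FALSE)
  tab <- cbind(tab, compute_cvi(tab))
  attr(tab, "class_counts") <- table(tab$cvi_class)
  attr(tab, "cvi_histogram") <- table(round(tab$cvi, 6))
  tab
}

#' Compare the CVI aggregator with the arithmetic mean
#'
#' For every score combination, the arithmetic mean (a + ... + f)/6 is
#' computed alongside the CVI, and the two aggregators are compared by
#' Spearman rank correlation and by the number of combination pairs they
#' order differently (one strictly increasing where the other strictly
#' decreases).
#'
#' @param tab enumeration table from [enumerate_score_space()] (default:
#'   computed fresh)
#' @return a list with `table` (the enumeration table plus a `mean`
#'   column), `spearman`, `discordant_pairs` and `n_pairs`
#' @export
compare_aggregators <- function(tab = enumerate_score_space()) {
  tab$mean <- rowMeans(tab[, c("a", "b", "c", "d", "e", "f")])
  dc <- sign(outer(tab$cvi, tab$cvi, "-"))
  dm <- sign(outer(tab$mean, tab$mean, "-"))
  discordant <- sum(dc * dm < 0) / 2
  list(table = tab,
       spearman = stats::cor(tab$cvi, tab$mean, method = "spearman"),
       discordant_pairs = discordant,
       n_pairs = nrow(tab) * (nrow(tab) - 1) / 2)
}

#' Assess coastal cells: scores, CVI and vulnerability class
#'
#' The main entry point of the package. Takes attributed coastal grid
#' cells, applies the six ordinal classifiers, computes the CVI for every
#' coastal cell and classifies it with the published limits. Non-coastal
#' cells are skipped.
#'
#' @param cells a `coastal_cells` data frame (from [build_grid()] or
#'   [read_cells_csv()]) carrying the attribute columns `elevation_m`,
#'   `geomorph`, `cyclone_count`, `sept_rainfall_mm`, `groundwater`,
#'   `pop_density`
#' @param thresholds threshold block as from [default_thresholds()]
#' @return an object of class `cvi_assessment`: a list with `cells` (the
#'   input plus columns `a`..`f`, `product`, `cvi`, `cvi_class`),
#'   `thresholds` and `call`. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`.
#' @seealso [compute_cvi()], [score_cell()], [project_assessment()],
#'   [summary_report()]
#' @export
cvi_assess <- function(cells, thresholds = default_thresholds()) {
  cells <- as.data.frame(cells)
  # drop result columns from a previous assessment so re-assessment is clean
  cells <- cells[, setdiff(names(cells),
                           c("a", "b", "c", "d", "e", "f", "product", "cvi",
                             "cvi_class")), drop = FALSE]
  if (!"is_coastal" %in% names(cells)) cells$is_coastal <- TRUE
  coastal <- cells[cells$is_coastal, , drop = FALSE]
  if (nrow(coastal) > 0L) {
    need <- c("elevation_m", "geomorph", "cyclone_count", "sept_rainfall_mm",
              "groundwater", "pop_density")
    present <- intersect(need, names(coastal))
    gap <- if (length(present) < length(need)) rep(TRUE, nrow(coastal)) else
      rowSums(is.na(coastal[, need, drop = FALSE])) > 0
    if (any(gap)) {
      stop("unattributed coastal cell(s): ",
           paste(coastal$cell_id[gap], collapse = ", "))
    }
    sc <- score_cell(coastal, thresholds)
    coastal <- cbind(coastal, sc, compute_cvi(sc))
  } else {
    for (col in c("a", "b", "c", "d", "e", "f", "product", "cvi"))
      coastal[[col]] <- numeric(0)
    coastal$cvi_class <- character(0)
  }
  structure(list(cells = coastal, thresholds = thresholds,
                 call = match.call()),
            class = "cvi_assessment")
}

#' @export
print.cvi_assessment <- function(x, ...) {
  cat("Coastal drinking-water vulnerability assessment\n")
  cat("  coastal cells:", nrow(x$cells), "\n")
  if (nrow(x$cells)) {
    tb <- table(factor(x$cells$cvi_class, c("LOW", "MODERATE", "HIGH")))
    cat("  class counts: LOW", tb[["LOW"]], "| MODERATE", tb[["MODERATE"]],
        "| HIGH", tb[["HIGH"]], "\n")
    cat("  CVI range:", format(round(min(x$cells$cvi), 2), nsmall = 2), "-",
        format(round(max(x$cells$cvi), 2), nsmall = 2), "\n")
  }
  invisible(x)
}

#' @export
summary.cvi_assessment <- function(object, cl = NULL, buffer_km = 30, ...) {
  rep <- summary_report(object, cl = cl, buffer_km = buffer_km)
  structure(rep, class = "summary.cvi_assessment")
}

#' @export
print.summary.cvi_assessment <- function(x, ...) {
  cat(format_summary_report(unclass(x)), sep = "\n")
  invisible(x)
}

#' @export
as.data.frame.cvi_assessment <- function(x, ...) {
  df <- x$cells
  class(df) <- "data.frame"
  df
}

#' Map of assessed cells coloured by vulnerability class
#'
#' @param x a `cvi_assessment`
#' @param cl optional [coastline()] object drawn over the cells
#' @param ... passed to [graphics::plot()]
#' @export
plot.cvi_assessment <- function(x, cl = NULL, ...) {
  cells <- x$cells
  if (nrow(cells) == 0L) stop("nothing to plot: no coastal cells")
  pal <- c(LOW = "#2c7bb6", MODERATE = "#fdae61", HIGH = "#d7191c")
  graphics::plot(NA, xlim = range(cells$lon_min, cells$lon_max),
                 ylim = range(cells$lat_min, cells$lat_max),
                 xlab = "lon", ylab = "lat", asp = 1, ...)
  graphics::rect(cells$lon_min, cells$lat_min, cells$lon_max, cells$lat_max,
                 col = pal[cells$cvi_class], border = "grey40")
  if (!is.null(cl)) {
    for (pl in cl$lines) graphics::lines(pl, lwd = 2)
  }
  graphics::legend("topright", legend = names(pal), fill = pal, bty = "n",
                   title = "CVI class")
  invisible(x)
}
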