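#' Build the half-degree coastal grid
#'
#' Tiles the lon/lat plane with square cells of `cell_size_deg` degrees
#' anchored at (0, 0), with half-open bounds `[min, min + cell_size)`, and
#' returns the cells intersected by the coastline polylines together with
#' the great-circle length of coastline inside each cell. A cell is coastal
#' iff that length is positive; cells touched only at a point are excluded.
#'
#' @param cl a [coastline()] object
#' @param cell_size_deg cell edge in degrees (default 0.5, the roughly
#'   50 x 50 km analysis element)
#' @param land_fraction_res sub-sampling resolution (points per cell edge)
#'   used to estimate each cell's land-area fraction; 0 skips the estimate
#'   (column set to `NA`)
#' @return a data frame of class `coastal_cells` with columns `cell_id`,
#'   `row`, `col`, `lon_min`, `lat_min`, `lon_max`, `lat_max`, `is_coastal`,
#'   `coastline_length_km`, `land_fraction`
#' @examples
#' cl <- coastline(cbind(c(90, 90), c(20, 22)),
#'                 land = cbind(c(90, 95, 95, 90), c(18, 18, 24, 24)))
#' build_grid(cl)
#' @export
build_grid <- function(cl, cell_size_deg = 0.5, land_fraction_res = 10L) {
  stopifnot(inherits(cl, "coastline"), cell_size_deg > 0)
  pieces <- clip_lines_to_lattice(cl$lines, cell_size_deg)
  if (nrow(pieces) == 0L) stop("no coastal cells")
  agg <- stats::aggregate(len_km ~ row + col, data = pieces, FUN = sum)
  agg <- agg[agg$len_km > 0, , drop = FALSE]
  if (nrow(agg) == 0L) stop("no coastal cells")
  agg <- agg[order(agg$row, agg$col), , drop = FALSE]
  cells <- data.frame(
    cell_id = cell_id_for(agg$row, agg$col),
    row = agg$row, col = agg$col,
    lon_min = agg$col * cell_size_deg,
    lat_min = agg$row * cell_size_deg,
    lon_max = (agg$col + 1L) * cell_size_deg,
    lat_max = (agg$row + 1L) * cell_size_deg,
    is_coastal = TRUE,
    coastline_length_km = agg$len_km,
    stringsAsFactors = FALSE
  )
  cells$land_fraction <- if (land_fraction_res > 0) {
    vapply(seq_len(nrow(cells)), function(i)
      cell_land_fraction(cells[i, ], cl, land_fraction_res), numeric(1))
  } else NA_real_
  rownames(cells) <- NULL
  class(cells) <- c("coastal_cells", "data.frame")
  cells
}

cell_id_for <- function(row, col) sprintf("r%d_c%d", row, col)

# Split every polyline segment at the lattice lines (multiples of
# cell_size), assign each sub-segment to the cell containing its midpoint
# (half-open bounds fall out of the midpoint rule), and return per-piece
# rows (row, col, len_km). Exact-on-gridline segments land in the cell on
# the positive side of the line, matching floor().
clip_lines_to_lattice <- function(lines, cs) {
  out_row <- integer(0); out_col <- integer(0); out_len <- numeric(0)
  for (m in lines) {
    for (i in seq_len(nrow(m) - 1L)) {
      p <- m[i, ]; q <- m[i + 1, ]
      ts <- c(0, 1)
      for (dim in 1:2) {
        lo <- min(p[dim], q[dim]); hi <- max(p[dim], q[dim])
        ks <- seq(ceiling(lo / cs), floor(hi / cs))
        ks <- ks[ks * cs > lo & ks * cs < hi]
        if (length(ks) && q[dim] != p[dim]) {
          ts <- c(ts, (ks * cs - p[dim]) / (q[dim] - p[dim]))
        }
      }
      ts <- sort(unique(pmin(pmax(ts, 0), 1)))
      for (j in seq_len(length(ts) - 1L)) {
        a <- p + ts[j] * (q - p); b <- p + ts[j + 1L] * (q - p)
        mid <- (a + b) / 2
        len <- geosphere::distHaversine(a, b, r = 6371)
        if (len > 0) {
          out_row <- c(out_row, as.integer(floor(mid[2] / cs)))
          out_col <- c(out_col, as.integer(floor(mid[1] / cs)))
          out_len <- c(out_len, len)
        }
      }
    }
  }
  data.frame(row = out_row, col = out_col, len_km = out_len)
}

#' Great-circle coastline length inside one grid cell
#'
#' Additive over the grid: summed over all cells of [build_grid()] it
#' recovers the total coastline length.
#'
#' @param cl a [coastline()] object
#' @param cell a one-row slice of a `coastal_cells` data frame (or any list
#'   with `lon_min`, `lat_min`, `lon_max`, `lat_max` on the lattice)
#' @return length in km (0 if the polylines miss the cell)
#' @export
coastline_length_in_cell <- function(cl, cell) {
  cs <- cell$lon_max - cell$lon_min
  stopifnot(abs((cell$lat_max - cell$lat_min) - cs) < 1e-9, cs > 0)
  pieces <- clip_lines_to_lattice(cl$lines, cs)
  row <- as.integer(round(cell$lat_min / cs))
  col <- as.integer(round(cell$lon_min / cs))
  sum(pieces$len_km[pieces$row == row & pieces$col == col])
}

# Fraction of a cell's sub-sample midpoints that fall on land.
cell_land_fraction <- function(cell, cl, res = 10L) {
  g <- sub_sample_points(cell, res)
  mean(point_on_land(g$lon, g$lat, cl))
}

sub_sample_points <- function(cell, res) {
  step_lon <- (cell$lon_max - cell$lon_min) / res
  step_lat <- (cell$lat_max - cell$lat_min) / res
  lon <- cell$lon_min + (seq_len(res) - 0.5) * step_lon
  lat <- cell$lat_min + (seq_len(res) - 0.5) * step_lat
  expand.grid(lon = lon, lat = lat)
}

#' Spherical area of a grid cell in square km
#' @param cell one-row cell slice with lon/lat bounds in degrees
#' @return area in km^2 (spherical Earth, R = 6371 km)
#' @export
cell_area_km2 <- function(cell) {
  R <- 6371
  dlam <- (cell$lon_max - cell$lon_min) * pi / 180
  R^2 * dlam * (sinpi(cell$lat_max / 180) - sinpi(cell$lat_min / 180))
}

#' Centre coordinates of cells
#' @param cells a `coastal_cells` data frame
#' @return two-column lon/lat matrix of cell centres
#' @export
cell_centres <- function(cells) {
  cbind(lon = (cells$lon_min + cells$lon_max) / 2,
        lat = (cells$lat_min + cells$lat_max) / 2)
}

#' Write cells (with any attribute columns) to CSV
#' @param cells a `coastal_cells` data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' Read cells from CSV
#' @param path CSV written by [write_cells_csv()]
#' @return a `coastal_cells` data frame
#' @export
read_cells_csv <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "row", "col", "lon_min", "lat_min", "lon_max",
            "lat_max", "coastline_length_km")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  class(cells) <- c("coastal_cells", "data.frame")
  cells
}

#' Write cells to a GeoJSON FeatureCollection
#'
#' One Polygon feature per cell; all non-bound columns become properties.
#'
#' @param cells a `coastal_cells` data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cells_geojson <- function(cells, path) {
  prop_cols <- setdiff(names(cells),
                       c("lon_min", "lat_min", "lon_max", "lat_max"))
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    ring <- list(c(cc$lon_min, cc$lat_min), c(cc$lon_max, cc$lat_min),
                 c(cc$lon_max, cc$lat_max), c(cc$lon_min, cc$lat_max),
                 c(cc$lon_min, cc$lat_min))
    props <- as.list(as.data.frame(cc)[, prop_cols, drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
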