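test_that("track CSV parsing groups by storm and sorts by time", {
  p <- tempfile(fileext = ".csv")
  df <- two_storm_tracks()
  df <- df[c(3, 1, 5, 2, 6, 4), ]  # shuffle rows
  write.csv(df, p, row.names = FALSE)
  tracks <- read_tracks(p)
  expect_length(tracks, 2L)
  for (t in tracks) {
    expect_equal(nrow(t$points), 3L)
    expect_false(is.unsorted(t$points$time))
  }
  # blank category retained as missing
  b <- tracks[[which(vapply(tracks, function(t) t$storm_id, "") == "B")]]
  expect_true(is.na(b$points$category[1]))
})

test_that("track parsing rejects bad coordinates and missing columns", {
  df <- two_storm_tracks()
  df$lon[2] <- "not-a-number"
  expect_message(tracks <- read_tracks(df), "1 track row")
  expect_equal(sum(vapply(tracks, function(t) nrow(t$points), 1L)), 5L)
  expect_error(read_tracks(data.frame(storm_id = "x", lon = 1)),
               "missing column")
  p <- tempfile(fileext = ".csv")
  write.csv(two_storm_tracks()[0, ], p, row.names = FALSE)
  expect_warning(empty <- read_tracks(p), "empty")
  expect_length(empty, 0L)
})

test_that("category filter keeps hurricane-strength storms only", {
  mk <- function(id, cats) list(storm_id = id, points = data.frame(
    time = seq_along(cats), lon = seq_along(cats), lat = 0, category = cats))
  tracks <- structure(list(mk("cat3", c(1, 3, 2)),
                           mk("uncat", c(NA, NA, NA)),
                           mk("ts", c(0, 0, 0))),
                      class = "cyclone_tracks")
  kept <- filter_category(tracks, 1L)
  expect_equal(vapply(kept, function(t) t$storm_id, ""), "cat3")
  # threshold is configurable
  expect_length(filter_category(tracks, 4L), 0L)
})

test_that("landfall detection finds interpolated sea-to-land crossings", {
  cl <- meridian_coastline(18, 24, lon = 90)   # land at lon >= 90
  # wholly at sea
  sea <- list(storm_id = "S", points = data.frame(
    time = 1:3, lon = c(85, 86, 87), lat = 21, category = 2L))
  expect_equal(nrow(detect_landfall(sea, cl)), 0L)
  # two-point track crossing the meridian coast: oracle crossing by linear
  # interpolation where lon = 90 -> t = (90 - 89) / (91 - 89) = 0.5
  cross <- list(storm_id = "X", points = data.frame(
    time = 1:2, lon = c(89, 91), lat = c(20, 22), category = 2L))
  ev <- detect_landfall(cross, cl)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$lon, 90, tolerance = 1e-9)
  expect_equal(ev$lat, 21, tolerance = 1e-9)
  expect_equal(ev$category, 2L)
})

test_that("a track striking two distant coasts records two landfalls", {
  # island band: land between lon 90 and 92; track crosses in, out the far
  # side is sea again, then a second island at lon 97-99
  cl <- coastline(list(cbind(c(90, 90), c(18, 24)), cbind(c(97, 97), c(18, 24))),
                  land = list(cbind(c(90, 92, 92, 90), c(18, 18, 24, 24)),
                              cbind(c(97, 99, 99, 97), c(18, 18, 24, 24))))
  tr <- list(storm_id = "two", points = data.frame(
    time = 1:5, lon = c(88, 91, 94, 96, 98), lat = 21, category = 3L))
  ev <- detect_landfall(tr, cl)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$lon, c(90, 97), tolerance = 1e-9)
})

test_that("skimming landfalls closer than the merge radius collapse to one", {
  cl <- meridian_coastline(18, 24, lon = 90)
  # crosses in, pops back to sea, re-enters 0.4 degrees north: one event
  tr <- list(storm_id = "skim", points = data.frame(
    time = 1:4, lon = c(89.8, 90.2, 89.8, 90.2),
    lat = c(21.0, 21.1, 21.3, 21.5), category = 1L))
  ev <- detect_landfall(tr, cl)
  expect_equal(nrow(ev), 1L)
})

test_that("incidence counting matches the brute-force oracle", {
  cl <- zonal_coastline(85.05, 89.05)
  cells <- build_grid(cl, land_fraction_res = 0L)
  set.seed(42)
  n_ev <- 80
  events <- data.frame(
    storm_id = sprintf("S%02d", sample(40, n_ev, replace = TRUE)),
    lon = runif(n_ev, 84.5, 89.5), lat = 21.2, category = 1L,
    stringsAsFactors = FALSE)
  got <- count_incidence(events, cells, 1.0)
  expect_identical(as.integer(got), as.integer(oracle_incidence(events, cells, 1.0)))
  # permutation invariance over storm order
  perm <- events[sample(nrow(events)), ]
  expect_identical(count_incidence(perm, cells, 1.0), got)
  # monotonicity: adding an event never decreases any count
  more <- rbind(events, data.frame(storm_id = "NEW", lon = 87, lat = 21.2,
                                   category = 2L))
  expect_true(all(count_incidence(more, cells, 1.0) >= got))
})

test_that("the footprint spans about four half-degree elements on a straight coast", {
  cl <- zonal_coastline(85.05, 89.05)
  cells <- build_grid(cl, land_fraction_res = 0L)
  centre <- cell_centres(cells)[5, ]
  ev <- data.frame(storm_id = "one", lon = unname(centre["lon"]), lat = 21.2,
                   category = 1L)
  counts <- count_incidence(ev, cells, 1.0)
  expect_true(sum(counts > 0) %in% 3:5)   # 4 +/- 1 elements
  expect_true(all(counts %in% 0:1))
  # zero events, all zero
  expect_true(all(count_incidence(ev[0, ], cells, 1.0) == 0))
  # 12 co-located storms push the struck cell into the high class
  twelve <- data.frame(storm_id = sprintf("T%02d", 1:12),
                       lon = unname(centre["lon"]), lat = 21.2, category = 2L)
  c12 <- count_incidence(twelve, cells, 1.0)
  expect_equal(max(c12), 12L)
  expect_equal(classify_cyclone(max(c12)), 3L)
})
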