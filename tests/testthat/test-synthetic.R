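test_that("identical seed and spec give a bit-identical world", {
  w1 <- generate_world(world_spec(seed = 5))
  w2 <- generate_world(world_spec(seed = 5))
  expect_identical(w1$cells, w2$cells)
  expect_identical(w1$tracks, w2$tracks)
  expect_identical(w1$ground_truth, w2$ground_truth)
  w3 <- generate_world(world_spec(seed = 6))
  expect_false(identical(w1$cells, w3$cells))
})

test_that("deltaic fraction one makes every cell a delta plain", {
  w <- generate_world(world_spec(seed = 3, deltaic_fraction = 1))
  expect_true(all(w$cells$geomorph == "DELTA_PLAIN_RIVER_MOUTH"))
  expect_true(all(w$ground_truth$b == 3L))
  w0 <- generate_world(world_spec(seed = 3, deltaic_fraction = 0))
  expect_false(any(w0$cells$geomorph == "DELTA_PLAIN_RIVER_MOUTH"))
})

test_that("attribute draws sit strictly inside their class bands", {
  w <- generate_world(world_spec(seed = 9))
  gt <- w$ground_truth
  expect_identical(classify_elevation(w$cells$elevation_m), gt$a)
  expect_identical(classify_population(w$cells$pop_density), gt$f)
  expect_identical(classify_rainfall(w$cells$sept_rainfall_mm), gt$d)
  # margin of at least one output-precision unit from every boundary
  expect_false(any(w$cells$elevation_m %in% c(2, 5)))
  expect_false(any(w$cells$pop_density %in% c(100, 500)))
  expect_false(any(w$cells$sept_rainfall_mm %in% c(150, 300)))
})

test_that("the full pipeline recovers ground-truth scores on seeded worlds", {
  for (seed in 1:5) {
    w <- generate_world(world_spec(seed = seed))
    raw <- w$cells[, setdiff(names(w$cells), "cyclone_count")]
    cells <- cyclone_incidence(w$tracks, w$coastline, raw)
    expect_identical(as.integer(cells$cyclone_count),
                     w$cells$cyclone_count)
    sc <- score_cell(cells)
    expect_true(all(as.matrix(sc) ==
                      as.matrix(w$ground_truth[, c("a", "b", "c", "d", "e", "f")])))
    # class recovery through the assessment object as well
    a <- cvi_assess(cells)
    truth <- compute_cvi(w$ground_truth[, c("a", "b", "c", "d", "e", "f")])
    expect_identical(a$cells$cvi_class, truth$cvi_class)
  }
})

test_that("zero cyclone rate produces no storms", {
  w <- generate_world(world_spec(seed = 4,
                                 cyclone_rate = list(delta = 0, beach = 0)))
  expect_equal(nrow(w$tracks), 0L)
  expect_true(all(w$cells$cyclone_count == 0L))
  expect_true(all(w$ground_truth$c == 1L))
})

test_that("generated landfall counts match a brute-force recount of the tracks", {
  w <- generate_world(world_spec(seed = 8, cyclone_rate = list(delta = 12,
                                                               beach = 4)))
  tracks <- filter_category(read_tracks(w$tracks), 1L)
  events <- detect_landfalls(tracks, w$coastline)
  cells <- w$cells
  expect_identical(as.integer(oracle_incidence(events, cells, 1.0)),
                   w$cells$cyclone_count)
})

test_that("storm counts follow the specified Poisson rates", {
  # 3 deltaic + 3 beach segments at rates 9 and 2: expected total 33
  rates <- list(delta = 9, beach = 2)
  totals <- vapply(1:20, function(s) {
    w <- generate_world(world_spec(seed = 100 + s, cyclone_rate = rates))
    length(unique(w$tracks$storm_id))
  }, numeric(1))
  expected <- 3 * rates$delta + 3 * rates$beach
  se <- sqrt(expected / 20)
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("worlds write the pipeline's file dialects", {
  w <- generate_world(world_spec(seed = 2))
  d <- tempfile()
  write_world(w, d)
  expect_setequal(list.files(d),
                  c("coastline.geojson", "cells.csv", "cells.geojson",
                    "tracks.csv", "ground_truth.csv"))
  cells <- read_cells_csv(file.path(d, "cells.csv"))
  expect_equal(cells$cell_id, w$cells$cell_id)
  tracks <- read_tracks(file.path(d, "tracks.csv"))
  expect_length(tracks, length(unique(w$tracks$storm_id)))
  gt <- read.csv(file.path(d, "ground_truth.csv"))
  expect_identical(gt$a, w$ground_truth$a)
})
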