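test_that("CVI is the square root of the product mean", {
  r <- compute_cvi(c(1, 1, 1, 1, 1, 1))
  expect_equal(r$product, 1L)
  expect_equal(r$cvi, sqrt(1 / 6))
  expect_equal(round(r$cvi, 2), 0.41)
  expect_equal(round(compute_cvi(rep(3, 6))$cvi, 2), 11.02)
  expect_equal(round(compute_cvi(c(1, 1, 1, 2, 3, 3))$cvi, 2), 1.73)
  expect_equal(round(compute_cvi(rep(2, 6))$cvi, 2), 3.27)
  # invariant: cvi = sqrt(product/6) to machine precision
  s <- c(2, 3, 1, 3, 2, 1)
  expect_equal(compute_cvi(s)$cvi, sqrt(prod(s) / 6), tolerance = 1e-12)
  expect_error(compute_cvi(c(1, 2, 3, 4, 1, 1)), "\\{1, 2, 3\\}")
  expect_error(compute_cvi(c(1, 2, 3)), "6 components")
})

test_that("CVI is symmetric in its six arguments", {
  set.seed(7)
  for (i in 1:20) {
    s <- sample(1:3, 6, replace = TRUE)
    expect_equal(compute_cvi(s)$cvi, compute_cvi(sample(s))$cvi)
  }
})

test_that("class limits sit at products 18 and 64, limits on the lower class", {
  expect_equal(classify_cvi(prod(c(1, 1, 1, 2, 3, 3))), "LOW")     # 1.73 limit
  expect_equal(classify_cvi(19L), "MODERATE")
  expect_equal(classify_cvi(prod(rep(2, 6))), "MODERATE")          # 3.27 limit
  # smallest attainable product above 64, by enumeration
  tab <- enumerate_score_space()
  above <- min(tab$product[tab$product > 64])
  expect_equal(above, 72L)
  expect_equal(classify_cvi(above), "HIGH")
})

test_that("the full score space enumerates to 729 rows with the known range", {
  tab <- enumerate_score_space()
  expect_equal(nrow(tab), 729L)
  expect_equal(nrow(unique(tab[, c("a", "b", "c", "d", "e", "f")])), 729L)
  expect_equal(round(min(tab$cvi), 2), 0.41)
  expect_equal(round(max(tab$cvi), 2), 11.02)
  expect_true(all(tab$cvi >= 0.408 & tab$cvi <= 11.023))
  expect_equal(sum(attr(tab, "class_counts")), 729)
})

test_that("CVI is monotone in every component over all 729 combinations", {
  tab <- enumerate_score_space()
  lev <- c(LOW = 1L, MODERATE = 2L, HIGH = 3L)
  key <- function(df) do.call(paste, c(df, sep = "-"))
  idx <- stats::setNames(seq_len(nrow(tab)),
                         key(tab[, c("a", "b", "c", "d", "e", "f")]))
  for (comp in c("a", "b", "c", "d", "e", "f")) {
    lower <- tab[tab[[comp]] < 3, ]
    raised <- lower[, c("a", "b", "c", "d", "e", "f")]
    raised[[comp]] <- raised[[comp]] + 1L
    j <- idx[key(raised)]
    expect_true(all(tab$cvi[j] >= lower$cvi))
    expect_true(all(lev[tab$cvi_class[j]] >= lev[lower$cvi_class]))
  }
})

test_that("integer-product rule matches floating thresholds on all 729", {
  tab <- enumerate_score_space()
  float_class <- ifelse(tab$cvi > sqrt(64 / 6), "HIGH",
                        ifelse(tab$cvi > sqrt(18 / 6), "MODERATE", "LOW"))
  expect_identical(tab$cvi_class, float_class)
})

test_that("mean and CVI aggregators agree on order up to known discordance", {
  cmp <- compare_aggregators()
  tab <- cmp$table
  expect_equal(tab$mean[tab$product == 1], 1.0)
  expect_equal(round(tab$cvi[tab$product == 1], 2), 0.41)
  expect_equal(tab$mean[tab$product == 729], 3.0)
  expect_equal(round(tab$cvi[tab$product == 729], 2), 11.02)
  # raising one component raises both aggregators
  i <- which(key <- with(tab, a == 1 & b == 1 & c == 1 & d == 1 & e == 1 & f == 1))
  j <- which(with(tab, a == 1 & b == 1 & c == 1 & d == 1 & e == 1 & f == 2))
  expect_gt(tab$cvi[j], tab$cvi[i])
  expect_gt(tab$mean[j], tab$mean[i])
  expect_gt(cmp$spearman, 0.9)
  expect_gte(cmp$discordant_pairs, 1)           # product and sum do disagree
  expect_lt(cmp$discordant_pairs / cmp$n_pairs, 0.1)
  # oracle on a miniature: products 4*1=4 < 3*2=6 but sums 5 > 5 equal ->
  # count only strict reversals; verify against a direct 3-row brute force
  mini <- tab[c(1, 2, 5), ]
  d <- 0
  for (p in 1:2) for (q in (p + 1):3) {
    d <- d + (sign(mini$cvi[p] - mini$cvi[q]) *
                sign(mini$mean[p] - mini$mean[q]) < 0)
  }
  expect_equal(d, 0)
})

test_that("assess_cells scores coastal cells and skips the rest", {
  cells <- rbind(
    cbind(data.frame(cell_id = "low", row = 1L, col = 1L, lon_min = 0.5,
                     lat_min = 0.5, lon_max = 1, lat_max = 1,
                     is_coastal = TRUE, coastline_length_km = 50,
                     land_fraction = 1),
          attrs_row(10, "BEACH_CLIFF", 0, 400, "FRESH_SHALLOW", 10)),
    cbind(data.frame(cell_id = "mid", row = 1L, col = 2L, lon_min = 1,
                     lat_min = 0.5, lon_max = 1.5, lat_max = 1,
                     is_coastal = TRUE, coastline_length_km = 50,
                     land_fraction = 1),
          attrs_row(2.5, "BEACH_RIVER_MOUTH", 6, 200,
                    "SALINE_SHALLOW_FRESH_DEEP", 300)),
    cbind(data.frame(cell_id = "high", row = 1L, col = 3L, lon_min = 1.5,
                     lat_min = 0.5, lon_max = 2, lat_max = 1,
                     is_coastal = TRUE, coastline_length_km = 50,
                     land_fraction = 1),
          attrs_row(1, "DELTA_PLAIN_RIVER_MOUTH", 12, 140,
                    "SALINE_SHALLOW_AND_DEEP", 1200)))
  a <- cvi_assess(cells)
  expect_s3_class(a, "cvi_assessment")
  expect_equal(a$cells$cvi_class, c("LOW", "MODERATE", "HIGH"))
  # non-coastal rows are skipped
  cells2 <- cells
  cells2$is_coastal[2] <- FALSE
  expect_equal(nrow(cvi_assess(cells2)$cells), 2L)
  # empty coastal set is allowed
  cells3 <- cells
  cells3$is_coastal <- FALSE
  expect_equal(nrow(cvi_assess(cells3)$cells), 0L)
  # unattributed coastal cell errors with the offending id
  cells4 <- cells
  cells4$pop_density[3] <- NA
  expect_error(cvi_assess(cells4), "high")
})
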