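test_that("density lookup follows the half-open cell convention", {
  r <- flat_raster(100)
  expect_equal(lookup_density(r, c(0.1, 5.5, 9.9), c(0.1, 5.5, 10)), rep(100, 3))

  # 2x2 raster with distinct values: each quadrant returns its own cell
  r2 <- flat_raster(0, origin_lon = 0, origin_lat = 2, cell_size = 1,
                    n_rows = 2, n_cols = 2)
  r2$values <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)  # row 1 = north
  expect_equal(lookup_density(r2, 0.5, 1.5), 1)
  expect_equal(lookup_density(r2, 1.5, 1.5), 2)
  expect_equal(lookup_density(r2, 0.5, 0.5), 3)
  expect_equal(lookup_density(r2, 1.5, 0.5), 4)
  # interior west edge belongs to the cell east of it
  expect_equal(lookup_density(r2, 1, 0.5), 4)
  # north boundary of the raster belongs to row 1
  expect_equal(lookup_density(r2, 0.5, 2), 1)
  expect_error(lookup_density(r2, 2.5, 0.5), "outside the raster")
  expect_error(lookup_density(r2, 0.5, 0), "outside the raster")
})

test_that("weighted aggregation reproduces hand-computed values", {
  s <- two_household_setup(weights = c(1, 1), scores = c(0.2, 0.4))
  agg <- aggregate_scores(s$scores, s$households, s$clusters, s$raster,
                          level = "admin1", use_density = FALSE)
  expect_equal(agg$pdi_raw, 0.3)
  expect_equal(agg$n_households, 2L)

  s <- two_household_setup(weights = c(1, 3), scores = c(0, 1))
  agg <- aggregate_scores(s$scores, s$households, s$clusters, s$raster,
                          level = "admin1", use_density = FALSE)
  expect_equal(agg$pdi_raw, 0.75)

  # densities {e-1, e^3-1} give log-weights {1, 3}: aggregate 0.75 by hand
  s <- two_household_setup(weights = c(1, 1), scores = c(0, 1),
                           densities = c(exp(1) - 1, exp(3) - 1))
  agg <- aggregate_scores(s$scores, s$households, s$clusters, s$raster,
                          level = "admin1", use_density = TRUE)
  expect_equal(agg$pdi_density_weighted, 0.75, tolerance = 1e-12)
})

test_that("constant density cancels and weight rescaling is invariant", {
  s <- two_household_setup(weights = c(0.7, 2.2), scores = c(-0.3, 0.9),
                           densities = c(555, 555))
  agg <- aggregate_scores(s$scores, s$households, s$clusters, s$raster,
                          level = "admin1", use_density = TRUE)
  expect_equal(agg$pdi_density_weighted, agg$pdi_raw, tolerance = 1e-14)

  s2 <- s
  s2$households$sample_weight <- s$households$sample_weight * 13.7
  agg2 <- aggregate_scores(s2$scores, s2$households, s2$clusters, s2$raster,
                           level = "admin1", use_density = TRUE)
  expect_equal(agg2$pdi_raw, agg$pdi_raw, tolerance = 1e-12)
  expect_equal(agg2$pdi_density_weighted, agg$pdi_density_weighted,
               tolerance = 1e-12)
})

test_that("aggregates stay within household score bounds and shift toward dense deprived clusters", {
  set.seed(10)
  sim <- simulate_pdi_data(tiny_config(seed = 10))
  im <- indicator_matrix(sim$households)
  scores <- data.frame(household_id = im$household_id,
                       score = score_households(fit_pdi_model(im$matrix), im$matrix))
  agg <- aggregate_scores(scores, sim$households, sim$clusters, sim$raster,
                          regions = sim$regions, level = "admin1",
                          use_density = TRUE)
  merged <- merge(merge(scores, sim$households[, c("household_id", "cluster_id")]),
                  sim$clusters[, c("cluster_id", "region_id")])
  for (i in seq_len(nrow(agg))) {
    rng <- range(merged$score[merged$region_id == agg$region_id[i]])
    expect_gte(agg$pdi_raw[i], rng[1])
    expect_lte(agg$pdi_raw[i], rng[2])
    expect_gte(agg$pdi_density_weighted[i], rng[1])
    expect_lte(agg$pdi_density_weighted[i], rng[2])
  }
  expect_true(all(agg$pdi_normalized >= 0 & agg$pdi_normalized <= 1))

  # two clusters, denser one more deprived -> density weighting raises the aggregate
  s <- two_household_setup(weights = c(1, 1), scores = c(0, 1),
                           densities = c(10, 1000))
  agg2 <- aggregate_scores(s$scores, s$households, s$clusters, s$raster,
                           level = "admin1", use_density = TRUE)
  expect_gte(agg2$pdi_density_weighted, agg2$pdi_raw)
})

test_that("admin0 pools everything and missing region mapping errors", {
  s <- two_household_setup(weights = c(1, 3), scores = c(0, 1))
  agg0 <- aggregate_scores(s$scores, s$households, s$clusters, s$raster,
                           level = "admin0", use_density = FALSE,
                           normalize_domain = c(0, 1))
  expect_equal(agg0$region_id, "ALL")
  expect_equal(agg0$pdi_raw, 0.75)
  s$clusters$region_id[1] <- NA
  expect_error(aggregate_scores(s$scores, s$households, s$clusters, s$raster,
                                level = "admin1", use_density = FALSE),
               "map to a region")
})

test_that("min-max normalization contract", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_minmax(2.5, domain = c(0, 10)), 0.25)
  # idempotent on an already-normalized set with the unit domain
  v <- c(0, 0.25, 0.8, 1)
  expect_identical(normalize_minmax(v, domain = c(0, 1)), v)
  # monotone, endpoints mapped to 0 and 1, most deprived unit gets 1
  x <- c(0.3, -1.2, 2.5, 0.9)
  nx <- normalize_minmax(x)
  expect_identical(order(nx), order(x))
  expect_equal(nx[which.min(x)], 0)
  expect_equal(nx[which.max(x)], 1)
  expect_error(normalize_minmax(c(3, 3, 3)), "degenerate")
})
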