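test_that("generation is a pure function of the configuration", {
  cfg <- tiny_config(seed = 7)
  a <- simulate_pdi_data(cfg)
  b <- simulate_pdi_data(cfg)
  expect_identical(a$field, b$field)
  expect_identical(a$households, b$households)
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$raster, b$raster)
  expect_identical(a$caseloads, b$caseloads)
})

test_that("latent field honours its contract", {
  cfg <- synthetic_config(seed = 2, n_regions = 9, clusters_per_region = 22)
  f <- generate_latent_field(cfg)
  expect_equal(nrow(f), 9 * 22)
  expect_equal(mean(f$deprivation), 0, tolerance = 1e-10)
  expect_equal(sd(f$deprivation), cfg$factor_sd, tolerance = 1e-10)
  # clusters inside their region rectangles
  regions <- make_regions(cfg)
  assigned <- region_for_points(regions, f$true_lon, f$true_lat)
  expect_identical(assigned, f$region_id)

  # factor_sd = 0 -> exactly zero field
  f0 <- generate_latent_field(tiny_config(seed = 3, factor_sd = 0))
  expect_identical(f0$deprivation, rep(0, nrow(f0)))
})

test_that("spatial range controls the correlation of neighbouring clusters", {
  nn_lag_cor <- function(f) {
    d <- as.matrix(dist(cbind(f$true_lon, f$true_lat)))
    diag(d) <- Inf
    nn <- apply(d, 1, which.min)
    cor(f$deprivation, f$deprivation[nn])
  }
  r_indep <- sapply(1:4, function(s) {
    nn_lag_cor(generate_latent_field(
      synthetic_config(seed = s, n_regions = 9, clusters_per_region = 25,
                       factor_spatial_range = 0)))
  })
  # Monte-Carlo bound at 225 clusters: |r| stays well below 0.2
  expect_lt(max(abs(r_indep)), 0.2)
  r_smooth <- nn_lag_cor(generate_latent_field(
    synthetic_config(seed = 1, n_regions = 9, clusters_per_region = 25,
                     factor_spatial_range = 2, factor_nugget = 0.1)))
  expect_gt(r_smooth, 0.4)
})

test_that("households: zero noise and constant deprivation give identical binaries within clusters", {
  cfg <- tiny_config(seed = 5, factor_sd = 0, indicator_noise_sd = 0)
  f <- generate_latent_field(cfg)
  hh <- generate_households(f, cfg)
  for (col in c("water_public", "has_mobile", "has_vehicle")) {
    expect_equal(length(unique(hh[[col]])), 1)
  }
  expect_equal(length(unique(hh$toilet_sharing_count >= 1)), 1)
  expect_error(generate_households(f[0, ], cfg), "non-empty")
})

test_that("each indicator is a monotone function of latent deprivation (zero noise)", {
  cfg <- synthetic_config(seed = 11, indicator_noise_sd = 0)
  f <- generate_latent_field(cfg)
  hh <- generate_households(f, cfg)
  ind <- derive_indicators(hh)
  z <- f$deprivation[match(hh$cluster_id, f$cluster_id)]
  dec <- cut(z, quantile(z, 0:10 / 10), include.lowest = TRUE, labels = FALSE)
  for (col in indicator_names()) {
    m <- tapply(ind[[col]], dec, mean)
    expect_true(all(diff(m) >= -1e-9),
                info = paste("decile means not monotone for", col))
  }
})

test_that("displacement respects radii and determinism", {
  skip_if_not_installed("geosphere")
  cfg <- synthetic_config(seed = 4, n_regions = 9, clusters_per_region = 30)
  f <- generate_latent_field(cfg)
  cl <- displace_coordinates(f, cfg)
  d_km <- geosphere::distHaversine(cbind(f$true_lon, f$true_lat),
                                   cbind(cl$lon, cl$lat)) / 1000
  r <- ifelse(f$urban, cfg$displacement_urban_km, cfg$displacement_rural_km)
  # planar degree conversion is accurate to well under 0.5% at these scales
  expect_true(all(d_km <= r * 1.005))
  expect_identical(cl, displace_coordinates(f, cfg))

  cfg0 <- synthetic_config(seed = 4, n_regions = 9, clusters_per_region = 30,
                           displacement_urban_km = 0, displacement_rural_km = 0)
  cl0 <- displace_coordinates(f, cfg0)
  expect_equal(cl0$lon, f$true_lon, tolerance = 1e-7)
  expect_equal(cl0$lat, f$true_lat, tolerance = 1e-7)
})

test_that("density raster covers the box, stays in range, and is reproducible", {
  cfg <- tiny_config(seed = 6)
  f <- generate_latent_field(cfg)
  r <- generate_density_raster(cfg, f)
  expect_equal(dim(r$values), c(r$n_rows, r$n_cols))
  expect_equal(r$n_cols, ceiling((cfg$bbox[3] - cfg$bbox[1]) / cfg$grid_cell_size))
  expect_true(all(r$values >= cfg$density_range[1] &
                    r$values <= cfg$density_range[2]))
  expect_identical(r, generate_density_raster(cfg, f))

  cfg_flat <- tiny_config(seed = 6, density_range = c(250, 250))
  rf <- generate_density_raster(cfg_flat, f)
  expect_true(all(rf$values == 250))
})

test_that("caseloads: null effect uncorrelated, strong effect strongly rank-correlated", {
  risk <- data.frame(region_id = sprintf("R%02d", 1:50), risk = NA_real_)
  sp <- sapply(1:40, function(s) {
    set.seed(1000 + s)
    risk$risk <- rnorm(50)
    cfg <- synthetic_config(seed = s, n_regions = 50, caseload_effect = 0)
    cor(risk$risk, generate_caseloads(risk, cfg)$cumulative_cases,
        method = "spearman")
  })
  expect_lt(abs(mean(sp)), 0.08)  # MC bound: sd(mean) ~ 0.14/sqrt(40)

  sp2 <- sapply(1:40, function(s) {
    set.seed(2000 + s)
    risk$risk <- rnorm(50)
    cfg <- synthetic_config(seed = s, n_regions = 50, caseload_effect = 2)
    cor(risk$risk, generate_caseloads(risk, cfg)$cumulative_cases,
        method = "spearman")
  })
  # Monte-Carlo oracle (500 reps, pre-build): E[spearman] ~ 0.88
  expect_gt(mean(sp2), 0.8)
  cfg <- synthetic_config(seed = 9, n_regions = 50)
  set.seed(1); risk$risk <- rnorm(50)
  expect_identical(generate_caseloads(risk, cfg), generate_caseloads(risk, cfg))
  expect_true(all(generate_caseloads(risk, cfg)$cumulative_cases >= 0))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_regions = 0), "strictly positive")
  expect_error(synthetic_config(grid_cell_size = 0), "grid_cell_size")
  expect_error(synthetic_config(factor_sd = -1), "standard deviations")
  expect_error(synthetic_config(indicator_calibration = list(share_toilet_rate = 1.2)),
               "rates")
  expect_error(synthetic_config(indicator_calibration = list(bogus = 1)), "unknown")
})
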