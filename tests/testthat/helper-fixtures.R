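# Small configurations and fixtures shared across test files.

tiny_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_regions = 4L, clusters_per_region = 5L,
                   households_per_cluster = 10L, ...)
}

# constant raster covering the unit-ish box used in aggregation tests
flat_raster <- function(value = 100, origin_lon = 0, origin_lat = 10,
                        cell_size = 1, n_rows = 10, n_cols = 10) {
  structure(
    list(origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
         values = matrix(value, n_rows, n_cols)),
    class = "density_raster"
  )
}

# minimal scored two-household setup on a single cluster/region
two_household_setup <- function(weights, scores, densities = c(100, 100)) {
  households <- data.frame(
    household_id = c("H1", "H2"),
    cluster_id = c("C1", "C2"),
    sample_weight = weights,
    stringsAsFactors = FALSE
  )
  clusters <- data.frame(
    cluster_id = c("C1", "C2"),
    lon = c(0.5, 1.5), lat = c(9.5, 9.5),
    urban = c(TRUE, FALSE), region_id = c("R1", "R1"),
    stringsAsFactors = FALSE
  )
  raster <- flat_raster(1)
  raster$values[1, 1] <- densities[1]
  raster$values[1, 2] <- densities[2]
  list(
    scores = data.frame(household_id = c("H1", "H2"), score = scores),
    households = households, clusters = clusters, raster = raster
  )
}

# random deprivation-style indicator matrix
random_indicator_matrix <- function(n = 50, seed = 1) {
  set.seed(seed)
  m <- cbind(
    share_toilet = rpois(n, 1.5),
    public_water = rbinom(n, 1, 0.4),
    persons_per_room = rlnorm(n, log(3), 0.4),
    no_ict = rbinom(n, 1, 0.3),
    no_vehicle = rbinom(n, 1, 0.5)
  )
  # guard against degenerate binary columns at small n
  m[1, ] <- c(0, 0, 1, 0, 0)
  m[2, ] <- c(3, 1, 5, 1, 1)
  m
}
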