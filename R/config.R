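#' Configuration for the synthetic survey generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_pdi_data()] and the individual generator stages. The defaults
#' describe a DHS-like study: 30 admin-1 regions tiling a 10 x 10 degree
#' bounding box, 20 clusters (primary sampling units) per region and 25
#' households per cluster, with a spatially correlated latent deprivation
#' factor driving all five infrastructure indicators. The default indicator
#' calibration targets the continental averages reported for African DHS
#' rounds: 45% of households sharing a toilet (with two other households on
#' average among sharers), 40% relying on a public water source, a mean of
#' 3.2 persons per sleeping room, 30% without a mobile phone and 50% without
#' any vehicle.
#'
#' @param seed integer master seed; every sub-generator derives its own child
#'   seed from it, so a config is a complete description of the output.
#' @param n_regions number of admin-1 regions (axis-aligned rectangles tiling
#'   the bounding box).
#' @param clusters_per_region number of survey clusters per region.
#' @param households_per_cluster number of households interviewed per cluster.
#' @param bbox numeric length-4: lon_min, lat_min, lon_max, lat_max (degrees).
#' @param factor_spatial_range range (degrees) of the exponential spatial
#'   correlation of the latent deprivation factor; 0 gives independent
#'   clusters.
#' @param factor_sd standard deviation of the latent deprivation factor
#'   across clusters.
#' @param factor_nugget share (0-1) of the factor variance that is
#'   spatially independent cluster noise.
#' @param indicator_noise_sd sd of the household-level noise added to the
#'   cluster factor before thresholding/transforming into indicators; 0 makes
#'   all households in a cluster identical on the binary indicators.
#' @param indicator_calibration named list of marginal targets:
#'   `share_toilet_rate`, `extra_sharers_mean`, `public_water_rate`,
#'   `persons_per_room_mean`, `no_mobile_rate`, `no_vehicle_rate`,
#'   `household_size_mean`.
#' @param sharing_count_slope log-linear slope of the extra-sharing-household
#'   count on the latent factor.
#' @param crowding_slope log-linear slope of persons-per-room on the latent
#'   factor.
#' @param household_size_slope log-linear slope of household size on the
#'   latent factor (deprived households are somewhat larger, as in DHS
#'   data); the marginal mean stays at `household_size_mean`.
#' @param urban_share probability that a cluster is urban.
#' @param weight_sd log-scale sd of the household sample weights (mean 1).
#' @param density_range numeric length-2, min and max population density
#'   (people per km^2) of the generated raster.
#' @param grid_cell_size raster cell size in degrees.
#' @param displacement_urban_km,displacement_rural_km maximum random
#'   displacement of public cluster coordinates (DHS anonymisation
#'   convention: 2 km urban, 5 km rural).
#' @param caseload_intercept log of the expected regional caseload at average
#'   latent risk.
#' @param caseload_effect slope of the log caseload rate per standard
#'   deviation of regional latent risk.
#' @param caseload_noise_sd sd of region-level log-normal noise on the
#'   caseload rate, representing determinants of detected caseloads
#'   (testing intensity, importation) unrelated to infrastructure.
#'
#' @return a validated list of class `pdi_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_regions = 30L,
                             clusters_per_region = 20L,
                             households_per_cluster = 25L,
                             bbox = c(0, 0, 10, 10),
                             factor_spatial_range = 1,
                             factor_sd = 1,
                             factor_nugget = 0.25,
                             indicator_noise_sd = 0.3,
                             indicator_calibration = list(),
                             sharing_count_slope = 1.0,
                             crowding_slope = 0.7,
                             household_size_slope = 0.3,
                             urban_share = 0.35,
                             weight_sd = 0.2,
                             density_range = c(1, 1000),
                             grid_cell_size = 0.25,
                             displacement_urban_km = 2,
                             displacement_rural_km = 5,
                             caseload_intercept = log(500),
                             caseload_effect = 1.5,
                             caseload_noise_sd = 1) {
  calib <- list(
    share_toilet_rate = 0.45,
    extra_sharers_mean = 2,
    public_water_rate = 0.40,
    persons_per_room_mean = 3.2,
    no_mobile_rate = 0.30,
    no_vehicle_rate = 0.50,
    household_size_mean = 4.5
  )
  stopifnot(is.list(indicator_calibration))
  unknown <- setdiff(names(indicator_calibration), names(calib))
  if (length(unknown) > 0) {
    stop("unknown indicator_calibration entries: ", paste(unknown, collapse = ", "))
  }
  calib[names(indicator_calibration)] <- indicator_calibration

  cfg <- list(
    seed = as.integer(seed),
    n_regions = as.integer(n_regions),
    clusters_per_region = as.integer(clusters_per_region),
    households_per_cluster = as.integer(households_per_cluster),
    bbox = as.numeric(bbox),
    factor_spatial_range = factor_spatial_range,
    factor_sd = factor_sd,
    factor_nugget = factor_nugget,
    indicator_noise_sd = indicator_noise_sd,
    indicator_calibration = calib,
    sharing_count_slope = sharing_count_slope,
    crowding_slope = crowding_slope,
    household_size_slope = household_size_slope,
    urban_share = urban_share,
    weight_sd = weight_sd,
    density_range = as.numeric(density_range),
    grid_cell_size = grid_cell_size,
    displacement_urban_km = displacement_urban_km,
    displacement_rural_km = displacement_rural_km,
    caseload_intercept = caseload_intercept,
    caseload_effect = caseload_effect,
    caseload_noise_sd = caseload_noise_sd
  )
  class(cfg) <- "pdi_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pdi_config"))
  if (cfg$n_regions < 1 || cfg$clusters_per_region < 1 ||
      cfg$households_per_cluster < 1) {
    stop("configuration error: all counts must be strictly positive")
  }
  if (length(cfg$bbox) != 4 || cfg$bbox[3] <= cfg$bbox[1] ||
      cfg$bbox[4] <= cfg$bbox[2]) {
    stop("configuration error: bbox must be (lon_min, lat_min, lon_max, lat_max) with positive extent")
  }
  if (cfg$grid_cell_size <= 0) stop("configuration error: grid_cell_size must be > 0")
  sds <- c(cfg$factor_sd, cfg$indicator_noise_sd, cfg$weight_sd, cfg$caseload_noise_sd)
  if (any(sds < 0)) stop("configuration error: standard deviations must be >= 0")
  if (cfg$factor_spatial_range < 0) stop("configuration error: factor_spatial_range must be >= 0")
  if (cfg$factor_nugget < 0 || cfg$factor_nugget > 1) {
    stop("configuration error: factor_nugget must lie in [0, 1]")
  }
  if (cfg$urban_share < 0 || cfg$urban_share > 1) {
    stop("configuration error: urban_share must lie in [0, 1]")
  }
  if (length(cfg$density_range) != 2 || any(cfg$density_range < 0) ||
      cfg$density_range[2] < cfg$density_range[1]) {
    stop("configuration error: density_range must be 0 <= min <= max")
  }
  if (cfg$displacement_urban_km < 0 || cfg$displacement_rural_km < 0) {
    stop("configuration error: displacement radii must be >= 0")
  }
  rates <- with(cfg$indicator_calibration,
                c(share_toilet_rate, public_water_rate, no_mobile_rate, no_vehicle_rate))
  if (any(rates <= 0) || any(rates >= 1)) {
    stop("configuration error: calibration rates must lie strictly in (0, 1)")
  }
  if (cfg$indicator_calibration$persons_per_room_mean <= 0 ||
      cfg$indicator_calibration$household_size_mean < 1 ||
      cfg$indicator_calibration$extra_sharers_mean < 1) {
    stop("configuration error: calibration means out of range")
  }
  invisible(cfg)
}

#' Read a generator configuration from a JSON file
#'
#' Accepts any subset of [synthetic_config()]'s arguments; unknown keys are
#' an error. A demo configuration ships with the package:
#' `system.file("extdata", "demo_config.json", package = "pdindex")`.
#'
#' @param path path to a JSON configuration file.
#' @return a validated `pdi_config`.
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s) in '", path, "': ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(obj$indicator_calibration)) {
    obj$indicator_calibration <- as.list(obj$indicator_calibration)
  }
  do.call(synthetic_config, obj)
}

# Deterministic child seeds so each generator stage has its own stream.
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
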