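#' Synthetic DHS-like survey data
#'
#' The generator emulates the statistical structure the index pipeline
#' assumes: clusters of co-located households, a single spatially correlated
#' latent deprivation factor that drives all five infrastructure indicators,
#' survey sample weights, anonymising displacement of cluster GPS
#' coordinates, a population density raster and regional epidemic caseloads
#' positively associated with latent risk. Everything is a pure function of
#' the configuration (including its seed).
#'
#' @name synthetic
NULL

#' Admin region polygons for a configuration
#'
#' Regions are axis-aligned rectangles tiling the configured bounding box
#' row by row (sufficient for point-in-polygon aggregation; arbitrary
#' polygons can be supplied through [read_regions()]).
#'
#' @param config a [synthetic_config()] object.
#' @return object of class `pdi_regions`: a list of `list(region_id, ring)`
#'   where `ring` is a closed lon/lat matrix.
#' @export
make_regions <- function(config) {
  validate_config(config)
  n <- config$n_regions
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  bb <- config$bbox
  w <- (bb[3] - bb[1]) / nx
  h <- (bb[4] - bb[2]) / ny
  regions <- vector("list", n)
  for (r in seq_len(n)) {
    ix <- (r - 1) %% nx
    iy <- (r - 1) %/% nx
    x0 <- bb[1] + ix * w
    y0 <- bb[2] + iy * h
    ring <- cbind(
      lon = c(x0, x0 + w, x0 + w, x0, x0),
      lat = c(y0, y0, y0 + h, y0 + h, y0)
    )
    regions[[r]] <- list(region_id = sprintf("R%02d", r), ring = ring)
  }
  structure(regions, class = "pdi_regions")
}

#' Assign points to regions
#'
#' @param regions a `pdi_regions` object.
#' @param lon,lat point coordinates (degrees).
#' @return character vector of region ids (`NA` where no polygon contains
#'   the point).
#' @export
region_for_points <- function(regions, lon, lat) {
  stopifnot(inherits(regions, "pdi_regions"), length(lon) == length(lat))
  pts <- cbind(lon, lat)
  out <- rep(NA_character_, length(lon))
  for (rg in regions) {
    hit <- is.na(out) & mgcv::in.out(rg$ring, pts)
    out[hit] <- rg$region_id
  }
  out
}

#' Generate the latent deprivation field
#'
#' Places clusters uniformly inside their region rectangles and draws the
#' cluster-level deprivation factor from a Gaussian process with exponential
#' correlation `exp(-d / factor_spatial_range)` plus an independent nugget,
#' scaled to overall sd `factor_sd`.
#'
#' @param config a [synthetic_config()] object.
#' @return data frame with `cluster_id`, `region_id`, `true_lon`, `true_lat`,
#'   `urban`, `deprivation`.
#' @export
generate_latent_field <- function(config) {
  validate_config(config)
  seeds <- child_seeds(config$seed, 8L)
  set.seed(seeds[1])
  regions <- make_regions(config)
  m <- config$n_regions * config$clusters_per_region
  region_id <- character(m)
  lon <- numeric(m)
  lat <- numeric(m)
  k <- 1L
  for (rg in regions) {
    xr <- range(rg$ring[, "lon"])
    yr <- range(rg$ring[, "lat"])
    idx <- k:(k + config$clusters_per_region - 1L)
    lon[idx] <- runif(config$clusters_per_region, xr[1], xr[2])
    lat[idx] <- runif(config$clusters_per_region, yr[1], yr[2])
    region_id[idx] <- rg$region_id
    k <- k + config$clusters_per_region
  }
  urban <- runif(m) < config$urban_share

  if (config$factor_sd == 0) {
    z <- numeric(m)
  } else {
    u <- rnorm(m)
    nug <- config$factor_nugget
    if (config$factor_spatial_range == 0 || nug >= 1) {
      z <- u
    } else {
      d <- as.matrix(dist(cbind(lon, lat)))
      K <- (1 - nug) * exp(-d / config$factor_spatial_range)
      diag(K) <- diag(K) + nug + 1e-8
      L <- chol(K)
      z <- drop(crossprod(L, u))
    }
    # standardize the realized field so the LatentField contract (mean 0,
    # sd = factor_sd across clusters) holds exactly; under spatial
    # correlation the raw draw's mean drifts with the field's effective
    # sample size, which would leak into every indicator margin
    if (m > 1 && stats::sd(z) > 0) z <- (z - mean(z)) / stats::sd(z)
    z <- config$factor_sd * z
  }
  data.frame(
    cluster_id = sprintf("C%04d", seq_len(m)),
    region_id = region_id,
    true_lon = lon,
    true_lat = lat,
    urban = urban,
    deprivation = z,
    stringsAsFactors = FALSE
  )
}

# Multiplicative correction so the realized mean of n_members / rooms hits
# the persons-per-room calibration target despite integer rooms; fitted once
# by simulation at the default configuration.
ppr_rounding_cal <- 1.20

#' Generate household survey records
#'
#' Each indicator is a monotone stochastic function of the household latent
#' deprivation `t = z_cluster + e`, `e ~ N(0, indicator_noise_sd^2)` (drawn
#' independently per indicator). Binary indicators are thresholds on `t`,
#' with the threshold chosen in closed form so the marginal rate equals its
#' calibration target; the extra-sharing-household count and persons per
#' room are log-linear in `t` with mean-preserving log-normal calibration.
#'
#' @param field output of [generate_latent_field()].
#' @param config a [synthetic_config()] object.
#' @return data frame of household records (see [derive_indicators()] for
#'   the raw schema).
#' @export
generate_households <- function(field, config) {
  validate_config(config)
  if (!is.data.frame(field) || nrow(field) == 0) {
    stop("latent field must be a non-empty data frame")
  }
  seeds <- child_seeds(config$seed, 8L)
  set.seed(seeds[2])
  calib <- config$indicator_calibration
  hpc <- config$households_per_cluster
  n <- nrow(field) * hpc
  cl <- rep(seq_len(nrow(field)), each = hpc)
  z <- field$deprivation[cl]
  s2 <- config$factor_sd^2 + config$indicator_noise_sd^2
  s <- sqrt(s2)
  noise <- function() rnorm(n, 0, config$indicator_noise_sd)

  thresh_binary <- function(rate) {
    t <- z + noise()
    as.integer(t > s * qnorm(1 - rate))
  }

  # shared sanitation: probability of sharing at all, then 1 + Poisson extra
  # households with a log-linear rate in the same latent draw; the rate is
  # normalized by E[exp(b t) | t > c] (truncated log-normal mean) so the
  # conditional mean count among sharers equals the calibration target
  t_s <- z + noise()
  c_s <- s * qnorm(1 - calib$share_toilet_rate)
  shares <- t_s > c_s
  b <- config$sharing_count_slope
  cond_mean <- if (s > 0) {
    exp(0.5 * b^2 * s2) * pnorm((b * s2 - c_s) / s) / pnorm(-c_s / s)
  } else {
    1
  }
  lam <- (calib$extra_sharers_mean - 1) * exp(b * t_s) / cond_mean
  toilet_sharing_count <- ifelse(shares, 1L + rpois(n, lam), 0L)

  water_public <- thresh_binary(calib$public_water_rate)
  has_mobile <- 1L - thresh_binary(calib$no_mobile_rate)
  has_vehicle <- 1L - thresh_binary(calib$no_vehicle_rate)

  hs <- config$household_size_slope
  n_members <- 1L + rpois(n, (calib$household_size_mean - 1) *
                            exp(hs * (z + noise()) - 0.5 * hs^2 * s2))
  g <- config$crowding_slope
  t_p <- z + noise()
  ppr_target <- ppr_rounding_cal * calib$persons_per_room_mean *
    exp(g * t_p - 0.5 * g^2 * s2)
  n_sleeping_rooms <- pmax(1L, as.integer(round(n_members / ppr_target)))

  w <- exp(rnorm(n, -0.5 * config$weight_sd^2, config$weight_sd))

  data.frame(
    household_id = sprintf("H%06d", seq_len(n)),
    cluster_id = field$cluster_id[cl],
    sample_weight = w,
    toilet_sharing_count = as.integer(toilet_sharing_count),
    water_public = water_public,
    n_members = as.integer(n_members),
    n_sleeping_rooms = as.integer(n_sleeping_rooms),
    has_mobile = has_mobile,
    has_vehicle = has_vehicle,
    stringsAsFactors = FALSE
  )
}

#' Displace cluster coordinates for anonymisation
#'
#' Mirrors the DHS convention of displacing published cluster GPS positions
#' by a uniformly distributed angle and a distance uniform on (0, radius),
#' with a larger radius for rural clusters. The true coordinates are kept in
#' the latent field for oracle tests only.
#'
#' @param field output of [generate_latent_field()].
#' @param config a [synthetic_config()] object.
#' @return cluster table: `cluster_id`, `lon`, `lat` (public, displaced),
#'   `urban`, `region_id`.
#' @export
displace_coordinates <- function(field, config) {
  validate_config(config)
  seeds <- child_seeds(config$seed, 8L)
  set.seed(seeds[3])
  m <- nrow(field)
  r_km <- ifelse(field$urban, config$displacement_urban_km,
                 config$displacement_rural_km)
  theta <- runif(m, 0, 2 * pi)
  d <- runif(m) * r_km
  km_per_deg_lat <- 110.574
  km_per_deg_lon <- 111.320 * cos(field$true_lat * pi / 180)
  bb <- config$bbox
  eps <- 1e-9
  # clamp to the study bounding box (DHS keeps displaced points inside the
  # country); projection onto the box never increases the displacement
  data.frame(
    cluster_id = field$cluster_id,
    lon = pmin(pmax(field$true_lon + d * sin(theta) / km_per_deg_lon,
                    bb[1] + eps), bb[3] - eps),
    lat = pmin(pmax(field$true_lat + d * cos(theta) / km_per_deg_lat,
                    bb[2] + eps), bb[4] - eps),
    urban = field$urban,
    region_id = field$region_id,
    stringsAsFactors = FALSE
  )
}

#' Generate a population density raster
#'
#' A smooth log-density field (bilinear interpolation of a coarse Gaussian
#' grid) plus Gaussian bumps at urban cluster locations, squashed to the
#' configured density range. Cell values therefore lie inside
#' `density_range` by construction; collapsing the range yields a constant
#' raster.
#'
#' @param config a [synthetic_config()] object.
#' @param field output of [generate_latent_field()] (used for urban bumps);
#'   may be `NULL` for a purely smooth raster.
#' @return object of class `density_raster`: list with `origin_lon`,
#'   `origin_lat` (upper-left corner), `cell_size`, `n_rows`, `n_cols`,
#'   `values` (matrix, row 1 = northernmost).
#' @export
generate_density_raster <- function(config, field = NULL) {
  validate_config(config)
  seeds <- child_seeds(config$seed, 8L)
  set.seed(seeds[4])
  bb <- config$bbox
  cs <- config$grid_cell_size
  n_cols <- ceiling((bb[3] - bb[1]) / cs)
  n_rows <- ceiling((bb[4] - bb[2]) / cs)
  # cell-centre coordinates; row 1 is the northern edge
  cx <- bb[1] + (seq_len(n_cols) - 0.5) * cs
  cy <- bb[2] + n_rows * cs - (seq_len(n_rows) - 0.5) * cs

  # coarse latent grid, bilinearly interpolated
  nc <- 6L
  gx <- seq(bb[1], bb[1] + n_cols * cs, length.out = nc)
  gy <- seq(bb[2], bb[2] + n_rows * cs, length.out = nc)
  gz <- matrix(rnorm(nc * nc), nc, nc)
  interp <- function(x, grid) {
    i <- pmin(pmax(findInterval(x, grid), 1L), nc - 1L)
    w <- (x - grid[i]) / (grid[i + 1L] - grid[i])
    list(i = i, w = w)
  }
  ix <- interp(cx, gx)
  iy <- interp(cy, gy)
  smooth <- matrix(0, n_rows, n_cols)
  for (r in seq_len(n_rows)) {
    i <- iy$i[r]; wy <- iy$w[r]
    row0 <- gz[i, ix$i] * (1 - ix$w) + gz[i, ix$i + 1L] * ix$w
    row1 <- gz[i + 1L, ix$i] * (1 - ix$w) + gz[i + 1L, ix$i + 1L] * ix$w
    smooth[r, ] <- row0 * (1 - wy) + row1 * wy
  }

  if (!is.null(field) && any(field$urban)) {
    ux <- field$true_lon[field$urban]
    uy <- field$true_lat[field$urban]
    sigma <- 0.5
    for (k in seq_along(ux)) {
      dx2 <- outer(rep(1, n_rows), (cx - ux[k])^2)
      dy2 <- outer((cy - uy[k])^2, rep(1, n_cols))
      smooth <- smooth + 1.5 * exp(-(dx2 + dy2) / (2 * sigma^2))
    }
  }

  u <- 1 / (1 + exp(-smooth))
  vals <- config$density_range[1] +
    (config$density_range[2] - config$density_range[1]) * u
  structure(
    list(
      origin_lon = bb[1],
      origin_lat = bb[2] + n_rows * cs,
      cell_size = cs,
      n_rows = n_rows,
      n_cols = n_cols,
      values = vals
    ),
    class = "density_raster"
  )
}

#' Generate regional epidemic caseloads
#'
#' Cumulative detected cases are Poisson with log-rate
#' `caseload_intercept + caseload_effect * standardized latent risk +
#' region noise`, where the noise (sd `caseload_noise_sd`) represents
#' caseload determinants unrelated to infrastructure, such as testing
#' intensity and importation.
#'
#' @param regional_risk data frame with `region_id` and `risk` (regional
#'   mean latent deprivation).
#' @param config a [synthetic_config()] object.
#' @return data frame with `region_id`, `cumulative_cases`.
#' @export
generate_caseloads <- function(regional_risk, config) {
  validate_config(config)
  stopifnot(is.data.frame(regional_risk),
            all(c("region_id", "risk") %in% names(regional_risk)))
  seeds <- child_seeds(config$seed, 8L)
  set.seed(seeds[5])
  r <- regional_risk$risk
  zs <- if (stats::sd(r) > 0) (r - mean(r)) / stats::sd(r) else rep(0, length(r))
  eta <- config$caseload_intercept + config$caseload_effect * zs +
    rnorm(length(r), 0, config$caseload_noise_sd)
  data.frame(
    region_id = regional_risk$region_id,
    cumulative_cases = rpois(length(r), exp(eta)),
    stringsAsFactors = FALSE
  )
}

#' Regional mean latent deprivation (ground truth)
#'
#' @param field output of [generate_latent_field()].
#' @return data frame with `region_id`, `risk`.
#' @export
regional_truth <- function(field) {
  agg <- aggregate(field$deprivation, by = list(region_id = field$region_id), FUN = mean)
  names(agg)[2] <- "risk"
  agg[order(agg$region_id), , drop = FALSE]
}

#' Run the full synthetic generator
#'
#' @param config a [synthetic_config()] object.
#' @return list with `config`, `regions`, `field` (truth, including latent
#'   deprivation), `clusters` (public displaced coordinates), `households`,
#'   `raster`, `truth` (regional mean deprivation) and `caseloads`.
#' @export
simulate_pdi_data <- function(config = synthetic_config()) {
  validate_config(config)
  field <- generate_latent_field(config)
  households <- generate_households(field, config)
  clusters <- displace_coordinates(field, config)
  raster <- generate_density_raster(config, field)
  truth <- regional_truth(field)
  caseloads <- generate_caseloads(truth, config)
  list(
    config = config,
    regions = make_regions(config),
    field = field,
    clusters = clusters,
    households = households,
    raster = raster,
    truth = truth,
    caseloads = caseloads
  )
}
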