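#' Density lookup in a raster
#'
#' Cells are half-open: a cell owns longitudes in `[west, east)` and
#' latitudes in `(south, north]`; row 1 is the northernmost row. Points
#' outside the raster extent are an error.
#'
#' @param raster a `density_raster`.
#' @param lon,lat coordinates (degrees); vectorized.
#' @return people per km^2 at each point.
#' @export
lookup_density <- function(raster, lon, lat) {
  stopifnot(inherits(raster, "density_raster"), length(lon) == length(lat))
  col <- 1L + floor((lon - raster$origin_lon) / raster$cell_size)
  row <- 1L + floor((raster$origin_lat - lat) / raster$cell_size)
  # the northern boundary itself belongs to row 1
  row[lat == raster$origin_lat] <- 1L
  bad <- col < 1 | col > raster$n_cols | row < 1 | row > raster$n_rows
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point (%.6f, %.6f) lies outside the raster extent", lon[i], lat[i]))
  }
  raster$values[cbind(row, col)]
}

#' Aggregate household scores to regions
#'
#' The regional index is the weighted mean of household scores, with weight
#' `sample_weight` alone (`use_density = FALSE`) or
#' `sample_weight * log(1 + density)` at the household's cluster location
#' (`use_density = TRUE`). The natural logarithm is used; the base only
#' rescales all weights by a constant and leaves aggregates unchanged.
#' Density is looked up at the public (displaced) cluster coordinates — the
#' only coordinates available in real use. Regions with no households are
#' omitted with a warning.
#'
#' @param scores data frame with `household_id`, `score`.
#' @param households household records (for `cluster_id`, `sample_weight`).
#' @param clusters cluster table with `cluster_id`, `lon`, `lat` and,
#'   unless `regions` is given, a `region_id` column.
#' @param raster a `density_raster` (required when `use_density = TRUE`).
#' @param regions optional `pdi_regions`; when supplied, cluster membership
#'   is recomputed by point-in-polygon.
#' @param level `"admin1"` (per region) or `"admin0"` (whole study area as
#'   one unit).
#' @param use_density logical, apply the log(1 + density) weight.
#' @param normalize_domain optional explicit c(min, max) for the final
#'   min-max normalization; default is the observed range of the aggregates
#'   at this level.
#' @return data frame of class `region_aggregate` with `region_id`, `level`,
#'   `pdi_raw`, `pdi_density_weighted`, `pdi_normalized`, `n_households`,
#'   `mean_log_density`. `pdi_normalized` normalizes the density-weighted
#'   aggregate when `use_density` is on, the raw one otherwise.
#' @export
aggregate_scores <- function(scores, households, clusters, raster = NULL,
                             regions = NULL, level = c("admin1", "admin0"),
                             use_density = TRUE, normalize_domain = NULL) {
  level <- match.arg(level)
  stopifnot(is.data.frame(scores), all(c("household_id", "score") %in% names(scores)))
  if (use_density && is.null(raster)) {
    stop("use_density = TRUE requires a density raster")
  }
  if (!is.null(regions)) {
    clusters$region_id <- region_for_points(regions, clusters$lon, clusters$lat)
  }
  if (!("region_id" %in% names(clusters)) || anyNA(clusters$region_id)) {
    stop("every cluster must map to a region")
  }
  hh <- merge(households[, c("household_id", "cluster_id", "sample_weight")],
              scores, by = "household_id")
  hh <- merge(hh, clusters[, c("cluster_id", "lon", "lat", "region_id")],
              by = "cluster_id")
  if (nrow(hh) < nrow(scores)) {
    stop("some scored households have no cluster with coordinates")
  }
  dens <- if (!is.null(raster)) lookup_density(raster, hh$lon, hh$lat) else NA_real_
  hh$log_density <- if (!is.null(raster)) log1p(dens) else NA_real_
  hh$group <- if (level == "admin1") hh$region_id else "ALL"

  ids <- sort(unique(hh$group))
  out <- do.call(rbind, lapply(ids, function(g) {
    sub <- hh[hh$group == g, , drop = FALSE]
    w0 <- sub$sample_weight
    raw <- sum(w0 * sub$score) / sum(w0)
    if (!is.null(raster)) {
      wd <- w0 * sub$log_density
      dw <- sum(wd * sub$score) / sum(wd)
      mld <- mean(sub$log_density)
    } else {
      dw <- NA_real_
      mld <- NA_real_
    }
    data.frame(region_id = g, level = level, pdi_raw = raw,
               pdi_density_weighted = dw, n_households = nrow(sub),
               mean_log_density = mld, stringsAsFactors = FALSE)
  }))
  if (!is.null(regions) && level == "admin1") {
    all_ids <- vapply(regions, `[[`, character(1), "region_id")
    empty <- setdiff(all_ids, ids)
    if (length(empty) > 0) {
      warning("regions with zero households omitted: ", paste(empty, collapse = ", "))
    }
  }
  target <- if (use_density) out$pdi_density_weighted else out$pdi_raw
  out$pdi_normalized <- if (nrow(out) >= 2 || !is.null(normalize_domain)) {
    normalize_minmax(target, domain = normalize_domain)
  } else {
    NA_real_
  }
  class(out) <- c("region_aggregate", class(out))
  out
}

#' Min-max normalization to the unit interval
#'
#' `v' = (v - min) / (max - min)`; the observed (or supplied) minimum maps
#' to 0 and the maximum to 1, so the most deprived unit gets index 1.
#'
#' @param values numeric vector.
#' @param domain optional explicit `c(min, max)`; defaults to the observed
#'   range of `values`.
#' @return normalized values.
#' @export
normalize_minmax <- function(values, domain = NULL) {
  stopifnot(is.numeric(values))
  if (is.null(domain)) domain <- range(values)
  if (length(domain) != 2 || !all(is.finite(domain))) {
    stop("normalization domain must be two finite numbers")
  }
  if (domain[2] <= domain[1]) {
    stop("degenerate normalization range: max must exceed min")
  }
  (values - domain[1]) / (domain[2] - domain[1])
}
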