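#' Readers and writers for the pipeline's plain-text formats
#'
#' CSV tables (UTF-8, comma separated, header required), GeoJSON region
#' polygons (RFC 7946, lon-lat order) and ESRI ASCII grids for rasters.
#'
#' @name io
NULL

check_columns <- function(df, required, what, path) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s file '%s' missing column(s): %s", what, path,
                 paste(miss, collapse = ", ")))
  }
  invisible(df)
}

#' @rdname io
#' @param path file path.
#' @return typed data frames / objects mirroring the synthetic generator's
#'   outputs.
#' @export
read_households <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("household_id", "cluster_id", "sample_weight",
                      "toilet_sharing_count", "water_public", "n_members",
                      "n_sleeping_rooms", "has_mobile", "has_vehicle"),
                "households", path)
  bad <- which(!is.na(df$sample_weight) & df$sample_weight <= 0)
  if (length(bad) > 0) {
    stop("non-positive sample_weight at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!is.na(df$n_members) & df$n_members < 1)
  if (length(bad) > 0) {
    stop("n_members < 1 at data row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  df
}

#' @rdname io
#' @export
read_clusters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("cluster_id", "lon", "lat", "urban", "region_id"),
                "clusters", path)
  df$urban <- as.logical(df$urban)
  df
}

#' @rdname io
#' @export
read_caseloads <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("region_id", "cumulative_cases"), "caseloads", path)
  if (any(df$cumulative_cases < 0, na.rm = TRUE)) {
    stop("cumulative_cases must be >= 0 in ", path)
  }
  df
}

#' @rdname io
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("household_id", "score"), "scores", path)
  df
}

#' @rdname io
#' @param x object to write.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @param regions a `pdi_regions` object.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "pdi_regions"))
  feats <- lapply(regions, function(rg) {
    coords <- lapply(seq_len(nrow(rg$ring)), function(i) unname(rg$ring[i, ]))
    list(
      type = "Feature",
      properties = list(region_id = rg$region_id),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_regions <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("regions file '", path, "' is not a GeoJSON FeatureCollection")
  }
  regions <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon geometries are supported in ", path)
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(lon = p[[1]], lat = p[[2]])))
    list(region_id = as.character(f$properties$region_id), ring = ring)
  })
  structure(regions, class = "pdi_regions")
}

#' @rdname io
#' @param raster a `density_raster`.
#' @param digits number of significant digits written per cell.
#' @export
write_raster_asc <- function(raster, path, digits = 8) {
  stopifnot(inherits(raster, "density_raster"))
  hdr <- c(
    sprintf("ncols %d", raster$n_cols),
    sprintf("nrows %d", raster$n_rows),
    sprintf("xllcorner %.10g", raster$origin_lon),
    sprintf("yllcorner %.10g", raster$origin_lat - raster$n_rows * raster$cell_size),
    sprintf("cellsize %.10g", raster$cell_size),
    "NODATA_value -9999"
  )
  rows <- apply(raster$values, 1, function(v)
    paste(formatC(v, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname io
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss) > 0) {
    stop("ESRI ASCII header in '", path, "' missing: ", paste(miss, collapse = ", "))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("raster '", path, "' has ", length(vals), " cells; header implies ",
         hdr$ncols * hdr$nrows)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals[vals == nodata] <- NA_real_
  structure(
    list(
      origin_lon = hdr$xllcorner,
      origin_lat = hdr$yllcorner + hdr$nrows * hdr$cellsize,
      cell_size = hdr$cellsize,
      n_rows = as.integer(hdr$nrows),
      n_cols = as.integer(hdr$ncols),
      values = matrix(vals, as.integer(hdr$nrows), as.integer(hdr$ncols),
                      byrow = TRUE)
    ),
    class = "density_raster"
  )
}

#' Run the full index pipeline on a synthetic configuration
#'
#' Generates the study data, writes the inputs, then runs every stage
#' through the file-based readers: indicator derivation, index model fit,
#' household scoring, admin-1 aggregation with and without the density
#' weight, min-max normalization, an optional smooth surface, and the
#' validation report. A manifest records the configuration hash and seed so
#' identical configurations reproduce byte-identical artifact directories.
#'
#' @param config a [synthetic_config()].
#' @param out_dir artifact directory (created if needed).
#' @param surface logical, also fit and write the pixel surface grids.
#' @param surface_cell_deg cell size (degrees) of the surface grids.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, surface = FALSE,
                         surface_cell_deg = 0.25) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    sim <- simulate_pdi_data(config)
    write_table(sim$households, file.path(out_dir, "households.csv"))
    write_table(sim$clusters, file.path(out_dir, "clusters.csv"))
    write_regions(sim$regions, file.path(out_dir, "regions.geojson"))
    write_raster_asc(sim$raster, file.path(out_dir, "density.asc"))
    write_table(sim$caseloads, file.path(out_dir, "caseloads.csv"))
    write_table(sim$truth, file.path(out_dir, "truth.csv"))

    stage <- "index"
    households <- read_households(file.path(out_dir, "households.csv"))
    im <- indicator_matrix(households)
    model <- fit_pdi_model(im$matrix)
    write_pdi_model(model, file.path(out_dir, "model.json"))
    scores <- data.frame(household_id = im$household_id,
                         score = score_households(model, im$matrix))
    write_table(scores, file.path(out_dir, "scores.csv"))

    stage <- "aggregate"
    clusters <- read_clusters(file.path(out_dir, "clusters.csv"))
    regions <- read_regions(file.path(out_dir, "regions.geojson"))
    raster <- read_raster_asc(file.path(out_dir, "density.asc"))
    agg <- aggregate_scores(scores, households, clusters, raster,
                            regions = regions, level = "admin1",
                            use_density = TRUE)
    write_table(agg, file.path(out_dir, "aggregates_admin1.csv"))
    agg0 <- aggregate_scores(scores, households, clusters, raster,
                             level = "admin0", use_density = TRUE,
                             normalize_domain = range(agg$pdi_density_weighted))
    write_table(agg0, file.path(out_dir, "aggregates_admin0.csv"))

    surf <- NULL
    if (surface) {
      stage <- "surface"
      cl_scores <- merge(households[, c("household_id", "cluster_id")], scores,
                         by = "household_id")
      by_cl <- aggregate(cl_scores$score,
                         by = list(cluster_id = cl_scores$cluster_id),
                         FUN = mean)
      names(by_cl)[2] <- "mean_score"
      by_cl$n_households <- as.vector(table(cl_scores$cluster_id)[by_cl$cluster_id])
      by_cl <- merge(by_cl, clusters[, c("cluster_id", "lon", "lat")],
                     by = "cluster_id")
      surf <- fit_surface(by_cl, lambda = "auto")
      sp <- surf$spec
      n_cols <- max(2L, floor((sp$lon_hi - sp$lon_lo) / surface_cell_deg))
      n_rows <- max(2L, floor((sp$lat_hi - sp$lat_lo) / surface_cell_deg))
      grid <- predict_grid(surf, sp$lon_lo, sp$lat_hi, surface_cell_deg,
                           n_rows, n_cols)
      gr <- function(values) {
        structure(list(origin_lon = grid$origin_lon, origin_lat = grid$origin_lat,
                       cell_size = grid$cell_size, n_rows = grid$n_rows,
                       n_cols = grid$n_cols, values = values),
                  class = "density_raster")
      }
      write_raster_asc(gr(normalize_surface(grid)$mean),
                       file.path(out_dir, "surface_mean.asc"))
      write_raster_asc(gr(grid$sd), file.path(out_dir, "surface_sd.asc"))
    }

    stage <- "validate"
    caseloads <- read_caseloads(file.path(out_dir, "caseloads.csv"))
    truth <- utils::read.csv(file.path(out_dir, "truth.csv"))
    report <- validation_report(agg, caseloads, x = im$matrix, truth = truth)
    write_table(
      data.frame(metric = c("pearson_caseload", "spearman_caseload",
                            "spearman_truth",
                            paste0("loo_", names(report$loo))),
                 value = c(report$pearson$correlation,
                           report$spearman$correlation,
                           report$truth$spearman, unname(report$loo))),
      file.path(out_dir, "validation.csv"))

    stage <- "manifest"
    cfg_json <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest <- data.frame(
      key = c("config_hash", "seed"),
      value = c(unname(tools::md5sum(cfg_json)), as.character(config$seed))
    )
    write_table(manifest, file.path(out_dir, "manifest.csv"))

    list(sim = sim, model = model, scores = scores, aggregates = agg,
         aggregates_admin0 = agg0, surface = surf, report = report)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
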