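#!/usr/bin/env Rscript
# Stage 4: smooth pixel-level index surface.
#
# Fits the penalized tensor-product B-spline posterior to cluster-level
# mean scores (weights = households per cluster), selects the smoothing
# parameter by GCV, and writes normalized mean and sd grids as ESRI ASCII
# rasters at the study's pixel size.

library(pdindex)

study <- "results/study"
scores <- read_scores(file.path(study, "scores.csv"))
households <- read_households(file.path(study, "households.csv"))
clusters <- read_clusters(file.path(study, "clusters.csv"))

merged <- merge(households[, c("household_id", "cluster_id")], scores,
                by = "household_id")
by_cl <- aggregate(merged$score, by = list(cluster_id = merged$cluster_id),
                   FUN = mean)
names(by_cl)[2] <- "mean_score"
by_cl$n_households <- as.vector(table(merged$cluster_id)[by_cl$cluster_id])
by_cl <- merge(by_cl, clusters[, c("cluster_id", "lon", "lat")],
               by = "cluster_id")

surf <- fit_surface(by_cl, lambda = "auto")
cat(sprintf("fitted surface on %d clusters: lambda = %.3g, edf = %.1f, sigma = %.3f\n",
            surf$n_clusters, surf$lambda, surf$edf, sqrt(surf$noise_variance)))

cell <- 0.1  # ~11 km pixels at the equator
sp <- surf$spec
n_cols <- floor((sp$lon_hi - sp$lon_lo) / cell)
n_rows <- floor((sp$lat_hi - sp$lat_lo) / cell)
grid <- predict_grid(surf, sp$lon_lo, sp$lat_hi, cell, n_rows, n_cols)
norm <- normalize_surface(grid)

as_raster <- function(values) {
  structure(list(origin_lon = grid$origin_lon, origin_lat = grid$origin_lat,
                 cell_size = grid$cell_size, n_rows = grid$n_rows,
                 n_cols = grid$n_cols, values = values),
            class = "density_raster")
}
write_raster_asc(as_raster(norm$mean), file.path(study, "surface_mean.asc"))
write_raster_asc(as_raster(grid$sd), file.path(study, "surface_sd.asc"))
cat(sprintf("wrote %d x %d normalized mean and sd grids (cell %.2f deg)\n",
            n_rows, n_cols, cell))
cat(sprintf("prediction sd: %.3f to %.3f\n", min(grid$sd), max(grid$sd)))
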