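#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study population.
#
# A DHS-like survey over 30 admin-1 regions (20 clusters x 25 households),
# with a spatially correlated latent deprivation factor driving all five
# infrastructure indicators, a population density raster, displaced public
# cluster coordinates, and regional epidemic caseloads. Writes the study
# inputs under results/study/.

library(pdindex)

out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- synthetic_config(seed = 20260926L)
sim <- simulate_pdi_data(config)

write_table(sim$households, file.path(out, "households.csv"))
write_table(sim$clusters, file.path(out, "clusters.csv"))
write_regions(sim$regions, file.path(out, "regions.geojson"))
write_raster_asc(sim$raster, file.path(out, "density.asc"))
write_table(sim$caseloads, file.path(out, "caseloads.csv"))
write_table(sim$truth, file.path(out, "truth.csv"))
jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

ppr <- sim$households$n_members / pmax(sim$households$n_sleeping_rooms, 1)
cat(sprintf("simulated %d households in %d clusters, %d regions\n",
            nrow(sim$households), nrow(sim$clusters), config$n_regions))
cat(sprintf("  sharing a toilet: %.1f%% (mean %.2f other households among sharers)\n",
            100 * mean(sim$households$toilet_sharing_count >= 1),
            mean(sim$households$toilet_sharing_count[
              sim$households$toilet_sharing_count >= 1])))
cat(sprintf("  public water source: %.1f%%   persons per room: %.2f\n",
            100 * mean(sim$households$water_public), mean(ppr)))
cat(sprintf("  no mobile: %.1f%%   no vehicle: %.1f%%\n",
            100 * mean(1 - sim$households$has_mobile),
            100 * mean(1 - sim$households$has_vehicle)))
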