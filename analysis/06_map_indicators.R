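#!/usr/bin/env Rscript
# Stage 6: inverse-distance-weighted indicator maps.
#
# Annual per-station means of both indicators interpolated (power 2, all
# stations) onto a regular grid over the basin, as CSV and ESRI ASCII.

suppressPackageStartupMessages(library(lakexergy))
out <- "results/analysis"

ind <- read.csv(file.path(out, "indicators.csv"), stringsAsFactors = FALSE)
coords <- read.csv(file.path(out, "stations.csv"), stringsAsFactors = FALSE)

annual <- aggregate(ind[c("Ex_kJ_per_L", "Ex_sp_kJ_per_g")],
                    by = list(site_id = ind$site_id), FUN = mean)
st <- merge(coords, annual, by = "site_id")
gs <- grid_spec(min(st$x) - 2, max(st$x) + 2, min(st$y) - 2, max(st$y) + 2, 2)

for (target in c("Ex_kJ_per_L", "Ex_sp_kJ_per_g")) {
  g <- idw(data.frame(x = st$x, y = st$y, value = st[[target]]), gs)
  write.csv(g, file.path(out, paste0("idw_", target, ".csv")),
            row.names = FALSE)
  write_esri_ascii(g, gs, file.path(out, paste0("idw_", target, ".asc")))
  cat(sprintf("%s: %d cells, interpolated range %.2f-%.2f (stations %.2f-%.2f)\n",
              target, nrow(g), min(g$value), max(g$value),
              min(st[[target]]), max(st[[target]])))
}
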