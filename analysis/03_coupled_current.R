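#!/usr/bin/env Rscript
# The Current-scenario coupled run: 22 water years of flow routing, annual
# MII summaries, vegetation transitions and roughness feedback. Writes the
# per-class extent series, the MII series, the transition log and the
# degraded-fraction series.

library(wetsim)

out_dir <- "results/coupled"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

dom <- make_dem(domain_spec(n_rows = 20, n_cols = 17, seed = 11))
veg <- make_initial_vegetation(dom)
hg <- make_hydrograph(hydrograph_spec())
years <- water_year_labels(1991, 22)

t0 <- Sys.time()
run <- run_coupled(dom, hg, veg)
cat(sprintf("Coupled 22-year run finished in %.0f s\n",
            as.numeric(Sys.time() - t0, units = "secs")))

ext <- data.frame(water_year = years, t(run$extent))
write.csv(ext, file.path(out_dir, "class_extent.csv"), row.names = FALSE)
mii <- data.frame(patch_id = rep(veg$patches$patch_id, 22),
                  water_year = rep(years, each = nrow(veg$patches)),
                  mii_percent = as.vector(run$mii))
write.csv(mii, file.path(out_dir, "mii_series.csv"), row.names = FALSE)
log <- run$log; log$year <- years[log$year]
write.csv(log, file.path(out_dir, "transitions.csv"), row.names = FALSE)
write.csv(data.frame(water_year = years, degraded_pct = run$degraded_pct),
          file.path(out_dir, "degraded_fraction.csv"), row.names = FALSE)

nonwoody <- colSums(run$extent[c("CommonReed", "MixedMarsh"), ])
cat("Non-woody wetland extent (cells) by water year:\n")
print(stats::setNames(nonwoody, years))
cat("RRG condition (good/intermediate/poor) at the drought peak (WY2007):\n")
print(run$extent[4:6, match(2007, years)])
cat(sprintf("Peak degraded fraction: %.1f%% (WY%d); final: %.1f%%\n",
            max(run$degraded_pct), years[which.max(run$degraded_pct)],
            run$degraded_pct[22]))
cat(sprintf("Transitions logged: %d\n", nrow(log)))
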