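#!/usr/bin/env Rscript
# Density-map occupancy along a curvature-coupled frame series.
#
# Generates a ten-frame synthetic variability series in which filament
# curvature, strand twist asymmetry and convex-strand decoration increase
# together; splits each frame's map between filament and per-site bound
# complexes; integrates and normalises site intensities; and correlates
# the most curved frame's local strand twist with occupancy.

library(actinlattice)
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(seed = 8)
out <- frame_series_occupancy(cfg)

write.csv(out$trajectory, "results/occupancy_trajectory.csv",
          row.names = FALSE)
tr0 <- out$trajectory[out$trajectory$strand == 0, ]
tr1 <- out$trajectory[out$trajectory$strand == 1, ]
cat("decorated-strand mean normalised intensity per frame:\n")
cat(sprintf("  %.3f", tr0$mean_normalized_intensity), "\n")
cat(sprintf("bare strand stays at %.3f-%.3f (baseline %.2f)\n",
            min(tr1$mean_normalized_intensity),
            max(tr1$mean_normalized_intensity),
            cfg$frames$baseline_occupancy))

err <- abs(out$site_table$normalized_intensity -
             out$site_table$truth_occupancy)
cat(sprintf("occupancy proxy vs truth: max |error| %.4f over %d sites\n",
            max(err), nrow(out$site_table)))
write.csv(out$site_table, "results/site_occupancies.csv",
          row.names = FALSE)

write.csv(out$correlation$table, "results/twist_vs_intensity.csv",
          row.names = FALSE)
cat(sprintf(
  "final frame twist vs intensity: Spearman %.3f, Pearson %.3f\n",
  out$correlation$spearman, out$correlation$pearson))
cat("(under-twisted strand carries the occupancy: negative association)\n")

# one representative frame volume for inspection in a map viewer
fr <- generate_frame_series(cfg)[[10]]
write_mrc(fr$grid, "results/frame10_density.mrc")
cat("wrote results/occupancy_trajectory.csv, site_occupancies.csv,",
    "twist_vs_intensity.csv, frame10_density.mrc\n")
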