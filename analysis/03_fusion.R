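#!/usr/bin/env Rscript
# Fusion dynamics: the automated GFP-only pixel-loss half-time and the
# object-level event detection, per simulated cell, compared against each
# run's ground truth.

suppressMessages(library(mitodyn))
dir.create("results", showWarnings = FALSE)

tiffs <- Sys.glob("results/simulated/*_cell*.tif")
if (!length(tiffs)) stop("run analysis/01_simulate.R first")

rows <- lapply(tiffs, function(tf) {
  s <- read_series(tf)
  truth <- read.csv(sub("\\.tif$", "_truth.csv", tf))
  fit <- gfp_only_decay(s)
  ev <- detect_fusion_events(s)
  sm <- summarize_fusion(ev, window_s = 400)
  data.frame(cell = sub("\\.tif$", "", basename(tf)),
             half_time_s = fit$half_time_s, b_per_s = fit$b, r2 = fit$r2,
             detected_events = sm$n_events,
             events_per_min = sm$events_per_min,
             truth_events = sum(truth$event == "fusion"))
})
tab <- do.call(rbind, rows)
print(tab, digits = 3)
write.csv(tab, "results/fusion_cells.csv", row.names = FALSE)
tab$group <- sub("_cell.*$", "", tab$cell)
med <- aggregate(cbind(b_per_s, truth_events) ~ group, tab, median)
cat(sprintf("median fitted decay constant b: %s\n",
            paste(sprintf("%s %.2g/s", med$group, med$b_per_s),
                  collapse = ", ")))
cat(sprintf("median ground-truth fusion count: %s\n",
            paste(sprintf("%s %.0f", med$group, med$truth_events),
                  collapse = ", ")))
cat("Note the per-cell spread: at this cohort size (4 cells/group) single\n")
cat("flat-fit cells dominate the half-time scale; the cohort comparison\n")
cat("belongs to 06_group_report.R, and power comes from cell numbers.\n")
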