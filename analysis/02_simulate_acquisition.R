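#!/usr/bin/env Rscript
# Simulate one complete awake resting acquisition and write it in the
# pipeline's on-disk formats: the gated-cycle CSV container (+ gate JSON
# sidecar), the planted ground truth, the detected-event table, and a
# line-scan TIFF (+ sidecar). Later scripts analyze in memory; this one
# demonstrates the file interfaces.

library(plmox)
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

truth <- preset("awake_dry_37C")
sim <- generate_capillary_trace(truth, duration_s = 2, seed = 11)
write_trace_csv(sim$trace, "results/sim/awake_dry_trace.csv",
                meta = list(condition = "awake_dry_37C", seed = 11))
write_ground_truth_json(truth, "results/sim/awake_dry_truth.json")

ev <- detect_rbc_passages(sim$trace$on_phase_intensity,
                          sim$trace$cycle_start_ms)
write_events_csv(ev, "results/sim/awake_dry_events.csv")

ls <- generate_linescan(truth, duration_s = 12, seed = 12)
write_linescan_tiff(ls$image, "results/sim/awake_dry_linescan.tif")

cat(sprintf("wrote %d cycles (%d planted, %d detected RBC passages) and a %d x %d line scan\n",
            sim$trace$n_cycles, nrow(sim$events), nrow(ev),
            nrow(ls$image$pixels), ncol(ls$image$pixels)))

# roundtrip sanity: reload from disk and re-measure
trace <- read_trace_csv("results/sim/awake_dry_trace.csv")
calset <- read_calibration_json("results/calibration.json")
po2 <- po2_mean_from_trace(trace, calset, truth$temperature_c, conf = FALSE)
vel <- estimate_velocity(read_linescan_tiff("results/sim/awake_dry_linescan.tif"))
cat(sprintf("reloaded from disk: Po2 Mean %.1f mmHg, velocity %.3f mm/s\n",
            po2$po2_mmHg, vel$velocity_mm_s))
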