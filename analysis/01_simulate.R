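#!/usr/bin/env Rscript
# Stage 1 — simulate everything the pipeline consumes.
#
# Generates (a) the Simon Go/Nogo task design and behavioral responses,
# (b) the three-channel ground-truth-coupled oscillatory benchmark, placed
# at three voxels of a synthetic labeled grid and mixed to sensors, and
# (c) amplitude artifacts planted in known trials. Everything downstream is
# therefore testable against known ground truth.

suppressMessages(library(ncreann))
seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE)

## task and behavior ----------------------------------------------------
design <- generate_task_design(n_trials = 720, go_fraction = 0.7,
                               congruent_fraction = 0.5, n_blocks = 6,
                               iti_range_ms = c(1300, 1700), seed = seed)
behavior <- simulate_behavior(design, seed = seed + 1)
write_task_design(design, file.path(out, "task_design.csv"))
utils::write.csv(as.data.frame(behavior), file.path(out, "behavior.csv"),
                 row.names = FALSE)
message(sprintf("task: %d trials (%d Go / %d Nogo), %d blocks",
                nrow(design), sum(design$trial_type == "Go"),
                sum(design$trial_type == "Nogo"), max(design$block)))

## coupled sources on a labeled grid ------------------------------------
n_trials <- 40; spt <- 1024                       # 40 x 4 s epochs at 256 Hz
sys <- benchmark_b1()
sim <- simulate_nmvar(sys, n_trials * spt, seed = seed)
grid <- make_synthetic_grid(dims = c(10, 10, 10), edge_mm = 10,
                            n_sensors = 32, n_regions = 6, seed = seed)
regions <- unique(grid$labels)
pick <- regions[round(seq(1, length(regions), length.out = 3))]
true_vox <- vapply(pick, function(r) {
  cand <- which(grid$labels == r)
  ctr <- colMeans(grid$positions[cand, , drop = FALSE])
  cand[which.min(rowSums(sweep(grid$positions[cand, , drop = FALSE], 2, ctr)^2))]
}, integer(1))
message("true source voxels: ", paste(true_vox, collapse = ", "),
        " in ", paste(pick, collapse = ", "))

src <- scale(sim$series) * 20                     # standardized, ~20 uV
sensors <- mix_to_sensors(src, grid$leadfield[, true_vox],
                          sensor_noise_sd = 2, seed = seed + 2, fs_hz = 256)
epochs <- segment_into_trials(sensors, n_trials, spt, t0_ms = -2000)

## planted artifacts -----------------------------------------------------
set.seed(seed + 3)
bad <- sort(sample.int(n_trials, 3))
# the flatline spans the whole epoch (a dead channel), so it survives the
# high-pass stage that precedes rejection
art <- data.frame(trial = bad, kind = c("spike", "flatline", "spike"),
                  amplitude_uv = 300, duration_ms = c(400, 4000, 400))
inj <- inject_artifacts(epochs, art, seed = seed + 3)
message("planted artifact trials: ", paste(inj$bad_trials, collapse = ", "))

write_epochs_h5(inj$epochs, file.path(out, "sensor_epochs.h5"))
saveRDS(list(grid = grid, true_vox = true_vox, seed = seed,
             planted_bad = inj$bad_trials,
             true_linear = sim$linear_edges, true_nonlinear = sim$nonlinear_edges),
        file.path(out, "ground_truth.rds"))
message("stage 1 done -> ", out)
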