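#!/usr/bin/env Rscript
# Stage 3 — source localization: LCMV beamforming of the clean alpha-band
# epochs, neural-activity-index thresholding (top 2% within labeled
# regions), DBSCAN clustering of the retained voxels, and cluster-mean
# time courses as node signals for the connectivity stage.

suppressMessages(library(ncreann))
out <- "results"
gt <- readRDS(file.path(out, "ground_truth.rds"))
epochs <- read_epochs_h5(file.path(out, "clean_alpha_epochs.h5"))
grid <- gt$grid
# the sensors were re-referenced; express the forward model likewise
leadfield <- sweep(grid$leadfield, 2, colMeans(grid$leadfield))

d <- dim(epochs$data)
flat <- matrix(aperm(epochs$data, c(2, 3, 1)), nrow = d[2])
C <- stats::cov(t(flat))
filt <- lcmv_filters(leadfield, C)
nai <- neural_activity_index(filt, C)
sel <- select_top_voxels(nai, grid$labels, top_fraction = 0.02)
message(length(sel), " voxels retained (top 2% of ",
        sum(nzchar(grid$labels)), " labeled)")
message("true voxels among retained: ",
        sum(gt$true_vox %in% sel), " of ", length(gt$true_vox))

cl <- dbscan_cluster(grid$positions[sel, , drop = FALSE],
                     eps = 1.5 * grid$voxel_edge_mm, min_pts = 2,
                     labels = grid$labels[sel], voxel_ids = sel)
print(cl)
cl_df <- do.call(rbind, lapply(seq_along(cl$clusters), function(k)
  data.frame(cluster = k, label = cl$clusters[[k]]$label,
             n_voxels = cl$clusters[[k]]$size,
             x = cl$clusters[[k]]$centroid[1],
             y = cl$clusters[[k]]$centroid[2],
             z = cl$clusters[[k]]$centroid[3])))
utils::write.csv(cl_df, file.path(out, "clusters.csv"), row.names = FALSE)

filt_sel <- filt; filt_sel$W <- filt$W[sel, , drop = FALSE]
src <- beamform_timecourses(filt_sel, epochs)     # trials x Vsel x samples
remap <- match(seq_len(nrow(grid$positions)), sel)
node_arr <- array(0, dim = c(d[1], length(cl$clusters), d[3]))
for (k in seq_along(cl$clusters)) {
  ids <- remap[cl$clusters[[k]]$voxel_ids]
  node_arr[, k, ] <- apply(src[, ids, , drop = FALSE], c(1, 3), mean)
}
nodes <- eeg_epochs(node_arr, epochs$fs_hz, epochs$t0_ms,
                    channel_names = paste0("cluster", seq_along(cl$clusters)),
                    trial_indices = epochs$trial_indices)
write_epochs_h5(nodes, file.path(out, "node_timecourses.h5"))
saveRDS(cl, file.path(out, "clusters.rds"))
message("stage 3 done: ", length(cl$clusters), " source nodes")
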