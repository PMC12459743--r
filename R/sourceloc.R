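#' Source grid with lead field and region labels
#'
#' A regular voxel grid with one lead-field column per voxel (scalar
#' orientation) and a free-text anatomical label per voxel (empty string =
#' unlabeled).
#'
#' @param positions V x 3 voxel coordinates in mm.
#' @param voxel_edge_mm grid spacing in mm.
#' @param leadfield sensors x V gain matrix.
#' @param labels character vector of per-voxel region labels.
#' @return An object of class `source_grid`.
#' @export
source_grid <- function(positions, voxel_edge_mm, leadfield,
                        labels = rep("", nrow(positions))) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            is.matrix(leadfield), ncol(leadfield) == nrow(positions),
            length(labels) == nrow(positions), voxel_edge_mm > 0)
  offs <- sweep(positions, 2, positions[1, ])
  if (nrow(positions) > 1 &&
      max(abs(offs / voxel_edge_mm - round(offs / voxel_edge_mm))) > 1e-6)
    warning("voxel positions do not lie on a regular grid of the stated edge length")
  structure(list(positions = positions, voxel_edge_mm = voxel_edge_mm,
                 leadfield = leadfield, labels = as.character(labels)),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d voxels (%g mm edge), %d sensors, %d labeled\n",
              nrow(x$positions), x$voxel_edge_mm, nrow(x$leadfield),
              sum(nzchar(x$labels))))
  invisible(x)
}

#' Build a synthetic labeled source grid
#'
#' A regular 3-D grid with a point-dipole lead field standing in for a
#' volume-conduction model: sensors sit on a shell enclosing the grid, each
#' voxel carries a random unit dipole moment, and the gain at a sensor is
#' the dipole field `q . (r_s - r_v) / |r_s - r_v|^3`. Columns are signed
#' and spatially smooth — neighboring voxels project similar topographies,
#' the property that makes density clustering of high-activity voxels
#' meaningful. Labels are assigned to contiguous blocks of voxels, emulating
#' atlas regions.
#'
#' @param dims length-3 integer grid dimensions.
#' @param edge_mm voxel edge length in mm (default 10).
#' @param n_sensors number of sensors.
#' @param n_regions number of labeled regions (labels `region_1`, ...);
#'   voxels are split into contiguous index blocks.
#' @param unlabeled_fraction fraction of voxels left unlabeled (drawn at
#'   random).
#' @param seed integer seed for the sensor placement.
#' @return a `source_grid`.
#' @export
make_synthetic_grid <- function(dims = c(10, 10, 10), edge_mm = 10,
                                n_sensors = 32, n_regions = 6,
                                unlabeled_fraction = 0, seed = 1) {
  set.seed(seed)
  pos <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3]))) * edge_mm
  V <- nrow(pos)
  center <- colMeans(pos)
  radius <- 1.4 * max(sqrt(rowSums(sweep(pos, 2, center)^2)))
  # sensors spread uniformly over a shell enclosing the grid; full coverage
  # keeps the inverse problem well conditioned at depth
  az <- stats::runif(n_sensors, 0, 2 * pi)
  el <- asin(stats::runif(n_sensors, -1, 1))
  sens <- cbind(center[1] + radius * cos(el) * cos(az),
                center[2] + radius * cos(el) * sin(az),
                center[3] + radius * sin(el))
  # radially oriented unit moments: smooth over the grid and signed
  q <- sweep(pos, 2, center + 1e-3 * edge_mm)
  q <- q / pmax(sqrt(rowSums(q^2)), 1e-9)
  lf <- matrix(0, n_sensors, V)
  for (s in seq_len(n_sensors)) {
    dv <- sweep(-pos, 2, sens[s, ], "+")    # r_s - r_v
    d3 <- (rowSums(dv^2) + edge_mm^2)^1.5
    lf[s, ] <- rowSums(q * dv) / d3
  }
  lf <- sweep(lf, 2, sqrt(colSums(lf^2)), "/")   # unit-norm columns
  region <- cut(seq_len(V), breaks = n_regions, labels = FALSE)
  labels <- paste0("region_", region)
  if (unlabeled_fraction > 0) {
    drop <- sort(sample.int(V, round(unlabeled_fraction * V)))
    labels[drop] <- ""
  }
  source_grid(pos, edge_mm, lf, labels)
}

#' LCMV beamformer spatial filters
#'
#' For each voxel v with lead-field column l_v, the linearly constrained
#' minimum-variance filter is
#' `w_v = (l_v' Cr^-1 l_v)^-1 l_v' Cr^-1` with `Cr = C + lambda I`, which
#' passes voxel activity with unit gain (`w_v' l_v = 1`) while minimizing
#' total output variance. Voxels whose constrained system is numerically
#' singular are marked invalid and skipped.
#'
#' @param leadfield sensors x V gain matrix (scalar orientation).
#' @param C sensor covariance (symmetric positive semi-definite).
#' @param lambda Tikhonov regularization; default 5% of the mean sensor
#'   variance `mean(diag(C))`.
#' @return list of class `lcmv_filters`: `W` (V x sensors filter matrix,
#'   invalid rows zero), `valid` (logical), `lambda`.
#' @export
lcmv_filters <- function(leadfield, C, lambda = NULL) {
  stopifnot(is.matrix(leadfield), is.matrix(C),
            nrow(C) == ncol(C), nrow(C) == nrow(leadfield))
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("covariance must be symmetric")
  if (is.null(lambda)) lambda <- 0.05 * mean(diag(C))
  stopifnot(lambda >= 0)
  Cr <- C + lambda * diag(nrow(C))
  Cinv <- tryCatch(solve(Cr), error = function(e)
    stop("regularized covariance is singular; increase lambda"))
  V <- ncol(leadfield)
  W <- matrix(0, V, nrow(C))
  valid <- logical(V)
  CiL <- Cinv %*% leadfield
  denom <- colSums(leadfield * CiL)
  for (v in seq_len(V)) {
    if (is.finite(denom[v]) && abs(denom[v]) > 1e-12) {
      W[v, ] <- CiL[, v] / denom[v]
      valid[v] <- TRUE
    }
  }
  structure(list(W = W, valid = valid, lambda = lambda),
            class = "lcmv_filters")
}

#' Condition-specific filters sharing a common solution
#'
#' Recomputes LCMV filters per condition from that condition's sensor
#' covariance while keeping the common filter's regularization (and voxel
#' validity), as when a standard filter computed on pooled conditions seeds
#' per-condition filters.
#'
#' @param leadfield sensors x V gain matrix.
#' @param common an `lcmv_filters` from the pooled data.
#' @param condition_covs named list of per-condition sensor covariances.
#' @return named list of `lcmv_filters`.
#' @export
condition_filters <- function(leadfield, common, condition_covs) {
  stopifnot(inherits(common, "lcmv_filters"), length(condition_covs) >= 1)
  lapply(condition_covs, function(C) {
    if (is.null(C) || !nrow(C)) stop("empty condition covariance")
    f <- lcmv_filters(leadfield, C, lambda = common$lambda)
    f$valid <- f$valid & common$valid
    f$W[!f$valid, ] <- 0
    f
  })
}

#' Neural activity index
#'
#' Source power normalized by projected noise power,
#' `NAI_v = (w_v' C w_v) / (sigma2 * w_v' w_v)`, which corrects the
#' beamformer's depth-dependent noise amplification. Invalid voxels get 0.
#'
#' @param filters an `lcmv_filters`.
#' @param C sensor covariance of the data being scored.
#' @param sigma2 noise power; default the smallest eigenvalue of `C`
#'   (white-noise-floor estimate).
#' @return numeric vector of per-voxel NAI values.
#' @export
neural_activity_index <- function(filters, C, sigma2 = NULL) {
  stopifnot(inherits(filters, "lcmv_filters"))
  if (is.null(sigma2)) {
    sigma2 <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    sigma2 <- max(sigma2, 1e-12 * mean(diag(C)))
  }
  stopifnot(sigma2 > 0)
  W <- filters$W
  num <- rowSums((W %*% C) * W)
  den <- sigma2 * rowSums(W * W)
  nai <- ifelse(filters$valid & den > 0, num / den, 0)
  nai
}

#' Select the top fraction of voxels by NAI within labeled regions
#'
#' Retains the `ceiling(top_fraction * V_labeled)` labeled voxels with the
#' highest NAI. Ties are broken by ascending voxel index.
#'
#' @param nai per-voxel NAI values.
#' @param labels per-voxel region labels ("" or NA = unlabeled, excluded).
#' @param top_fraction fraction retained (default 0.02).
#' @return integer vector of selected voxel indices (ascending).
#' @export
select_top_voxels <- function(nai, labels, top_fraction = 0.02) {
  stopifnot(length(nai) == length(labels),
            top_fraction > 0, top_fraction < 1)
  labeled <- which(!is.na(labels) & nzchar(labels))
  if (!length(labeled)) stop("no labeled voxels to threshold within")
  k <- ceiling(top_fraction * length(labeled))
  ord <- labeled[order(-nai[labeled], labeled)]
  sort(ord[seq_len(k)])
}

#' DBSCAN clustering of selected voxels
#'
#' Standard DBSCAN on voxel centroids with the Euclidean metric: a voxel is
#' a core point if at least `min_pts` selected voxels (itself included) lie
#' within `eps`; clusters are the connected components of core points plus
#' their border points; everything else is noise.
#'
#' @param positions n x 3 coordinates of the selected voxels (mm).
#' @param eps neighborhood radius; conventionally 1.5 x the voxel edge.
#' @param min_pts minimum neighborhood size for a core point (default 2).
#' @param labels optional per-voxel region labels for majority labeling.
#' @param voxel_ids optional original voxel indices carried through.
#' @return list of class `voxel_clusters`: `clusters` (list of lists with
#'   `members`, `voxel_ids`, `centroid`, `label`, `size`), `noise` (indices
#'   into the input), `assignment` (0 = noise).
#' @export
dbscan_cluster <- function(positions, eps, min_pts = 2,
                           labels = NULL, voxel_ids = NULL) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  if (is.null(voxel_ids)) voxel_ids <- seq_len(n)
  if (n == 0)
    return(structure(list(clusters = list(), noise = integer(0),
                          assignment = integer(0)), class = "voxel_clusters"))
  D <- as.matrix(stats::dist(positions))
  neigh <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neigh, length, integer(1)) >= min_pts
  assignment <- integer(n)   # 0 = unassigned/noise
  cl_id <- 0
  for (i in seq_len(n)) {
    if (!core[i] || assignment[i] != 0) next
    cl_id <- cl_id + 1
    queue <- i
    assignment[i] <- cl_id
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (nb in neigh[[q]]) {
        if (assignment[nb] == 0) {
          assignment[nb] <- cl_id
          if (core[nb]) queue <- c(queue, nb)
        }
      }
    }
  }
  clusters <- lapply(seq_len(cl_id), function(k) {
    members <- which(assignment == k)
    lab <- if (!is.null(labels)) {
      tb <- sort(table(labels[members]), decreasing = TRUE)
      names(tb)[1]
    } else NA_character_
    list(members = members, voxel_ids = voxel_ids[members],
         centroid = colMeans(positions[members, , drop = FALSE]),
         label = lab, size = length(members))
  })
  structure(list(clusters = clusters, noise = which(assignment == 0),
                 assignment = assignment),
            class = "voxel_clusters")
}

#' @export
print.voxel_clusters <- function(x, ...) {
  cat(sprintf("<voxel_clusters> %d clusters, %d noise voxels\n",
              length(x$clusters), length(x$noise)))
  for (k in seq_along(x$clusters)) {
    cl <- x$clusters[[k]]
    cat(sprintf("  #%d: %d voxels, label %s, centroid (%.1f, %.1f, %.1f)\n",
                k, cl$size, cl$label, cl$centroid[1], cl$centroid[2], cl$centroid[3]))
  }
  invisible(x)
}

#' Representative cluster time course
#'
#' The arithmetic mean of the member voxels' source time courses, per trial
#' and sample.
#'
#' @param cluster one element of `voxel_clusters$clusters`.
#' @param voxel_series per-voxel source series: a V x L matrix (continuous)
#'   or trials x V x samples array, indexed by original voxel id.
#' @return vector (continuous input) or trials x samples matrix.
#' @export
cluster_timecourse <- function(cluster, voxel_series) {
  ids <- cluster$voxel_ids
  if (is.matrix(voxel_series)) {
    colMeans(voxel_series[ids, , drop = FALSE])
  } else if (is.array(voxel_series) && length(dim(voxel_series)) == 3) {
    apply(voxel_series[, ids, , drop = FALSE], c(1, 3), mean)
  } else stop("voxel_series must be a V x L matrix or trials x V x samples array")
}

#' Beamform sensor data to per-voxel source series
#'
#' @param filters an `lcmv_filters`.
#' @param x `eeg_continuous`, `eeg_epochs`, or channels x samples matrix.
#' @return V x samples matrix (continuous) or trials x V x samples array.
#' @export
beamform_timecourses <- function(filters, x) {
  W <- filters$W
  if (inherits(x, "eeg_continuous")) return(W %*% x$data)
  if (is.matrix(x)) return(W %*% x)
  if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    out <- array(0, dim = c(d[1], nrow(W), d[3]))
    for (tr in seq_len(d[1]))
      out[tr, , ] <- W %*% matrix(x$data[tr, , ], nrow = d[2])
    return(out)
  }
  stop("unsupported input")
}
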