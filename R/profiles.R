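#' Accumulated xy density map
#'
#' Histogram of selected molecules' oxygen positions projected onto the xy
#' plane, accumulated over frames.
#'
#' @param trajectory an `md_trajectory`.
#' @param molids optional molecule ids (default all waters).
#' @param bin_width bin width in nm (default 0.02).
#' @return list of class `density_map`: `x_edges`, `y_edges`, `counts`
#'   (matrix), `frames`.
#' @export
density_map_xy <- function(trajectory, molids = NULL, bin_width = 0.02) {
  box <- trajectory$frames[[1]]$box
  x_edges <- seq(0, bin_width * ceiling(box[1] / bin_width - 1e-9), by = bin_width)
  y_edges <- seq(0, bin_width * ceiling(box[2] / bin_width - 1e-9), by = bin_width)
  counts <- matrix(0, length(x_edges) - 1L, length(y_edges) - 1L)
  wm0 <- water_molecules(trajectory$frames[[1]], warn = FALSE)
  if (!is.null(molids)) wm0 <- wm0[wm0$molid %in% molids, , drop = FALSE]
  if (!nrow(wm0)) {
    warning("empty selection; density map has zero counts")
  } else {
    for (f in trajectory$frames) {
      p <- wrap_positions(f$positions[wm0$O, , drop = FALSE], f$box)
      ix <- pmin(findInterval(p[, 1], x_edges, rightmost.closed = TRUE), nrow(counts))
      iy <- pmin(findInterval(p[, 2], y_edges, rightmost.closed = TRUE), ncol(counts))
      for (r in seq_along(ix)) counts[ix[r], iy[r]] <- counts[ix[r], iy[r]] + 1
    }
  }
  structure(list(x_edges = x_edges, y_edges = y_edges, counts = counts,
                 frames = length(trajectory$frames)),
            class = "density_map")
}

#' Peak positions and mean spacing of a 1D profile
#'
#' Histograms 1D positions, smooths with a Gaussian kernel of one-bin width,
#' and reports local maxima above a prominence threshold (fraction of the
#' maximum bin) together with the mean consecutive peak spacing. Used for
#' channel-water site spacing along the groove axis.
#'
#' @param positions numeric vector of 1D coordinates (nm).
#' @param bin_width histogram bin width in nm (default 0.02).
#' @param min_prominence peak threshold as a fraction of the maximum
#'   smoothed bin value (default 0.05).
#' @param smooth_sigma_bins Gaussian smoothing width in bins (default 1).
#' @return list with `peaks` (positions in nm), `spacings` and
#'   `mean_spacing`.
#' @export
profile_peak_spacing <- function(positions, bin_width = 0.02,
                                 min_prominence = 0.05, smooth_sigma_bins = 1) {
  positions <- positions[is.finite(positions)]
  if (length(positions) < 2) stop("insufficient peaks: need at least 2 positions")
  lo <- min(positions) - 3 * bin_width
  hi <- max(positions) + 3 * bin_width
  edges <- seq(lo, hi + bin_width, by = bin_width)
  h <- graphics::hist(positions, breaks = edges, plot = FALSE)
  y <- h$counts
  if (smooth_sigma_bins > 0) {
    half <- ceiling(4 * smooth_sigma_bins)
    kern <- stats::dnorm(seq(-half, half), sd = smooth_sigma_bins)
    kern <- kern / sum(kern)
    ypad <- c(rep(0, half), y, rep(0, half))
    y <- stats::filter(ypad, kern, sides = 2)[(half + 1):(half + length(h$counts))]
  }
  thr <- min_prominence * max(y)
  n <- length(y)
  is_peak <- rep(FALSE, n)
  for (i in seq_len(n)) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    is_peak[i] <- y[i] >= thr & y[i] > l & y[i] >= r
  }
  # refine each peak to the mean of the raw positions in its bin window
  # (one bin either side) so positions are not quantized to the bin grid
  peaks <- vapply(which(is_peak), function(i) {
    lo2 <- edges[max(1, i - 1)]
    hi2 <- edges[min(length(edges), i + 2)]
    inw <- positions >= lo2 & positions <= hi2
    if (any(inw)) mean(positions[inw]) else h$mids[i]
  }, numeric(1))
  if (length(peaks) < 2) {
    stop("insufficient peaks: found ", length(peaks), ", need at least 2")
  }
  spac <- diff(peaks)
  list(peaks = peaks, spacings = spac, mean_spacing = mean(spac))
}

#' Molecular dipole directions
#'
#' Unit dipole of each selected water: the bisector direction from the
#' oxygen through the midpoint of the two hydrogens, independent of any
#' virtual sites of the water model.
#'
#' @param frame an `md_frame`.
#' @param molids optional molecule id filter.
#' @return matrix n x 3 of unit vectors, rownames = molecule ids.
#' @export
dipole_vectors <- function(frame, molids = NULL) {
  wm <- water_molecules(frame, warn = FALSE)
  if (!is.null(molids)) wm <- wm[wm$molid %in% molids, , drop = FALSE]
  if (!nrow(wm)) stop("no water molecules selected")
  o <- frame$positions[wm$O, , drop = FALSE]
  hm <- (frame$positions[wm$H1, , drop = FALSE] +
         frame$positions[wm$H2, , drop = FALSE]) / 2
  d <- hm - o
  d <- d / sqrt(rowSums(d^2))
  rownames(d) <- wm$molid
  d
}

#' Dipole-angle distribution
#'
#' Distribution of the angle theta between each selected water's dipole and
#' a reference axis, accumulated over frames. theta lies in [0, 180] degrees
#' and the histogram is normalized so that `sum(P * dtheta) = 1`.
#'
#' @param trajectory an `md_trajectory`.
#' @param axis reference axis: "x", "y", "z" or a length-3 vector.
#' @param molids optional molecule id filter.
#' @param bin_width angular bin width in degrees (default 2).
#' @return list of class `dipole_distribution`: `theta_edges`, `theta_mids`,
#'   `p` (probability density per degree), `mean_theta`, `n`.
#' @export
dipole_distribution <- function(trajectory, axis = "x", molids = NULL,
                                bin_width = 2) {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  axis <- axis / sqrt(sum(axis^2))
  thetas <- unlist(lapply(trajectory$frames, function(f) {
    d <- dipole_vectors(f, molids)
    acos(pmin(1, pmax(-1, d %*% axis))) * 180 / pi
  }))
  edges <- seq(0, 180, by = bin_width)
  h <- graphics::hist(thetas, breaks = edges, plot = FALSE)
  p <- h$counts / sum(h$counts) / bin_width
  structure(list(theta_edges = edges, theta_mids = h$mids, p = p,
                 mean_theta = mean(thetas), n = length(thetas)),
            class = "dipole_distribution")
}

#' Partition molecules into layers above a surface
#'
#' Slab k (k = 0, 1, ...) spans `[surface_z + k d, surface_z + (k+1) d)`
#' along z; molecules are assigned by oxygen z coordinate. Molecules below
#' the surface or beyond the last slab are unassigned (`NA`).
#'
#' @param frame an `md_frame`.
#' @param surface_z z coordinate of the surface plane (nm); must lie inside
#'   the box.
#' @param slab_thickness layer thickness in nm (default 0.35, one molecular
#'   layer).
#' @param n_layers number of layers (default 3).
#' @return list of class `layer_partition`: `boundaries` (z values),
#'   `layer` (0-based layer index per molecule, `NA` if unassigned),
#'   `molid`.
#' @export
partition_layers <- function(frame, surface_z, slab_thickness = 0.35,
                             n_layers = 3) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (surface_z < 0 || surface_z > frame$box[3]) stop("surface_z outside the box")
  top <- surface_z + n_layers * slab_thickness
  if (top > frame$box[3]) {
    warning("layer stack extends beyond the box; molecules beyond are unassigned")
  }
  wm <- water_molecules(frame, warn = FALSE)
  z <- frame$positions[wm$O, 3]
  k <- floor((z - surface_z) / slab_thickness)
  k[k < 0 | k >= n_layers] <- NA
  structure(list(boundaries = surface_z + (0:n_layers) * slab_thickness,
                 layer = as.integer(k), molid = wm$molid),
            class = "layer_partition")
}

#' Per-layer mean q6 versus time
#'
#' Mean Steinhardt q6 over the molecules of each layer, per frame. The
#' partition is re-evaluated every frame (molecules migrate between
#' layers). Empty layers give `NA`.
#'
#' @param trajectory an `md_trajectory`.
#' @param surface_z,slab_thickness,n_layers as in [partition_layers()].
#' @param neighbor_cutoff,periodic passed to [local_q6()].
#' @return data frame with columns `time`, `layer` (0-based), `mean_q6`,
#'   `n_molecules`.
#' @export
layer_q6_timeseries <- function(trajectory, surface_z, slab_thickness = 0.35,
                                n_layers = 3, neighbor_cutoff = 0.35,
                                periodic = c(TRUE, TRUE, TRUE)) {
  rows <- lapply(seq_along(trajectory$frames), function(i) {
    f <- trajectory$frames[[i]]
    lp <- partition_layers(f, surface_z, slab_thickness, n_layers)
    lq <- local_q6(f, neighbor_cutoff, periodic)
    stopifnot(identical(lp$molid, lq$molid))
    do.call(rbind, lapply(0:(n_layers - 1L), function(k) {
      sel <- which(lp$layer == k)
      data.frame(time = trajectory$times[i], layer = k,
                 mean_q6 = if (length(sel)) mean(lq$q6[sel], na.rm = TRUE) else NA_real_,
                 n_molecules = length(sel))
    }))
  })
  do.call(rbind, rows)
}

#' Signed projected-distance distribution between two selections
#'
#' Per frame and per molecule of selection A, the signed projection onto an
#' axis of the displacement from its nearest selection-B atom. Measures
#' e.g. the lateral offset of channel water from the hydroxyl row it binds
#' to.
#'
#' @param trajectory an `md_trajectory`.
#' @param sel_a,sel_b functions `frame -> atom index vector` (e.g. wrappers
#'   over [select_atoms()]), or fixed index vectors.
#' @param axis "x", "y", "z" or a length-3 unit vector.
#' @param bin_width histogram bin width in nm.
#' @return list with `values` (all signed distances, nm), `mids`, `p`
#'   (normalized density), `mean`, `sd`.
#' @export
projected_distance_distribution <- function(trajectory, sel_a, sel_b,
                                            axis = "y", bin_width = 0.02) {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  axis <- axis / sqrt(sum(axis^2))
  resolve <- function(sel, f) if (is.function(sel)) sel(f) else sel
  vals <- unlist(lapply(trajectory$frames, function(f) {
    ia <- resolve(sel_a, f); ib <- resolve(sel_b, f)
    if (!length(ia) || !length(ib)) stop("empty selection in projected-distance distribution")
    pa <- f$positions[ia, , drop = FALSE]
    pb <- f$positions[ib, , drop = FALSE]
    vapply(seq_len(nrow(pa)), function(r) {
      d <- rbind(minimum_image_displacement(
        pb, matrix(pa[r, ], nrow(pb), 3, byrow = TRUE), f$box))
      nb <- which.min(rowSums(d^2))
      sum(d[nb, ] * axis)
    }, numeric(1))
  }))
  lo <- floor(min(vals) / bin_width) * bin_width - bin_width
  hi <- ceiling(max(vals) / bin_width) * bin_width + bin_width
  h <- graphics::hist(vals, breaks = seq(lo, hi, by = bin_width), plot = FALSE)
  list(values = vals, mids = h$mids,
       p = h$counts / sum(h$counts) / bin_width,
       mean = mean(vals), sd = stats::sd(vals))
}
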