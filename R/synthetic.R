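#' @title Synthetic reference systems
#' @description Generators for every input class the analysis stages assume:
#'   proton-disordered ice Ih/Ic lattices, disordered liquid boxes, liquid
#'   boxes with embedded crystalline nuclei, single-file channel-water chains
#'   at ice-lattice spacing, stochastic nucleus-size time series, and boolean
#'   hydrogen-bond event series. Configurations are geometric fixtures with
#'   exact, testable properties — not thermalized snapshots.
#' @name synthetic_systems
NULL

# Rigid water geometry used by all generators: H-O-H angle 104.5 degrees,
# O-H bond 0.09572 nm.
.OH_BOND <- 0.09572
.HOH_HALF <- 104.5 / 2 * pi / 180

# Place two hydrogens around an oxygen given the unit dipole direction
# (bisector O -> H-midpoint) and a unit vector perpendicular to it.
.place_hydrogens <- function(o, dipole, perp) {
  h1 <- o + .OH_BOND * (cos(.HOH_HALF) * dipole + sin(.HOH_HALF) * perp)
  h2 <- o + .OH_BOND * (cos(.HOH_HALF) * dipole - sin(.HOH_HALF) * perp)
  rbind(h1, h2)
}

.unit <- function(v) v / sqrt(sum(v^2))

# A random unit vector perpendicular to u.
.random_perp <- function(u) {
  repeat {
    r <- stats::rnorm(3)
    w <- r - sum(r * u) * u
    n <- sqrt(sum(w^2))
    if (n > 1e-8) return(w / n)
  }
}

.random_unit <- function() .unit(stats::rnorm(3))

# Assemble an md_frame of water molecules from an n x 3 oxygen matrix and a
# 2n x 3 hydrogen matrix (H1, H2 blocks interleaved per molecule).
.water_frame <- function(o_pos, h_pos, box, time = 0) {
  n <- nrow(o_pos)
  pos <- matrix(0, 3 * n, 3)
  pos[seq(1, 3 * n, by = 3), ] <- o_pos
  pos[seq(2, 3 * n, by = 3), ] <- h_pos[seq(1, 2 * n, by = 2), , drop = FALSE]
  pos[seq(3, 3 * n, by = 3), ] <- h_pos[seq(2, 2 * n, by = 2), , drop = FALSE]
  molid <- rep(seq_len(n) - 1L, each = 3L)
  md_frame(
    positions = pos, box = box,
    atoms = data.frame(name = rep(c("OW", "HW1", "HW2"), n),
                       resname = "SOL", resid = molid + 1L, molid = molid),
    time = time
  )
}

# Oxygen sublattice of ice Ih: wurtzite in an orthorhombic cell
# Lx = a, Ly = sqrt(3) a, Lz = c with a = sqrt(8/3) d and c = (8/3) d,
# 8 oxygens per cell. d is the nearest-neighbor O-O distance.
.ih_oxygens <- function(d_oo, repeats) {
  a <- sqrt(8 / 3) * d_oo
  c_ <- (8 / 3) * d_oo
  base <- rbind(
    c(0,     sqrt(3) / 3 * a, 0),
    c(a / 2, sqrt(3) / 6 * a, c_ / 2),
    c(0,     sqrt(3) / 3 * a, 3 * c_ / 8),
    c(a / 2, sqrt(3) / 6 * a, 7 * c_ / 8)
  )
  shift <- c(a / 2, sqrt(3) / 2 * a, 0)
  cell <- rbind(base, sweep(base, 2, shift, "+"))
  box <- c(a, sqrt(3) * a, c_)
  .tile_cell(cell, box, repeats)
}

# Oxygen sublattice of ice Ic: diamond cubic, cell a_c = 4 d / sqrt(3),
# 8 oxygens per cell.
.ic_oxygens <- function(d_oo, repeats) {
  ac <- 4 * d_oo / sqrt(3)
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  cell <- rbind(fcc, sweep(fcc, 2, c(.25, .25, .25), "+")) * ac
  .tile_cell(cell, c(ac, ac, ac), repeats)
}

.tile_cell <- function(cell, cell_box, repeats) {
  reps <- expand.grid(i = seq_len(repeats[1]) - 1,
                      j = seq_len(repeats[2]) - 1,
                      k = seq_len(repeats[3]) - 1)
  offs <- as.matrix(reps) %*% diag(cell_box)
  pos <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
    sweep(cell, 2, offs[r, ], "+")
  }))
  box <- cell_box * repeats
  list(positions = wrap_positions(pos, box), box = box)
}

#' Build an ideal ice lattice with proton disorder
#'
#' Generates the oxygen sublattice of hexagonal (Ih, wurtzite-like) or cubic
#' (Ic, diamond-like) ice at an exact nearest-neighbor O-O distance, then
#' assigns hydrogens along O-O bonds subject to the Bernal-Fowler ice rules:
#' every oxygen donates exactly two hydrogens and every O-O link carries
#' exactly one. Proton disorder is randomized (set the seed for
#' reproducibility) by random bond orientation followed by path-reversal
#' repair until the two-donor rule holds everywhere.
#'
#' The derived lattice constants of the Ih cell are `b = sqrt(8/3) d` (repeat
#' along a basal row, 0.449 nm at the default `d_oo`) and `c = (8/3) d`
#' (bilayer repeat along the c axis, 0.733 nm) — matching the basal-plane ice
#' constants usually quoted as 0.45 and 0.73 nm.
#'
#' @param polytype "ih" (hexagonal) or "ic" (cubic).
#' @param d_oo nearest-neighbor O-O distance in nm (default 0.275).
#' @param repeats integer length-3: unit-cell repeats per axis. Each box edge
#'   must end up at least 2.5 `d_oo` so that minimum-image neighbor finding
#'   is unambiguous.
#' @param seed optional integer seed for the proton-disorder assignment.
#' @return an `md_frame` of water molecules (O, H1, H2 per molecule) with the
#'   box set to the lattice extents.
#' @export
build_ice_lattice <- function(polytype = c("ih", "ic"), d_oo = 0.275,
                              repeats = c(2, 2, 2), seed = NULL) {
  polytype <- match.arg(polytype)
  if (d_oo <= 0) stop("d_oo must be positive")
  repeats <- as.integer(rep(repeats, length.out = 3))
  if (any(repeats < 1)) stop("repeats must be >= 1")
  lat <- if (polytype == "ih") .ih_oxygens(d_oo, repeats) else .ic_oxygens(d_oo, repeats)
  if (any(lat$box < 2.5 * d_oo)) {
    stop("repeats too small: box edge below 2.5 * d_oo; increase repeats")
  }
  if (!is.null(seed)) set.seed(seed)
  o <- lat$positions
  nl <- neighbor_list(o, lat$box, d_oo + 0.02)
  orient <- .ice_rule_orientation(nl)
  h <- matrix(0, 2 * nrow(o), 3)
  for (i in seq_len(nrow(o))) {
    tos <- orient[[i]]
    for (k in 1:2) {
      u <- .unit(minimum_image_displacement(o[i, ], o[tos[k], ], lat$box))
      h[2 * (i - 1) + k, ] <- o[i, ] + .OH_BOND * u
    }
  }
  .water_frame(o, h, lat$box)
}

# Orient the 4-regular O-O bond graph so every vertex has out-degree 2
# (out-edges = donated hydrogens). Random initial orientation; repair by
# reversing a directed path from an over-donor to an under-donor.
.ice_rule_orientation <- function(nl) {
  n <- length(nl)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- nl[[i]][nl[[i]] > i]
    if (length(js)) cbind(i, js) else NULL
  }))
  ne <- nrow(edges)
  dir <- sample(c(TRUE, FALSE), ne, replace = TRUE)  # TRUE: edges[,1] -> edges[,2]
  tail_of <- function(e) if (dir[e]) edges[e, 1] else edges[e, 2]
  head_of <- function(e) if (dir[e]) edges[e, 2] else edges[e, 1]
  outdeg <- tabulate(ifelse(dir, edges[, 1], edges[, 2]), nbins = n)
  edge_at <- lapply(seq_len(n), function(i) which(edges[, 1] == i | edges[, 2] == i))
  while (any(outdeg > 2)) {
    u <- which(outdeg > 2)[1]
    # BFS along directed edges from u to any vertex with out-degree < 2
    parent_edge <- rep(NA_integer_, n)
    visited <- rep(FALSE, n); visited[u] <- TRUE
    queue <- u; target <- NA_integer_
    while (length(queue) && is.na(target)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in edge_at[[v]]) {
        if (tail_of(e) != v) next
        w <- head_of(e)
        if (visited[w]) next
        visited[w] <- TRUE; parent_edge[w] <- e
        if (outdeg[w] < 2) { target <- w; break }
        queue <- c(queue, w)
      }
    }
    if (is.na(target)) stop("ice-rule repair failed to find an augmenting path")
    w <- target
    while (w != u) {
      e <- parent_edge[w]
      v <- tail_of(e)
      dir[e] <- !dir[e]
      w <- v
    }
    outdeg[u] <- outdeg[u] - 1L
    outdeg[target] <- outdeg[target] + 1L
  }
  # out-neighbors per vertex (exactly 2 each once all excesses are repaired:
  # sum(outdeg) = ne = 2n forces the deficit side to close too)
  lapply(seq_len(n), function(i) {
    es <- edge_at[[i]][vapply(edge_at[[i]], function(e) tail_of(e) == i, logical(1))]
    vapply(es, head_of, numeric(1))
  })
}

#' Build a disordered liquid-like water box
#'
#' Random sequential insertion of rigid waters with a hard minimum O-O
#' distance and isotropic random orientations. The result is a disordered
#' reference configuration whose ice-classified fraction should be near zero.
#'
#' @param n_molecules number of waters.
#' @param box length-3 box in nm.
#' @param min_oo minimum O-O distance in nm (default 0.26).
#' @param seed optional integer seed.
#' @param max_attempts insertion attempts per molecule before giving up.
#' @return an `md_frame`.
#' @export
build_liquid_box <- function(n_molecules, box = c(3, 3, 3), min_oo = 0.26,
                             seed = NULL, max_attempts = 5000) {
  if (!is.null(seed)) set.seed(seed)
  box <- as.numeric(box)
  o <- matrix(NA_real_, n_molecules, 3)
  placed <- 0L
  while (placed < n_molecules) {
    ok <- FALSE
    for (try in seq_len(max_attempts)) {
      cand <- stats::runif(3) * box
      if (placed == 0L ||
          all(minimum_image_distance(o[seq_len(placed), , drop = FALSE],
                                     matrix(cand, placed, 3, byrow = TRUE),
                                     box) >= min_oo)) {
        placed <- placed + 1L
        o[placed, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("packing failure: could not place molecule ", placed + 1L,
           " of ", n_molecules, " at min_oo = ", min_oo)
    }
  }
  h <- matrix(0, 2 * n_molecules, 3)
  for (i in seq_len(n_molecules)) {
    u <- .random_unit()
    h[(2 * i - 1):(2 * i), ] <- .place_hydrogens(o[i, ], u, .random_perp(u))
  }
  .water_frame(o, h, box)
}

#' Embed a crystalline nucleus in a liquid box
#'
#' Carves a compact (spherical) cluster of `n_cluster` molecules from an
#' ideal proton-disordered lattice, inserts it at `center`, and removes any
#' liquid water whose oxygen comes within `min_oo` of a cluster oxygen.
#'
#' @param liquid_frame an `md_frame` of water (e.g. from
#'   [build_liquid_box()]).
#' @param n_cluster cluster size in molecules; 0 returns the frame unchanged.
#' @param center length-3 insertion point in nm (default box center).
#' @param polytype,d_oo,seed lattice parameters as in [build_ice_lattice()].
#' @param min_oo overlap-removal O-O distance in nm.
#' @return list with `frame` (the combined `md_frame`) and `inserted`
#'   (0-based molecule indices of the cluster members in the new frame).
#' @export
embed_nucleus <- function(liquid_frame, n_cluster, center = NULL,
                          polytype = "ih", d_oo = 0.275, seed = NULL,
                          min_oo = 0.26) {
  box <- liquid_frame$box
  if (is.null(center)) center <- box / 2
  if (n_cluster == 0) {
    return(list(frame = liquid_frame, inserted = integer()))
  }
  # lattice block comfortably larger than the cluster
  reps <- pmax(2L, ceiling((n_cluster / 8)^(1 / 3)) + 1L)
  lat <- build_ice_lattice(polytype, d_oo, repeats = rep(reps, 3), seed = seed)
  wm <- water_molecules(lat, warn = FALSE)
  o_lat <- lat$positions[wm$O, , drop = FALSE]
  ctr <- colMeans(o_lat)
  ord <- order(rowSums(sweep(o_lat, 2, ctr)^2))
  pick <- ord[seq_len(n_cluster)]
  # recentre the carved cluster on its own centroid, then on `center`
  cl_o <- o_lat[pick, , drop = FALSE]
  shift <- center - colMeans(cl_o)
  if (any(apply(cl_o, 2, function(v) diff(range(v))) > box)) {
    stop("cluster larger than the target box")
  }
  idx <- as.vector(t(cbind(wm$O[pick], wm$H1[pick], wm$H2[pick])))
  cl_pos <- sweep(lat$positions[idx, , drop = FALSE], 2, shift, "+")
  cl_pos <- wrap_positions(cl_pos, box)
  # drop overlapping liquid molecules
  wl <- water_molecules(liquid_frame, warn = FALSE)
  o_liq <- liquid_frame$positions[wl$O, , drop = FALSE]
  cl_o_new <- cl_pos[seq(1, nrow(cl_pos), by = 3), , drop = FALSE]
  dmat <- matrix(0, nrow(o_liq), nrow(cl_o_new))
  for (k in 1:3) {
    dk <- outer(o_liq[, k], cl_o_new[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    dmat <- dmat + dk^2
  }
  keep_liq <- which(apply(dmat, 1, min) >= min_oo^2)
  n_keep <- length(keep_liq)
  liq_idx <- as.vector(t(cbind(wl$O[keep_liq], wl$H1[keep_liq], wl$H2[keep_liq])))
  pos <- rbind(liquid_frame$positions[liq_idx, , drop = FALSE], cl_pos)
  n_tot <- n_keep + n_cluster
  molid <- rep(seq_len(n_tot) - 1L, each = 3L)
  frame <- md_frame(
    positions = pos, box = box,
    atoms = data.frame(name = rep(c("OW", "HW1", "HW2"), n_tot),
                       resname = "SOL", resid = molid + 1L, molid = molid),
    time = liquid_frame$time
  )
  list(frame = frame, inserted = seq(n_keep, n_tot - 1L))
}

#' Build a single-file channel-water chain
#'
#' Collinear waters along one axis at the ice in-row repeat distance
#' (`sqrt(8/3) * d_oo`, about 0.449 nm by default), with dipoles set by mode:
#' perpendicular to the axis (random azimuth), aligned with it, or isotropic.
#' This emulates channel water anchored in the groove of an ice-binding
#' surface.
#'
#' @param n_waters chain length (>= 2).
#' @param spacing O-O spacing in nm; default `sqrt(8/3) * 0.275`.
#' @param axis "x", "y" or "z".
#' @param dipole_mode "perpendicular", "aligned" or "isotropic".
#' @param seed optional integer seed (used by the random modes).
#' @param origin chain start coordinate along the axis, nm.
#' @return an `md_frame`.
#' @export
build_cw_chain <- function(n_waters, spacing = NULL,
                           axis = c("x", "y", "z"),
                           dipole_mode = c("perpendicular", "aligned", "isotropic"),
                           seed = NULL, origin = 0) {
  axis <- match.arg(axis)
  dipole_mode <- match.arg(dipole_mode)
  if (n_waters < 2) stop("n_waters must be >= 2")
  if (is.null(spacing)) spacing <- sqrt(8 / 3) * 0.275
  if (!is.null(seed)) set.seed(seed)
  ax <- match(axis, c("x", "y", "z"))
  e <- c(0, 0, 0); e[ax] <- 1
  pad <- 1
  box <- rep(2 * pad, 3)
  box[ax] <- (n_waters - 1) * spacing + 2 * pad + origin
  o <- matrix(rep(c(pad, pad, pad), each = n_waters), n_waters, 3)
  o[, ax] <- origin + pad + (seq_len(n_waters) - 1) * spacing
  h <- matrix(0, 2 * n_waters, 3)
  for (i in seq_len(n_waters)) {
    u <- switch(dipole_mode,
      aligned = e,
      perpendicular = .random_perp(e),
      isotropic = .random_unit()
    )
    h[(2 * i - 1):(2 * i), ] <- .place_hydrogens(o[i, ], u, .random_perp(u))
  }
  .water_frame(o, h, box)
}

#' Simulate a stochastic nucleus-size time series
#'
#' Euler-Maruyama integration of `dn = k (n - n_c) dt + sigma dW`, reflected
#' at zero and rounded to integer counts for reporting. With `k > 0`, series
#' started above the critical size `n_c` drift upward and series started
#' below drift downward — the sign structure the seeding method relies on.
#'
#' @param n0 initial nucleus size (molecules).
#' @param n_c critical size.
#' @param k drift gain per ns (> 0 for growth above `n_c`). The default 0.1
#'   keeps the exponential amplification over the default duration modest
#'   (e^1), as in observed nucleus-size traces; large `k * duration`
#'   products make paths explode or pile onto the reflecting boundary.
#' @param sigma diffusion amplitude (molecules / sqrt(ns)).
#' @param duration length of the series in ns.
#' @param dt timestep in ns.
#' @param seed optional integer seed.
#' @return a [nucleus_series()] with integer sizes.
#' @export
simulate_nucleus_series <- function(n0, n_c, k = 0.1, sigma = 2,
                                    duration = 10, dt = 0.05, seed = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (n0 < 0 || n_c < 1) stop("n0 must be >= 0 and n_c >= 1")
  if (!is.null(seed)) set.seed(seed)
  nt <- floor(duration / dt) + 1L
  n <- numeric(nt)
  n[1] <- n0
  if (nt > 1L) {
    dw <- stats::rnorm(nt - 1L, sd = sqrt(dt))
    for (i in 2:nt) {
      n[i] <- abs(n[i - 1] + k * (n[i - 1] - n_c) * dt + sigma * dw[i - 1])
    }
  }
  nucleus_series(times = (seq_len(nt) - 1) * dt, n = round(n))
}

#' Simulate boolean hydrogen-bond event series
#'
#' Each pair starts bonded and switches state as a two-state Markov process:
#' breakage at rate `lambda` per ns, reformation at rate `reform` per ns
#' (0 by default, so a broken bond stays broken and the bonded-state survival
#' is exactly `exp(-lambda t)`). States are sampled on a regular frame grid
#' using the exact two-state transition probabilities over one interval.
#'
#' @param n_pairs number of donor-acceptor pairs.
#' @param lambda breakage rate per ns.
#' @param reform reformation rate per ns.
#' @param duration series length in ns (0 gives the single initial frame).
#' @param interval frame interval in ns.
#' @param seed optional integer seed.
#' @return list with `events` (logical `n_pairs` x n_frames matrix) and
#'   `times` (ns).
#' @export
simulate_bond_events <- function(n_pairs, lambda, reform = 0,
                                 duration = 20, interval = 0.1, seed = NULL) {
  if (lambda < 0 || reform < 0) stop("rates must be nonnegative")
  if (interval <= 0) stop("interval must be positive")
  if (interval > duration && duration > 0) stop("frame interval exceeds duration")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration, by = interval)
  nf <- length(times)
  ev <- matrix(FALSE, n_pairs, nf)
  ev[, 1] <- TRUE
  if (nf > 1L) {
    s <- lambda + reform
    if (s == 0) {
      ev[] <- TRUE
    } else {
      # exact CTMC transition probabilities over one interval
      p_bb <- (reform + lambda * exp(-s * interval)) / s  # bonded -> bonded
      p_ub <- (reform - reform * exp(-s * interval)) / s  # unbonded -> bonded
      for (j in 2:nf) {
        p <- ifelse(ev[, j - 1], p_bb, p_ub)
        ev[, j] <- stats::runif(n_pairs) < p
      }
    }
  }
  list(events = ev, times = times)
}
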