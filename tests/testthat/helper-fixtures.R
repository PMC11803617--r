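# Shared fixtures, built in code at test time.

# three-water frame with known coordinates (nm)
three_water_frame <- function(box = c(3, 3, 3)) {
  o <- rbind(c(0.5, 0.5, 0.5), c(1.5, 1.2, 0.8), c(2.2, 2.4, 1.9))
  pos <- NULL
  for (i in 1:3) {
    pos <- rbind(pos, o[i, ], o[i, ] + c(0.0957, 0, 0), o[i, ] + c(-0.024, 0.0927, 0))
  }
  molid <- rep(0:2, each = 3L)
  md_frame(pos, box,
           data.frame(name = rep(c("OW", "HW1", "HW2"), 3),
                      resname = "SOL", resid = molid + 1L, molid = molid))
}

write_three_water_gro <- function(path = tempfile(fileext = ".gro")) {
  write_structure(three_water_frame(), path)
  path
}

# a linear water dimer: donor at origin with one H pointing along +x toward
# the acceptor oxygen at distance r_oo
water_dimer <- function(r_oo = 0.28, angle_deg = 0) {
  th <- angle_deg * pi / 180
  pos <- rbind(
    c(1, 1, 1),                                        # donor O
    c(1, 1, 1) + 0.0957 * c(cos(th), sin(th), 0),      # donor H1 (toward acceptor)
    c(1, 1, 1) + 0.0957 * c(-0.25, -0.97, 0),          # donor H2 (away)
    c(1 + r_oo, 1, 1),                                 # acceptor O
    c(1 + r_oo, 1, 1) + c(0.03, 0.09, 0),
    c(1 + r_oo, 1, 1) + c(0.03, -0.09, 0)
  )
  molid <- rep(0:1, each = 3L)
  md_frame(pos, c(4, 4, 4),
           data.frame(name = rep(c("OW", "HW1", "HW2"), 2),
                      resname = "SOL", resid = molid + 1L, molid = molid))
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rotate a frame about the box center, expanding the box so nothing clips
rotate_frame <- function(frame, rot, pad = 4) {
  ctr <- frame$box / 2
  pos <- sweep(frame$positions, 2, ctr) %*% t(rot)
  big <- max(frame$box) + 2 * pad
  pos <- sweep(pos, 2, rep(big / 2, 3), "+")
  md_frame(pos, rep(big, 3), frame$atoms, frame$time)
}

# brute-force connected components by label propagation (independent of
# igraph) over ice-labeled molecules; returns the largest component size
brute_force_largest <- function(o_pos, box, cutoff, periodic = rep(TRUE, 3)) {
  n <- nrow(o_pos)
  if (n == 0) return(0L)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (minimum_image_distance(o_pos[i, ], o_pos[j, ], box, periodic) <= cutoff &&
            lab[j] != lab[i]) {
          m <- min(lab[i], lab[j]); lab[lab == lab[i] | lab == lab[j]] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  max(table(lab))
}

# keep only the listed molecule ids (waters), renumbering molids from 0
subset_molecules <- function(frame, keep_molids) {
  wm <- water_molecules(frame, warn = FALSE)
  wm <- wm[wm$molid %in% keep_molids, , drop = FALSE]
  idx <- as.vector(t(cbind(wm$O, wm$H1, wm$H2)))
  n <- nrow(wm)
  molid <- rep(seq_len(n) - 1L, each = 3L)
  md_frame(frame$positions[idx, , drop = FALSE], frame$box,
           data.frame(name = rep(c("OW", "HW1", "HW2"), n),
                      resname = "SOL", resid = molid + 1L, molid = molid),
           frame$time)
}

# isolated ice cluster (no periodic bonds) centred in a large box, for
# rotation-invariance checks
isolated_ice_cluster <- function(n_mol = 40, seed = 1, box = 8) {
  lat <- build_ice_lattice("ih", repeats = c(3, 3, 2), seed = seed)
  wm <- water_molecules(lat, warn = FALSE)
  o <- lat$positions[wm$O, , drop = FALSE]
  ctr <- colMeans(o)
  pick <- order(rowSums(sweep(o, 2, ctr)^2))[seq_len(n_mol)]
  f <- subset_molecules(lat, wm$molid[pick])
  shift <- rep(box / 2, 3) - colMeans(f$positions[water_molecules(f)$O, , drop = FALSE])
  md_frame(sweep(f$positions, 2, shift, "+"), rep(box, 3), f$atoms, f$time)
}
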