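#' Ice-binding-site residue layout
#'
#' The ice-binding surface of the beta-helical insect antifreeze protein
#' carries two ordered rows of threonine residues: a long side of six
#' (T17, T29, T41, T53, T65, T77) and a short side of four (T27, T39, T51,
#' T63). Within one helix loop a short-side residue pairs with the long-side
#' residue two positions downstream (the T-x-T motif); across adjacent loops
#' the same-row residues repeat at the helix rise.
#'
#' @param long_side residue numbers of the six-threonine row.
#' @param short_side residue numbers of the four-threonine row.
#' @param hydroxyl_names accepted hydroxyl oxygen atom names (threonine OG1,
#'   serine OG).
#' @return list of class `ibs_layout` with `long_side`, `short_side`,
#'   `motifs` (two-column matrix of within-loop cross-row residue pairs) and
#'   `hydroxyl_names`.
#' @export
ibs_layout <- function(long_side = c(17, 29, 41, 53, 65, 77),
                       short_side = c(27, 39, 51, 63),
                       hydroxyl_names = c("OG1", "OG")) {
  if (!length(long_side) || !length(short_side)) stop("rows must be nonempty")
  n_mot <- min(length(short_side), length(long_side) - 1L)
  motifs <- cbind(short = short_side[seq_len(n_mot)],
                  long = long_side[1L + seq_len(n_mot)])
  structure(list(long_side = long_side, short_side = short_side,
                 motifs = motifs, hydroxyl_names = hydroxyl_names),
            class = "ibs_layout")
}

# hydroxyl O atom row for one residue; error naming the residue if absent
.hydroxyl_atom <- function(frame, resid, hydroxyl_names) {
  i <- select_atoms(frame, name = hydroxyl_names, resid = resid)
  if (!length(i)) stop("missing hydroxyl oxygen (", paste(hydroxyl_names, collapse = "/"),
                       ") for residue ", resid)
  i[1L]
}

#' Hydroxyl-array lattice match against the ice basal plane
#'
#' Measures the mean cross-row within-motif hydroxyl O-O distance (`a_oh`)
#' and the mean along-row adjacent-loop hydroxyl O-O distance (`b_oh`) of an
#' ice-binding site, and their deviations from the ice lattice constants
#' (0.73 and 0.45 nm by default). A near-zero deviation is the geometric
#' signature of an ice-nucleating hydroxyl array.
#'
#' @param frame an `md_frame` of the protein structure (e.g. read from PDB).
#' @param layout an [ibs_layout()].
#' @param a_ice,b_ice reference ice lattice constants in nm.
#' @return list of class `lattice_match_report`: `a_oh`, `b_oh`, `a_ice`,
#'   `b_ice`, `dev_a`, `dev_b`, and the individual pair distances.
#' @export
hydroxyl_lattice_spacing <- function(frame, layout = ibs_layout(),
                                     a_ice = 0.73, b_ice = 0.45) {
  ox <- function(r) frame$positions[.hydroxyl_atom(frame, r, layout$hydroxyl_names), ]
  a_pairs <- apply(layout$motifs, 1L, function(m) {
    minimum_image_distance(ox(m[1]), ox(m[2]), frame$box)
  })
  row_spacings <- function(row) {
    if (length(row) < 2) return(numeric())
    vapply(seq_len(length(row) - 1L), function(i) {
      minimum_image_distance(ox(row[i]), ox(row[i + 1L]), frame$box)
    }, numeric(1))
  }
  b_pairs <- c(row_spacings(layout$long_side), row_spacings(layout$short_side))
  a_oh <- mean(a_pairs); b_oh <- mean(b_pairs)
  structure(list(a_oh = a_oh, b_oh = b_oh, a_ice = a_ice, b_ice = b_ice,
                 dev_a = abs(a_oh - a_ice), dev_b = abs(b_oh - b_ice),
                 a_pairs = a_pairs, b_pairs = b_pairs),
            class = "lattice_match_report")
}

#' @export
print.lattice_match_report <- function(x, ...) {
  cat(sprintf("<lattice_match_report> a_OH = %.3f nm (ice %.2f, dev %.3f); b_OH = %.3f nm (ice %.2f, dev %.3f)\n",
              x$a_oh, x$a_ice, x$dev_a, x$b_oh, x$b_ice, x$dev_b))
  invisible(x)
}

#' Signed dihedral angle of four points, in [0, 360)
#'
#' @param p1,p2,p3,p4 length-3 coordinates (nm).
#' @return angle in degrees in [0, 360); `NA` for degenerate (colinear)
#'   geometry.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10 || nb2 < 1e-10) return(NA_real_)
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  ang %% 360
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Side-chain hydroxyl dihedral series (N-CA-CB-OG)
#'
#' Per-frame dihedral of the backbone nitrogen, the alpha and beta carbons
#' and the side-chain hydroxyl oxygen of one residue — the angle tracking
#' threonine/serine hydroxyl orientation stability. Degenerate (colinear)
#' frames are flagged `NA` and excluded from the histogram.
#'
#' @param trajectory an `md_trajectory`.
#' @param resid residue number.
#' @param atom_names the four atom names, in chain order.
#' @param bin_width histogram bin width in degrees.
#' @return list with `times`, `angles` (degrees in [0, 360)), `mids`, `p`
#'   (normalized histogram over non-degenerate samples).
#' @export
dihedral_series <- function(trajectory, resid,
                            atom_names = c("N", "CA", "CB", "OG1"),
                            bin_width = 2) {
  angles <- vapply(trajectory$frames, function(f) {
    rows <- vapply(atom_names, function(nm) {
      i <- select_atoms(f, name = nm, resid = resid)
      if (!length(i)) stop("missing atom ", nm, " for residue ", resid)
      i[1L]
    }, integer(1))
    p <- f$positions
    dihedral_angle(p[rows[1], ], p[rows[2], ], p[rows[3], ], p[rows[4], ])
  }, numeric(1))
  ok <- angles[!is.na(angles)]
  edges <- seq(0, 360, by = bin_width)
  h <- graphics::hist(ok, breaks = edges, plot = FALSE)
  list(times = trajectory$times, angles = angles, mids = h$mids,
       p = if (length(ok)) h$counts / sum(h$counts) / bin_width else rep(0, length(h$mids)))
}

#' Cross-loop hydroxyl O-O distance series
#'
#' Per-frame minimum-image distance between the hydroxyl oxygens of two
#' residues (equivalent hydroxyls of T-x-T motifs on adjacent helix loops),
#' with summary statistics. Excursions of this distance away from the ice
#' repeat signal loss of the lattice match.
#'
#' @param trajectory an `md_trajectory`.
#' @param resid_pair length-2 residue numbers.
#' @param hydroxyl_names accepted hydroxyl atom names.
#' @return list with `times`, `d_oo` (nm), `mean`, `sd`, `range`.
#' @export
cross_loop_oo_series <- function(trajectory, resid_pair,
                                 hydroxyl_names = c("OG1", "OG")) {
  d <- vapply(trajectory$frames, function(f) {
    i <- .hydroxyl_atom(f, resid_pair[1], hydroxyl_names)
    j <- .hydroxyl_atom(f, resid_pair[2], hydroxyl_names)
    minimum_image_distance(f$positions[i, ], f$positions[j, ], f$box)
  }, numeric(1))
  list(times = trajectory$times, d_oo = d, mean = mean(d), sd = stats::sd(d),
       range = range(d))
}

#' Synthetic ice-binding-site structure (stand-in)
#'
#' Builds a synthetic threonine-array structure with the two IBS rows laid
#' out on a regular grid at the published hydroxyl spacings, plus minimal
#' backbone atoms (N, CA, CB) in a fixed side-chain geometry so that the
#' dihedral and distance operations are exercisable. This is a geometric
#' stand-in for a crystallographic structure, not a reconstruction of one;
#' use it to validate the measurement operations, and feed real PDB input
#' for structural conclusions.
#'
#' @param a_oh cross-row hydroxyl spacing in nm (default 0.74).
#' @param b_oh along-row adjacent-loop spacing in nm (default 0.46).
#' @param jitter Gaussian positional noise sd in nm applied to every atom.
#' @param layout an [ibs_layout()].
#' @param seed optional integer seed for the jitter.
#' @return an `md_frame` with THR residues carrying N, CA, CB, OG1 atoms.
#' @export
build_synthetic_ibs <- function(a_oh = 0.74, b_oh = 0.46, jitter = 0,
                                layout = ibs_layout(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # long row at x = 1, short row at x = 1 + a_oh; loop index sets y
  place <- list()
  for (i in seq_along(layout$long_side)) {
    place[[as.character(layout$long_side[i])]] <- c(1, 1 + (i - 1) * b_oh, 1)
  }
  for (i in seq_along(layout$short_side)) {
    # short-side residue shares the loop of its motif partner long_side[i+1]
    place[[as.character(layout$short_side[i])]] <- c(1 + a_oh, 1 + i * b_oh, 1)
  }
  resids <- as.integer(names(place))
  pos <- NULL; atoms <- NULL
  # fixed local side-chain geometry (nm): OG1 above CB; CA and N stepping away
  offs <- rbind(N  = c(0.000, -0.245, -0.290),
                CA = c(0.000, -0.145, -0.190),
                CB = c(0.000,  0.000, -0.145),
                OG1 = c(0.000, 0.000, 0.000))
  for (k in seq_along(resids)) {
    base <- place[[k]]
    p <- sweep(offs, 2, base, "+")
    if (jitter > 0) p <- p + matrix(stats::rnorm(12, sd = jitter), 4, 3)
    pos <- rbind(pos, p)
    atoms <- rbind(atoms, data.frame(name = rownames(offs), resname = "THR",
                                     resid = resids[k], molid = k - 1L))
  }
  box <- c(2 + a_oh + 1, 2 + max(length(layout$long_side),
                                 length(layout$short_side)) * b_oh, 3)
  md_frame(pos, box, atoms)
}
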