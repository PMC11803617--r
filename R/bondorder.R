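#' @title Steinhardt bond-orientational order and ice classification
#' @description The l = 6 Steinhardt parameter q6 measures how coherently a
#'   molecule's O-O neighbor directions are arranged; the normalized
#'   correlation of two molecules' l = 3 bond-order vectors classifies each
#'   O-O bond as staggered or eclipsed, from which hexagonal and cubic ice
#'   environments are told apart (CHILL+-style): a cubic-ice molecule has
#'   four staggered bonds, a hexagonal-ice molecule three staggered and one
#'   eclipsed.
#' @name ice_structure
NULL

# Spherical harmonics Y_lm evaluated at unit vectors, m = -l..l, with the
# Condon-Shortley phase (pracma::legendre follows the MATLAB convention and
# already includes it). Returns a complex n x (2l+1) matrix.
.ylm <- function(l, vecs) {
  vecs <- rbind(vecs)
  r <- sqrt(rowSums(vecs^2))
  ct <- vecs[, 3] / r
  ct <- pmin(1, pmax(-1, ct))
  phi <- atan2(vecs[, 2], vecs[, 1])
  plm <- pracma::legendre(l, ct)           # (l+1) x n, rows m = 0..l
  if (is.null(dim(plm))) plm <- matrix(plm, ncol = 1)
  out <- matrix(complex(real = 0), nrow = length(r), ncol = 2 * l + 1)
  for (m in 0:l) {
    nlm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    ypos <- nlm * plm[m + 1, ] * exp(1i * m * phi)
    out[, l + 1 + m] <- ypos
    if (m > 0) out[, l + 1 - m] <- (-1)^m * Conj(ypos)
  }
  out
}

# Per-molecule bond-order vectors q_lm = <Y_lm(r_ij)>_j over the neighbor
# list. Returns complex n x (2l+1); rows with no neighbors are NA.
.qlm <- function(l, o_pos, box, neighbors, periodic = c(TRUE, TRUE, TRUE)) {
  n <- nrow(o_pos)
  q <- matrix(complex(real = NA_real_), n, 2 * l + 1)
  for (i in seq_len(n)) {
    js <- neighbors[[i]]
    if (!length(js)) next
    d <- rbind(minimum_image_displacement(
      o_pos[rep(i, length(js)), , drop = FALSE],
      o_pos[js, , drop = FALSE], box, periodic))
    q[i, ] <- colMeans(.ylm(l, d))
  }
  q
}

#' Local q6 bond-orientational order parameter
#'
#' Computes the rotationally invariant Steinhardt parameter
#' `q6 = sqrt(4 pi / 13 * sum_m |<Y_6m>|^2)` over each water oxygen's O-O
#' neighbor directions under the minimum-image convention. Values lie in
#' (0, 1]; an ideal FCC environment gives about 0.574, disordered liquid
#' much lower.
#'
#' @param frame an `md_frame` containing water.
#' @param neighbor_cutoff O-O neighbor cutoff in nm (default 0.35, the first
#'   coordination minimum).
#' @param periodic logical length-3 axis periodicity.
#' @return list with `q6` (per-molecule, `NA` for molecules without
#'   neighbors), `neighbors` (neighbor molecule indices, 1-based into the
#'   molecule list), `molid`, and `o_idx` (atom row of each oxygen).
#' @export
local_q6 <- function(frame, neighbor_cutoff = 0.35,
                     periodic = c(TRUE, TRUE, TRUE)) {
  wm <- water_molecules(frame, warn = FALSE)
  if (nrow(wm) < 2) stop("need at least 2 water molecules for q6")
  if (neighbor_cutoff <= 0) stop("neighbor_cutoff must be positive")
  o <- frame$positions[wm$O, , drop = FALSE]
  nb <- neighbor_list(o, frame$box, neighbor_cutoff, periodic)
  q6m <- .qlm(6, o, frame$box, nb, periodic)
  q6 <- sqrt(4 * pi / 13 * rowSums(Mod(q6m)^2))
  list(q6 = q6, neighbors = nb, molid = wm$molid, o_idx = wm$O)
}

#' Classify water molecules as hexagonal, cubic or interfacial ice
#'
#' Each O-O neighbor bond is scored by the normalized correlation `c_ij` of
#' the two molecules' l = 3 bond-order vectors and classed as staggered
#' (`c_ij <= staggered_max`) or eclipsed (inside `eclipsed_range`). A
#' molecule with exactly four neighbor bonds is HEX when three are staggered
#' and one eclipsed, CUBIC when all four are staggered; molecules with at
#' least two classified (staggered or eclipsed) bonds that miss both
#' patterns are INTERFACIAL; everything else is LIQUID. Molecules with fewer
#' than four neighbors can never be HEX or CUBIC.
#'
#' @inheritParams local_q6
#' @param staggered_max staggered-bond threshold on `c_ij` (default -0.8).
#' @param eclipsed_range eclipsed-bond window on `c_ij`
#'   (default `c(-0.35, 0.25)`).
#' @return data frame of class `ice_labels`: `molid`, `q6`, `n_neighbors`,
#'   `n_staggered`, `n_eclipsed`, `label` (factor HEX/CUBIC/INTERFACIAL/
#'   LIQUID). The frame time is attached as attribute `time`, the oxygen
#'   atom rows as attribute `o_idx`.
#' @export
classify_ice <- function(frame, neighbor_cutoff = 0.35, staggered_max = -0.8,
                         eclipsed_range = c(-0.35, 0.25),
                         periodic = c(TRUE, TRUE, TRUE)) {
  lq <- local_q6(frame, neighbor_cutoff, periodic)
  o <- frame$positions[lq$o_idx, , drop = FALSE]
  n <- nrow(o)
  q3m <- .qlm(3, o, frame$box, lq$neighbors, periodic)
  q3norm <- sqrt(rowSums(Mod(q3m)^2))
  nS <- integer(n); nE <- integer(n)
  for (i in seq_len(n)) {
    js <- lq$neighbors[[i]]
    js <- js[js > i]
    for (j in js) {
      if (is.na(q3norm[i]) || is.na(q3norm[j]) || q3norm[i] == 0 || q3norm[j] == 0) next
      cij <- Re(sum(q3m[i, ] * Conj(q3m[j, ]))) / (q3norm[i] * q3norm[j])
      if (cij <= staggered_max) {
        nS[i] <- nS[i] + 1L; nS[j] <- nS[j] + 1L
      } else if (cij >= eclipsed_range[1] && cij <= eclipsed_range[2]) {
        nE[i] <- nE[i] + 1L; nE[j] <- nE[j] + 1L
      }
    }
  }
  nn <- lengths(lq$neighbors)
  label <- rep("LIQUID", n)
  label[nS + nE >= 2L] <- "INTERFACIAL"
  label[nn == 4L & nS == 4L] <- "CUBIC"
  label[nn == 4L & nS == 3L & nE == 1L] <- "HEX"
  out <- data.frame(
    molid = lq$molid, q6 = lq$q6, n_neighbors = nn,
    n_staggered = nS, n_eclipsed = nE,
    label = factor(label, levels = c("HEX", "CUBIC", "INTERFACIAL", "LIQUID"))
  )
  attr(out, "time") <- frame$time
  attr(out, "o_idx") <- lq$o_idx
  class(out) <- c("ice_labels", class(out))
  out
}
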