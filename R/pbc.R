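#' Minimum-image displacement vectors
#'
#' Displacement b - a wrapped into the nearest periodic image for an
#' orthorhombic box. Periodicity can be restricted to the xy plane (the plane
#' of the ice surface in slab geometries), leaving z non-periodic.
#'
#' @param a,b numeric length-3 vectors or n x 3 matrices (nm).
#' @param box orthorhombic box edge lengths (nm).
#' @param periodic logical length-3: which axes are periodic. Use
#'   `c(TRUE, TRUE, FALSE)` for slab (xy-periodic) systems.
#' @return displacement matrix (or vector) of the same shape as the inputs.
#' @export
minimum_image_displacement <- function(a, b, box, periodic = c(TRUE, TRUE, TRUE)) {
  if (any(box <= 0)) stop("box lengths must be positive")
  a <- rbind(a); b <- rbind(b)
  d <- b - a
  for (k in 1:3) {
    if (periodic[k]) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  if (nrow(d) == 1L) drop(d) else d
}

#' Minimum-image distance
#'
#' Shortest distance between two points (or row-paired point sets) across
#' periodic images of an orthorhombic box.
#'
#' @inheritParams minimum_image_displacement
#' @return numeric distance(s) in nm.
#' @export
minimum_image_distance <- function(a, b, box, periodic = c(TRUE, TRUE, TRUE)) {
  d <- rbind(minimum_image_displacement(a, b, box, periodic))
  sqrt(rowSums(d^2))
}

# All-pairs minimum-image distance matrix for one coordinate set (n x 3).
# O(n^2); fine for the system sizes this package targets.
pairwise_min_image <- function(pos, box, periodic = c(TRUE, TRUE, TRUE)) {
  n <- nrow(pos)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(pos[, k], pos[, k], "-")
    if (periodic[k]) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

# Neighbor lists within a cutoff from a coordinate set, minimum image.
# Returns list of integer vectors (1-based, self excluded).
neighbor_list <- function(pos, box, cutoff, periodic = c(TRUE, TRUE, TRUE)) {
  dm <- pairwise_min_image(pos, box, periodic)
  diag(dm) <- Inf
  apply(dm <= cutoff, 1L, which, simplify = FALSE)
}

# Wrap coordinates into [0, box) along periodic axes.
wrap_positions <- function(pos, box, periodic = c(TRUE, TRUE, TRUE)) {
  for (k in 1:3) {
    if (periodic[k]) pos[, k] <- pos[, k] - box[k] * floor(pos[, k] / box[k])
  }
  pos
}
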