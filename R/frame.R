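#' Construct a molecular configuration frame
#'
#' A frame holds one snapshot of a molecular system: atomic positions in an
#' orthorhombic periodic box, the frame time, and per-atom metadata. All
#' lengths are in nanometres, all times in nanoseconds.
#'
#' @param positions numeric matrix, one row per atom, columns x/y/z in nm.
#' @param box numeric length-3 vector of orthorhombic box edge lengths in nm.
#' @param atoms data frame with columns `name` (atom name), `resname`
#'   (residue name), `resid` (residue number) and `molid` (molecule index,
#'   0-based). One row per atom, aligned with `positions`.
#' @param time frame time in ns.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(positions, box, atoms, time = 0) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  if (ncol(positions) != 3L) stop("positions must have 3 columns (x, y, z)")
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be 3 positive finite edge lengths (nm)")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("name", "resname", "resid", "molid")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms metadata missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) != nrow(positions)) stop("atoms metadata and positions disagree in length")
  structure(
    list(positions = positions, box = box, atoms = atoms, time = as.numeric(time)),
    class = "md_frame"
  )
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf(
    "<md_frame> %d atoms, %d molecules, box %.3f x %.3f x %.3f nm, t = %g ns\n",
    nrow(x$positions), length(unique(x$atoms$molid)),
    x$box[1], x$box[2], x$box[3], x$time
  ))
  invisible(x)
}

#' Number of atoms in a frame
#' @param frame an `md_frame`.
#' @return integer atom count.
#' @export
n_atoms <- function(frame) nrow(frame$positions)

# Residue names recognised as water. Six-site models carry virtual sites that
# are ignored for geometry; only O, H1, H2 (by name) are used.
.water_resnames_default <- c("SOL", "HOH", "WAT", "TIP6")

#' Identify water molecules in a frame
#'
#' A molecule is treated as water when its residue name belongs to
#' `water_resnames` and it contains at least one oxygen and two hydrogens
#' (by atom-name convention: O/OW and H*/HW*). Virtual sites of multi-site
#' water models are ignored.
#'
#' @param frame an `md_frame`.
#' @param water_resnames residue names recognised as water.
#' @param warn warn about molecules with a water residue name that fail
#'   O + 2H recognition.
#' @return data frame with one row per water molecule: `molid`, atom indices
#'   `O`, `H1`, `H2` (1-based into the frame's atom table).
#' @export
water_molecules <- function(frame, water_resnames = .water_resnames_default,
                            warn = TRUE) {
  at <- frame$atoms
  is_wat_res <- at$resname %in% water_resnames
  if (!any(is_wat_res)) {
    return(data.frame(molid = integer(), O = integer(), H1 = integer(), H2 = integer()))
  }
  idx <- which(is_wat_res)
  sp <- split(idx, at$molid[idx])
  out <- lapply(sp, function(ii) {
    nm <- toupper(at$name[ii])
    o <- ii[grepl("^OW?[0-9]*$", nm)]
    h <- ii[grepl("^HW?[0-9]*$", nm)]
    if (length(o) >= 1L && length(h) >= 2L) {
      c(O = o[1L], H1 = h[1L], H2 = h[2L])
    } else {
      NULL
    }
  })
  bad <- names(sp)[vapply(out, is.null, logical(1))]
  if (warn && length(bad)) {
    warning(length(bad), " molecule(s) with water residue names failed O+2H recognition: ",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  keep <- !vapply(out, is.null, logical(1))
  mat <- do.call(rbind, out[keep])
  data.frame(
    molid = as.integer(names(sp)[keep]),
    O = as.integer(mat[, "O"]), H1 = as.integer(mat[, "H1"]), H2 = as.integer(mat[, "H2"])
  )
}

#' Construct a trajectory from frames
#'
#' @param frames list of `md_frame` objects with identical atom counts.
#' @param times optional explicit frame times in ns; otherwise taken from the
#'   frames, and if those are all zero, filled from `dt`.
#' @param dt frame spacing in ns used when no explicit times are available.
#' @return An object of class `md_trajectory` (list of frames + `times`).
#' @export
md_trajectory <- function(frames, times = NULL, dt = NULL) {
  if (!length(frames)) stop("empty trajectory: no frames supplied")
  nat <- vapply(frames, n_atoms, integer(1))
  if (length(unique(nat)) != 1L) {
    stop("structural mismatch: frames carry differing atom counts (",
         paste(unique(nat), collapse = ", "), ")")
  }
  if (is.null(times)) {
    times <- vapply(frames, function(f) f$time, numeric(1))
    if (length(frames) > 1L && all(times == times[1L])) {
      if (is.null(dt)) dt <- 1
      times <- (seq_along(frames) - 1) * dt
    }
  }
  if (length(times) != length(frames)) stop("times and frames differ in length")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  for (i in seq_along(frames)) frames[[i]]$time <- times[i]
  structure(list(frames = frames, times = as.numeric(times)), class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames, %d atoms, t = [%g, %g] ns\n",
              length(x$frames), n_atoms(x$frames[[1]]),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
length.md_trajectory <- function(x) length(x$frames)

#' Select atoms of a frame by metadata and spatial region
#'
#' Predicates combine with AND; omitted predicates match everything. The
#' result is a deterministic, ordered index vector.
#'
#' @param frame an `md_frame`.
#' @param name,resname character vectors of accepted atom / residue names.
#' @param resid integer vector of accepted residue numbers.
#' @param molid integer vector of accepted molecule indices.
#' @param region optional list with `min` and `max` (length-3, nm): an
#'   axis-aligned box the atom position must fall inside (inclusive).
#' @return sorted integer vector of 1-based atom indices.
#' @export
select_atoms <- function(frame, name = NULL, resname = NULL, resid = NULL,
                         molid = NULL, region = NULL) {
  at <- frame$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(name))    keep <- keep & at$name %in% name
  if (!is.null(resname)) keep <- keep & at$resname %in% resname
  if (!is.null(resid))   keep <- keep & at$resid %in% resid
  if (!is.null(molid))   keep <- keep & at$molid %in% molid
  if (!is.null(region)) {
    p <- frame$positions
    keep <- keep &
      p[, 1] >= region$min[1] & p[, 1] <= region$max[1] &
      p[, 2] >= region$min[2] & p[, 2] <= region$max[2] &
      p[, 3] >= region$min[3] & p[, 3] <= region$max[3]
  }
  which(keep)
}
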