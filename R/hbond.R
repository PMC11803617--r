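#' Hydrogen-bond detection criteria
#'
#' Geometric criterion: donor-acceptor O-O distance at most `r_oo` and the
#' angle between the donor O-H vector and the donor-acceptor O-O vector at
#' most `angle_max`.
#'
#' @param r_oo O-O distance cutoff in nm (default 0.35).
#' @param angle_max H-donor-acceptor angle cutoff in degrees (default 30).
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(r_oo = 0.35, angle_max = 30) {
  if (r_oo <= 0 || angle_max <= 0) stop("criteria cutoffs must be positive")
  structure(list(r_oo = r_oo, angle_max = angle_max), class = "hbond_criteria")
}

#' Detect hydrogen bonds in a frame
#'
#' Finds unordered donor-acceptor pairs satisfying the geometric criterion
#' under the minimum-image convention. Donors are oxygens with attached
#' hydrogens; by default all waters of the frame act as both donors and
#' acceptors. Protein partners (threonine/serine hydroxyl O, backbone
#' carbonyl O) can be supplied through the `donors` / `acceptors` arguments.
#'
#' @param frame an `md_frame`.
#' @param criteria an [hbond_criteria()].
#' @param donors data frame with columns `O`, `H1`, `H2` (atom rows; `H2`
#'   may be `NA` for single-H donors) and `molid`. Default: the frame's
#'   waters.
#' @param acceptors data frame with columns `O` (atom row) and `molid`.
#'   Default: the frame's waters.
#' @param periodic logical length-3 axis periodicity.
#' @return data frame with one row per bond: `donor_mol`, `acceptor_mol`,
#'   `donor_O`, `acceptor_O`, `r_oo` (nm), `angle` (degrees). Each donor
#'   hydrogen is counted at most once (its best acceptor).
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria(), donors = NULL,
                          acceptors = NULL, periodic = c(TRUE, TRUE, TRUE)) {
  if (is.null(donors) || is.null(acceptors)) {
    wm <- water_molecules(frame, warn = FALSE)
    if (is.null(donors)) donors <- wm
    if (is.null(acceptors)) acceptors <- wm[, c("molid", "O")]
  }
  empty <- data.frame(donor_mol = integer(), acceptor_mol = integer(),
                      donor_O = integer(), acceptor_O = integer(),
                      r_oo = numeric(), angle = numeric())
  if (!nrow(donors) || !nrow(acceptors)) {
    warning("empty donor or acceptor selection; no hydrogen bonds")
    return(empty)
  }
  box <- frame$box
  pos <- frame$positions
  d_o <- pos[donors$O, , drop = FALSE]
  a_o <- pos[acceptors$O, , drop = FALSE]
  d2 <- matrix(0, nrow(d_o), nrow(a_o))
  for (k in 1:3) {
    dk <- outer(d_o[, k], a_o[, k], "-")
    if (periodic[k]) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  cand <- which(d2 <= criteria$r_oo^2 & d2 > 1e-12, arr.ind = TRUE)
  rows <- list()
  hcols <- intersect(c("H1", "H2"), names(donors))
  for (r in seq_len(nrow(cand))) {
    di <- cand[r, 1]; ai <- cand[r, 2]
    if (donors$molid[di] == acceptors$molid[ai]) next
    roo <- sqrt(d2[di, ai])
    v_oa <- minimum_image_displacement(pos[donors$O[di], ], pos[acceptors$O[ai], ],
                                       box, periodic)
    for (hc in hcols) {
      hrow <- donors[[hc]][di]
      if (is.na(hrow)) next
      v_oh <- minimum_image_displacement(pos[donors$O[di], ], pos[hrow, ], box, periodic)
      ang <- acos(pmin(1, pmax(-1, sum(v_oh * v_oa) /
                                 sqrt(sum(v_oh^2) * sum(v_oa^2))))) * 180 / pi
      if (ang <= criteria$angle_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          donor_mol = donors$molid[di], acceptor_mol = acceptors$molid[ai],
          donor_O = donors$O[di], acceptor_O = acceptors$O[ai],
          r_oo = roo, angle = ang, h = hrow
        )
        break  # one bond per donor hydrogen candidate pair
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # each donor H counted once: keep its closest acceptor
  out <- out[order(out$h, out$r_oo), ]
  out <- out[!duplicated(out$h), ]
  # deduplicate unordered molecule pairs
  pk <- paste(pmin(out$donor_mol, out$acceptor_mol),
              pmax(out$donor_mol, out$acceptor_mol))
  out <- out[!duplicated(pk), ]
  rownames(out) <- NULL
  out$h <- NULL
  out
}

#' Correlation curve container
#'
#' @param lags lag times in ns.
#' @param values correlation values in `[0, 1]`.
#' @param counts samples per lag.
#' @param window window length in ns.
#' @return object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, values, counts, window) {
  if (any(values < -1e-9 | values > 1 + 1e-9)) stop("correlation values must lie in [0,1]")
  structure(list(lags = as.numeric(lags), values = pmin(1, pmax(0, values)),
                 counts = as.numeric(counts), window = as.numeric(window)),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %d lags over %g ns, C(0) = %.3f, C(T) = %.3f\n",
              length(x$lags), x$window, x$values[1], x$values[length(x$values)]))
  invisible(x)
}

#' Intermittent hydrogen-bond time correlation C_H(t)
#'
#' `C_H(t) = <h(0) h(t)> / <h(0)>` over the pairs bonded at the window
#' start, where `h` is the bond indicator. The definition is intermittent: a
#' bond that breaks and later reforms counts again, so the curve need not be
#' monotone.
#'
#' @param events logical pairs x frames matrix of bond indicators (e.g. from
#'   [simulate_bond_events()] or [bond_event_matrix()]).
#' @param times frame times in ns (same length as `ncol(events)`).
#' @param window correlation window length in ns; lags are limited to it.
#'   Default: the full span of `times`.
#' @param start window start time (default `times[1]`).
#' @return a [correlation_curve()].
#' @export
intermittent_correlation <- function(events, times, window = NULL, start = NULL) {
  if (is.null(dim(events))) events <- matrix(events, nrow = 1)
  if (ncol(events) != length(times)) stop("events columns and times differ in length")
  if (is.null(start)) start <- times[1]
  i0 <- which(times >= start - 1e-12)[1]
  if (is.na(i0)) stop("window start beyond the series")
  if (is.null(window)) window <- times[length(times)] - times[i0]
  if (window <= 0) stop("window must be positive")
  sel <- which(times >= times[i0] - 1e-12 & times <= times[i0] + window + 1e-12)
  if (length(sel) < 2) stop("need at least 2 frames inside the window")
  bonded0 <- which(events[, sel[1]])
  if (!length(bonded0)) stop("undefined curve: no bonds at the window start")
  sub <- events[bonded0, sel, drop = FALSE]
  correlation_curve(
    lags = times[sel] - times[sel[1]],
    values = colMeans(sub),
    counts = rep(length(bonded0), length(sel)),
    window = window
  )
}

#' Hydrogen-bond event matrix from a trajectory
#'
#' Evaluates [detect_hbonds()] on every frame and returns the bond indicator
#' matrix over the union of molecule pairs ever bonded.
#'
#' @inheritParams detect_hbonds
#' @param trajectory an `md_trajectory`.
#' @return list with `events` (logical pairs x frames), `pairs` (two-column
#'   molecule-id matrix) and `times`.
#' @export
bond_event_matrix <- function(trajectory, criteria = hbond_criteria(),
                              donors = NULL, acceptors = NULL,
                              periodic = c(TRUE, TRUE, TRUE)) {
  per_frame <- lapply(trajectory$frames, function(f) {
    hb <- detect_hbonds(f, criteria, donors, acceptors, periodic)
    paste(pmin(hb$donor_mol, hb$acceptor_mol), pmax(hb$donor_mol, hb$acceptor_mol))
  })
  keys <- sort(unique(unlist(per_frame)))
  ev <- vapply(per_frame, function(k) keys %in% k, logical(length(keys)))
  if (is.null(dim(ev))) ev <- matrix(ev, nrow = length(keys))
  pairs <- do.call(rbind, lapply(strsplit(keys, " "), as.numeric))
  list(events = ev, pairs = pairs, times = trajectory$times)
}

#' Window-normalized hydrogen-bond persistence Gamma_HB
#'
#' The integral of C_H(t) over the correlation window, normalized by the
#' window length (trapezoidal rule on the native lag grid):
#' `Gamma_HB = (1/T_w) * integral_0^T_w C_H(t) dt`, the probability that an
#' initially bonded pair remains bonded within the window.
#'
#' @param curve a [correlation_curve()].
#' @param window integration window in ns; defaults to the curve's window.
#'   Must be covered by the curve's lags.
#' @return scalar in `[0, 1]`.
#' @export
gamma_hb <- function(curve, window = NULL) {
  if (is.null(window)) window <- curve$window
  if (window <= 0) stop("window must be positive")
  keep <- curve$lags <= window + 1e-12
  lags <- curve$lags[keep]; vals <- curve$values[keep]
  if (length(lags) < 2) stop("curve does not cover the integration window")
  pracma::trapz(lags, vals) / (lags[length(lags)] - lags[1])
}

#' Residence-time correlation C_R(t)
#'
#' Fraction of the molecules initially inside a region that have remained
#' continuously inside up to lag t; departure is absorbing, so the curve is
#' monotone nonincreasing.
#'
#' @param trajectory an `md_trajectory`.
#' @param region list with `min` and `max` (length-3, nm) defining an
#'   axis-aligned box.
#' @param molids optional molecule ids restricting the tracked set
#'   (default: all waters).
#' @param window window length in ns (default full span).
#' @param start window start time.
#' @return a [correlation_curve()].
#' @export
residence_correlation <- function(trajectory, region, molids = NULL,
                                  window = NULL, start = NULL) {
  occ <- .inside_matrix(trajectory, region, molids)
  times <- trajectory$times
  if (is.null(start)) start <- times[1]
  i0 <- which(times >= start - 1e-12)[1]
  if (is.null(window)) window <- times[length(times)] - times[i0]
  sel <- which(times >= times[i0] - 1e-12 & times <= times[i0] + window + 1e-12)
  inside0 <- which(occ[, sel[1]])
  if (!length(inside0)) stop("undefined curve: region empty at the window start")
  sub <- occ[inside0, sel, drop = FALSE]
  stayed <- t(apply(sub, 1, cumprod)) # absorbing: continuous presence
  if (is.null(dim(stayed))) stayed <- matrix(stayed, nrow = 1)
  correlation_curve(
    lags = times[sel] - times[sel[1]],
    values = colMeans(stayed),
    counts = rep(length(inside0), length(sel)),
    window = window
  )
}

#' Region occupancy per frame
#'
#' Integer count of selected molecules (by oxygen position) inside an
#' axis-aligned box region, per frame, with the time average.
#'
#' @inheritParams residence_correlation
#' @return list with `times`, `counts` and `mean`.
#' @export
occupancy_series <- function(trajectory, region, molids = NULL) {
  occ <- .inside_matrix(trajectory, region, molids)
  counts <- colSums(occ)
  list(times = trajectory$times, counts = as.integer(counts), mean = mean(counts))
}

# molecule-inside-region indicator matrix (molecules x frames), by oxygen
.inside_matrix <- function(trajectory, region, molids = NULL) {
  wm0 <- water_molecules(trajectory$frames[[1]], warn = FALSE)
  if (!is.null(molids)) wm0 <- wm0[wm0$molid %in% molids, , drop = FALSE]
  if (!nrow(wm0)) stop("no molecules selected")
  sapply(trajectory$frames, function(f) {
    p <- f$positions[wm0$O, , drop = FALSE]
    p[, 1] >= region$min[1] & p[, 1] <= region$max[1] &
      p[, 2] >= region$min[2] & p[, 2] <= region$max[2] &
      p[, 3] >= region$min[3] & p[, 3] <= region$max[3]
  }) |> matrix(nrow = nrow(wm0))
}
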