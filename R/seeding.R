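#' Seeding ensemble of nucleus-size trajectories
#'
#' Groups of replicate [nucleus_series()] keyed by initial seed size `n0`,
#' the input of the seeding estimate of the critical nucleus size.
#'
#' @param groups named list: names are initial sizes `n0`, elements are
#'   lists of `nucleus_series` replicates.
#' @return object of class `seeding_ensemble`.
#' @export
seeding_ensemble <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named by initial size n0")
  }
  n0 <- as.numeric(names(groups))
  if (any(is.na(n0))) stop("group names must be numeric n0 values")
  structure(list(groups = groups, n0 = n0), class = "seeding_ensemble")
}

#' Ensemble mean nucleus-size curve
#'
#' Pointwise mean and standard error over replicate series. Series are
#' linearly interpolated onto the first replicate's time grid restricted to
#' the common (intersection) time window.
#'
#' @param series_list list of [nucleus_series()].
#' @return list with `times`, `mean`, `se`, `n_replicates`.
#' @export
ensemble_mean <- function(series_list) {
  if (!length(series_list)) stop("empty group: no replicate series")
  t_lo <- max(vapply(series_list, function(s) min(s$times), numeric(1)))
  t_hi <- min(vapply(series_list, function(s) max(s$times), numeric(1)))
  if (t_hi <= t_lo && length(series_list[[1]]$times) > 1L) {
    stop("replicate time grids do not overlap")
  }
  grid <- series_list[[1]]$times
  grid <- grid[grid >= t_lo - 1e-12 & grid <= t_hi + 1e-12]
  vals <- vapply(series_list, function(s) {
    if (length(s$times) == 1L) rep(s$n, length(grid))
    else stats::approx(s$times, s$n, xout = grid)$y
  }, numeric(length(grid)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(grid))
  m <- rowMeans(vals)
  se <- if (ncol(vals) > 1L) apply(vals, 1, stats::sd) / sqrt(ncol(vals)) else rep(NA_real_, length(grid))
  list(times = grid, mean = m, se = se, n_replicates = length(series_list))
}

#' Growth rate of a mean nucleus-size curve
#'
#' Ordinary-least-squares slope of the ensemble-mean curve over an analysis
#' window, with its standard error. The sign of this slope is the seeding
#' verdict: growth above the critical size, shrinkage below.
#'
#' @param mean_curve result of [ensemble_mean()] (or any list with `times`
#'   and `mean`).
#' @param window length-2 time window in ns; default drops the first 10% of
#'   the curve as transient and uses the rest.
#' @return list with `slope` (per ns), `stderr`, `window`, `n_points`.
#' @export
growth_rate <- function(mean_curve, window = NULL) {
  tt <- mean_curve$times; yy <- mean_curve$mean
  if (is.null(window)) {
    t0 <- min(tt) + 0.1 * (max(tt) - min(tt))
    window <- c(t0, max(tt))
  }
  sel <- tt >= window[1] - 1e-12 & tt <= window[2] + 1e-12
  if (sum(sel) < 3) stop("degenerate window: need at least 3 points")
  fit <- stats::lm(y ~ t, data = data.frame(t = tt[sel], y = yy[sel]))
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are legitimate here
  list(slope = unname(sm["t", "Estimate"]), stderr = unname(sm["t", "Std. Error"]),
       window = window, n_points = sum(sel))
}

#' Critical nucleus size by the seeding method
#'
#' Each seed-size group receives a verdict from the sign of its ensemble
#' growth rate d<n>/dt: `grow` when the slope exceeds `threshold` standard
#' errors above zero, `shrink` when below, otherwise `indeterminate`. The
#' critical size is bracketed between the largest shrinking and the smallest
#' growing seed size; the point estimate is the bracket midpoint.
#'
#' @param ensemble a [seeding_ensemble()].
#' @param window analysis window passed to [growth_rate()].
#' @param threshold verdict significance in standard errors (default 2).
#' @return list of class `critical_size_estimate`: `table` (per-group n0,
#'   slope, stderr, verdict), `bracket` `(n_low, n_high)`, `n_star`
#'   (midpoint).
#' @export
critical_size <- function(ensemble, window = NULL, threshold = 2) {
  if (length(ensemble$groups) < 2) stop("need at least 2 seed-size groups")
  ord <- order(ensemble$n0)
  rows <- lapply(ord, function(i) {
    grp <- ensemble$groups[[i]]
    # group slope = mean of per-replicate slopes; its standard error comes
    # from the between-replicate scatter, which stays honest where the
    # nominal OLS error of the ensemble-mean curve is anti-conservative
    # (the residuals of a stochastic nucleus-size curve are autocorrelated)
    reps <- vapply(grp, function(s) {
      growth_rate(list(times = s$times, mean = s$n), window)$slope
    }, numeric(1))
    slope <- mean(reps)
    se <- if (length(reps) > 1L) stats::sd(reps) / sqrt(length(reps)) else {
      growth_rate(ensemble_mean(grp), window)$stderr
    }
    verdict <- if (slope > threshold * se) "grow"
               else if (slope < -threshold * se) "shrink"
               else "indeterminate"
    data.frame(n0 = ensemble$n0[i], slope = slope, stderr = se,
               verdict = verdict)
  })
  tab <- do.call(rbind, rows)
  shr <- tab$n0[tab$verdict == "shrink"]
  gro <- tab$n0[tab$verdict == "grow"]
  if (!length(shr) || !length(gro)) {
    side <- if (length(gro)) {
      paste0("all growing: critical size <= ", min(gro))
    } else if (length(shr)) {
      paste0("all shrinking: critical size >= ", max(shr))
    } else "all verdicts indeterminate"
    stop("unbracketed critical size (no sign change across groups); ", side)
  }
  n_low <- max(shr); n_high <- min(gro)
  if (n_low >= n_high) {
    stop("inconsistent verdict ordering: largest shrinking seed (", n_low,
         ") is not below the smallest growing seed (", n_high, ")")
  }
  structure(list(table = tab, bracket = c(n_low = n_low, n_high = n_high),
                 n_star = (n_low + n_high) / 2),
            class = "critical_size_estimate")
}

#' @export
print.critical_size_estimate <- function(x, ...) {
  cat(sprintf("<critical_size_estimate> n* = %.1f, bracket (%g, %g)\n",
              x$n_star, x$bracket[1], x$bracket[2]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Generate a synthetic seeding ensemble
#'
#' Convenience wrapper: replicate stochastic nucleus-size series per seed
#' size via [simulate_nucleus_series()], as used to validate the
#' [critical_size()] estimator against a known critical size.
#'
#' @param n0_values seed sizes.
#' @param n_c true critical size of the generator.
#' @param n_replicates replicates per seed size (default 20).
#' @param k,sigma,duration,dt generator parameters.
#' @param seed master seed; replicate seeds are derived deterministically.
#' @return a [seeding_ensemble()].
#' @export
simulate_seeding_ensemble <- function(n0_values, n_c, n_replicates = 20,
                                      k = 0.1, sigma = 2, duration = 10,
                                      dt = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- lapply(n0_values, function(n0) {
    lapply(seq_len(n_replicates), function(r) {
      simulate_nucleus_series(n0, n_c, k, sigma, duration, dt)
    })
  })
  names(groups) <- n0_values
  seeding_ensemble(groups)
}
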