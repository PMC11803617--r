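#' @title Classical nucleation theory with a line-tension term
#' @description Forward model of the nucleus free energy as a function of
#'   size n (molecules). Homogeneous nucleation:
#'   `dG(n) = -n dmu + gamma^N n^(2/3)`, with the bulk driving force dmu =
#'   mu_wat - mu_ice (kJ/mol per molecule) and a per-molecule surface
#'   coefficient gamma^N. Heterogeneous (on-surface) nucleation:
#'   `dG(n) = -n dmu + dgamma^N n^(2/3) + tau l^N 0.6022 n^e`, where
#'   dgamma^N is the crystal-liquid surface-energy difference over the
#'   surface, tau the line tension (pN) of the three-phase contact line,
#'   l^N its per-molecule length coefficient (nm) and e the contact-line
#'   scaling exponent (1/3 for a cap-like nucleus, 1/2 for a disk-like
#'   one). 1 pN nm = 0.6022 kJ/mol.
#' @name cnt_model
NULL

#' Unit conversion: 1 pN nm in kJ/mol
#' @export
PN_NM_TO_KJ_MOL <- 0.6022

#' Load a thermodynamic table
#'
#' Reads a delimited text table of per-temperature chemical potentials and
#' surface-energy differences (kJ/mol) and derives the freezing driving
#' force `dmu = mu_wat - mu_ice` per row. Required columns (case
#' insensitive): `temp_K`, `mu_ice`, `mu_wat`, `dgamma_N`; extra columns are
#' carried through untouched.
#'
#' @param path file path (tab- or whitespace-delimited, with header).
#' @return data frame of class `thermo_table` with an added `dmu` column.
#' @export
load_thermo_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "", check.names = FALSE,
                           comment.char = "#")
  want <- c("temp_K", "mu_ice", "mu_wat", "dgamma_N")
  nm_lower <- tolower(names(tab))
  for (w in want) {
    hit <- which(nm_lower == tolower(w))
    if (!length(hit)) stop("thermo table parse error: missing column '", w, "'")
    names(tab)[hit[1]] <- w
  }
  if (any(!is.finite(tab$temp_K)) || any(diff(tab$temp_K) <= 0)) {
    stop("thermo table parse error: temperatures must be strictly increasing")
  }
  tab$dmu <- tab$mu_wat - tab$mu_ice
  class(tab) <- c("thermo_table", class(tab))
  tab
}

#' Bundle CNT parameters
#'
#' @param dmu driving force mu_wat - mu_ice in kJ/mol (> 0 below melting).
#' @param gamma_hom homogeneous per-molecule surface coefficient (kJ/mol,
#'   multiplies n^(2/3)).
#' @param dgamma heterogeneous surface coefficient (kJ/mol, multiplies
#'   n^(2/3)); may be negative for an ice-templating surface.
#' @param tau line tension in pN (default 5, temperature independent).
#' @param l_line per-molecule contact-line length coefficient in nm
#'   (multiplies n^exponent).
#' @param line_exponent contact-line scaling exponent, 1/3 (cap-like,
#'   default) or 1/2 (disk-like).
#' @return list of class `cnt_params`.
#' @export
cnt_params <- function(dmu, gamma_hom = NULL, dgamma = NULL, tau = 5,
                       l_line = 1, line_exponent = 1/3) {
  if (!line_exponent %in% c(1/3, 1/2)) {
    stop("line_exponent must be 1/3 (cap-like) or 1/2 (disk-like)")
  }
  structure(list(dmu = dmu, gamma_hom = gamma_hom, dgamma = dgamma,
                 tau = tau, l_line = l_line, line_exponent = line_exponent),
            class = "cnt_params")
}

#' Nucleus free-energy curve
#'
#' @param params a [cnt_params()].
#' @param mode "hom" (homogeneous) or "het" (surface nucleation with the
#'   line-tension term).
#' @param n nucleus sizes (molecules), n >= 0.
#' @return numeric `dG(n)` in kJ/mol (`dG(0) = 0`).
#' @export
free_energy_curve <- function(params, mode = c("hom", "het"), n) {
  mode <- match.arg(mode)
  if (any(n < 0)) stop("n must be nonnegative")
  if (mode == "hom") {
    if (is.null(params$gamma_hom)) stop("gamma_hom required for homogeneous mode")
    -n * params$dmu + params$gamma_hom * n^(2/3)
  } else {
    if (is.null(params$dgamma)) stop("dgamma required for heterogeneous mode")
    line <- params$tau * params$l_line * PN_NM_TO_KJ_MOL
    -n * params$dmu + params$dgamma * n^(2/3) + line * n^params$line_exponent
  }
}

#' Nucleation barrier and critical size
#'
#' Maximizes the free-energy curve. The pure `n^(2/3)` homogeneous case has
#' the closed form `n* = (2 gamma / (3 dmu))^3` and
#' `dG* = 4 gamma^3 / (27 dmu^2) = n* dmu / 2`; the heterogeneous curve with
#' a line-tension term is maximized numerically. The continuous maximizer is
#' always cross-checked against brute-force integer evaluation over
#' `[1, 10 n*]`.
#'
#' @param params a [cnt_params()].
#' @param mode "hom" or "het".
#' @return list of class `barrier_result`: `n_star` (real), `n_star_int`
#'   (integer argmax), `dg_star` (kJ/mol), `dg_star_int`, `mode`.
#' @export
cnt_barrier <- function(params, mode = c("hom", "het")) {
  mode <- match.arg(mode)
  if (params$dmu <= 0) stop("no barrier: dmu <= 0 (no freezing driving force)")
  if (mode == "hom") {
    g <- params$gamma_hom
    if (is.null(g) || g <= 0) stop("no barrier: gamma_hom must be positive")
    n_star <- (2 * g / (3 * params$dmu))^3
    dg_star <- 4 * g^3 / (27 * params$dmu^2)
  } else {
    f <- function(n) free_energy_curve(params, "het", n)
    # the curve is smooth with at most one interior maximum before the bulk
    # term takes over; search on a log-spaced bracket
    up <- max(1, (2 * max(params$dgamma, 0) / (3 * params$dmu))^3) * 1e3 + 1e3
    opt <- stats::optimize(f, interval = c(1e-9, up), maximum = TRUE, tol = 1e-10)
    n_star <- opt$maximum
    dg_star <- opt$objective
    if (dg_star <= f(1e-9) + 1e-12 || dg_star <= 0) {
      stop("no barrier: heterogeneous curve has no positive interior maximum")
    }
  }
  n_grid <- seq_len(max(10L, ceiling(10 * n_star)))
  dg_grid <- free_energy_curve(params, mode, n_grid)
  i_best <- which.max(dg_grid)
  structure(list(n_star = n_star, n_star_int = n_grid[i_best],
                 dg_star = dg_star, dg_star_int = dg_grid[i_best], mode = mode),
            class = "barrier_result")
}

#' @export
print.barrier_result <- function(x, ...) {
  cat(sprintf("<barrier_result> %s: n* = %.2f (int %d), dG* = %.3f kJ/mol\n",
              x$mode, x$n_star, x$n_star_int, x$dg_star))
  invisible(x)
}

#' Calibrate the homogeneous surface coefficient
#'
#' Solves `gamma^N` from a target critical size at a given driving force,
#' inverting `n* = (2 gamma / (3 dmu))^3`:
#' `gamma = (3/2) dmu n*^(1/3)`.
#'
#' @param n_star target critical size (molecules).
#' @param dmu driving force in kJ/mol.
#' @return `gamma_hom` in kJ/mol.
#' @export
calibrate_gamma_hom <- function(n_star, dmu) {
  if (n_star <= 0 || dmu <= 0) stop("n_star and dmu must be positive")
  1.5 * dmu * n_star^(1/3)
}

#' Heterogeneous-to-homogeneous barrier ratio f(T)
#'
#' For every temperature of a thermodynamic table, computes the
#' heterogeneous and homogeneous barriers and their ratio
#' `f = dG*_het / dG*_hom` (the potency factor of the surface: small f means
#' strong barrier lowering), plus a least-squares polynomial fit of f(T) for
#' trend display.
#'
#' @param thermo a [load_thermo_table()] result.
#' @param gamma_hom homogeneous surface coefficient (kJ/mol), fixed across
#'   temperatures.
#' @param tau,l_line,line_exponent heterogeneous line-term parameters.
#' @param fit_degree polynomial degree of the descriptive trend fit
#'   (default 2).
#' @return list of class `potency_result`: `table` (temp_K, dmu, dg_het,
#'   dg_hom, f), `fit` (lm object or NULL if too few rows).
#' @export
potency_factor <- function(thermo, gamma_hom, tau = 5, l_line = 1,
                           line_exponent = 1/3, fit_degree = 2) {
  rows <- lapply(seq_len(nrow(thermo)), function(i) {
    pr <- cnt_params(dmu = thermo$dmu[i], gamma_hom = gamma_hom,
                     dgamma = thermo$dgamma_N[i], tau = tau, l_line = l_line,
                     line_exponent = line_exponent)
    het <- tryCatch(cnt_barrier(pr, "het"), error = function(e) NULL)
    hom <- tryCatch(cnt_barrier(pr, "hom"), error = function(e) NULL)
    if (is.null(het) || is.null(hom)) {
      stop("missing barrier at T = ", thermo$temp_K[i], " K")
    }
    data.frame(temp_K = thermo$temp_K[i], dmu = thermo$dmu[i],
               dg_het = het$dg_star, dg_hom = hom$dg_star,
               f = het$dg_star / hom$dg_star)
  })
  tab <- do.call(rbind, rows)
  fit <- if (nrow(tab) > fit_degree) {
    stats::lm(f ~ poly(temp_K, fit_degree, raw = TRUE), data = tab)
  }
  structure(list(table = tab, fit = fit), class = "potency_result")
}
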