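#' Default run configuration
#'
#' Central registry of every stage parameter with its default. Values mirror
#' the package-wide conventions: lengths in nm, times in ns, energies in
#' kJ/mol, angles in degrees.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "afpice_out",
    stages = c("generate", "classify", "nucleus"),
    periodic_xy_only = FALSE,
    water_resnames = c("SOL", "HOH", "WAT", "TIP6"),
    generate = list(kind = "ih", n_molecules = 100L, box = c(3, 3, 3),
                    d_oo = 0.275, repeats = c(2, 2, 2), n_cluster = 30L,
                    n_waters = 8L, dipole_mode = "perpendicular",
                    n0 = 50, n_c = 38, k = 0.1, sigma = 2,
                    duration = 10, dt = 0.05,
                    n_pairs = 1000L, lambda = 0.0107, reform = 0,
                    interval = 0.1),
    classify = list(input = NULL, neighbor_cutoff = 0.35,
                    staggered_max = -0.8, eclipsed_range = c(-0.35, 0.25)),
    nucleus = list(input = NULL, link_cutoff = 0.35),
    hbond = list(input = NULL, r_oo = 0.35, angle_max = 30,
                 window = 50, gamma_window = 20),
    profiles = list(input = NULL, bin_width = 0.02, angle_bin = 2,
                    axis = "x", surface_z = NULL, slab_thickness = 0.35,
                    n_layers = 3L),
    geometry = list(input = NULL, a_ice = 0.73, b_ice = 0.45),
    seeding = list(input = NULL, threshold = 2),
    cnt = list(input = NULL, gamma_hom = NULL, n_star_hom = 80,
               tau = 5, l_line = 1, line_exponent = 1/3, fit_degree = 2)
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration file and merges it over [default_config()]
#' (file values win; unknown keys are rejected). `run_config(NULL)` returns
#' the defaults.
#'
#' @param path YAML file path, or `NULL`.
#' @param overrides optional named list merged over the file values.
#' @return nested named list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  merge_in <- function(base, upd, where = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base)) {
        stop("config error: unknown key '", paste0(where, nm), "'")
      }
      if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]], paste0(where, nm, "."))
      } else {
        base[nm] <- list(upd[[nm]])  # keeps explicit NULLs
      }
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_in(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_in(cfg, overrides)
  structure(cfg, class = c("run_config", "list"))
}

#' Write a configuration to YAML
#'
#' The write/read round trip is lossless for every default parameter.
#'
#' @param config a [run_config()] (or plain list).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
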