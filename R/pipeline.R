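#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing one CSV/JSON
#' result set per stage into `config$outdir`, plus a log of parameters,
#' inputs and the seed. Stages that consume a structure or series fall back
#' to the output of the `generate` stage when no explicit input is
#' configured, and raise a dependency error naming the stage otherwise.
#'
#' Stage outputs:
#' \describe{
#'   \item{generate}{`generated.gro` (structures) or `generated_series.csv` /
#'     `generated_events.csv` (series kinds).}
#'   \item{classify}{`classify.csv`: frame, time, molid, q6, label.}
#'   \item{nucleus}{`nucleus.csv`: time, n; `nucleus_members.json`.}
#'   \item{hbond}{`hbond_curve.csv`: lag, value, count; `hbond_summary.json`
#'     with Gamma_HB.}
#'   \item{profiles}{`dipole.csv`, `density_xy.csv`.}
#'   \item{geometry}{`geometry.json` lattice-match report,
#'     `geometry_pairs.csv`.}
#'   \item{seeding}{`seeding.json` estimate, `seeding_slopes.csv`.}
#'   \item{cnt}{`cnt_barriers.json`, `cnt_curve.csv`, `cnt_potency.csv`.}
#' }
#'
#' @param config a [run_config()] (or the path of a YAML config file).
#' @return named list of per-stage output file paths, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- run_config(config)
  order_all <- c("generate", "classify", "nucleus", "hbond", "profiles",
                 "geometry", "seeding", "cnt")
  unknown <- setdiff(config$stages, order_all)
  if (length(unknown)) {
    stop("config error: unknown stage(s): ", paste(unknown, collapse = ", "))
  }
  stages <- order_all[order_all %in% config$stages]
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "pipeline.log")
  cat(sprintf("afpice %s | seed %d | stages: %s\n",
              as.character(utils::packageVersion("afpice")), config$seed,
              paste(stages, collapse = ", ")),
      file = logfile)
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logfile, append = TRUE)
  outputs <- list()
  state <- new.env()

  structure_input <- function(stage) {
    p <- config[[stage]]$input
    if (!is.null(p)) return(p)
    if (!is.null(state$generated_structure)) return(state$generated_structure)
    stop("dependency error: stage '", stage,
         "' needs an input structure; configure ", stage,
         ".input or run the generate stage first")
  }

  for (st in stages) {
    set.seed(config$seed)
    log_line("stage %s: params %s", st,
             paste(utils::capture.output(utils::str(config[[st]], give.head = FALSE)),
                   collapse = " "))
    outputs[[st]] <- switch(st,
      generate = .stage_generate(config, outdir, state),
      classify = .stage_classify(config, outdir, structure_input("classify")),
      nucleus  = .stage_nucleus(config, outdir, structure_input("nucleus")),
      hbond    = .stage_hbond(config, outdir, state),
      profiles = .stage_profiles(config, outdir, structure_input("profiles")),
      geometry = .stage_geometry(config, outdir),
      seeding  = .stage_seeding(config, outdir, state),
      cnt      = .stage_cnt(config, outdir)
    )
    for (f in outputs[[st]]) {
      if (file.exists(f)) log_line("stage %s: wrote %s (md5 %s)", st, f,
                                   unname(tools::md5sum(f)))
    }
  }
  invisible(outputs)
}

.stage_generate <- function(config, outdir, state) {
  g <- config$generate
  kind <- g$kind
  if (kind %in% c("ih", "ic", "liquid", "embedded", "cw-chain")) {
    frame <- switch(kind,
      ih = build_ice_lattice("ih", g$d_oo, g$repeats, seed = config$seed),
      ic = build_ice_lattice("ic", g$d_oo, g$repeats, seed = config$seed),
      liquid = build_liquid_box(g$n_molecules, g$box, seed = config$seed),
      embedded = embed_nucleus(
        build_liquid_box(g$n_molecules, g$box, seed = config$seed),
        g$n_cluster, seed = config$seed)$frame,
      `cw-chain` = build_cw_chain(g$n_waters, dipole_mode = g$dipole_mode,
                                  seed = config$seed)
    )
    path <- file.path(outdir, "generated.gro")
    write_structure(frame, path)
    state$generated_structure <- path
    path
  } else if (kind == "nucleus-series") {
    s <- simulate_nucleus_series(g$n0, g$n_c, g$k, g$sigma, g$duration, g$dt,
                                 seed = config$seed)
    path <- file.path(outdir, "generated_series.csv")
    utils::write.csv(data.frame(time = s$times, n = s$n), path, row.names = FALSE)
    state$generated_series <- path
    path
  } else if (kind == "bond-events") {
    ev <- simulate_bond_events(g$n_pairs, g$lambda, g$reform, g$duration,
                               g$interval, seed = config$seed)
    path <- file.path(outdir, "generated_events.csv")
    df <- as.data.frame(ev$events * 1L)
    names(df) <- sprintf("t%g", ev$times)
    utils::write.csv(df, path, row.names = FALSE)
    state$generated_events <- path
    path
  } else {
    stop("config error: unknown generate kind '", kind, "'")
  }
}

.stage_classify <- function(config, outdir, input) {
  trj <- read_trajectory(input)
  p <- config$classify
  rows <- lapply(seq_along(trj$frames), function(i) {
    lab <- classify_ice(trj$frames[[i]], p$neighbor_cutoff, p$staggered_max,
                        p$eclipsed_range, .periodic(config))
    data.frame(frame = i - 1L, time = trj$times[i], molid = lab$molid,
               q6 = lab$q6, label = as.character(lab$label))
  })
  path <- file.path(outdir, "classify.csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  path
}

.stage_nucleus <- function(config, outdir, input) {
  trj <- read_trajectory(input)
  p <- config$nucleus
  ns <- nucleus_timeseries(trj, config$classify$neighbor_cutoff, p$link_cutoff,
                           config$classify$staggered_max,
                           config$classify$eclipsed_range, .periodic(config))
  path <- file.path(outdir, "nucleus.csv")
  utils::write.csv(data.frame(time = ns$times, n = ns$n), path, row.names = FALSE)
  jpath <- file.path(outdir, "nucleus_members.json")
  jsonlite::write_json(ns$members, jpath)
  c(path, jpath)
}

.stage_hbond <- function(config, outdir, state) {
  p <- config$hbond
  input <- p$input
  if (is.null(input)) input <- state$generated_events
  if (is.null(input)) {
    stop("dependency error: stage 'hbond' needs an event table; configure ",
         "hbond.input or generate kind 'bond-events' first")
  }
  df <- utils::read.csv(input, check.names = FALSE)
  times <- as.numeric(sub("^t", "", names(df)))
  ev <- as.matrix(df) > 0
  curve <- intermittent_correlation(ev, times, window = min(p$window, max(times)))
  g <- gamma_hb(curve, window = min(p$gamma_window, max(curve$lags)))
  path <- file.path(outdir, "hbond_curve.csv")
  utils::write.csv(data.frame(lag = curve$lags, value = curve$values,
                              count = curve$counts), path, row.names = FALSE)
  jpath <- file.path(outdir, "hbond_summary.json")
  jsonlite::write_json(list(gamma_hb = g, window = curve$window,
                            gamma_window = min(p$gamma_window, max(curve$lags))),
                       jpath, auto_unbox = TRUE, digits = NA)
  c(path, jpath)
}

.stage_profiles <- function(config, outdir, input) {
  trj <- read_trajectory(input)
  p <- config$profiles
  dd <- dipole_distribution(trj, p$axis, bin_width = p$angle_bin)
  path <- file.path(outdir, "dipole.csv")
  utils::write.csv(data.frame(theta = dd$theta_mids, p = dd$p), path, row.names = FALSE)
  dm <- density_map_xy(trj, bin_width = p$bin_width)
  dpath <- file.path(outdir, "density_xy.csv")
  utils::write.csv(dm$counts, dpath, row.names = FALSE)
  c(path, dpath)
}

.stage_geometry <- function(config, outdir) {
  p <- config$geometry
  frame <- if (is.null(p$input)) {
    build_synthetic_ibs(seed = config$seed)
  } else {
    read_structure(p$input)
  }
  rep <- hydroxyl_lattice_spacing(frame, a_ice = p$a_ice, b_ice = p$b_ice)
  jpath <- file.path(outdir, "geometry.json")
  jsonlite::write_json(rep[c("a_oh", "b_oh", "a_ice", "b_ice", "dev_a", "dev_b")],
                       jpath, auto_unbox = TRUE, digits = NA)
  cpath <- file.path(outdir, "geometry_pairs.csv")
  utils::write.csv(data.frame(
    kind = c(rep("cross_row", length(rep$a_pairs)),
             rep("along_row", length(rep$b_pairs))),
    d_oo = c(rep$a_pairs, rep$b_pairs)), cpath, row.names = FALSE)
  c(jpath, cpath)
}

.stage_seeding <- function(config, outdir, state) {
  p <- config$seeding
  if (is.null(p$input)) {
    stop("dependency error: stage 'seeding' needs a directory of (time, n) ",
         "CSVs with an index.csv mapping file -> n0; configure seeding.input")
  }
  idx <- utils::read.csv(file.path(p$input, "index.csv"))
  groups <- lapply(split(idx$file, idx$n0), function(files) {
    lapply(files, function(fl) {
      df <- utils::read.csv(file.path(p$input, fl))
      nucleus_series(df$time, df$n)
    })
  })
  est <- critical_size(seeding_ensemble(groups), threshold = p$threshold)
  jpath <- file.path(outdir, "seeding.json")
  jsonlite::write_json(list(n_star = est$n_star,
                            bracket = as.list(est$bracket)),
                       jpath, auto_unbox = TRUE, digits = NA)
  cpath <- file.path(outdir, "seeding_slopes.csv")
  utils::write.csv(est$table, cpath, row.names = FALSE)
  c(jpath, cpath)
}

.stage_cnt <- function(config, outdir) {
  p <- config$cnt
  input <- p$input
  if (is.null(input)) {
    input <- system.file("extdata", "table1.tsv", package = "afpice")
  }
  thermo <- load_thermo_table(input)
  gamma_hom <- p$gamma_hom
  if (is.null(gamma_hom)) {
    gamma_hom <- calibrate_gamma_hom(p$n_star_hom, thermo$dmu[1])
  }
  barriers <- lapply(seq_len(nrow(thermo)), function(i) {
    pr <- cnt_params(thermo$dmu[i], gamma_hom = gamma_hom,
                     dgamma = thermo$dgamma_N[i], tau = p$tau,
                     l_line = p$l_line, line_exponent = p$line_exponent)
    hom <- cnt_barrier(pr, "hom"); het <- cnt_barrier(pr, "het")
    list(temp_K = thermo$temp_K[i], dmu = thermo$dmu[i],
         n_star_hom = hom$n_star, dg_star_hom = hom$dg_star,
         n_star_het = het$n_star, dg_star_het = het$dg_star)
  })
  jpath <- file.path(outdir, "cnt_barriers.json")
  jsonlite::write_json(barriers, jpath, auto_unbox = TRUE, digits = NA)
  n <- seq_len(200)
  pr1 <- cnt_params(thermo$dmu[1], gamma_hom = gamma_hom,
                    dgamma = thermo$dgamma_N[1], tau = p$tau,
                    l_line = p$l_line, line_exponent = p$line_exponent)
  cpath <- file.path(outdir, "cnt_curve.csv")
  utils::write.csv(data.frame(n = n,
                              dg_hom = free_energy_curve(pr1, "hom", n),
                              dg_het = free_energy_curve(pr1, "het", n)),
                   cpath, row.names = FALSE)
  pf <- potency_factor(thermo, gamma_hom, p$tau, p$l_line, p$line_exponent,
                       p$fit_degree)
  fpath <- file.path(outdir, "cnt_potency.csv")
  utils::write.csv(pf$table, fpath, row.names = FALSE)
  c(jpath, cpath, fpath)
}

.periodic <- function(config) {
  if (isTRUE(config$periodic_xy_only)) c(TRUE, TRUE, FALSE) else rep(TRUE, 3)
}
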