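test_that("geometric criterion accepts and rejects water dimers", {
  expect_equal(nrow(detect_hbonds(water_dimer(0.28, 0))), 1L)
  expect_equal(nrow(detect_hbonds(water_dimer(0.40, 0))), 0L)   # beyond cutoff
  expect_equal(nrow(detect_hbonds(water_dimer(0.28, 45))), 0L)  # bad angle
  expect_equal(nrow(detect_hbonds(water_dimer(0.28, 25))), 1L)
  expect_error(hbond_criteria(r_oo = -1), "positive")
})

test_that("ideal ice Ih carries four hydrogen bonds per molecule", {
  f <- build_ice_lattice("ih", repeats = c(3, 2, 2), seed = 6)
  hb <- detect_hbonds(f)
  n_mol <- nrow(water_molecules(f))
  expect_equal(2 * nrow(hb) / n_mol, 4)
})

test_that("hbond detection is rotation invariant", {
  f <- isolated_ice_cluster(40, seed = 7)
  n0 <- nrow(detect_hbonds(f))
  expect_gt(n0, 0)
  set.seed(5)
  fr <- rotate_frame(f, random_rotation())
  expect_equal(nrow(detect_hbonds(fr)), n0)
})

test_that("intermittent correlation reproduces analytic limits", {
  # permanent bonds: identically 1
  ev <- simulate_bond_events(100, lambda = 0, duration = 10, interval = 1)
  cv <- intermittent_correlation(ev$events, ev$times)
  expect_true(all(cv$values == 1))
  expect_equal(cv$values[1], 1)  # C_H(0) = 1 exactly
  # Poisson breakage, no reformation: e^(-lambda t) within 3 binomial sigma
  lam <- 0.0107
  ev2 <- simulate_bond_events(10000, lam, duration = 20, interval = 0.5, seed = 31)
  cv2 <- intermittent_correlation(ev2$events, ev2$times)
  expected <- exp(-lam * cv2$lags)
  sig <- sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(cv2$values - expected) <= 3 * sig + 1e-12))
  # log-linear fit recovers lambda within 5%
  fit <- stats::lm(log(cv2$values[-1]) ~ cv2$lags[-1])
  expect_equal(unname(-stats::coef(fit)[2]), lam, tolerance = 0.05)
  # no initial bonds -> error
  ev3 <- ev2
  ev3$events[, 1] <- FALSE
  expect_error(intermittent_correlation(ev3$events, ev3$times), "no bonds")
})

test_that("gamma_hb integrates curves correctly", {
  lags <- seq(0, 20, by = 0.5)
  one <- correlation_curve(lags, rep(1, length(lags)), rep(10, length(lags)), 20)
  expect_equal(gamma_hb(one), 1)
  tri <- correlation_curve(lags, 1 - lags / 20, rep(10, length(lags)), 20)
  expect_equal(gamma_hb(tri), 0.5)
  # exponential with lambda T = 0.214: (1 - e^-x)/x at x = 0.214
  lam <- 0.0107
  expc <- correlation_curve(lags, exp(-lam * lags), rep(10, length(lags)), 20)
  expect_equal(gamma_hb(expc), (1 - exp(-0.214)) / 0.214, tolerance = 1e-4)
  expect_equal((1 - exp(-0.214)) / 0.214, 0.90, tolerance = 0.005)
  # bounded by the curve's range
  set.seed(2)
  vals <- stats::runif(length(lags))
  vals[1] <- 1
  rnd <- correlation_curve(lags, vals, rep(10, length(lags)), 20)
  g <- gamma_hb(rnd)
  expect_gte(g, min(vals)); expect_lte(g, max(vals))
  expect_error(gamma_hb(one, window = 0), "positive")
})

test_that("residence correlation is an absorbing survival curve", {
  # stationary molecules never leave
  f <- three_water_frame()
  trj <- md_trajectory(rep(list(f), 10), times = 0:9)
  region <- list(min = c(0, 0, 0), max = c(3, 3, 3))
  cr <- residence_correlation(trj, region)
  expect_true(all(cr$values == 1))
  # all depart at frame 4 (t = 3): step from 1 to 0
  frames <- lapply(0:9, function(t) {
    g <- three_water_frame(box = c(30, 30, 30))
    if (t >= 3) g$positions[, 1] <- g$positions[, 1] + 20
    g$time <- t
    g
  })
  trj2 <- md_trajectory(frames)
  region2 <- list(min = c(0, 0, 0), max = c(5, 5, 5))
  cr2 <- residence_correlation(trj2, region2)
  expect_equal(cr2$values, c(1, 1, 1, rep(0, 7)))
  expect_true(all(diff(cr2$values) <= 0))
  # once out, return does not count (absorbing)
  frames3 <- frames
  frames3[[6]]$positions[, 1] <- frames3[[6]]$positions[, 1] - 20
  cr3 <- residence_correlation(md_trajectory(frames3), region2)
  expect_true(all(diff(cr3$values) <= 0))
  expect_error(residence_correlation(trj2, list(min = c(25, 25, 25),
                                                max = c(26, 26, 26))),
               "empty")
})

test_that("poisson exits give exponential residence decay", {
  # molecules leave at rate lambda: place each molecule outside from its
  # sampled exit frame onward
  set.seed(17)
  lam <- 0.2
  n <- 2000
  times <- seq(0, 10, by = 0.5)
  exit <- stats::rexp(n, lam)
  base <- md_frame(matrix(rep(c(1, 1, 1), n), ncol = 3, byrow = TRUE) +
                     cbind(stats::runif(n, -0.3, 0.3), stats::runif(n, -0.3, 0.3),
                           stats::runif(n, -0.3, 0.3)),
                   c(40, 40, 40),
                   data.frame(name = "OW", resname = "SOL", resid = seq_len(n),
                              molid = seq_len(n) - 1L))
  # attach hydrogens so water recognition works
  addH <- function(fr) {
    pos <- NULL; atoms <- NULL
    for (i in seq_len(n)) {
      o <- fr$positions[i, ]
      pos <- rbind(pos, o, o + c(0.0957, 0, 0), o + c(-0.024, 0.0927, 0))
      atoms <- rbind(atoms, data.frame(name = c("OW", "HW1", "HW2"),
                                       resname = "SOL", resid = i,
                                       molid = i - 1L))
    }
    md_frame(pos, fr$box, atoms, fr$time)
  }
  frames <- lapply(times, function(t) {
    fr <- base
    out <- exit <= t
    fr$positions[out, 1] <- fr$positions[out, 1] + 30
    fr$time <- t
    addH(fr)
  })
  cr <- residence_correlation(md_trajectory(frames),
                              list(min = c(0, 0, 0), max = c(5, 5, 5)))
  expected <- exp(-lam * cr$lags)
  sig <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(cr$values - expected) <= 3 * sig + 1e-12))
})

test_that("occupancy counts molecules inside the region per frame", {
  f <- three_water_frame()
  trj <- md_trajectory(rep(list(f), 4), times = 0:3)
  region <- list(min = c(0, 0, 0), max = c(3, 3, 3))
  occ <- occupancy_series(trj, region)
  expect_equal(occ$counts, rep(3L, 4))
  expect_equal(occ$mean, 3)
  empty <- occupancy_series(trj, list(min = c(2.9, 2.9, 2.9), max = c(3, 3, 3)))
  expect_equal(empty$mean, 0)
  # alternate frames 2 and 4 inside -> mean 3
  frames <- lapply(0:3, function(t) {
    g <- three_water_frame()
    if (t %% 2 == 1) g$positions[7:9, ] <- g$positions[7:9, ] - 10  # 2 inside
    g$time <- t
    g
  })
  occ2 <- occupancy_series(md_trajectory(frames), region)
  expect_equal(occ2$counts, c(3L, 2L, 3L, 2L))
  # trajectory-level event matrix feeds the correlation machinery
  dim_tr <- md_trajectory(rep(list(water_dimer(0.28, 0)), 3), times = 0:2)
  bem <- bond_event_matrix(dim_tr)
  expect_equal(dim(bem$events), c(1L, 3L))
  expect_true(all(bem$events))
})
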