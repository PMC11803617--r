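test_that("density map conserves counts and localizes stationary molecules", {
  f <- three_water_frame()
  trj <- md_trajectory(rep(list(f), 10), times = 0:9)
  dm <- density_map_xy(trj, bin_width = 0.1)
  expect_equal(sum(dm$counts), 10 * 3)
  expect_equal(sort(dm$counts[dm$counts > 0]), rep(10, 3))
  expect_equal(dm$frames, 10)
})

test_that("uniform positions produce no outlier bins", {
  set.seed(23)
  n <- 5000
  pos <- NULL; atoms <- NULL
  for (i in seq_len(n)) {
    o <- stats::runif(3) * 3
    pos <- rbind(pos, o, o + c(0.0957, 0, 0), o + c(-0.024, 0.0927, 0))
    atoms <- rbind(atoms, data.frame(name = c("OW", "HW1", "HW2"),
                                     resname = "SOL", resid = i, molid = i - 1L))
  }
  f <- md_frame(pos, c(3, 3, 3), atoms)
  dm <- density_map_xy(md_trajectory(list(f)), bin_width = 0.5)
  mu <- mean(dm$counts)
  expect_true(all(abs(dm$counts - mu) <= 4 * sqrt(mu)))
})

test_that("peak spacing recovers printed and generated site spacings", {
  pk <- profile_peak_spacing(rep(c(2.91, 3.37, 3.82), each = 50))
  expect_equal(pk$peaks, c(2.91, 3.37, 3.82), tolerance = 1e-9)
  expect_equal(pk$spacings, c(0.46, 0.45), tolerance = 1e-9)
  expect_equal(pk$mean_spacing, 0.455, tolerance = 1e-9)
  expect_error(profile_peak_spacing(rep(1, 100)), "insufficient peaks")
  # noiseless chains of 3..20 sites: spacing within one bin width
  for (ns in c(3, 8, 20)) {
    ch <- build_cw_chain(ns, seed = ns)
    wm <- water_molecules(ch)
    got <- profile_peak_spacing(ch$positions[wm$O, 1])$mean_spacing
    expect_equal(got, sqrt(8 / 3) * 0.275, tolerance = 0.02)
  }
})

test_that("dipole distributions match constructed orientations", {
  al <- build_cw_chain(50, dipole_mode = "aligned")
  trj <- md_trajectory(list(al))
  d <- dipole_distribution(trj, axis = "x")
  expect_equal(d$mean_theta, 0, tolerance = 1e-6)
  pe <- build_cw_chain(200, dipole_mode = "perpendicular", seed = 3)
  dp <- dipole_distribution(md_trajectory(list(pe)), axis = "x")
  expect_equal(dp$mean_theta, 90, tolerance = 1e-6)
  # normalization: sum(P dtheta) = 1
  expect_equal(sum(dp$p) * 2, 1, tolerance = 1e-12)
  # isotropic dipoles: P(theta) ~ sin(theta), mean 90 within estimator error
  iso <- build_cw_chain(4000, dipole_mode = "isotropic", seed = 4)
  di <- dipole_distribution(md_trajectory(list(iso)), axis = "x", bin_width = 10)
  expect_equal(di$mean_theta, 90, tolerance = 2)
  expected <- sin(di$theta_mids * pi / 180)
  expected <- expected / (sum(expected) * 10)
  counts <- di$p * 10 * di$n
  sig <- sqrt(pmax(expected * 10 * di$n, 1))
  expect_true(all(abs(counts - expected * 10 * di$n) <= 3 * sig))
})

test_that("layer partition assigns slabs by z offset", {
  pos <- NULL; atoms <- NULL
  zs <- c(0.1, 0.5, 0.9, -0.1)
  for (i in seq_along(zs)) {
    o <- c(1, 1, 1 + zs[i])
    pos <- rbind(pos, o, o + c(0.0957, 0, 0), o + c(-0.024, 0.0927, 0))
    atoms <- rbind(atoms, data.frame(name = c("OW", "HW1", "HW2"),
                                     resname = "SOL", resid = i, molid = i - 1L))
  }
  f <- md_frame(pos, c(3, 3, 3), atoms)
  lp <- partition_layers(f, surface_z = 1, slab_thickness = 0.35, n_layers = 3)
  expect_equal(lp$layer, c(0L, 1L, 2L, NA))
  expect_equal(lp$boundaries, 1 + 0.35 * (0:3))
  expect_error(partition_layers(f, surface_z = 5), "outside")
  expect_warning(partition_layers(f, surface_z = 2.5), "beyond")
})

test_that("layer q6 separates ordered from disordered layers", {
  # layer 0: ideal lattice slab; layer 2: random liquid slab
  lat <- build_ice_lattice("ih", repeats = c(3, 3, 1), seed = 5)
  wm <- water_molecules(lat)
  box <- c(lat$box[1], lat$box[2], 3)
  idx <- as.vector(t(cbind(wm$O, wm$H1, wm$H2)))
  pos_l <- lat$positions[idx, ]
  pos_l[, 3] <- pos_l[, 3] + 0.05
  liq <- build_liquid_box(25, box = c(box[1], box[2], 0.33), seed = 6)
  wl <- water_molecules(liq)
  idx2 <- as.vector(t(cbind(wl$O, wl$H1, wl$H2)))
  pos_q <- liq$positions[idx2, ]
  pos_q[, 3] <- pos_q[, 3] + 0.75
  n1 <- nrow(wm); n2 <- nrow(wl)
  molid <- rep(seq_len(n1 + n2) - 1L, each = 3L)
  f <- md_frame(rbind(pos_l, pos_q), box,
                data.frame(name = rep(c("OW", "HW1", "HW2"), n1 + n2),
                           resname = "SOL", resid = molid + 1L, molid = molid))
  trj <- md_trajectory(rep(list(f), 2), times = 0:1)
  lq <- layer_q6_timeseries(trj, surface_z = 0, slab_thickness = 0.35,
                            n_layers = 3, periodic = c(TRUE, TRUE, FALSE))
  m0 <- lq$mean_q6[lq$layer == 0 & lq$time == 0]
  m2 <- lq$mean_q6[lq$layer == 2 & lq$time == 0]
  expect_gt(m0, m2)
  # static trajectory: series constant over time
  expect_equal(lq$mean_q6[lq$time == 0], lq$mean_q6[lq$time == 1])
})

test_that("projected distances report signed nearest-partner offsets", {
  mk <- function(ys_a, ys_b) {
    pos <- NULL; atoms <- NULL
    i <- 0L
    for (y in ys_a) {
      i <- i + 1L
      pos <- rbind(pos, c(1, y, 1))
      atoms <- rbind(atoms, data.frame(name = "CW", resname = "CWR", resid = i,
                                       molid = i - 1L))
    }
    for (y in ys_b) {
      i <- i + 1L
      pos <- rbind(pos, c(1, y, 1))
      atoms <- rbind(atoms, data.frame(name = "OG1", resname = "THR", resid = i,
                                       molid = i - 1L))
    }
    md_frame(pos, c(10, 10, 10), atoms)
  }
  f <- mk(1.0, 0.8)
  trj <- md_trajectory(list(f))
  sel_a <- function(fr) select_atoms(fr, name = "CW")
  sel_b <- function(fr) select_atoms(fr, name = "OG1")
  pd <- projected_distance_distribution(trj, sel_a, sel_b, axis = "y")
  expect_equal(pd$values, 0.2, tolerance = 1e-12)
  # symmetric placements average to zero
  f2 <- mk(c(0.8, 1.2), 1.0)
  pd2 <- projected_distance_distribution(md_trajectory(list(f2)), sel_a, sel_b, "y")
  expect_equal(pd2$mean, 0, tolerance = 1e-12)
  # jittered fixture recovers the generator sigma within 10%
  set.seed(33)
  f3 <- mk(1.5 + stats::rnorm(10000, sd = 0.05), 1.5)
  pd3 <- projected_distance_distribution(md_trajectory(list(f3)), sel_a, sel_b, "y")
  expect_equal(pd3$sd, 0.05, tolerance = 0.1)
  expect_error(projected_distance_distribution(trj, function(fr) integer(),
                                               sel_b, "y"), "empty selection")
})
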