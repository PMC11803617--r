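test_that("ice Ih lattice reproduces closed-form wurtzite geometry", {
  f <- build_ice_lattice("ih", d_oo = 0.275, repeats = c(3, 2, 2), seed = 1)
  wm <- water_molecules(f)
  o <- f$positions[wm$O, , drop = FALSE]
  # every oxygen has exactly 4 neighbors at d_oo
  dm <- afpice:::pairwise_min_image(o, f$box)
  diag(dm) <- Inf
  nn <- rowSums(dm <= 0.30)
  expect_true(all(nn == 4L))
  expect_equal(min(dm), 0.275, tolerance = 1e-9)
  nd <- dm[dm <= 0.30]
  expect_true(all(abs(nd - 0.275) < 1e-6))
  # basal in-row repeat sqrt(8/3) d and c-axis repeat (8/3) d
  expect_equal(f$box[1] / 3, sqrt(8 / 3) * 0.275, tolerance = 1e-12)
  expect_equal(f$box[3] / 2, (8 / 3) * 0.275, tolerance = 1e-12)
  # measured from coordinates: x-spacing within one basal row
  row_sel <- abs(o[, 2] - o[1, 2]) < 1e-6 & abs(o[, 3] - o[1, 3]) < 1e-6
  xs <- sort(o[row_sel, 1])
  expect_equal(mean(diff(xs)), sqrt(8 / 3) * 0.275, tolerance = 1e-9)
})

test_that("ice Ic lattice is diamond cubic with 4 neighbors at d_oo", {
  f <- build_ice_lattice("ic", d_oo = 0.275, repeats = c(2, 2, 2), seed = 1)
  wm <- water_molecules(f)
  o <- f$positions[wm$O, , drop = FALSE]
  dm <- afpice:::pairwise_min_image(o, f$box)
  diag(dm) <- Inf
  expect_true(all(rowSums(dm <= 0.30) == 4L))
  expect_true(all(abs(dm[dm <= 0.30] - 0.275) < 1e-6))
  expect_equal(f$box[1] / 2, 4 * 0.275 / sqrt(3), tolerance = 1e-12)
})

test_that("ice rules hold for every proton-disorder seed", {
  for (sd in 1:20) {
    f <- build_ice_lattice("ih", repeats = c(2, 2, 1), seed = sd)
    wm <- water_molecules(f)
    o <- f$positions[wm$O, , drop = FALSE]
    # 2 covalent H per O by construction of the frame; check H placement:
    # every H sits on an O-O link, and every link carries exactly one H
    dm <- afpice:::pairwise_min_image(o, f$box)
    diag(dm) <- Inf
    links <- which(dm <= 0.30 & upper.tri(dm), arr.ind = TRUE)
    h_on_link <- integer(nrow(links))
    hpos <- f$positions[c(wm$H1, wm$H2), , drop = FALSE]
    hmol <- rep(seq_len(nrow(wm)), 2)
    for (r in seq_len(nrow(links))) {
      i <- links[r, 1]; j <- links[r, 2]
      # an H belongs to this link if it is covalent to i or j and lies
      # within 0.20 nm of the other oxygen
      cand <- which(hmol %in% c(i, j))
      dists_i <- minimum_image_distance(hpos[cand, , drop = FALSE],
                                        o[rep(i, length(cand)), , drop = FALSE], f$box)
      dists_j <- minimum_image_distance(hpos[cand, , drop = FALSE],
                                        o[rep(j, length(cand)), , drop = FALSE], f$box)
      on_link <- (hmol[cand] == i & dists_j < 0.20) | (hmol[cand] == j & dists_i < 0.20)
      h_on_link[r] <- sum(on_link)
    }
    expect_true(all(h_on_link == 1L), label = paste("one H per link, seed", sd))
  }
})

test_that("generators are deterministic under a fixed seed", {
  expect_equal(build_ice_lattice("ih", seed = 7)$positions,
               build_ice_lattice("ih", seed = 7)$positions)
  expect_equal(build_liquid_box(50, seed = 7)$positions,
               build_liquid_box(50, seed = 7)$positions)
  s1 <- simulate_nucleus_series(50, 38, seed = 7)
  s2 <- simulate_nucleus_series(50, 38, seed = 7)
  expect_equal(s1$n, s2$n)
  e1 <- simulate_bond_events(100, 0.1, duration = 5, seed = 7)
  e2 <- simulate_bond_events(100, 0.1, duration = 5, seed = 7)
  expect_equal(e1$events, e2$events)
})

test_that("liquid box respects the minimum O-O distance and density limits", {
  f <- build_liquid_box(100, box = c(3, 3, 3), seed = 3)
  wm <- water_molecules(f)
  expect_equal(nrow(wm), 100L)
  dm <- afpice:::pairwise_min_image(f$positions[wm$O, ], f$box)
  diag(dm) <- Inf
  expect_gte(min(dm), 0.26)
  expect_error(build_liquid_box(500, box = c(1, 1, 1), seed = 1,
                                max_attempts = 200), "packing failure")
})

test_that("embedded nucleus is recovered by downstream clustering", {
  liq <- build_liquid_box(150, box = c(4, 4, 4), seed = 5)
  emb <- embed_nucleus(liq, 60, seed = 5)
  expect_length(emb$inserted, 60L)
  lab <- classify_ice(emb$frame)
  nuc <- largest_nucleus(lab, emb$frame)
  # the cluster core (interior molecules of the carved sphere) must appear;
  # surface members classify interfacial and are excluded by design
  expect_gte(nuc$n, 5)
  expect_true(all(nuc$members %in% emb$inserted))
  # identity for n_cluster = 0
  emb0 <- embed_nucleus(liq, 0)
  expect_identical(emb0$frame$positions, liq$positions)
  expect_length(emb0$inserted, 0L)
})

test_that("channel-water chain has exact spacing and dipole geometry", {
  ch <- build_cw_chain(3, seed = 1)
  wm <- water_molecules(ch)
  x <- ch$positions[wm$O, 1] - ch$positions[wm$O[1], 1]
  expect_equal(x, c(0, 1, 2) * sqrt(8 / 3) * 0.275, tolerance = 1e-12)
  # aligned: all dipole angles to the axis are 0
  al <- build_cw_chain(5, dipole_mode = "aligned")
  d <- dipole_vectors(al)
  expect_equal(unname(drop(d %*% c(1, 0, 0))), rep(1, 5), tolerance = 1e-9)
  # perpendicular: all angles are 90 degrees
  pe <- build_cw_chain(5, dipole_mode = "perpendicular", seed = 2)
  dp <- dipole_vectors(pe)
  expect_equal(unname(drop(dp %*% c(1, 0, 0))), rep(0, 5), tolerance = 1e-9)
  expect_error(build_cw_chain(1), "n_waters")
})

test_that("nucleus-series drift has the seeding sign structure", {
  # zero noise: strictly increasing above n_c, constant at n_c
  up <- simulate_nucleus_series(50, 38, k = 0.5, sigma = 0, duration = 5)
  expect_true(all(diff(up$n) >= 0) && up$n[length(up$n)] > up$n[1])
  flat <- simulate_nucleus_series(38, 38, k = 0.5, sigma = 0, duration = 5)
  expect_true(all(flat$n == 38))
  expect_error(simulate_nucleus_series(10, 5, dt = 0), "dt")
  # Monte-Carlo sign check at 200 replicates per side
  set.seed(11)
  slope_of <- function(n0) {
    mean(vapply(1:200, function(i) {
      s <- simulate_nucleus_series(n0, 38)
      stats::coef(stats::lm(s$n ~ s$times))[2]
    }, numeric(1)))
  }
  expect_lt(slope_of(28), 0)
  expect_gt(slope_of(50), 0)
})

test_that("bond events follow the exponential survival law", {
  ev0 <- simulate_bond_events(50, lambda = 0, duration = 5, interval = 0.5)
  expect_true(all(ev0$events))
  ev1 <- simulate_bond_events(10, lambda = 0.5, duration = 0, interval = 0.1)
  expect_equal(ncol(ev1$events), 1L)
  expect_true(all(ev1$events[, 1]))
  expect_error(simulate_bond_events(10, 0.1, duration = 1, interval = 2),
               "interval")
  # survival within 3 binomial sigma of exp(-lambda t) at every frame
  lam <- 0.0107
  ev <- simulate_bond_events(10000, lam, duration = 20, interval = 1, seed = 9)
  surv <- colMeans(ev$events)
  expected <- exp(-lam * ev$times)
  sig <- sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(surv - expected) <= 3 * sig + 1e-12))
})
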