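# independent oracle: q6 by direct spherical-harmonic summation over a fixed
# set of neighbor directions (no shared code path with local_q6's neighbor
# machinery beyond the Ylm kernel, which is itself checked against FCC)
q6_of_directions <- function(dirs) {
  y <- afpice:::.ylm(6, dirs)
  q <- colMeans(y)
  sqrt(4 * pi / 13 * sum(Mod(q)^2))
}

test_that("q6 of an ideal FCC shell matches the known constant", {
  fcc <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
               c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
               c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1)) / sqrt(2)
  expect_equal(q6_of_directions(fcc), 0.57452, tolerance = 1e-4)
  # build an actual 13-molecule FCC cluster and run local_q6 on it
  o <- rbind(c(0, 0, 0), fcc * 0.3)
  pos <- NULL
  for (i in seq_len(nrow(o))) {
    pos <- rbind(pos, o[i, ], o[i, ] + c(0.0957, 0, 0), o[i, ] + c(-0.024, 0.0927, 0))
  }
  molid <- rep(seq_len(nrow(o)) - 1L, each = 3L)
  f <- md_frame(sweep(pos, 2, rep(2, 3), "+"), c(6, 6, 6),
                data.frame(name = rep(c("OW", "HW1", "HW2"), nrow(o)),
                           resname = "SOL", resid = molid + 1L, molid = molid))
  lq <- local_q6(f, neighbor_cutoff = 0.31)
  expect_equal(lq$q6[1], 0.57452, tolerance = 1e-4)
})

test_that("q6 is invariant under rotation, translation and relabeling", {
  fl <- build_ice_lattice("ih", repeats = c(3, 2, 2), seed = 2)
  # all interior molecules of the ideal (periodic) lattice share one q6
  expect_lt(diff(range(local_q6(fl)$q6)), 1e-6)
  # rotation acts on an isolated cluster (a periodic lattice cannot be
  # rotated without cutting its wrapped bonds)
  f <- isolated_ice_cluster(40, seed = 2)
  lq <- local_q6(f)
  set.seed(4)
  rot <- random_rotation()
  fr <- rotate_frame(f, rot)
  lqr <- local_q6(fr)
  expect_equal(sort(lqr$q6), sort(lq$q6), tolerance = 1e-10)
  # relabeling molecules leaves the multiset of q6 values unchanged
  wm <- water_molecules(f)
  perm <- sample(nrow(wm))
  idx <- as.vector(t(cbind(wm$O[perm], wm$H1[perm], wm$H2[perm])))
  molid <- rep(seq_len(nrow(wm)) - 1L, each = 3L)
  fp <- md_frame(f$positions[idx, ], f$box,
                 data.frame(name = rep(c("OW", "HW1", "HW2"), nrow(wm)),
                            resname = "SOL", resid = molid + 1L, molid = molid))
  expect_equal(sort(local_q6(fp)$q6), sort(lq$q6), tolerance = 1e-10)
})

test_that("classifier is exact on ideal lattices for any disorder seed", {
  for (sd in c(1, 13, 99)) {
    lab_h <- classify_ice(build_ice_lattice("ih", repeats = c(3, 2, 2), seed = sd))
    expect_true(all(lab_h$label == "HEX"), label = paste("Ih seed", sd))
    lab_c <- classify_ice(build_ice_lattice("ic", repeats = c(2, 2, 2), seed = sd))
    expect_true(all(lab_c$label == "CUBIC"), label = paste("Ic seed", sd))
  }
})

test_that("liquid false-positive rate is below 1% over 10 random boxes", {
  set.seed(21)
  total <- 0L; fp <- 0L
  for (b in 1:10) {
    f <- build_liquid_box(100, box = c(3, 3, 3), seed = 1000 + b)
    lab <- classify_ice(f)
    total <- total + nrow(lab)
    fp <- fp + sum(lab$label %in% c("HEX", "CUBIC"))
  }
  expect_lt(fp / total, 0.01)
})

test_that("largest nucleus matches brute-force components and handles PBC", {
  liq <- build_liquid_box(120, box = c(4, 4, 4), seed = 8)
  emb <- embed_nucleus(liq, 30, seed = 8)
  lab <- classify_ice(emb$frame)
  nuc <- largest_nucleus(lab, emb$frame)
  sel <- which(lab$label %in% c("HEX", "CUBIC"))
  o <- emb$frame$positions[attr(lab, "o_idx")[sel], , drop = FALSE]
  expect_equal(nuc$n, as.integer(brute_force_largest(o, emb$frame$box, 0.35)))
  # two separated clusters: the larger one wins
  liq2 <- build_liquid_box(60, box = c(6, 6, 6), seed = 9)
  e1 <- embed_nucleus(liq2, 30, center = c(1.5, 1.5, 1.5), seed = 9)
  e2 <- embed_nucleus(e1$frame, 12, center = c(4.5, 4.5, 4.5), seed = 10)
  lab2 <- classify_ice(e2$frame)
  nuc2 <- largest_nucleus(lab2, e2$frame)
  sel2 <- which(lab2$label %in% c("HEX", "CUBIC"))
  o2 <- e2$frame$positions[attr(lab2, "o_idx")[sel2], , drop = FALSE]
  expect_equal(nuc2$n, as.integer(brute_force_largest(o2, e2$frame$box, 0.35)))
  # cluster straddling the periodic boundary counts as one component:
  # compare against brute force on an unwrapped copy
  liq3 <- build_liquid_box(80, box = c(4, 4, 4), seed = 11)
  e3 <- embed_nucleus(liq3, 24, center = c(0.05, 2, 2), seed = 11)
  lab3 <- classify_ice(e3$frame)
  nuc3 <- largest_nucleus(lab3, e3$frame)
  sel3 <- which(lab3$label %in% c("HEX", "CUBIC"))
  o3 <- e3$frame$positions[attr(lab3, "o_idx")[sel3], , drop = FALSE]
  # unwrap across x about the insertion point, then measure non-periodically
  o3u <- o3
  o3u[, 1] <- ifelse(o3u[, 1] > 2, o3u[, 1] - 4, o3u[, 1])
  o3u[, 1] <- o3u[, 1] + 10  # move away from edges
  expect_equal(nuc3$n,
               as.integer(brute_force_largest(o3u, c(20, 4, 4), 0.35,
                                              periodic = rep(FALSE, 3))))
})

test_that("empty and degenerate nucleus cases behave", {
  liq <- build_liquid_box(50, box = c(3, 3, 3), seed = 12)
  lab <- classify_ice(liq)
  lab$label[] <- "LIQUID"
  expect_equal(largest_nucleus(lab, liq)$n, 0L)
  expect_error(local_q6(md_frame(matrix(c(1, 1, 1), 1, 3), c(3, 3, 3),
                                 data.frame(name = "OW", resname = "SOL",
                                            resid = 1L, molid = 0L))),
               "at least 2")
})

test_that("adding an ice-labeled molecule never shrinks the largest cluster", {
  # monotonicity of the largest component in the labeled set
  liq <- build_liquid_box(100, box = c(4, 4, 4), seed = 13)
  emb <- embed_nucleus(liq, 25, seed = 13)
  lab <- classify_ice(emb$frame)
  base <- largest_nucleus(lab, emb$frame)$n
  cand <- which(lab$label == "INTERFACIAL")
  for (i in utils::head(cand, 5)) {
    lab2 <- lab
    lab2$label[i] <- "CUBIC"
    expect_gte(largest_nucleus(lab2, emb$frame)$n, base)
  }
})

test_that("nucleus time series tracks constructed growth", {
  liq <- build_liquid_box(100, box = c(4, 4, 4), seed = 14)
  raw <- lapply(c(10, 20, 30), function(nc) embed_nucleus(liq, nc, seed = 14))
  # equalize molecule counts (larger clusters displace more liquid) so the
  # frames form a valid trajectory
  n_target <- min(vapply(raw, function(e) {
    nrow(water_molecules(e$frame, warn = FALSE))
  }, integer(1)))
  frames <- lapply(raw, function(e) {
    wm <- water_molecules(e$frame, warn = FALSE)
    liquid_ids <- setdiff(wm$molid, e$inserted)
    drop_n <- nrow(wm) - n_target
    keep <- c(setdiff(liquid_ids, utils::head(liquid_ids, drop_n)), e$inserted)
    subset_molecules(e$frame, keep)
  })
  trj <- md_trajectory(frames, times = c(0, 1, 2))
  ns <- nucleus_timeseries(trj)
  expect_true(all(diff(ns$n) >= 0))
  # static trajectory -> constant series; pure liquid -> all zeros
  stat <- md_trajectory(rep(list(frames[[3]]), 3), times = 0:2)
  expect_equal(length(unique(nucleus_timeseries(stat)$n)), 1L)
  pure <- md_trajectory(rep(list(liq), 2), times = 0:1)
  expect_true(all(nucleus_timeseries(pure)$n == 0))
})

test_that("hexagonal ring search matches an independent cycle count", {
  # single bonded hexagon -> exactly one ring
  hex_pairs <- cbind(1:6, c(2:6, 1))
  expect_length(find_hexagonal_rings(hex_pairs), 1L)
  expect_length(find_hexagonal_rings(hex_pairs[1:4, , drop = FALSE]), 0L)
  expect_length(find_hexagonal_rings(NULL), 0L)
  # ice Ih hydrogen-bond graph vs igraph subgraph-isomorphism count
  f <- build_ice_lattice("ih", repeats = c(2, 2, 1), seed = 3)
  hb <- detect_hbonds(f)
  pairs <- cbind(hb$donor_mol + 1L, hb$acceptor_mol + 1L)
  rings <- find_hexagonal_rings(pairs)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  iso <- igraph::subgraph_isomorphisms(igraph::make_ring(6), g, method = "vf2")
  expect_equal(length(rings), length(iso) / 12L)
  expect_gt(length(rings), 0L)
})
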