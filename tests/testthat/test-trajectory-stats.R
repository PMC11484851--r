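static_traj <- function(n_frames = 5) {
  b <- make_bundle()
  new_trajectory(b$structure,
                 replicate(n_frames, structure_coords(b$structure),
                           simplify = FALSE))
}

test_that("RMSD series is zero for static and rigidly drifting trajectories", {
  tr <- static_traj()
  ca <- atom_select(tr$topology, elety = "CA")
  expect_equal(rmsd_series(tr, ca)$value, rep(0, 5), tolerance = 1e-9)
  # frames under growing rigid transforms, fit = report -> still zero
  set.seed(3)
  frames <- lapply(1:5, function(t) {
    R <- random_rotation()
    apply_rigid(tr$frames[[1]], R, rnorm(3, sd = t))
  })
  tr2 <- new_trajectory(tr$topology, frames)
  expect_equal(rmsd_series(tr2, ca)$value, rep(0, 5), tolerance = 1e-9)
  expect_equal(nrow(rmsd_series(tr2, ca)), frame_count(tr2))
})

test_that("a planted drift of the report atoms appears in the series", {
  tr <- static_traj()
  top <- tr$topology
  fit <- atom_select(top, resno = c(90:110, 135:155), elety = "CA")
  rep_idx <- atom_select(top, resno = 369:389, elety = "CA")
  frames <- lapply(1:5, function(t) {
    x <- tr$frames[[1]]
    x[rep_idx, 1] <- x[rep_idx, 1] + 2 * (t - 1)
    x
  })
  tr3 <- new_trajectory(top, frames)
  got <- rmsd_series(tr3, fit, rep_idx)$value
  # per-frame oracle: fit atoms unmoved -> identity fit; RMSD is the shift
  expect_equal(got, 2 * (0:4), tolerance = 1e-9)
})

test_that("minimum-distance series matches the per-frame exhaustive scan", {
  hb <- make_hbond_traj(0.5, 6, seed = 4)
  tr <- hb$trajectory
  got <- min_distance_series(tr, "A:1", "B:2")
  expect_equal(nrow(got), 6L)
  ia <- residue_atom_idx(tr$topology, "A:1")
  ib <- residue_atom_idx(tr$topology, "B:2")
  for (t in 1:6)
    expect_equal(got$value[t],
                 oracle_min_distance(tr$frames[[t]][ia, , drop = FALSE],
                                     tr$frames[[t]][ib, , drop = FALSE]),
                 tolerance = 1e-12)
  # two fixed atoms 7 A apart stay at a constant 7
  s <- point_structure(matrix(c(0, 0, 0, 7, 0, 0), ncol = 3, byrow = TRUE))
  tr7 <- new_trajectory(s, replicate(10, structure_coords(s),
                                     simplify = FALSE))
  expect_equal(min_distance_series(tr7, "A:1", "A:2")$value, rep(7, 10))
  # linearly separating pair -> strictly increasing
  frames <- lapply(1:6, function(t) {
    x <- structure_coords(s); x[2, 1] <- 7 + 0.5 * t; x
  })
  inc <- min_distance_series(new_trajectory(s, frames), "A:1", "A:2")$value
  expect_true(all(diff(inc) > 0))
})

test_that("hydrogen-bond occupancy equals the planted fraction", {
  hb <- make_hbond_traj(0.7, 10, seed = 1)
  expect_equal(as.numeric(hbond_probability(hb$trajectory, "A:1", "B:2")),
               0.7)
  hb0 <- make_hbond_traj(0, 10, seed = 1)
  expect_equal(as.numeric(hbond_probability(hb0$trajectory, "A:1", "B:2")), 0)
  p <- hbond_probability(hb$trajectory, "A:1", "B:2")
  expect_gte(as.numeric(p), 0); expect_lte(as.numeric(p), 1)
})

test_that("occupancy is monotone in the donor-acceptor cutoff", {
  hb <- make_hbond_traj(0.4, 10, seed = 6)
  cuts <- c(2.0, 2.8, 3.5, 9.5)
  probs <- vapply(cuts, function(cc)
    as.numeric(hbond_probability(hb$trajectory, "A:1", "B:2",
                                 hbond_criterion(donor_acceptor_cutoff = cc))),
    numeric(1))
  expect_true(all(diff(probs) >= 0))
  expect_equal(probs[4], 1)  # even unbonded frames sit at 9.0 A
})

test_that("a lone stationary water gives the closed-form density", {
  # a single water oxygen exactly on a grid point: rho = 1/V_r = 3/(4 pi)
  rec <- point_structure(matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0),
                                ncol = 3, byrow = TRUE))
  wat <- data.frame(chain = "W", resno = 1L, insert = "", resid = "HOH",
                    elety = "O", elesy = "O", x = 2, y = 2, z = 2, o = 1,
                    is_h = FALSE, stringsAsFactors = FALSE)
  top <- new_structure(rbind(rec$atoms, wat))
  tr <- new_trajectory(top, replicate(4, structure_coords(top),
                                      simplify = FALSE))
  g <- water_density_grid(tr, list(min = c(0, 0, 0), max = c(4, 4, 4)),
                          spacing = 1, r = 1)
  expect_equal(g$values[3, 3, 3], 3 / (4 * pi), tolerance = 1e-12)
  # grid points farther than r are exactly zero
  expect_equal(g$values[1, 1, 1], 0)
  expect_equal(sum(g$values > 0), 7)  # the point itself + 6 face neighbours
})

test_that("the density grid is bit-equal to the brute-force double sum", {
  set.seed(12)
  rec <- point_structure(matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0),
                                ncol = 3, byrow = TRUE))
  nw <- 3
  wat <- data.frame(chain = "W", resno = seq_len(nw), insert = "",
                    resid = "HOH", elety = "O", elesy = "O",
                    x = runif(nw, 0, 2), y = runif(nw, 0, 2),
                    z = runif(nw, 0, 2), o = 1, is_h = FALSE,
                    stringsAsFactors = FALSE)
  top <- new_structure(rbind(rec$atoms, wat))
  frames <- lapply(1:2, function(t) {
    x <- structure_coords(top)
    x[4:6, ] <- matrix(runif(9, 0, 2), ncol = 3)
    x
  })
  tr <- new_trajectory(top, frames)
  region <- list(min = c(0, 0, 0), max = c(1.2, 1.2, 1.2))
  g <- water_density_grid(tr, region, spacing = 0.4, r = 1)
  wframes <- lapply(frames, function(x) x[4:6, , drop = FALSE])
  orc <- oracle_density_grid(wframes, region$min, g$dims, 0.4, 1)
  expect_identical(g$values, orc)
})

test_that("the estimator is unbiased on uniform synthetic hydration", {
  hy <- make_hydration_traj(hydration_spec(box = c(20, 20, 20),
                                           density = 0.0334, frames = 50,
                                           seed = 42))
  region <- list(min = c(2, 2, 2), max = c(18, 18, 18))  # interior only
  g <- water_density_grid(hy$trajectory, region, spacing = 0.8, r = 1)
  expect_equal(mean(g$values), 0.0334, tolerance = 0.05)
})

test_that("the grid is invariant under rigid co-transformation of frames", {
  hy <- make_hydration_traj(hydration_spec(box = c(10, 10, 10), frames = 3,
                                           seed = 9))
  tr <- hy$trajectory
  fit <- atom_select(tr$topology, chain = "R")
  region <- list(min = c(2, 2, 2), max = c(8, 8, 8))
  g1 <- water_density_grid(tr, region, spacing = 0.8, r = 1, fit_idx = fit)
  R <- random_rotation()
  tr2 <- new_trajectory(tr$topology, lapply(seq_len(frame_count(tr)),
                                            function(t) {
    if (t == 1) tr$frames[[t]]
    else apply_rigid(tr$frames[[t]], R, c(5, -3, 2))
  }))
  g2 <- water_density_grid(tr2, region, spacing = 0.8, r = 1, fit_idx = fit)
  expect_equal(g2$values, g1$values, tolerance = 1e-9)
})

test_that("waterless trajectories yield an all-zero grid with a warning", {
  s <- point_structure(matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0),
                              ncol = 3, byrow = TRUE))
  tr <- new_trajectory(s, list(structure_coords(s)))
  expect_warning(
    g <- water_density_grid(tr, list(min = c(0, 0, 0), max = c(2, 2, 2))),
    "no water")
  expect_true(all(g$values == 0))
  expect_error(water_density_grid(tr, list(min = c(0, 0, 0),
                                           max = c(2, 2, 2)), r = -1),
               "positive")
})

test_that("high-density regions are the 26-connected super-threshold blocks", {
  bulk <- 0.0334
  vals <- array(bulk, dim = c(10, 10, 10))
  vals[2:4, 2:4, 2:4] <- 2.5 * bulk
  g <- new_density_grid(c(0, 0, 0), 0.4, vals,
                        params = list(bulk_density = bulk))
  cl <- high_density_regions(g, k = 2)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 27L)
  expect_equal(cl[[1]]$peak_ratio, 2.5, tolerance = 1e-12)
  # uniform grid at bulk: nothing exceeds 2x bulk
  gu <- new_density_grid(c(0, 0, 0), 0.4, array(bulk, dim = c(6, 6, 6)),
                         params = list(bulk_density = bulk))
  expect_length(high_density_regions(gu, k = 2), 0L)
  # two separated blocks -> two clusters (flood-fill check)
  vals2 <- array(bulk, dim = c(10, 10, 10))
  vals2[1:2, 1:2, 1:2] <- 3 * bulk
  vals2[7:8, 7:8, 7:8] <- 2.2 * bulk
  g2 <- new_density_grid(c(0, 0, 0), 0.4, vals2,
                         params = list(bulk_density = bulk))
  cl2 <- high_density_regions(g2, k = 2)
  expect_length(cl2, 2L)
  expect_equal(cl2[[1]]$peak_ratio, 3, tolerance = 1e-12)  # sorted by peak
  expect_equal(vapply(cl2, `[[`, integer(1), "size"), c(8L, 8L))
  gnb <- new_density_grid(c(0, 0, 0), 0.4, vals2)
  expect_error(high_density_regions(gnb, k = 2), "bulk")
})

test_that("a planted hotspot is found at the planted density ratio", {
  hy <- make_hydration_traj(hydration_spec(
    box = c(14, 14, 14), density = 0.0334, frames = 40,
    hotspot = list(center = c(7, 7, 7), radius = 2.5, multiplier = 2.5),
    seed = 8))
  region <- list(min = c(2, 2, 2), max = c(12, 12, 12))
  g <- water_density_grid(hy$trajectory, region, spacing = 0.8, r = 1)
  cl <- high_density_regions(g, k = 2)
  expect_gte(length(cl), 1L)
  # the dominant cluster's peak lies inside the hotspot sphere
  peak <- region$min + (cl[[1]]$peak_index - 1) * 0.8
  expect_lt(sqrt(sum((peak - c(7, 7, 7))^2)), 2.5)
})
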