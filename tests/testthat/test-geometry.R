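test_that("superposing a set onto itself gives identity and zero RMSD", {
  pts <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  sp <- superpose(pts, pts)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp$n_atoms, 4L)
})

test_that("a planted rotation + translation is recovered exactly", {
  set.seed(11)
  ref <- matrix(rnorm(30), ncol = 3)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # 90 deg z
  mobile <- sweep(ref %*% t(Rz), 2, c(1, 2, 3), "+")
  sp <- superpose(ref, mobile)
  expect_lt(sp$rmsd, 1e-9)
  moved <- apply_superposition(sp, mobile)
  expect_equal(moved, ref, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
})

test_that("best-fit RMSD matches the quaternion-method oracle on seeded sets", {
  for (seed in 1:10) {
    set.seed(seed)
    ref <- matrix(rnorm(30), ncol = 3)
    mobile <- matrix(rnorm(30), ncol = 3)
    sp <- superpose(ref, mobile)
    expect_equal(sp$rmsd, oracle_rmsd_quaternion(ref, mobile),
                 tolerance = 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  }
})

test_that("RMSD is invariant under rigid pre-transforms and symmetric", {
  set.seed(21)
  ref <- matrix(rnorm(24), ncol = 3)
  mobile <- matrix(rnorm(24), ncol = 3)
  base <- superpose(ref, mobile)$rmsd
  for (i in 1:5) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    expect_equal(superpose(ref, apply_rigid(mobile, R, t))$rmsd, base,
                 tolerance = 1e-9)
  }
  expect_equal(superpose(mobile, ref)$rmsd, base, tolerance = 1e-9)
})

test_that("degenerate and mismatched point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
  expect_error(superpose(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "mismatch")
  expect_error(superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
})

test_that("report-selection RMSD isolates a planted shift", {
  b <- make_bundle()
  s <- b$structure
  # identical structures -> 0
  expect_equal(rmsd_after_superposition(s, s), 0, tolerance = 1e-9)
  # co-transformed copy -> 0 after fitting
  R <- random_rotation(); tv <- c(4, -2, 7)
  s2 <- transform_structure(s, R, tv)
  expect_equal(rmsd_after_superposition(s, s2), 0, tolerance = 1e-9)
  # plant a 2.0 A shift of the TM7 report set only
  s3 <- s
  xyz <- structure_coords(s3)
  tm7 <- atom_select(s3, resno = 369:389)
  xyz[tm7, 1] <- xyz[tm7, 1] + 2.0
  s3 <- set_structure_coords(s3, xyz)
  core <- c(90:110, 135:155, 185:205, 230:250)
  fit_sel <- list(ref = atom_select(s, resno = core, elety = "CA"),
                  mobile = atom_select(s3, resno = core, elety = "CA"))
  rep_sel <- list(ref = atom_select(s, resno = 369:389, elety = "CA"),
                  mobile = atom_select(s3, resno = 369:389, elety = "CA"))
  expect_equal(rmsd_after_superposition(s, s3, fit_sel, rep_sel), 2.0,
               tolerance = 1e-9)
})

test_that("minimum residue distance matches the exhaustive oracle", {
  s <- point_structure(matrix(c(0, 0, 0, 3, 0, 0), ncol = 3, byrow = TRUE))
  expect_equal(min_residue_distance(s, "A:1", "A:2")$distance, 3.0)
  expect_equal(min_residue_distance(s, "A:1", "A:1")$distance, 0)
  b <- make_bundle()
  xyz <- structure_coords(b$structure)
  for (pair in list(c("R:195", "R:386"), c("R:198", "R:199"),
                    c("R:140", "R:386"))) {
    ia <- residue_atom_idx(b$structure, pair[1])
    ib <- residue_atom_idx(b$structure, pair[2])
    expect_equal(min_residue_distance(b$structure, pair[1], pair[2])$distance,
                 oracle_min_distance(xyz[ia, , drop = FALSE],
                                     xyz[ib, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("helix axis recovers the generating direction", {
  # ideal helix along z with an integer number of turns
  n <- 18
  phi <- (0:(n - 1)) * 100 * pi / 180
  ca <- cbind(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * (0:(n - 1)))
  ax <- helix_axis(ca)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-3)
  expect_gt(sum(ax$direction * c(0, 0, 1)), 0)  # oriented first -> last
  # same helix rotated 30 degrees about x
  th <- 30 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
               3, 3, byrow = TRUE)
  ax2 <- helix_axis(ca %*% t(Rx))
  expect_equal(axis_angle(ax2$direction, c(0, 0, 1)), 30, tolerance = 0.5)
  # noisy helix: axis within 2 degrees of the generating axis
  set.seed(5)
  noisy <- ca + matrix(rnorm(length(ca), sd = 0.2), ncol = 3)
  expect_lt(axis_angle(helix_axis(noisy)$direction, c(0, 0, 1)), 2)
  expect_error(helix_axis(ca[1:4, ]), "at least 5")
})

test_that("axial displacement is the signed projection", {
  expect_equal(displacement_along_axis(c(0, 0, 0), c(0, 0, -1.5), c(0, 0, 1)),
               -1.5)
  expect_equal(displacement_along_axis(c(0, 0, 0), c(3, 4, 0), c(0, 0, 1)), 0)
  set.seed(9)
  for (i in 1:5) {
    p1 <- rnorm(3); p2 <- rnorm(3)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    expect_equal(displacement_along_axis(p1, p2, ax),
                 sum((p2 - p1) * ax), tolerance = 1e-12)
  }
  expect_error(displacement_along_axis(c(0, 0, 0), c(1, 1, 1), c(0, 0, 2)),
               "unit")
})
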