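test_that("motif gap reports the planted distance and the contact rule", {
  b <- make_bundle()  # planted 7.3 A: no direct contact
  g <- motif_gap(b$structure, b$map)
  expect_equal(g$distance, 7.3, tolerance = 1e-6)
  expect_false(g$contact)
  # a pair planted just inside the 4.5 A rule is a contact
  b2 <- make_bundle(bundle_spec(gap_346_753 = 4.4))
  g2 <- motif_gap(b2$structure, b2$map)
  expect_equal(g2$distance, 4.4, tolerance = 1e-6)
  expect_true(g2$contact)
  expect_error(motif_gap(b$structure, b$map, "6.99", "7.53"), "6.99")
})

test_that("polar-contact calls agree with a brute-force polar-pair scan", {
  set.seed(31)
  for (seed in 1:6) {
    dry <- runif(1, 2.6, 6.5)
    b <- make_bundle(bundle_spec(seed = seed, dry_distance = dry))
    got <- salt_bridge_or_hbond(b$structure, b$map, c("3.49", "3.50"),
                                "salt_bridge")
    expect_equal(got$distance, dry, tolerance = 1e-6)
    expect_equal(got$present, dry <= 4.0)
    # oracle: exhaustive scan over the charged atoms
    a <- b$structure$atoms
    asp <- a[a$resno == 198 & a$elety %in% c("OD1", "OD2"), ]
    arg <- a[a$resno == 199 & a$elety %in% c("NE", "NH1", "NH2"), ]
    expect_equal(got$distance,
                 oracle_min_distance(as.matrix(asp[, c("x", "y", "z")]),
                                     as.matrix(arg[, c("x", "y", "z")])),
                 tolerance = 1e-9)
  }
  b <- make_bundle()
  ry <- salt_bridge_or_hbond(b$structure, b$map, c("3.50", "5.58"), "hbond")
  expect_equal(ry$distance, 2.9, tolerance = 1e-6)
  expect_true(ry$present)
  far <- make_bundle(bundle_spec(ry_distance = 6.0))
  expect_false(salt_bridge_or_hbond(far$structure, far$map,
                                    c("3.50", "5.58"), "hbond")$present)
})

test_that("residues without qualifying polar atoms are rejected by name", {
  b <- make_bundle()
  # 3.46 is leucine: no polar side-chain atoms
  expect_error(salt_bridge_or_hbond(b$structure, b$map, c("3.46", "3.50"),
                                    "hbond"), "R:195")
})

test_that("TM6/TM7 displacements are zero against an identical reference", {
  b <- make_bundle()
  expect_equal(tm6_outward(b$structure, b$structure, b$map), 0,
               tolerance = 1e-9)
  expect_equal(tm7_downward(b$structure, b$structure, b$map), 0,
               tolerance = 1e-9)
})

test_that("planted TM displacements are recovered exactly", {
  pair <- make_bundle_pair()
  act <- pair$active; ina <- pair$inactive
  expect_equal(tm6_outward(act$structure, ina$structure, act$map), 7.0,
               tolerance = 1e-6)
  expect_equal(tm7_downward(act$structure, ina$structure, act$map), 1.5,
               tolerance = 1e-6)
})

test_that("an oblique TM6 plant decomposes into its in-plane component", {
  pair <- make_bundle_pair()
  act <- pair$active
  # move TM6 of the inactive copy by a hand-chosen oblique vector
  s <- act$structure
  xyz <- structure_coords(s)
  tm6 <- which(s$atoms$resno >= 315 & s$atoms$resno <= 335)
  shift <- c(3, 4, 2)  # in-plane norm 5, axial 2
  xyz[tm6, ] <- sweep(xyz[tm6, , drop = FALSE], 2, shift, "-")
  ina <- set_structure_coords(s, xyz)
  expect_equal(tm6_outward(act$structure, ina, act$map), 5.0,
               tolerance = 1e-6)
  # and a mixed TM7 plant projects onto the intracellular-positive axis
  xyz <- structure_coords(act$structure)
  tm7 <- which(act$structure$atoms$resno >= 369 &
                 act$structure$atoms$resno <= 389)
  xyz[tm7, ] <- sweep(xyz[tm7, , drop = FALSE], 2, c(1, -2, 0.8), "+")
  ina7 <- set_structure_coords(act$structure, xyz)
  # reference moved +0.8 z (extracellular); active - ref along -z axis: +0.8
  expect_equal(tm7_downward(act$structure, ina7, act$map), 0.8,
               tolerance = 1e-6)
})

test_that("hallmark metrics are invariant under a global rigid transform", {
  pair <- make_bundle_pair()
  act <- pair$active; ina <- pair$inactive
  R <- random_rotation(); tv <- c(13, -4, 8)
  act_t <- transform_structure(act$structure, R, tv)
  ina_t <- transform_structure(ina$structure, R, tv)
  expect_equal(motif_gap(act_t, act$map)$distance, 7.3, tolerance = 1e-9)
  expect_equal(tm6_outward(act_t, ina_t, act$map), 7.0, tolerance = 1e-6)
  expect_equal(tm7_downward(act_t, ina_t, act$map), 1.5, tolerance = 1e-6)
})

test_that("the aggregated report reproduces every planted value", {
  pair <- make_bundle_pair()
  rep <- hallmark_report(pair$active$structure, pair$active$map,
                         pair$inactive$structure, pair$inactive$map)
  expect_equal(rep$gap_346_753, pair$ledger$gap_346_753, tolerance = 1e-6)
  expect_false(rep$contact_346_753)
  expect_equal(rep$dry_salt_bridge_distance, pair$ledger$dry_distance,
               tolerance = 1e-6)
  expect_false(rep$dry_salt_bridge_present)
  expect_equal(rep$r350_y558_hbond_distance, pair$ledger$ry_distance,
               tolerance = 1e-6)
  expect_true(rep$r350_y558_hbond_present)
  expect_equal(rep$tm6_outward, pair$ledger$tm6_outward, tolerance = 1e-6)
  expect_equal(rep$tm7_downward, pair$ledger$tm7_downward, tolerance = 1e-6)
})

test_that("an active-only report flags the reference metrics unavailable", {
  b <- make_bundle()
  rep <- hallmark_report(b$structure, b$map)
  expect_true(is.na(rep$tm6_outward))
  expect_true(is.na(rep$tm7_downward))
  expect_match(rep$notes[["reference"]], "unavailable")
})

test_that("hallmark reports serialize to JSON and round-trip", {
  pair <- make_bundle_pair()
  rep <- hallmark_report(pair$active$structure, pair$active$map,
                         pair$inactive$structure)
  p <- tempfile(fileext = ".json")
  hallmark_report_json(rep, p)
  back <- jsonlite::fromJSON(p)
  expect_equal(back$gap_346_753, rep$gap_346_753, tolerance = 1e-9)
  expect_equal(back$tm6_outward, rep$tm6_outward, tolerance = 1e-9)
  expect_equal(back$contact_346_753, rep$contact_346_753)
  expect_equal(back$schema_version, "1.0")
})
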