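test_that("a single planted polar pair yields exactly one hydrogen bond", {
  # backbone carbonyl acceptor 2.9 A from a serine hydroxyl donor
  don <- place_residue_fixture("A", 1, "SER", c(0, 0, 0), c(1, 0, 0))
  acc <- place_residue_fixture("B", 2, "LEU", c(8, 0, 0), c(-1, 0, 0))
  s <- new_structure(rbind(don, acc))
  og <- which(s$atoms$elety == "OG")
  o <- which(s$atoms$elety == "O" & s$atoms$chain == "B")
  xyz <- structure_coords(s)
  shift <- xyz[og, ] + c(2.9, 0, 0) - xyz[o, ]
  bidx <- which(s$atoms$chain == "B")
  xyz[bidx, ] <- sweep(xyz[bidx, , drop = FALSE], 2, shift, "+")
  # push the rest of B away so only OG...O qualifies
  s <- set_structure_coords(s, xyz)
  rep <- detect_contacts(s, "A", "B")
  hb <- rep$contacts[rep$contacts$type == "hbond", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$min_dist, 2.9, tolerance = 1e-9)
})

test_that("the van der Waals cutoff is a sharp boundary", {
  mk <- function(d) {
    a <- place_residue_fixture("A", 1, "LEU", c(0, 0, 0), c(1, 0, 0))
    b <- place_residue_fixture("B", 2, "LEU", c(20, 0, 0), c(-1, 0, 0))
    s <- new_structure(rbind(a, b))
    gpcrprofiler:::plant_distance(
      s, gpcrprofiler:::heavy_idx(s, "A:1"), gpcrprofiler:::heavy_idx(s, "B:2"),
      which(s$atoms$chain == "B"), d)
  }
  at40 <- detect_contacts(mk(4.0), "A", "B")
  expect_equal(at40$vdw_count, 1L)
  expect_equal(at40$hbond_count, 0L)
  at46 <- detect_contacts(mk(4.6), "A", "B")
  expect_equal(at46$vdw_count + at46$hbond_count, 0L)
})

test_that("the planted complex ledger is reproduced exactly", {
  cx <- make_complex()
  rep <- detect_contacts(cx$structure, "R", "A", cx$receptor_map,
                         cx$galpha_map)
  expect_equal(rep$hbond_count, 4L)
  expect_equal(rep$vdw_count, 6L)
  got <- rep$contacts[order(rep$contacts$receptor_res, rep$contacts$ga_res), ]
  want <- cx$ledger$contacts[order(cx$ledger$contacts$rec_res,
                                   cx$ledger$contacts$ga_res), ]
  expect_equal(got$receptor_res, want$rec_res)
  expect_equal(got$ga_res, want$ga_res)
  expect_equal(got$type, want$type)
  expect_equal(got$min_dist, want$min_dist, tolerance = 1e-6)
  # counts equal list tallies
  expect_equal(rep$hbond_count + rep$vdw_count, nrow(rep$contacts))
})

test_that("contact detection matches the brute-force all-pairs oracle", {
  for (seed in c(2, 7)) {
    cx <- make_complex(complex_spec(seed = seed, tilt_deg = 5 + seed))
    rep <- detect_contacts(cx$structure, "R", "A")
    orc <- oracle_contacts(cx$structure, "R", "A")
    got <- rep$contacts
    got$rn <- as.integer(sub("^R:", "", got$receptor_res))
    got$gn <- as.integer(sub("^A:", "", got$ga_res))
    got <- got[order(got$rn, got$gn), ]
    orc <- orc[order(orc$res_a, orc$res_b), ]
    expect_equal(nrow(got), nrow(orc))
    expect_equal(got$rn, orc$res_a)
    expect_equal(got$gn, orc$res_b)
    expect_equal(got$type, orc$type)
    expect_equal(got$min_dist, orc$dist, tolerance = 1e-9)
  }
})

test_that("contact sets are invariant under a global rigid transform", {
  cx <- make_complex()
  R <- random_rotation(); tv <- c(-6, 3, 11)
  st <- transform_structure(cx$structure, R, tv)
  r1 <- detect_contacts(cx$structure, "R", "A")
  r2 <- detect_contacts(st, "R", "A")
  expect_equal(r2$hbond_count, r1$hbond_count)
  expect_equal(r2$vdw_count, r1$vdw_count)
  expect_equal(r2$contacts$min_dist, r1$contacts$min_dist, tolerance = 1e-9)
  # swapping chain roles preserves the contact set (roles re-labelled)
  r3 <- detect_contacts(cx$structure, "A", "R")
  expect_equal(r3$hbond_count, r1$hbond_count)
  expect_equal(r3$vdw_count, r1$vdw_count)
})

test_that("records never double-count a pair and grow with the cutoff", {
  cx <- make_complex()
  rep <- detect_contacts(cx$structure, "R", "A")
  keys <- paste(rep$contacts$receptor_res, rep$contacts$ga_res)
  expect_false(any(duplicated(keys)))
  wide <- detect_contacts(cx$structure, "R", "A", vdw_cutoff = 6.0)
  keys_wide <- paste(wide$contacts$receptor_res, wide$contacts$ga_res)
  expect_true(all(keys %in% keys_wide))
})

test_that("pocket composition returns the receptor labels near H5.20/H5.25", {
  cx <- make_complex()
  pocket <- pocket_composition(cx$structure, "R", cx$receptor_map,
                               cx$galpha_map)
  # the planted vdw partners of L348 and L353
  expect_setequal(pocket, c("3.54", "5.61", "6.33", "6.37"))
  expect_error(pocket_composition(cx$structure, "R", cx$receptor_map,
                                  cx$galpha_map, galpha_labels = "H9.99"),
               "H9.99")
  # probes moved far away: empty set
  far <- cx$structure
  xyz <- structure_coords(far)
  aidx <- which(far$atoms$chain == "A")
  xyz[aidx, 1] <- xyz[aidx, 1] + 100
  far <- set_structure_coords(far, xyz)
  expect_length(pocket_composition(far, "R", cx$receptor_map, cx$galpha_map),
                0)
})

test_that("alpha5 insertion angle recovers planted tilts", {
  cx0 <- make_complex(complex_spec(tilt_deg = 0))
  bundle_ca <- structure_coords(cx0$structure)[
    atom_select(cx0$structure, chain = "R", resno = 601:612, elety = "CA"), ]
  a5 <- atom_select(cx0$structure, chain = "A", elety = "CA")
  expect_equal(alpha5_tilt(cx0$structure, a5, bundle_ca), 0, tolerance = 1e-6)
  cx25 <- make_complex(complex_spec(tilt_deg = 25))
  a5 <- atom_select(cx25$structure, chain = "A", elety = "CA")
  bundle_ca <- structure_coords(cx25$structure)[
    atom_select(cx25$structure, chain = "R", resno = 601:612, elety = "CA"), ]
  expect_equal(alpha5_tilt(cx25$structure, a5, bundle_ca), 25,
               tolerance = 1)
  # noisy alpha5 trace: within 3 degrees of the generating tilt
  set.seed(17)
  xyz <- structure_coords(cx25$structure)
  xyz[a5, ] <- xyz[a5, ] + matrix(rnorm(length(a5) * 3, sd = 0.2), ncol = 3)
  noisy <- set_structure_coords(cx25$structure, xyz)
  expect_equal(alpha5_tilt(noisy, a5, bundle_ca), 25, tolerance = 3)
})

test_that("interface reports write tidy CSV", {
  cx <- make_complex()
  rep <- detect_contacts(cx$structure, "R", "A", cx$receptor_map,
                         cx$galpha_map)
  p <- tempfile(fileext = ".csv")
  write_contacts_csv(rep, p)
  back <- read.csv(p, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 10L)
  expect_true(all(c("receptor_label", "ga_label", "type", "min_dist") %in%
                    names(back)))
})
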