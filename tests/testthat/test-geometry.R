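test_that("catheter spec encodes the orientation-matched insertion depths", {
  expect_equal(catheter_spec(90)$insertion_depth, 0.5)
  expect_equal(catheter_spec(45)$insertion_depth, 0.498)
  expect_equal(catheter_spec(0)$insertion_depth, 0.193)
  expect_equal(catheter_spec(90)$electrode_diameter, 2.5)
  expect_equal(catheter_spec(90)$electrode_length, 3.5)
  expect_error(catheter_spec(30), "orientation")
  expect_error(catheter_spec(90, insertion_depth = 4), "smaller")
})

test_that("electrode-tissue contact area is orientation-invariant", {
  a90 <- electrode_contact_area(catheter_spec(90), n = 300)
  a45 <- electrode_contact_area(catheter_spec(45), n = 300)
  a00 <- electrode_contact_area(catheter_spec(0), n = 300)
  # perpendicular case has the exact spherical-cap value 2 pi R h
  expect_equal(a90, 2 * pi * 1.25 * 0.5, tolerance = 5e-3)
  expect_lt(abs(a45 - a90) / a90, 0.05)
  expect_lt(abs(a00 - a90) / a90, 0.05)
})

test_that("axisymmetric meshes are tagged and geometrically consistent", {
  mbh <- coarse_mesh("BH")
  expect_true(all(mbh$nodes[, 1] >= 0))
  expect_true(all(mbh$region %in% 1:4))
  vols <- region_volumes(mbh)
  rmax <- 41.25; depth <- 40.5
  cap <- pi * 0.5^2 * (1.25 - 0.5 / 3)          # embedded spherical cap
  expect_equal(vols[["tissue"]], pi * rmax^2 * depth - cap,
               tolerance = 0.01)
  expect_equal(vols[["electrode"]],
               pi * 1.25^2 * 2.25 + 2 / 3 * pi * 1.25^3, tolerance = 0.05)
  # BH: every exterior facet is electrically grounded (dispersive patch),
  # apart from the symmetry axis
  tags <- rfablate:::TAG_LEVELS[mbh$facet_tag]
  ext_tags <- tags[tags %in% c("dispersive_0V", "air_blood_zero_current",
                               "symmetry", "outer_body_37C")]
  expect_false("air_blood_zero_current" %in% ext_tags)
  mtm <- coarse_mesh("TM")
  tags_tm <- rfablate:::TAG_LEVELS[mtm$facet_tag]
  expect_true("air_blood_zero_current" %in% tags_tm)
  # TM top surface facets are all at the blood top
  top <- mtm$facets[mtm$facet_tag == 2L, , drop = FALSE]
  expect_true(all(abs(mtm$nodes[as.integer(top), 2] - mtm$blood_top) < 1e-9))
  # irrigation is confined to the cylindrical electrode zone
  irr <- mtm$facets[mtm$facet_tag == 4L, , drop = FALSE]
  zc <- mtm$frame$centre[3]
  expect_true(all(mtm$nodes[as.integer(irr), 2] >= zc - 1e-9))
})

test_that("axisymmetric mode is restricted to the perpendicular catheter", {
  expect_error(build_geometry(scenario_geometry("BH", orientation = 45),
                              mode = "axisymmetric"), "perpendicular")
  expect_error(scenario_geometry("TM", blood_height = -1), "positive")
  expect_error(scenario_geometry("TM", blood_height = 2), "protrusion")
})

test_that("half-domain tetrahedral meshes match the revolved geometry", {
  m3 <- cached("mesh_bh90_3d",
               build_geometry(scenario_geometry("BH", orientation = 90),
                              mesh_resolution(scale = 6), mode = "3d_half"))
  mbh <- coarse_mesh("BH")
  v3 <- region_volumes(m3)
  v2 <- region_volumes(mbh)
  # the far field differs by construction (box vs revolved cylinder); the
  # catheter solids must match the analytic capsule at mode-appropriate
  # accuracy (the coarse tetrahedral staircase resolves the 1.25 mm radius
  # with only a couple of cells)
  v_el <- pi * 1.25^2 * 2.25 + 2 / 3 * pi * 1.25^3
  expect_equal(v2[["electrode"]], v_el, tolerance = 0.05)
  expect_equal(v3[["electrode"]], v_el, tolerance = 0.15)
  # each construction matches its own analytic solid to 1%
  cap <- pi * 0.5^2 * (1.25 - 0.5 / 3)
  expect_equal(v3[["tissue"]], 82.5^2 * 40.5 - cap, tolerance = 0.01)
  # symmetry facets lie on the y = 0 plane
  sym <- m3$facets[m3$facet_tag == 3L, , drop = FALSE]
  expect_true(all(abs(m3$nodes[as.integer(sym), 2]) < 1e-12))
  # region tags partition the element set
  expect_equal(sum(table(m3$region)), nrow(m3$elem))
})

test_that("convergence harness picks the coarsest converged resolution", {
  sc <- scenario_geometry("BH")
  st <- energy_setting(25, 20)
  stub <- function(values) {
    i <- 0
    function(sc, res, st) {
      i <<- i + 1
      values[[i]]
    }
  }
  # identical results twice: the first resolution qualifies
  out <- convergence_study(sc, list(1, 2), st,
                           runner = stub(list(list(depth = 3, max_T = 80),
                                              list(depth = 3, max_T = 80))))
  expect_equal(out$converged, 1L)
  # only the last pair meets the criteria
  out2 <- convergence_study(
    sc, list(1, 2, 3), st,
    runner = stub(list(list(depth = 5.0, max_T = 90),
                       list(depth = 4.0, max_T = 85),
                       list(depth = 3.9, max_T = 84.5))))
  expect_equal(out2$converged, 2L)
  # nothing converges: reported with the observed deltas
  out3 <- convergence_study(
    sc, list(1, 2), st,
    runner = stub(list(list(depth = 5, max_T = 90),
                       list(depth = 3, max_T = 80))))
  expect_true(is.na(out3$converged))
  expect_equal(out3$depth_deltas, 2)
  expect_error(convergence_study(sc, list(1), st), "two resolutions")
})
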