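test_that("the analytic verification suite passes end to end", {
  rep <- verify_analytic(dt = 0.1)
  expect_true(all(rep$pass))
  expect_setequal(
    grep("damage", rep$case, value = TRUE),
    c("damage_constant_72C_5s", "damage_constant_58C_5s",
      "damage_constant_37C_60s", "damage_ramp_37_90C_10s"))
})

test_that("damage fixture references sit where the field expects them", {
  cases <- make_damage_case()
  byname <- stats::setNames(cases, vapply(cases, `[[`, "", "name"))
  # 58 C for 5 s is just below the unity lesion threshold
  expect_gt(byname$constant_58C_5s$omega_ref, 0.5)
  expect_lt(byname$constant_58C_5s$omega_ref, 1)
  # body temperature for a minute is harmless
  expect_lt(byname$constant_37C_60s$omega_ref, 0.02)
  # 72 C for 5 s is far beyond coagulation
  expect_gt(byname$constant_72C_5s$omega_ref, 30)
})

test_that("mesh and field export writes a readable VTK file", {
  mesh <- coarse_mesh("BH")
  f <- tempfile(fileext = ".vtk")
  write_vtk(mesh, f, point_data = list(T = rep(37, nrow(mesh$nodes))))
  lines <- readLines(f, n = 6)
  expect_match(lines[1], "vtk DataFile")
  expect_match(lines[4], "UNSTRUCTURED_GRID")
  expect_match(lines[5], sprintf("POINTS %d double", nrow(mesh$nodes)))
  expect_true(file.size(f) > 1e4)
  unlink(f)
})
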