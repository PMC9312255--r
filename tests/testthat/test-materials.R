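test_that("material library carries the published constants", {
  lib <- material_library()
  myo <- lib$myocardium
  mus <- lib$striated_muscle
  expect_equal(myo$sigma_ref, 0.281)
  expect_equal(myo$k, 0.56)
  expect_equal(myo$rho, 1081)
  expect_equal(myo$c, 3686)
  expect_equal(myo$water_mass_fraction, 0.737)
  expect_equal(mus$sigma_ref, 0.446)
  expect_equal(mus$water_mass_fraction, 0.795)
  expect_equal(lib$blood$sigma_ref, 0.748)
  expect_true(is.na(lib$blood$k))
  # the conductivity contrast that drives the model comparison
  expect_equal(mus$sigma_ref / myo$sigma_ref, 1.587, tolerance = 1e-3)
})

test_that("electrical conductivity follows the linear rise and the
           two-decade collapse", {
  lib <- material_library()
  myo <- lib$myocardium
  expect_equal(electrical_conductivity(myo, 37), 0.281)
  expect_equal(electrical_conductivity(myo, 47), 0.281 * 1.15)
  s99 <- electrical_conductivity(myo, 99)
  s101 <- electrical_conductivity(myo, 101)
  expect_equal(s101 / s99, 0.01, tolerance = 1e-12)
  # continuity at the band edge and monotone collapse
  expect_equal(electrical_conductivity(myo, 99 - 1e-9), s99,
               tolerance = 1e-6)
  Ts <- seq(99, 101, by = 0.01)
  sig <- electrical_conductivity(myo, Ts)
  expect_true(all(diff(sig) <= 1e-15))
  expect_equal(electrical_conductivity(myo, 150), s99 / 100)
  expect_error(electrical_conductivity(myo, NaN), "finite")
})

test_that("apparent heat capacity implements the latent band", {
  lib <- material_library()
  myo <- lib$myocardium
  mus <- lib$striated_muscle
  expect_equal(apparent_heat_capacity(myo, 50), 1081 * 3686)
  Hw <- 2256e3 * 958
  expect_equal(apparent_heat_capacity(myo, 99.5), Hw * 0.737)
  expect_equal(apparent_heat_capacity(mus, 99.5), Hw * 0.795)
  # dehydrated tissue identical to hydrated above the band
  expect_equal(apparent_heat_capacity(myo, 105), 1081 * 3686)
})

test_that("capacity integrates to the enthalpy including the latent heat", {
  myo <- material_library()$myocardium
  Ht <- 2256e3 * 958 * 0.737
  # fine midpoint quadrature of the apparent capacity over [37, 110]
  Tg <- seq(37, 110, by = 1e-3)
  mid <- (Tg[-1] + Tg[-length(Tg)]) / 2
  num <- sum(apparent_heat_capacity(myo, mid)) * 1e-3
  expect_equal(num, 1081 * 3686 * (110 - 37 - 1) + Ht, tolerance = 1e-5)
  expect_equal(tissue_enthalpy(myo, 110),
               1081 * 3686 * (110 - 37 - 1) + Ht, tolerance = 1e-12)
})

test_that("thermal conductivity tensor preserves the isotropic mean", {
  myo <- material_library()$myocardium
  expect_equal(thermal_conductivity_tensor(myo, FALSE), 0.56)
  kt <- thermal_conductivity_tensor(myo, TRUE)
  expect_equal(unname(kt), c(0.633, 0.487, 0.487))
  expect_equal(mean(c(kt[["x"]], kt[["y"]])), 0.56)
  mus <- material_library()$striated_muscle
  expect_error(thermal_conductivity_tensor(mus, TRUE), "directional")
})

test_that("property constructors validate their inputs", {
  expect_error(tissue_properties("x", -1), "positive")
  expect_error(tissue_properties("x", 0.3, k = 0.5, rho = 1000, c = 3000,
                                 water_mass_fraction = 1.2), "0, 1")
  expect_error(tissue_properties("x", 0.3, k = 0.5, rho = 1000, c = 3000,
                                 k_transverse = 0.4), "both")
  expect_error(tissue_properties("x", 0.3, k = 0.5, rho = 1000, c = 3000,
                                 k_transverse = 0.4, k_longitudinal = 0.7),
               "mean")
})
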