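test_that("Arrhenius integration reproduces closed-form constant
           exposures", {
  # 72 C held 5 s: the classical near-instant coagulation point
  om <- arrhenius_integrate(rep(72, 51), seq(0, 5, by = 0.1))
  expect_equal(om, omega_const(72, 5), tolerance = 1e-9)
  expect_equal(om, 37.15, tolerance = 0.01)
  # 58 C for 5 s sits just below the unity threshold
  om58 <- arrhenius_integrate(rep(58, 51), seq(0, 5, by = 0.1))
  expect_equal(om58, omega_const(58, 5), tolerance = 1e-9)
  expect_lt(om58, 1)
  expect_gt(om58, 0.5)
  # body temperature stays far below threshold for a minute
  om37 <- arrhenius_integrate(rep(37, 61), seq(0, 60, by = 1))
  expect_lt(om37, 0.02)
})

test_that("damage is linear in exposure time and additive over segments", {
  t1 <- seq(0, 5, by = 0.05)
  t2 <- seq(0, 10, by = 0.05)
  o1 <- arrhenius_integrate(rep(65, length(t1)), t1)
  o2 <- arrhenius_integrate(rep(65, length(t2)), t2)
  expect_equal(o2, 2 * o1, tolerance = 1e-12)
  # piecewise program split at a shared sample point: damages add exactly
  times <- seq(0, 8, by = 0.05)
  temps <- 60 + 10 * pmax(0, times - 4) / 4
  o_all <- arrhenius_integrate(temps, times)
  o_a <- arrhenius_integrate(temps[times <= 4], times[times <= 4])
  o_b <- arrhenius_integrate(temps[times >= 4], times[times >= 4])
  expect_equal(o_a + o_b, o_all, tolerance = 1e-12)
  expect_equal(o_a, omega_const(60, 4), tolerance = 1e-9)
})

test_that("damage integration rejects bad histories and handles empty
           ones", {
  expect_equal(arrhenius_integrate(matrix(80, 2, 1), 0), c(0, 0))
  expect_error(arrhenius_integrate(rep(80, 3), c(0, 2, 1)), "increasing")
  expect_error(arrhenius_integrate(c(80, NA, 80), c(0, 1, 2)), "finite")
  expect_error(arrhenius_integrate(c(80, -300, 80), c(0, 1, 2)),
               "absolute zero")
})

test_that("hemispherical damage region yields the exact lesion metrics", {
  # structured tissue-only meridian mesh; Omega = 4 - rho(mm) puts the
  # unity contour exactly on the 3 mm hemisphere
  rs <- seq(0, 5, by = 0.1)
  zs <- seq(-5, 0, by = 0.1)
  mesh <- rfablate:::grid_mesh_axi(
    rs, zs, region_fun = function(cent) rep(1L, nrow(cent)),
    tag_fun = function(fc, ext_f, r1, r2) rep(NA_integer_, nrow(fc)))
  rho <- sqrt(rowSums((mesh$nodes * 1e3)^2))
  les <- extract_lesion(mesh, 4 - rho)
  expect_equal(les$depth, 3, tolerance = 2e-3)
  expect_equal(les$max_width, 6, tolerance = 2e-3)
  expect_equal(les$volume, 2 * pi * 27 / 3, tolerance = 5e-3)
  expect_equal(les$ratio, 2, tolerance = 5e-3)
})

test_that("sub-threshold fields give an empty lesion", {
  mbh <- coarse_mesh("BH")
  les <- extract_lesion(mbh, rep(0.5, nrow(mbh$nodes)))
  expect_true(les$empty)
  expect_equal(les$volume, 0)
})

test_that("isotherm contouring inverts a linear radial field", {
  rs <- seq(0, 8, by = 0.1)
  zs <- seq(-8, 0, by = 0.1)
  mesh <- rfablate:::grid_mesh_axi(
    rs, zs, region_fun = function(cent) rep(1L, nrow(cent)),
    tag_fun = function(fc, ext_f, r1, r2) rep(NA_integer_, nrow(fc)))
  rho <- sqrt(rowSums((mesh$nodes * 1e3)^2))
  ct <- isotherm_contour(mesh, 100 - 10 * rho, 50)
  expect_false(ct$empty)
  expect_equal(ct$max_width, 10, tolerance = 2e-3)
  expect_equal(ct$depth, 5, tolerance = 2e-3)
  empty <- isotherm_contour(mesh, rep(37, nrow(mesh$nodes)), 50)
  expect_true(empty$empty)
})

test_that("tetrahedron clipping is exact for linear fields", {
  set.seed(42)
  for (i in 1:30) {
    p <- matrix(stats::rnorm(12), 4, 3)
    v <- abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ],
                       p[4, ] - p[1, ]))) / 6
    if (v < 1e-4) next
    g <- stats::rnorm(3)
    fv <- as.numeric(p %*% g)
    lev <- stats::runif(1, min(fv), max(fv))
    va <- rfablate:::tet_clip_volume(p, fv, lev)
    vb <- rfablate:::tet_clip_volume(p, -fv, -lev)
    # above + strictly-below partitions the tet
    expect_equal(va + vb, v, tolerance = 1e-9)
    # Monte Carlo cross-check via barycentric sampling
    w <- matrix(stats::rexp(4 * 4000), 4000, 4)
    w <- w / rowSums(w)
    pts_f <- as.numeric((w %*% p) %*% g)
    expect_equal(va / v, mean(pts_f >= lev), tolerance = 0.12)
  }
})

test_that("power and energy accounting demand an in-pulse record and agree
           for a cold pulse", {
  mbh <- coarse_mesh("BH")
  # suppress irrigation cooling so the temperature (and hence conductivity)
  # field stays frozen during the negligible-power pulse
  cold <- run_simulation(mbh, energy_setting(1, 0.2, observation_time = 0.2),
                         bc = boundary_conditions(T_irrigation = 37),
                         dt = 0.05)
  acc <- power_energy_accounting(cold)
  # with negligible heating the conductivity field never changes, so the
  # energy split equals the instantaneous power split
  expect_equal(acc$E_T, acc$P_T, tolerance = 1e-3)
  none <- run_simulation(mbh, energy_setting(25, 0, observation_time = 0.2),
                         dt = 0.05)
  expect_error(power_energy_accounting(none), "in-pulse")
})
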