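test_that("concentric-spheres benchmark: conductance, power normalization
           and the r^-4 dissipation profile", {
  sph <- make_spherical_electrode_case()
  sys <- rfablate:::electro_thermal_system(sph$mesh)
  T0 <- rep(37, nrow(sph$mesh$nodes))
  es <- solve_electric(sys, T0, 10)
  # integrated power matches the request to numerical precision
  expect_equal(sum(es$power_split), 10, tolerance = 1e-9)
  # conductance against the closed form 4 pi sigma / (1/r1 - 1/r2)
  G_fem <- 10 / es$applied_voltage^2
  expect_equal(G_fem, sph$conductance, tolerance = 0.01)
  # dissipation density falls as r^-4: Q * r^4 constant away from the
  # boundaries
  prep <- sys$prep_e
  cent_r <- rowMeans(matrix(sph$mesh$nodes[prep$elem, 1], prep$ne, 3))
  cent_z <- rowMeans(matrix(sph$mesh$nodes[prep$elem, 2], prep$ne, 3))
  rho <- sqrt(cent_r^2 + cent_z^2) * 1e3
  mid <- which(rho > 3 & rho < 10)
  qr4 <- es$Q_rf[mid] * rho[mid]^4
  expect_lt((max(qr4) - min(qr4)) / stats::median(qr4), 0.1)
})

test_that("electrical solve is linear in the power target", {
  mbh <- coarse_mesh("BH")
  sys <- rfablate:::electro_thermal_system(mbh)
  T0 <- rep(37, nrow(mbh$nodes))
  e1 <- solve_electric(sys, T0, 36)
  e2 <- solve_electric(sys, T0, 72)
  expect_equal(e2$applied_voltage, sqrt(2) * e1$applied_voltage,
               tolerance = 1e-9)
  expect_equal(e2$Q_rf, 2 * e1$Q_rf, tolerance = 1e-9)
  expect_equal(sum(e1$power_split), 36, tolerance = 1e-9)
  expect_error(solve_electric(sys, T0, -5), "positive")
})

test_that("transient slab benchmark matches the series solution", {
  slab <- make_conduction_slab()
  expect_gt(slab$Bi, 1)                       # genuinely distributed regime
  sys <- rfablate:::electro_thermal_system(slab$mesh, bc = slab$bc)
  T_cur <- rep(37, nrow(slab$mesh$nodes))
  dt <- 0.05
  for (i in seq_len(round(30 / dt)))
    T_cur <- step_thermal(sys, T_cur, NULL, dt)$T
  for (z in c(0, 2.5, 5)) {
    sel <- abs(slab$mesh$nodes[, 2] * 1e3 - (z - slab$L)) < 1e-6
    expect_lt(abs(mean(T_cur[sel]) - slab$reference(z, 30)), 0.5)
  }
})

test_that("small-Biot slab follows the lumped-capacitance decay", {
  slab <- make_conduction_slab(L = 2, h = 20, T_amb = 57)
  expect_lt(slab$Bi, 0.1)
  sys <- rfablate:::electro_thermal_system(slab$mesh, bc = slab$bc)
  T_cur <- rep(37, nrow(slab$mesh$nodes))
  dt <- 0.5
  t_end <- 60
  for (i in seq_len(round(t_end / dt)))
    T_cur <- step_thermal(sys, T_cur, NULL, dt)$T
  # within 1% of the full 37 -> 57 C excursion
  expect_lt(abs(mean(T_cur) - slab$lumped(t_end)) / (57 - 37), 0.01)
})

test_that("a uniform field with matched ambient is a steady state", {
  slab <- make_conduction_slab(T_amb = 37)
  sys <- rfablate:::electro_thermal_system(slab$mesh, bc = slab$bc)
  T0 <- rep(37, nrow(slab$mesh$nodes))
  st <- step_thermal(sys, T0, NULL, 0.05)
  expect_equal(st$T, T0, tolerance = 1e-10)
})

test_that("RF heating raises the peak tissue temperature monotonically at
           onset and respects the temperature floor", {
  mbh <- coarse_mesh("BH")
  sys <- rfablate:::electro_thermal_system(mbh)
  T0 <- rep(37, nrow(mbh$nodes))
  T0[sys$th_fixed] <- sys$th_fixed_val
  es <- solve_electric(sys, T0, 20)
  th_src <- sys$reg_e %in% c(1L, 4L)
  q <- rfablate:::accumulate_nodal(
    sys$prep_e$elem[th_src, , drop = FALSE],
    sys$prep_e$w_node[th_src, , drop = FALSE] * es$Q_rf[th_src],
    nrow(mbh$nodes))
  st <- step_thermal(sys, T0, q, 0.05)
  tis_nodes <- sort(unique(as.integer(mbh$elem[mbh$region == 1L, ])))
  expect_gt(max(st$T[tis_nodes]), 37)
  expect_true(all(st$T[sys$th_active] >= 25 - 1e-6))
})

test_that("a zero-length pulse leaves the tissue unheated and lesion-free", {
  mbh <- coarse_mesh("BH")
  run <- run_simulation(mbh, energy_setting(25, 0, observation_time = 1),
                        dt = 0.05)
  tis <- run$tissue_nodes
  expect_true(all(run$T[tis] <= 37 + 1e-9))
  les <- extract_lesion(mbh, run$Omega)
  expect_true(les$empty)
  expect_true(is.na(run$P_T))
})

test_that("energy is conserved over a heated run", {
  mbh <- coarse_mesh("BH")
  run <- run_simulation(mbh, energy_setting(50, 2, observation_time = 3),
                        dt = 0.05)
  expect_lt(abs(run$energy$residual) / run$energy$deposited, 0.01)
  # power splits sum to the applied power during the pulse
  in_pulse <- !is.na(run$log$P_tissue)
  tot <- with(run$log[in_pulse, ], P_tissue + P_blood + P_shaft)
  expect_equal(tot, rep(40, sum(in_pulse)), tolerance = 1e-9)
})

test_that("thermal latency grows the lesion after power-off", {
  mbh <- coarse_mesh("BH")
  run <- run_simulation(mbh, energy_setting(90, 2, observation_time = 8),
                        dt = 0.05, snapshot_times = c(2, 8))
  m_rf <- lesion_at(run, 2)
  m_end <- lesion_at(run, 8)
  expect_false(m_rf$empty)
  expect_gte(m_end$depth, m_rf$depth)
  expect_gte(m_end$max_width, m_rf$max_width)
  expect_gte(m_end$volume, m_rf$volume)
})
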