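# Closed-form verification cases: every solver and analysis stage can be
# checked quantitatively without any external data. Each case carries its
# own independent reference solution (series expansion, exact conductance,
# scalar quadrature) and a tolerance tight enough to catch sign and scale
# errors on the coarse meshes the cases build.

# Hand-build a minimal tagged mesh from a structured (r, z) grid with a
# caller-supplied element classifier and facet tagger. Used by the analytic
# cases; production meshes come from build_geometry().
grid_mesh_axi <- function(rs, zs, region_fun, tag_fun,
                          scenario = list(model = "BH", orientation = 90,
                                          tissue_material = "myocardium")) {
  nr <- length(rs); nz <- length(zs)
  nodes <- cbind(rep(rs, times = nz), rep(zs, each = nr))
  idx <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nr - 1L)
  elem <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  cent <- (nodes[elem[, 1], ] + nodes[elem[, 2], ] + nodes[elem[, 3], ]) / 3
  region <- region_fun(cent)
  fac <- extract_facets(elem, nrow(nodes))
  ext_f <- is.na(fac$e2)
  fc <- (nodes[fac$facets[, 1], ] + nodes[fac$facets[, 2], ]) / 2
  tag <- tag_fun(fc, ext_f, region[fac$e1],
                 ifelse(ext_f, 0L, region[fac$e2]))
  keep <- !is.na(tag)
  structure(list(mode = "axisymmetric", nodes = nodes * 1e-3,
                 elem = elem, region = region,
                 facets = fac$facets[keep, , drop = FALSE],
                 facet_tag = tag[keep],
                 scenario = scenario, sym_factor = 1),
            class = "rf_mesh")
}

#' Transient conduction slab benchmark
#'
#' A tissue slab of thickness `L`, insulated at the base and sides, exposed
#' at the surface to a convective (Robin) condition whose ambient
#' temperature steps from the initial 37 C to `T_amb`. The exact solution is
#' the classical single-term-per-eigenvalue series in the Biot and Fourier
#' numbers; the lumped-capacitance exponential is the small-Biot limit.
#'
#' @param L slab thickness (mm).
#' @param h film coefficient (W/m2.K).
#' @param T_amb ambient temperature after the step (C).
#' @param h_mesh target element size (mm).
#' @param n_terms series terms in the reference solution.
#' @return a list with the `mesh`, matching [boundary_conditions()], the
#'   material, closed-form `reference(z_mm, t)` and `lumped(t)` callables,
#'   and the eigenvalues used.
#' @export
make_conduction_slab <- function(L = 5, h = 694, T_amb = 57, h_mesh = 0.25,
                                 n_terms = 12) {
  mat <- material_library()[["myocardium"]]
  rs <- seq(0, 1, by = 0.5)
  zs <- seq(-L, 0, by = h_mesh)
  mesh <- grid_mesh_axi(
    rs, zs,
    region_fun = function(cent) rep(1L, nrow(cent)),
    tag_fun = function(fc, ext_f, r1, r2) {
      tag <- rep(NA_integer_, nrow(fc))
      tag[ext_f & abs(fc[, 2]) < 1e-9] <- 6L   # surface: tissue-blood Robin
      tag                                       # everything else insulated
    })
  Lm <- L * 1e-3
  alpha <- mat$k / (mat$rho * mat$c)
  Bi <- h * Lm / mat$k
  lam <- vapply(seq_len(n_terms), function(n) {
    stats::uniroot(function(x) x * sin(x) - Bi * cos(x),
                   c((n - 1) * pi + 1e-9, (n - 1) * pi + pi / 2 - 1e-9),
                   tol = 1e-13)$root
  }, 0)
  Cn <- 4 * sin(lam) / (2 * lam + sin(2 * lam))
  reference <- function(z_mm, t) {
    # z_mm measured from the insulated base (0) to the surface (L)
    x <- z_mm / L
    Fo <- alpha * t / Lm^2
    th <- vapply(x, function(xi)
      sum(Cn * exp(-lam^2 * Fo) * cos(lam * xi)), 0)
    T_amb + (37 - T_amb) * th
  }
  lumped <- function(t)
    T_amb + (37 - T_amb) * exp(-h * t / (mat$rho * mat$c * Lm))
  list(name = "conduction_slab", mesh = mesh, material = mat, L = L,
       bc = boundary_conditions(h_tissue_blood = h, T_blood = T_amb,
                                T_body = 37),
       reference = reference, lumped = lumped, Bi = Bi,
       eigenvalues = lam, tolerance = 0.5)
}

#' Concentric-spheres electrical benchmark
#'
#' A spherical electrode of radius `r1` inside a concentric grounded shell
#' of radius `r2` in a homogeneous conductor: the conductance is
#' `4 pi sigma / (1/r1 - 1/r2)` and the dissipated power density falls as
#' `r^-4`. Exercises the electrical assembly, the Dirichlet solve and the
#' constant-power normalization on an axisymmetric mesh.
#'
#' @param r1,r2 electrode and shell radii (mm).
#' @param n_rho,n_theta radial and angular resolution.
#' @return list with the `mesh`, the conductance `closed_form` (S, using the
#'   myocardium conductivity at 37 C) and the radii.
#' @export
make_spherical_electrode_case <- function(r1 = 1, r2 = 20, n_rho = 60,
                                          n_theta = 48) {
  mat <- material_library()[["myocardium"]]
  # geometric radial grading, polar mesh over the half disk
  rho <- r1 * 0.5 * (r2 / (r1 * 0.5))^(seq(0, 1, length.out = n_rho))
  theta <- seq(0, pi, length.out = n_theta)
  nodes_r <- outer(rho, theta, function(p, t) p * sin(t))
  nodes_z <- outer(rho, theta, function(p, t) p * cos(t))
  nr <- length(rho); nt <- length(theta)
  nodes <- cbind(as.numeric(nodes_r), as.numeric(nodes_z))
  idx <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1L), times = nt - 1L)
  j <- rep(seq_len(nt - 1L), each = nr - 1L)
  elem <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  cent_rho <- sqrt(((nodes[elem[, 1], 1] + nodes[elem[, 2], 1] +
                       nodes[elem[, 3], 1]) / 3)^2 +
                     ((nodes[elem[, 1], 2] + nodes[elem[, 2], 2] +
                         nodes[elem[, 3], 2]) / 3)^2)
  region <- ifelse(cent_rho < r1, 3L, 1L)
  fac <- extract_facets(elem, nrow(nodes))
  ext_f <- is.na(fac$e2)
  frho <- sqrt(((nodes[fac$facets[, 1], 1] + nodes[fac$facets[, 2], 1]) / 2)^2 +
                 ((nodes[fac$facets[, 1], 2] + nodes[fac$facets[, 2], 2]) / 2)^2)
  tag <- rep(NA_integer_, nrow(fac$facets))
  tag[ext_f & frho > 0.9 * r2] <- 1L            # grounded outer shell
  keep <- !is.na(tag)
  mesh <- structure(list(mode = "axisymmetric", nodes = nodes * 1e-3,
                         elem = elem, region = region,
                         facets = fac$facets[keep, , drop = FALSE],
                         facet_tag = tag[keep],
                         scenario = list(model = "BH", orientation = 90,
                                         tissue_material = "myocardium"),
                         sym_factor = 1), class = "rf_mesh")
  sigma <- mat$sigma_ref
  G <- 4 * pi * sigma / (1 / (r1 * 1e-3) - 1 / (r2 * 1e-3))
  list(name = "concentric_spheres", mesh = mesh, r1 = r1, r2 = r2,
       sigma = sigma, conductance = G, tolerance = 0.01)
}

#' Prescribed-temperature damage benchmarks
#'
#' Constant exposures and a linear ramp with independent high-precision
#' references for the Arrhenius damage integral: constants evaluate in
#' closed form (`t * A * exp(-Ea/(R T_K))`), the ramp by adaptive
#' quadrature.
#'
#' @param params an [arrhenius_params()].
#' @return list of cases, each with `times`, a temperature trajectory `T`
#'   and the reference damage `omega_ref`.
#' @export
make_damage_case <- function(params = arrhenius_params()) {
  const_ref <- function(T, t)
    t * params$A * exp(-params$Ea / (params$R * (T + 273.15)))
  ramp_ref <- function(T0, T1, t_tot) {
    stats::integrate(function(tau) {
      Ttau <- T0 + (T1 - T0) * tau / t_tot
      params$A * exp(-params$Ea / (params$R * (Ttau + 273.15)))
    }, 0, t_tot, rel.tol = 1e-12)$value
  }
  list(
    list(name = "constant_72C_5s", times = seq(0, 5, by = 0.05),
         T = rep(72, 101), omega_ref = const_ref(72, 5)),
    list(name = "constant_58C_5s", times = seq(0, 5, by = 0.05),
         T = rep(58, 101), omega_ref = const_ref(58, 5)),
    list(name = "constant_37C_60s", times = seq(0, 60, by = 0.5),
         T = rep(37, 121), omega_ref = const_ref(37, 60)),
    list(name = "ramp_37_90C_10s", times = seq(0, 10, by = 0.002),
         T = 37 + (90 - 37) * seq(0, 10, by = 0.002) / 10,
         omega_ref = ramp_ref(37, 90, 10))
  )
}

#' Run all analytic verification cases
#'
#' Executes the slab, concentric-spheres and damage benchmarks against the
#' package solvers and returns a pass/fail report.
#'
#' @param dt slab time step (s).
#' @return data.frame with one row per check: case, measured error, bound,
#'   pass.
#' @export
verify_analytic <- function(dt = 0.1) {
  rows <- list()
  # slab: step response against the series solution at t = 30 s
  slab <- make_conduction_slab()
  sys <- electro_thermal_system(slab$mesh, bc = slab$bc)
  T_cur <- rep(37, nrow(slab$mesh$nodes))
  t_end <- 30
  for (i in seq_len(round(t_end / dt)))
    T_cur <- step_thermal(sys, T_cur, NULL, dt)$T
  zq <- c(0, 2.5, 5)
  num <- vapply(zq, function(z) {
    sel <- abs(slab$mesh$nodes[, 2] * 1e3 - (z - slab$L)) < 1e-6
    mean(T_cur[sel])
  }, 0)
  err_slab <- max(abs(num - slab$reference(zq, t_end)))
  rows[[1]] <- data.frame(case = "conduction_slab_series", error = err_slab,
                          bound = slab$tolerance,
                          pass = err_slab < slab$tolerance)
  # spheres: conductance and power normalization
  sph <- make_spherical_electrode_case()
  sys2 <- electro_thermal_system(sph$mesh)
  es <- solve_electric(sys2, rep(37, nrow(sph$mesh$nodes)), 10)
  G_fem <- 10 / es$applied_voltage^2
  err_g <- abs(G_fem - sph$conductance) / sph$conductance
  rows[[2]] <- data.frame(case = "spheres_conductance", error = err_g,
                          bound = sph$tolerance, pass = err_g < sph$tolerance)
  p_tot <- sum(es$power_split)
  err_p <- abs(p_tot - 10) / 10
  rows[[3]] <- data.frame(case = "spheres_power_normalization",
                          error = err_p, bound = 1e-3, pass = err_p < 1e-3)
  # damage oracles
  for (cs in make_damage_case()) {
    om <- arrhenius_integrate(cs$T, cs$times)
    rel <- abs(om - cs$omega_ref) / max(cs$omega_ref, 1e-300)
    bound <- if (grepl("constant", cs$name)) 1e-6 else 1e-4
    rows[[length(rows) + 1L]] <-
      data.frame(case = paste0("damage_", cs$name), error = rel,
                 bound = bound, pass = rel < bound)
  }
  do.call(rbind, rows)
}
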