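#' Energy setting (power-duration protocol)
#'
#' The nominal generator power is reduced by 20 percent before application
#' because the model domain does not include the whole torso; the standard
#' protocol matrix is 25 W/20 s (moderate power, moderate duration),
#' 50 W/6 s (high power, short duration) and 90 W/4 s (very high power,
#' very short duration), each observed to 90 s after onset to capture
#' thermal latency.
#'
#' @param nominal_power generator power setting (W).
#' @param pulse_duration RF pulse length (s).
#' @param observation_time total simulated time from RF onset (s).
#' @param power_reduction fraction of nominal power not applied.
#' @return an `energy_setting` object with the `applied_power` actually
#'   driven through the electrode.
#' @export
energy_setting <- function(nominal_power, pulse_duration,
                           observation_time = 90, power_reduction = 0.2) {
  stopifnot(nominal_power > 0, pulse_duration >= 0,
            observation_time >= pulse_duration,
            power_reduction >= 0, power_reduction < 1)
  structure(list(nominal_power = nominal_power,
                 applied_power = nominal_power * (1 - power_reduction),
                 pulse_duration = pulse_duration,
                 observation_time = observation_time),
            class = "energy_setting")
}

#' The three standard ablation protocols
#' @return named list of [energy_setting()] objects.
#' @export
standard_settings <- function() {
  list(MPMD = energy_setting(25, 20),
       HPSD = energy_setting(50, 6),
       vHPvSD = energy_setting(90, 4))
}

#' Thermal boundary conditions
#'
#' Convective film coefficients for the electrode-blood and tissue-blood
#' interfaces (values for ~0.1 m/s local blood flow), blood and body
#' temperatures, and the saline irrigation temperature fixed on the
#' cylindrical zone of the electrode tip.
#'
#' @param h_electrode_blood,h_tissue_blood film coefficients (W/m2.K).
#' @param T_blood,T_body,T_irrigation temperatures (degrees C).
#' @return a `boundary_conditions` object.
#' @export
boundary_conditions <- function(h_electrode_blood = 3310,
                                h_tissue_blood = 694, T_blood = 37,
                                T_body = 37, T_irrigation = 25) {
  stopifnot(h_electrode_blood >= 0, h_tissue_blood >= 0)
  structure(list(h_electrode_blood = h_electrode_blood,
                 h_tissue_blood = h_tissue_blood, T_blood = T_blood,
                 T_body = T_body, T_irrigation = T_irrigation),
            class = "boundary_conditions")
}

# Assemble the full coupled system context for a mesh: element subsets,
# stiffness templates, node sets for Dirichlet data, constant thermal
# operator parts and factorization caches.
electro_thermal_system <- function(mesh, materials = material_library(),
                                   bc = boundary_conditions(),
                                   phase = phase_change_model(),
                                   anisotropic = FALSE) {
  if (anisotropic && mesh$mode == "axisymmetric")
    stop(paste("fiber anisotropy breaks axial symmetry;",
               "use the 3d_half mode for the anisotropy study"),
         call. = FALSE)
  nn <- nrow(mesh$nodes)
  by_kind <- split(materials, vapply(materials, `[[`, "", "kind"))
  tissue <- materials[[mesh$scenario$tissue_material]]
  if (is.null(tissue)) stop("unknown tissue material", call. = FALSE)
  blood <- by_kind$blood[[1]]
  electrode <- by_kind$electrode[[1]]
  shaft <- by_kind$shaft[[1]]

  e_elec <- which(mesh$region != 3L)            # electrode interior excluded
  e_th <- which(mesh$region != 2L)              # blood excluded
  prep_e <- fem_prep(mesh, e_elec)
  prep_t <- fem_prep(mesh, e_th)
  tmpl_e <- stiffness_template(prep_e)
  tmpl_t <- stiffness_template(prep_t)
  reg_e <- mesh$region[e_elec]
  reg_t <- mesh$region[e_th]

  # --- electrical node sets
  elec_active <- sort(unique(as.integer(prep_e$elem)))
  electrode_nodes <- sort(unique(as.integer(
    mesh$elem[mesh$region == 3L, ])))
  ground_tags <- c(1L, 7L)                      # dispersive + outer body
  ground_nodes <- sort(unique(as.integer(
    mesh$facets[mesh$facet_tag %in% ground_tags, ])))
  src_nodes <- intersect(electrode_nodes, elec_active)
  elec_fixed <- union(src_nodes, intersect(ground_nodes, elec_active))
  elec_fixed_val <- c(rep(1, length(src_nodes)),
                      rep(0, length(elec_fixed) - length(src_nodes)))

  # --- thermal node sets
  th_active <- sort(unique(as.integer(prep_t$elem)))
  irr_nodes <- sort(unique(as.integer(
    mesh$facets[mesh$facet_tag == 4L, ])))
  body_nodes <- setdiff(sort(unique(as.integer(
    mesh$facets[mesh$facet_tag == 7L, ]))), irr_nodes)
  th_fixed <- c(irr_nodes, body_nodes)
  th_fixed_val <- c(rep(bc$T_irrigation, length(irr_nodes)),
                    rep(bc$T_body, length(body_nodes)))

  # --- constant thermal stiffness (conductivities are T-independent)
  k_tis <- thermal_conductivity_tensor(tissue, anisotropic)
  if (is.numeric(k_tis) && length(k_tis) == 3)
    k_tis <- as.list(k_tis)
  kap_t <- if (is.list(k_tis)) {
    list(x = ifelse(reg_t == 1L, k_tis$x,
                    ifelse(reg_t == 3L, electrode$k, shaft$k)),
         y = ifelse(reg_t == 1L, k_tis$y,
                    ifelse(reg_t == 3L, electrode$k, shaft$k)),
         z = ifelse(reg_t == 1L, k_tis$z,
                    ifelse(reg_t == 3L, electrode$k, shaft$k)))
  } else {
    ifelse(reg_t == 1L, k_tis,
           ifelse(reg_t == 3L, electrode$k, shaft$k))
  }
  K_th <- assemble_stiffness(tmpl_t, kap_t, nn)

  # --- lumped Robin terms (constant): electrode/shaft-blood and
  # tissue-blood convective interfaces
  rob_diag <- numeric(nn)
  rob_load <- numeric(nn)
  for (tg in c(5L, 6L)) {
    wf <- which(mesh$facet_tag == tg)
    if (!length(wf)) next
    h <- if (tg == 5L) bc$h_electrode_blood else bc$h_tissue_blood
    fw <- facet_weights(mesh, wf)
    rob_diag <- rob_diag + accumulate_nodal(fw$facets, h * fw$w, nn)
  }
  rob_load <- rob_diag * bc$T_blood
  K_th_bc <- K_th + Matrix::Diagonal(nn, rob_diag)

  # --- capacity bookkeeping: constant part (electrode + shaft) and the
  # per-vertex weight/index arrays of the tissue elements (phase change)
  tis_el <- reg_t == 1L
  w_tis <- prep_t$w_node[tis_el, , drop = FALSE]
  id_tis <- prep_t$elem[tis_el, , drop = FALSE]
  const_cap <- accumulate_nodal(
    prep_t$elem[!tis_el, , drop = FALSE],
    prep_t$w_node[!tis_el, , drop = FALSE] *
      ifelse(reg_t[!tis_el] == 3L, electrode$rho * electrode$c,
             shaft$rho * shaft$c), nn)

  list(mesh = mesh, nn = nn, bc = bc, phase = phase,
       tissue = tissue, blood = blood, electrode = electrode, shaft = shaft,
       e_elec = e_elec, e_th = e_th, prep_e = prep_e, prep_t = prep_t,
       tmpl_e = tmpl_e, reg_e = reg_e, reg_t = reg_t,
       elec_active = elec_active, elec_fixed = elec_fixed,
       elec_fixed_val = elec_fixed_val,
       th_active = th_active, th_fixed = th_fixed,
       th_fixed_val = th_fixed_val,
       K_th_bc = K_th_bc, rob_diag = rob_diag, rob_load = rob_load,
       w_tis = w_tis, id_tis = id_tis, const_cap = const_cap,
       tis_el = tis_el, cache = new.env(parent = emptyenv()))
}

# Element-mean temperature over a prep's elements.
element_mean <- function(prep, T) {
  rowMeans(matrix(T[prep$elem], prep$ne, prep$k))
}

#' Quasi-static electrical solve with constant-power scaling
#'
#' Solves the Laplace problem `div(sigma(T) grad Phi) = 0` with unit voltage
#' on the electrode, 0 V on the dispersive boundaries and natural (zero
#' current) conditions on the symmetry and air-blood boundaries, then scales
#' the solution so that the total dissipated power equals `target_power`
#' (exact by linearity at frozen conductivity).
#'
#' @param sys system context from `electro_thermal_system`.
#' @param T nodal temperature field (degrees C).
#' @param target_power total power to dissipate (W, full domain).
#' @return list with nodal `Phi` (V), elemental power density `Q_rf` (W/m3,
#'   over the electrical element subset), `power_split` (W, named by
#'   region), `applied_voltage` (V) and `impedance` (ohm).
#' @export
solve_electric <- function(sys, T, target_power) {
  if (target_power <= 0) stop("target_power must be positive", call. = FALSE)
  sig <- numeric(sys$prep_e$ne)
  tis <- sys$reg_e == 1L
  Te <- element_mean(sys$prep_e, T)
  sig[tis] <- electrical_conductivity(sys$tissue, Te[tis], sys$phase)
  sig[sys$reg_e == 2L] <- sys$blood$sigma_ref
  sig[sys$reg_e == 4L] <- sys$shaft$sigma_ref
  A <- assemble_stiffness(sys$tmpl_e, sig, sys$nn)
  sol <- solve_dirichlet(A, numeric(sys$nn), sys$elec_fixed,
                         sys$elec_fixed_val, sys$elec_active,
                         cache = sys$cache, name = "ch_elec")
  Q <- elemental_grad_sq(sys$prep_e, sol$x, sig)       # sigma |E|^2 at 1 V
  P_el <- Q * sys$prep_e$weight
  P_unit <- sum(P_el)
  if (!is.finite(P_unit) || P_unit <= 0)
    stop("singular electrical system: no dissipation at unit voltage",
         call. = FALSE)
  s <- sqrt(target_power / P_unit)
  split <- vapply(c(1L, 2L, 4L), function(r) sum(P_el[sys$reg_e == r]), 0) *
    s^2
  names(split) <- c("tissue", "blood", "shaft")
  list(Phi = sol$x * s, Q_rf = Q * s^2, power_split = split,
       applied_voltage = s, impedance = s^2 / target_power)
}

#' One implicit step of the enthalpy-form thermal problem
#'
#' Backward-Euler update with mass-lumped apparent heat capacity evaluated
#' as the enthalpy secant between the previous temperature and the current
#' Picard iterate, which conserves deposited enthalpy across the latent
#' band. Robin convective conditions and the irrigation/body Dirichlet data
#' are those prepared in the system context.
#'
#' @param sys system context.
#' @param T_old nodal temperature at the previous time level.
#' @param q_src nodal heat load vector (W, full-domain, lumped), e.g. from
#'   [solve_electric()] densities; use `NULL` for no source.
#' @param dt time step (s).
#' @param tol Picard tolerance on the max nodal change (degrees C).
#' @param max_iter Picard iteration cap.
#' @return list with `T` (updated field), `iter`, and the step's energy
#'   tallies `robin_out` and `dirichlet_out` (J).
#' @export
step_thermal <- function(sys, T_old, q_src, dt, tol = 0.1, max_iter = 10L) {
  if (is.null(q_src)) q_src <- numeric(sys$nn)
  Tk <- T_old
  secant_cap <- function(Ta, Tb) {
    dh <- tissue_enthalpy(sys$tissue, Tb, sys$phase) -
      tissue_enthalpy(sys$tissue, Ta, sys$phase)
    dT <- Tb - Ta
    out <- dh / dT
    small <- abs(dT) < 1e-8
    if (any(small))
      out[small] <- apparent_heat_capacity(sys$tissue, Ta[small], sys$phase)
    out
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cs <- secant_cap(T_old[sys$id_tis], Tk[sys$id_tis])
    cap <- sys$const_cap +
      accumulate_nodal(sys$id_tis, sys$w_tis * cs, sys$nn)
    d <- cap / dt
    # the thermal operator changes only through the capacity diagonal (the
    # latent band); reuse the cached factorization when it is unchanged
    skip <- !is.null(sys$cache$th_diag) &&
      length(sys$cache$th_diag) == length(d) &&
      max(abs(d - sys$cache$th_diag)) <= 1e-9 * max(d)
    A <- sys$K_th_bc + Matrix::Diagonal(sys$nn, d)
    b <- d * T_old + q_src + sys$rob_load
    sol <- solve_dirichlet(A, b, sys$th_fixed, sys$th_fixed_val,
                           sys$th_active, cache = sys$cache,
                           name = "ch_th", reactions = TRUE,
                           skip_update = skip)
    sys$cache$th_diag <- d
    T_new <- sol$x
    delta <- max(abs(T_new[sys$th_active] - Tk[sys$th_active]))
    Tk <- T_new
    if (delta < tol || iter >= max_iter) break
  }
  act <- sys$th_active
  robin_out <- sum(sys$rob_diag[act] * T_new[act] - sys$rob_load[act]) * dt
  list(T = T_new, iter = iter, robin_out = robin_out,
       dirichlet_out = -sum(sol$reaction) * dt)
}

arrhenius_rate <- function(T, arr) {
  arr$A * exp(-arr$Ea / (arr$R * (T + 273.15)))
}

#' Run a coupled electro-thermal ablation simulation
#'
#' Alternates the quasi-static electrical solve (conductivity from the
#' current temperature, rescaled to hold the applied power constant) with
#' implicit thermal steps during the pulse, then integrates the source-free
#' thermal decay to the observation time. Arrhenius damage is accumulated
#' with trapezoidal quadrature on the solver's time grid.
#'
#' @param mesh an `rf_mesh` from [build_geometry()].
#' @param setting an [energy_setting()].
#' @param bc a [boundary_conditions()].
#' @param dt time step during the pulse (s); the range used for convergence
#'   checking is 0.02-0.1 s.
#' @param dt_post time step after the pulse (s).
#' @param snapshot_times times (s) at which nodal temperature and damage
#'   snapshots are stored; pulse end and the final time are always included.
#' @param materials material library.
#' @param phase a [phase_change_model()].
#' @param arr an [arrhenius_params()].
#' @param anisotropic use the anisotropic tissue conductivity tensor
#'   (3d_half mode only).
#' @param progress print per-second progress.
#' @return an object of class `rf_run`: per-step scalar log, power/energy
#'   splits, snapshots of temperature and damage, and energy-balance
#'   accounting.
#' @export
run_simulation <- function(mesh, setting, bc = boundary_conditions(),
                           dt = 0.05, dt_post = dt,
                           snapshot_times = numeric(0),
                           materials = material_library(),
                           phase = phase_change_model(),
                           arr = arrhenius_params(),
                           anisotropic = FALSE, progress = FALSE) {
  stopifnot(inherits(setting, "energy_setting"))
  if (dt <= 0 || dt_post <= 0) stop("time steps must be positive")
  sys <- electro_thermal_system(mesh, materials, bc, phase, anisotropic)
  t_rf <- setting$pulse_duration
  t_end <- setting$observation_time
  times_pulse <- if (t_rf > 0) seq_len(ceiling(t_rf / dt - 1e-9)) * dt else
    numeric(0)
  if (length(times_pulse)) times_pulse[length(times_pulse)] <- t_rf
  times_post <- if (t_end > t_rf + 1e-12)
    t_rf + seq_len(ceiling((t_end - t_rf) / dt_post - 1e-9)) * dt_post else
      numeric(0)
  if (length(times_post)) times_post[length(times_post)] <- t_end
  times <- c(times_pulse, times_post)
  snapshot_times <- sort(unique(c(snapshot_times, t_rf, t_end)))

  nn <- sys$nn
  T_cur <- rep(bc$T_body, nn)
  T_cur[sys$th_fixed] <- sys$th_fixed_val
  Omega <- numeric(nn)
  rate_old <- arrhenius_rate(T_cur, arr)
  tissue_nodes <- sort(unique(as.integer(sys$id_tis)))

  nstep <- length(times)
  log <- data.frame(time = times, applied_voltage = NA_real_,
                    impedance = NA_real_, P_tissue = NA_real_,
                    P_blood = NA_real_, P_shaft = NA_real_,
                    max_T = NA_real_, picard = NA_integer_)
  E_split <- c(tissue = 0, blood = 0, shaft = 0)
  P_T <- NA_real_
  E_T <- NA_real_
  dep <- 0; rob <- 0; dir_out <- 0
  snaps <- list()
  H0 <- sum(sys$w_tis * tissue_enthalpy(sys$tissue, T_cur[sys$id_tis],
                                        phase)) +
    sum(sys$const_cap * (T_cur - bc$T_body))
  t_prev <- 0
  for (s_i in seq_len(nstep)) {
    t_now <- times[s_i]
    h <- t_now - t_prev
    in_pulse <- t_now <= t_rf + 1e-12 && t_rf > 0
    if (in_pulse) {
      es <- solve_electric(sys, T_cur, setting$applied_power)
      q_src <- numeric(nn)
      th_src <- sys$reg_e %in% c(1L, 4L)
      q_src <- accumulate_nodal(
        sys$prep_e$elem[th_src, , drop = FALSE],
        sys$prep_e$w_node[th_src, , drop = FALSE] * es$Q_rf[th_src], nn)
      if (is.na(P_T)) {
        P_T <- 100 * es$power_split[["tissue"]] / sum(es$power_split)
      }
      E_split <- E_split + es$power_split * h
      log$applied_voltage[s_i] <- es$applied_voltage
      log$impedance[s_i] <- es$applied_voltage^2 / setting$applied_power
      log$P_tissue[s_i] <- es$power_split[["tissue"]]
      log$P_blood[s_i] <- es$power_split[["blood"]]
      log$P_shaft[s_i] <- es$power_split[["shaft"]]
      dep <- dep + sum(es$power_split[c("tissue", "shaft")]) * h
    } else {
      q_src <- NULL
    }
    st <- step_thermal(sys, T_cur, q_src, h)
    T_cur <- st$T
    rob <- rob + st$robin_out
    dir_out <- dir_out + st$dirichlet_out
    rate_new <- arrhenius_rate(T_cur, arr)
    Omega <- Omega + h * (rate_old + rate_new) / 2
    rate_old <- rate_new
    log$max_T[s_i] <- max(T_cur[tissue_nodes])
    log$picard[s_i] <- st$iter
    if (abs(t_now - t_rf) < 1e-9 && is.na(E_T))
      E_T <- 100 * E_split[["tissue"]] / sum(E_split)
    hit <- snapshot_times[abs(snapshot_times - t_now) < min(h, dt) / 2]
    if (length(hit))
      snaps[[sprintf("%.6g", hit[1])]] <-
        list(time = t_now, T = T_cur, Omega = Omega)
    if (progress && (s_i %% max(1L, round(1 / h)) == 0L))
      message(sprintf("t = %.2f s, max T = %.1f C", t_now,
                      log$max_T[s_i]))
    t_prev <- t_now
  }
  H1 <- sum(sys$w_tis * tissue_enthalpy(sys$tissue, T_cur[sys$id_tis],
                                        phase)) +
    sum(sys$const_cap * (T_cur - bc$T_body))
  structure(list(
    mesh = mesh, setting = setting, bc = bc, sys = sys, log = log,
    P_T = unname(P_T), E_T = unname(E_T), energy_split = E_split,
    snapshots = snaps, T = T_cur, Omega = Omega,
    tissue_nodes = tissue_nodes,
    energy = list(deposited = dep, stored = H1 - H0, robin_out = rob,
                  dirichlet_out = dir_out,
                  residual = dep - (H1 - H0) - rob - dir_out)),
    class = "rf_run")
}

#' @export
print.rf_run <- function(x, ...) {
  cat(sprintf("<rf_run> %s %d deg, %g W/%g s (applied %g W)\n",
              x$mesh$scenario$model, x$mesh$scenario$orientation,
              x$setting$nominal_power, x$setting$pulse_duration,
              x$setting$applied_power))
  cat(sprintf("  P_T = %.2f%%, E_T = %.2f%%, max T = %.1f C\n",
              x$P_T, x$E_T, max(x$log$max_T, na.rm = TRUE)))
  invisible(x)
}
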