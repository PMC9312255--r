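# Study orchestration: single scenarios, the full model x setting x
# orientation matrix, the blood-height sweep, the thermal-anisotropy study
# and between-model difference tables.

#' Simulate one scenario and summarize it
#'
#' Builds the mesh, runs the coupled simulation and extracts lesion metrics
#' at pulse end and at the end of the observation window, together with the
#' power/energy accounting.
#'
#' @param model `"BH"`, `"TM"` or `"INTERMEDIATE"`.
#' @param orientation catheter angle: 90, 45 or 0 degrees.
#' @param setting an [energy_setting()].
#' @param resolution a [mesh_resolution()].
#' @param blood_height blood layer height (mm, TM/INTERMEDIATE).
#' @param anisotropic use the anisotropic myocardium conductivity tensor.
#' @param dt,dt_post time steps (s).
#' @param mode mesh mode override; defaults to axisymmetric at 90 degrees.
#' @param bc boundary conditions.
#' @param materials material library.
#' @param mesh optional prebuilt mesh (skips meshing).
#' @param snapshot_times extra snapshot times (s).
#' @return a `scenario_result` list: the `run`, `metrics_rf` and
#'   `metrics_end` lesion metrics, `P_T`, `E_T` and the identifying fields.
#' @export
run_scenario <- function(model, orientation = 90, setting,
                         resolution = mesh_resolution(), blood_height = 20,
                         anisotropic = FALSE, dt = 0.05, dt_post = dt,
                         mode = NULL, bc = boundary_conditions(),
                         materials = material_library(), mesh = NULL,
                         snapshot_times = numeric(0)) {
  if (is.null(mesh)) {
    sc <- scenario_geometry(model, orientation, blood_height = blood_height)
    mesh <- if (is.null(mode)) build_geometry(sc, resolution)
    else build_geometry(sc, resolution, mode = mode)
  }
  run <- run_simulation(mesh, setting, bc = bc, dt = dt, dt_post = dt_post,
                        snapshot_times = snapshot_times,
                        materials = materials, anisotropic = anisotropic)
  structure(list(
    model = model, orientation = orientation, setting = setting,
    anisotropic = anisotropic,
    blood_height = if (model == "BH") NA_real_ else blood_height,
    run = run,
    metrics_rf = lesion_at(run, setting$pulse_duration),
    metrics_end = lesion_at(run, setting$observation_time),
    P_T = run$P_T, E_T = run$E_T), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s %d deg, %g W/%g s\n", x$model,
              x$orientation, x$setting$nominal_power,
              x$setting$pulse_duration))
  cat("  t_RF : "); print(x$metrics_rf)
  cat("  t_end: "); print(x$metrics_end)
  cat(sprintf("  P_T = %.2f%%, E_T = %.2f%%\n", x$P_T, x$E_T))
  invisible(x)
}

scenario_row <- function(res) {
  data.frame(
    model = res$model, orientation = res$orientation,
    nominal_power = res$setting$nominal_power,
    pulse_duration = res$setting$pulse_duration,
    depth_rf = res$metrics_rf$depth, depth_end = res$metrics_end$depth,
    width_rf = res$metrics_rf$max_width, width_end = res$metrics_end$max_width,
    ratio_rf = res$metrics_rf$ratio, ratio_end = res$metrics_end$ratio,
    volume_rf = res$metrics_rf$volume, volume_end = res$metrics_end$volume,
    P_T = res$P_T, E_T = res$E_T, error = NA_character_)
}

#' Run a study matrix of scenarios
#'
#' Runs a list of scenarios under identical numerical controls and collects
#' a results table shaped like the lesion-size and power-accounting tables
#' of the comparison study (3 models x 3 settings x 3 orientations in the
#' full design). Failures are reported per scenario without aborting the
#' rest.
#'
#' @param scenarios data.frame with columns `model`, `orientation`,
#'   `nominal_power`, `pulse_duration`; defaults to the full 27-scenario
#'   design.
#' @param observation_time seconds simulated after RF onset.
#' @param ... passed to [run_scenario()].
#' @return data.frame of lesion metrics (mm, mm3) and power/energy
#'   percentages, one row per scenario; failed rows carry the error message.
#' @export
run_matrix <- function(scenarios = NULL, observation_time = 90, ...) {
  if (is.null(scenarios))
    scenarios <- expand.grid(model = c("BH", "INTERMEDIATE", "TM"),
                             orientation = c(0, 45, 90),
                             setting = c("25/20", "50/6", "90/4"),
                             stringsAsFactors = FALSE)
  if (!nrow(scenarios)) return(data.frame())
  if (!is.null(scenarios$setting) && is.null(scenarios$nominal_power)) {
    ps <- strsplit(scenarios$setting, "/")
    scenarios$nominal_power <- as.numeric(vapply(ps, `[`, "", 1))
    scenarios$pulse_duration <- as.numeric(vapply(ps, `[`, "", 2))
  }
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    tryCatch({
      res <- run_scenario(sc$model, sc$orientation,
                          energy_setting(sc$nominal_power, sc$pulse_duration,
                                         observation_time), ...)
      scenario_row(res)
    }, error = function(e) {
      data.frame(model = sc$model, orientation = sc$orientation,
                 nominal_power = sc$nominal_power,
                 pulse_duration = sc$pulse_duration,
                 depth_rf = NA_real_, depth_end = NA_real_,
                 width_rf = NA_real_, width_end = NA_real_,
                 ratio_rf = NA_real_, ratio_end = NA_real_,
                 volume_rf = NA_real_, volume_end = NA_real_,
                 P_T = NA_real_, E_T = NA_real_,
                 error = conditionMessage(e))
    })
  })
  do.call(rbind, rows)
}

#' Between-model difference report
#'
#' Differences of lesion metrics and power/energy percentages between the
#' thigh-muscle (or intermediate) and beating-heart models at matched
#' setting and orientation, from one [run_matrix()] table.
#'
#' @param matrix_df output of [run_matrix()].
#' @param other `"TM"` or `"INTERMEDIATE"`.
#' @return data.frame of `other` minus BH deltas per (setting, orientation).
#' @export
difference_report <- function(matrix_df, other = "TM") {
  bh <- matrix_df[matrix_df$model == "BH", ]
  ot <- matrix_df[matrix_df$model == other, ]
  key <- function(d) paste(d$orientation, d$nominal_power, d$pulse_duration)
  m <- match(key(bh), key(ot))
  ot <- ot[m, ]
  cols <- c("depth_rf", "depth_end", "width_rf", "width_end",
            "volume_rf", "volume_end", "P_T", "E_T")
  out <- bh[c("orientation", "nominal_power", "pulse_duration")]
  for (cl in cols) out[[paste0("d_", cl)]] <- ot[[cl]] - bh[[cl]]
  out
}

#' Blood-height sweep on the thigh-muscle model
#'
#' Re-meshes and re-runs the TM scenario for each blood-pool height and
#' tabulates the lesion metrics, to locate the height above which the
#' air-blood interface no longer influences the lesion.
#'
#' @param heights blood heights (mm); output is sorted by height.
#' @param setting an [energy_setting()]; the study default is 25 W/20 s.
#' @param orientation catheter angle.
#' @param ... passed to [run_scenario()].
#' @return data.frame of metrics per height.
#' @export
blood_height_sweep <- function(heights,
                               setting = energy_setting(25, 20),
                               orientation = 90, ...) {
  if (any(heights <= 0)) stop("heights must be positive", call. = FALSE)
  heights <- sort(heights)
  rows <- lapply(heights, function(hh) {
    res <- run_scenario("TM", orientation, setting, blood_height = hh, ...)
    cbind(blood_height = hh, scenario_row(res))
  })
  do.call(rbind, rows)
}

#' Thermal anisotropy study
#'
#' Paired isotropic/anisotropic runs of the beating-heart model (fibers
#' parallel to the tissue surface along one axis), reporting the lesion
#' depth, directional widths and volume of both runs and their deltas.
#' Requires the half-domain tetrahedral mode, since fiber anisotropy breaks
#' axial symmetry.
#'
#' @param setting an [energy_setting()].
#' @param orientation catheter angle (degrees).
#' @param resolution a [mesh_resolution()].
#' @param at_time metrics time (s); defaults to the observation end.
#' @param ... passed to [run_scenario()].
#' @return list with both `scenario_result`s and the `deltas` (anisotropic
#'   minus isotropic, mm and mm3).
#' @export
anisotropy_study <- function(setting, orientation = 90,
                             resolution = mesh_resolution(),
                             at_time = setting$observation_time, ...) {
  sc <- scenario_geometry("BH", orientation)
  mesh <- build_geometry(sc, resolution, mode = "3d_half")
  iso <- run_scenario("BH", orientation, setting, mesh = mesh, ...)
  ani <- run_scenario("BH", orientation, setting, mesh = mesh,
                      anisotropic = TRUE, ...)
  mi <- lesion_at(iso$run, at_time)
  ma <- lesion_at(ani$run, at_time)
  list(isotropic = iso, anisotropic = ani,
       metrics_isotropic = mi, metrics_anisotropic = ma,
       deltas = c(depth = ma$depth - mi$depth,
                  width_fiber = ma$width_x - mi$width_x,
                  width_transverse = ma$width_y - mi$width_y,
                  volume = ma$volume - mi$volume))
}

#' Mesh convergence study
#'
#' Runs a scenario at successively finer resolutions and returns the
#' coarsest one whose lesion depth changes by less than `depth_tol` and
#' whose peak tissue temperature changes by less than `temp_tol` against
#' the next finer resolution.
#'
#' @param scenario a [scenario_geometry()].
#' @param resolutions list of [mesh_resolution()] objects ordered from
#'   coarse to fine.
#' @param setting an [energy_setting()].
#' @param depth_tol convergence criterion on lesion depth (mm).
#' @param temp_tol convergence criterion on peak temperature (degrees C).
#' @param runner function(scenario, resolution, setting) returning
#'   `list(depth =, max_T =)`; the default runs the full simulation and
#'   measures the pulse-end lesion. Injectable for testing.
#' @param ... passed to the default runner's [run_scenario()].
#' @return list with `converged` (index into `resolutions` or `NA`),
#'   `table` of per-resolution results and the observed deltas.
#' @export
convergence_study <- function(scenario, resolutions, setting,
                              depth_tol = 0.5, temp_tol = 1,
                              runner = NULL, ...) {
  if (length(resolutions) < 2)
    stop("need at least two resolutions", call. = FALSE)
  if (is.null(runner))
    runner <- function(sc, res, st) {
      r <- run_scenario(sc$model, sc$orientation, st, resolution = res,
                        blood_height = if (is.na(sc$blood_height)) 20 else
                          sc$blood_height, ...)
      list(depth = r$metrics_rf$depth, max_T = max(r$run$log$max_T))
    }
  out <- lapply(resolutions, function(res) runner(scenario, res, setting))
  depth <- vapply(out, `[[`, 0, "depth")
  maxT <- vapply(out, `[[`, 0, "max_T")
  dd <- abs(diff(depth)); dT <- abs(diff(maxT))
  ok <- which(dd < depth_tol & dT < temp_tol)
  list(converged = if (length(ok)) min(ok) else NA_integer_,
       table = data.frame(resolution = seq_along(resolutions),
                          depth = depth, max_T = maxT),
       depth_deltas = dd, temp_deltas = dT)
}
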