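# Shared builders and a per-file cache so expensive simulations are run at
# most once per test file.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) assign(key, force(expr), envir = .run_cache)
  .run_cache[[key]]
}

# Coarse axisymmetric meshes for fast unit tests.
coarse_mesh <- function(model = "BH", scale = 3, ...) {
  cached(paste0("mesh_", model, "_", scale),
         build_geometry(scenario_geometry(model, ...),
                        mesh_resolution(scale = scale)))
}

# Independent scalar oracle for the Arrhenius damage integral at constant
# temperature (closed form, not the package quadrature).
omega_const <- function(T_c, t_s, A = 7.39e39, Ea = 2.577e5, R = 8.3143) {
  t_s * A * exp(-Ea / (R * (T_c + 273.15)))
}
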