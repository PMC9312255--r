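#' Tissue and material properties
#'
#' Constructor for the physical constants of one material: electrical
#' conductivity at 37 degrees C and 500 kHz, thermal conductivity, density,
#' specific heat, and (for biological tissue) the water mass fraction that
#' scales the vaporization latent heat. Optional anisotropic thermal
#' conductivities describe muscle fiber orientation: the longitudinal value
#' applies along the fiber axis (parallel to the tissue surface), the
#' transverse value across fibers; their mean must equal the isotropic `k`.
#'
#' @param name character label.
#' @param sigma_ref electrical conductivity at 37 C (S/m).
#' @param k isotropic thermal conductivity (W/m.K). May be `NA` for blood,
#'   which never enters the thermal problem.
#' @param rho density (kg/m3).
#' @param c specific heat (J/kg.K).
#' @param water_mass_fraction dimensionless fraction of water by mass, in
#'   (0, 1); `NA` for non-biological materials.
#' @param k_transverse,k_longitudinal optional directional thermal
#'   conductivities (W/m.K) for the anisotropy study.
#' @param kind one of `"tissue"`, `"blood"`, `"electrode"`, `"shaft"`.
#' @return an object of class `tissue_properties`.
#' @export
tissue_properties <- function(name, sigma_ref, k = NA_real_, rho = NA_real_,
                              c = NA_real_, water_mass_fraction = NA_real_,
                              k_transverse = NULL, k_longitudinal = NULL,
                              kind = "tissue") {
  stopifnot(is.character(name), length(name) == 1L)
  kind <- match.arg(kind, c("tissue", "blood", "electrode", "shaft"))
  num1 <- function(x, what, positive = TRUE, allow_na = FALSE) {
    if (allow_na && (is.null(x) || is.na(x))) return(NA_real_)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a finite numeric scalar", what), call. = FALSE)
    if (positive && x <= 0)
      stop(sprintf("'%s' must be strictly positive", what), call. = FALSE)
    as.numeric(x)
  }
  sigma_ref <- num1(sigma_ref, "sigma_ref")
  thermal <- kind != "blood"
  k <- num1(k, "k", allow_na = !thermal)
  rho <- num1(rho, "rho", allow_na = !thermal)
  c <- num1(c, "c", allow_na = !thermal)
  wmf <- num1(water_mass_fraction, "water_mass_fraction", allow_na = TRUE)
  if (!is.na(wmf) && (wmf <= 0 || wmf >= 1))
    stop("'water_mass_fraction' must lie strictly inside (0, 1)", call. = FALSE)
  aniso <- !is.null(k_transverse) || !is.null(k_longitudinal)
  if (aniso) {
    if (is.null(k_transverse) || is.null(k_longitudinal))
      stop("anisotropy requires both 'k_transverse' and 'k_longitudinal'",
           call. = FALSE)
    k_transverse <- num1(k_transverse, "k_transverse")
    k_longitudinal <- num1(k_longitudinal, "k_longitudinal")
    if (abs((k_transverse + k_longitudinal) / 2 - k) > 1e-12)
      stop("mean of the directional conductivities must equal the isotropic k",
           call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, sigma_ref = sigma_ref, k = k, rho = rho,
         c = c, water_mass_fraction = wmf,
         k_transverse = if (aniso) k_transverse else NA_real_,
         k_longitudinal = if (aniso) k_longitudinal else NA_real_),
    class = "tissue_properties")
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat(sprintf("<%s> %s: sigma_ref = %g S/m", x$kind, x$name, x$sigma_ref))
  if (!is.na(x$k))
    cat(sprintf(", k = %g W/m.K, rho = %g kg/m3, c = %g J/kg.K",
                x$k, x$rho, x$c))
  if (!is.na(x$water_mass_fraction))
    cat(sprintf(", water fraction = %g", x$water_mass_fraction))
  cat("\n")
  invisible(x)
}

#' Load the material library
#'
#' Reads the structured text material library shipped with the package (or a
#' user-supplied file with the same layout) and returns a named list of
#' [tissue_properties()] records, one per material row.
#'
#' @param path path to a YAML material file; defaults to the library shipped
#'   with the package.
#' @return named list of `tissue_properties`.
#' @export
material_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials.yaml", package = "rfablate",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)$materials
  mats <- lapply(raw, function(m) {
    tissue_properties(
      name = m[["name"]], sigma_ref = m[["sigma"]],
      k = m[["k"]] %||% NA_real_, rho = m[["rho"]] %||% NA_real_,
      c = m[["c"]] %||% NA_real_,
      water_mass_fraction = m[["water_mass_fraction"]] %||% NA_real_,
      k_transverse = m[["k_transverse"]],
      k_longitudinal = m[["k_longitudinal"]],
      kind = m[["kind"]])
  })
  names(mats) <- vapply(mats, `[[`, "", "name")
  mats
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phase-change (vaporization) model constants
#'
#' The enthalpy formulation spreads the water-vaporization latent heat over a
#' 1 degree band below 100 C. The volumetric latent heat of water is the
#' product of the vaporization latent heat (2256 kJ/kg) and the density of
#' water (958 kg/m3), both at 100 C; a tissue's latent heat is this value
#' scaled by its water mass fraction. Electrical conductivity collapses by a
#' factor `drop_factor` (two decades) between `sigma_drop_lo` and
#' `sigma_drop_hi`.
#'
#' @param Hw_vol volumetric latent heat of water (J/m3).
#' @param T_lo,T_hi latent band edges (degrees C); `delta_T = T_hi - T_lo`.
#' @param sigma_drop_lo,sigma_drop_hi conductivity collapse band (degrees C).
#' @param drop_factor total conductivity drop across the band.
#' @return an object of class `phase_change_model`.
#' @export
phase_change_model <- function(Hw_vol = 2256e3 * 958, T_lo = 99, T_hi = 100,
                               sigma_drop_lo = 99, sigma_drop_hi = 101,
                               drop_factor = 100) {
  stopifnot(Hw_vol > 0, T_hi > T_lo, sigma_drop_hi > sigma_drop_lo,
            drop_factor > 1)
  structure(list(Hw_vol = Hw_vol, T_lo = T_lo, T_hi = T_hi,
                 delta_T = T_hi - T_lo, sigma_drop_lo = sigma_drop_lo,
                 sigma_drop_hi = sigma_drop_hi, drop_factor = drop_factor),
            class = "phase_change_model")
}

#' Arrhenius damage kinetics parameters
#'
#' First-order thermal denaturation kinetics: damage rate
#' `A * exp(-Ea / (R * T_K))` with `T_K` in Kelvin. The defaults are the
#' frequency factor and activation energy widely used for radiofrequency
#' ablation lesion assessment.
#'
#' @param A frequency factor (1/s).
#' @param Ea activation energy (J/mol).
#' @param R universal gas constant (J/mol.K).
#' @return an object of class `arrhenius_params`.
#' @export
arrhenius_params <- function(A = 7.39e39, Ea = 2.577e5, R = 8.3143) {
  stopifnot(A > 0, Ea > 0, R > 0)
  structure(list(A = A, Ea = Ea, R = R), class = "arrhenius_params")
}

#' Temperature-dependent electrical conductivity
#'
#' Linear rise of 1.5 percent per degree C relative to the 37 C reference up
#' to 99 C, then a log-linear collapse spanning two orders of magnitude
#' between 99 and 101 C (dehydration by vaporization), constant beyond.
#'
#' @param props a [tissue_properties()] record.
#' @param T temperature(s), degrees C. Vectorized.
#' @param phase a [phase_change_model()].
#' @return conductivity in S/m, same length as `T`.
#' @export
electrical_conductivity <- function(props, T, phase = phase_change_model()) {
  if (!all(is.finite(T))) stop("temperatures must be finite", call. = FALSE)
  if (any(T < 0)) stop("temperatures below 0 C are not supported", call. = FALSE)
  lo <- phase$sigma_drop_lo
  hi <- phase$sigma_drop_hi
  s_lo <- props$sigma_ref * (1 + 0.015 * (lo - 37))
  s <- props$sigma_ref * (1 + 0.015 * (T - 37))
  mid <- T > lo & T < hi
  s[mid] <- s_lo * phase$drop_factor^(-(T[mid] - lo) / (hi - lo))
  s[T >= hi] <- s_lo / phase$drop_factor
  s
}

#' Volumetric enthalpy of tissue relative to 37 C
#'
#' Piecewise enthalpy: sensible heat up to the latent band edge, latent heat
#' released linearly across the band, sensible heat of the (identical)
#' dehydrated tissue above. The nominal lower bound of the sensible branch is
#' relaxed to all temperatures below the band so that the irrigated 25 C
#' Dirichlet zone is representable.
#'
#' @inheritParams electrical_conductivity
#' @return enthalpy per unit volume (J/m3) relative to 37 C.
#' @export
tissue_enthalpy <- function(props, T, phase = phase_change_model()) {
  if (!all(is.finite(T))) stop("temperatures must be finite", call. = FALSE)
  rc <- props$rho * props$c
  Ht <- phase$Hw_vol * props$water_mass_fraction
  lo <- phase$T_lo
  hi <- phase$T_hi
  h <- rc * (T - 37)
  band <- T > lo & T <= hi
  h[band] <- rc * (lo - 37) + Ht * (T[band] - lo) / phase$delta_T
  above <- T > hi
  h[above] <- rc * (lo - 37) + Ht + rc * (T[above] - hi)
  h
}

#' Apparent volumetric heat capacity
#'
#' Derivative of [tissue_enthalpy()]: `rho * c` outside the latent band,
#' `H_t / delta_T` inside it, where `H_t` is the volumetric latent heat of
#' the tissue (water latent heat times water mass fraction). Dehydrated
#' density and specific heat are taken identical to the hydrated values.
#'
#' @inheritParams electrical_conductivity
#' @return volumetric heat capacity (J/m3.K), same length as `T`.
#' @export
apparent_heat_capacity <- function(props, T, phase = phase_change_model()) {
  if (!all(is.finite(T))) stop("temperatures must be finite", call. = FALSE)
  rc <- props$rho * props$c
  Ht <- phase$Hw_vol * props$water_mass_fraction
  out <- rep(rc, length(T))
  out[T > phase$T_lo & T <= phase$T_hi] <- Ht / phase$delta_T
  out
}

#' Thermal conductivity tensor
#'
#' Isotropic scalar `k`, or a diagonal tensor for the muscle-fiber anisotropy
#' study: the longitudinal conductivity acts along the fiber axis (taken as
#' the first surface-parallel coordinate), the transverse conductivity across
#' fibers (second surface-parallel coordinate and tissue depth).
#'
#' @param props a [tissue_properties()] record.
#' @param anisotropic logical flag.
#' @return for the isotropic case a scalar; otherwise a named numeric vector
#'   `c(x = k_longitudinal, y = k_transverse, z = k_transverse)` of diagonal
#'   entries (W/m.K).
#' @export
thermal_conductivity_tensor <- function(props, anisotropic = FALSE) {
  if (!anisotropic) return(props$k)
  if (is.na(props$k_transverse) || is.na(props$k_longitudinal))
    stop("anisotropic conductivity requested but directional values are unset",
         call. = FALSE)
  c(x = props$k_longitudinal, y = props$k_transverse, z = props$k_transverse)
}
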