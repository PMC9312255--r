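#' Irrigated ablation catheter specification
#'
#' Geometry of the 7.5 Fr (2.5 mm diameter), 3.5 mm long irrigated-tip
#' electrode: a cylinder capped by a hemispherical tip, followed by a
#' polyurethane shaft. Insertion depth depends on orientation so that the
#' electrode-tissue contact area is the same in all three positions
#' (0.5 mm perpendicular, 0.498 mm at 45 degrees, 0.193 mm parallel).
#'
#' @param electrode_diameter electrode diameter (mm); 7.5 Fr at 1 Fr = 1/3 mm.
#' @param electrode_length total electrode length including the tip (mm).
#' @param orientation catheter-to-surface angle in degrees: 90, 45 or 0.
#' @param insertion_depth tip embedding below the tissue surface (mm);
#'   defaults to the orientation-matched value.
#' @param shaft_length_modeled modeled shaft length above the electrode (mm);
#'   default four electrode diameters.
#' @return an object of class `catheter_spec`.
#' @export
catheter_spec <- function(orientation = 90,
                          electrode_diameter = 2.5,
                          electrode_length = 3.5,
                          insertion_depth = NULL,
                          shaft_length_modeled = 4 * electrode_diameter) {
  if (!orientation %in% c(0, 45, 90))
    stop("orientation must be one of 0, 45, 90 degrees", call. = FALSE)
  if (is.null(insertion_depth))
    insertion_depth <- switch(as.character(orientation),
                              "90" = 0.5, "45" = 0.498, "0" = 0.193)
  stopifnot(electrode_diameter > 0, electrode_length > electrode_diameter / 2,
            insertion_depth > 0, shaft_length_modeled > 0)
  if (insertion_depth >= electrode_length)
    stop("insertion_depth must be smaller than the electrode length",
         call. = FALSE)
  structure(list(
    electrode_diameter = electrode_diameter,
    electrode_radius = electrode_diameter / 2,
    electrode_length = electrode_length,
    cylinder_length = electrode_length - electrode_diameter / 2,
    insertion_depth = insertion_depth,
    orientation = orientation,
    shaft_length_modeled = shaft_length_modeled),
    class = "catheter_spec")
}

#' Scenario geometry
#'
#' One of the three preclinical model geometries: `"BH"` (beating heart:
#' blood fills the chamber above the tissue out to the domain boundary),
#' `"TM"` (thigh muscle: a blood layer of finite height with an air
#' interface on top) and `"INTERMEDIATE"` (the TM geometry with myocardium
#' properties, isolating geometric from material effects).
#'
#' @param model `"BH"`, `"TM"` or `"INTERMEDIATE"`.
#' @param orientation catheter angle (degrees), passed to [catheter_spec()].
#' @param blood_height blood layer height above the tissue (mm); only used by
#'   the TM and INTERMEDIATE models.
#' @param domain_margin tissue/blood extent around the electrode (mm).
#' @param tissue_material material name in the library; defaults to
#'   striated muscle for TM and myocardium otherwise.
#' @param catheter optional [catheter_spec()] override.
#' @return an object of class `scenario_geometry`.
#' @export
scenario_geometry <- function(model = c("BH", "TM", "INTERMEDIATE"),
                              orientation = 90, blood_height = 20,
                              domain_margin = 40, tissue_material = NULL,
                              catheter = NULL) {
  model <- match.arg(model)
  if (is.null(catheter)) catheter <- catheter_spec(orientation)
  if (is.null(tissue_material))
    tissue_material <- if (model == "TM") "striated_muscle" else "myocardium"
  if (model != "BH" && blood_height <= 0)
    stop("blood_height must be positive for the TM/INTERMEDIATE models",
         call. = FALSE)
  if (model != "BH" && blood_height <= catheter$electrode_length -
        catheter$insertion_depth)
    stop("blood layer must cover the electrode protrusion", call. = FALSE)
  stopifnot(domain_margin > 0)
  structure(list(model = model, orientation = orientation,
                 blood_height = if (model == "BH") NA_real_ else blood_height,
                 domain_margin = domain_margin,
                 tissue_material = tissue_material, catheter = catheter),
            class = "scenario_geometry")
}

# --- graded 1-D coordinate utilities (all in mm) -------------------------

# Sequence from `from` to `to` whose first step is ~h0 and grows geometrically
# by `growth` up to h_max; steps are rescaled so the last point lands exactly
# on `to`. Returns increasing coordinates when to > from, else decreasing.
grow_seq <- function(from, to, h0, growth = 1, h_max = Inf) {
  span <- abs(to - from)
  if (span < h0 * 0.5) return(c(from, to))
  steps <- numeric(0)
  h <- h0
  total <- 0
  while (total < span) {
    steps <- c(steps, h)
    total <- total + h
    h <- min(h * growth, h_max)
  }
  steps <- steps * (span / total)
  sgn <- sign(to - from)
  c(from, from + sgn * cumsum(steps))
}

# Replace the grid line nearest to each snap point with the exact value
# (insert instead when the nearest line is far on the local grid scale).
snap_insert <- function(coords, pts) {
  coords <- sort(coords)
  for (p in pts) {
    if (p < min(coords) || p > max(coords)) next
    i <- which.min(abs(coords - p))
    gap <- if (i == 1) coords[2] - coords[1] else
      if (i == length(coords)) diff(coords[(i - 1):i]) else
        min(diff(coords[(i - 1):(i + 1)]))
    if (abs(coords[i] - p) <= 0.45 * gap) coords[i] <- p
    else coords <- sort(c(coords, p))
  }
  unique(sort(coords))
}

# Piecewise coordinate vector: fine uniform band [fine_lo, fine_hi] at h_fine,
# optional intermediate band at h_mid, geometric growth to the domain ends.
graded_axis <- function(lo, hi, fine_lo, fine_hi, h_fine, growth, h_max,
                        mid_lo = fine_lo, mid_hi = fine_hi, h_mid = h_fine,
                        snap = numeric(0)) {
  parts <- list(seq(fine_lo, fine_hi, length.out =
                      max(2L, ceiling((fine_hi - fine_lo) / h_fine) + 1L)))
  if (mid_lo < fine_lo)
    parts <- c(parts, list(grow_seq(fine_lo, mid_lo, h_fine, sqrt(growth), h_mid)))
  if (mid_hi > fine_hi)
    parts <- c(parts, list(grow_seq(fine_hi, mid_hi, h_fine, sqrt(growth), h_mid)))
  if (lo < mid_lo)
    parts <- c(parts, list(grow_seq(mid_lo, lo, h_mid, growth, h_max)))
  if (hi > mid_hi)
    parts <- c(parts, list(grow_seq(mid_hi, hi, h_mid, growth, h_max)))
  coords <- sort(unique(round(unlist(parts), 9)))
  coords <- snap_insert(coords, snap)
  # collapse any pair of planes closer than the build tolerance
  coords[c(TRUE, diff(coords) > 1e-8)]
}

#' Mesh resolution controls
#'
#' @param scale global multiplier on all target element sizes; smaller is
#'   finer. `scale = 1` is the package default desk-scale fidelity.
#' @param h_tip target edge length next to the electrode (mm).
#' @param h_lesion target edge length in the expected lesion zone (mm).
#' @param growth geometric growth factor toward the far field.
#' @param h_max maximum far-field edge length (mm).
#' @return a `mesh_resolution` list.
#' @export
mesh_resolution <- function(scale = 1, h_tip = 0.14 * scale,
                            h_lesion = 0.3 * scale, growth = 1.4,
                            h_max = 5) {
  stopifnot(h_tip > 0, h_lesion >= h_tip, growth > 1, h_max > h_lesion)
  structure(list(scale = scale, h_tip = h_tip, h_lesion = h_lesion,
                 growth = growth, h_max = h_max), class = "mesh_resolution")
}

# --- electrode geometry helpers (mm, tissue surface at z = 0) ------------

# Tip-sphere centre, axis direction and key lengths for a catheter at the
# given orientation. The tip sphere centre sits on the catheter axis one
# electrode radius above the deepest point of the electrode.
catheter_frame <- function(cat) {
  th <- cat$orientation * pi / 180
  a <- c(cos(th), 0, sin(th))                  # unit axis, tip -> shaft
  a[abs(a) < 1e-12] <- 0
  centre_z <- cat$electrode_radius - cat$insertion_depth
  list(axis = a, centre = c(0, 0, centre_z),
       cyl_len = cat$cylinder_length, R = cat$electrode_radius,
       shaft_len = cat$shaft_length_modeled)
}

# Distance from points (n x 3 matrix) to the segment [p0, p0 + len * a].
seg_dist <- function(pts, p0, a, len) {
  d <- sweep(pts, 2, p0)
  t <- pmin(pmax(d %*% a, 0), len)
  dx <- d - outer(as.numeric(t), as.numeric(a))
  sqrt(rowSums(dx^2))
}

# Region id for 3-D points: 1 tissue, 2 blood, 3 electrode, 4 shaft.
# The electrode is a hemispherically tipped cylinder with a flat far end
# where the shaft cylinder starts.
classify_points3 <- function(pts, frame, blood_top) {
  d <- sweep(pts, 2, frame$centre)
  t_ax <- as.numeric(d %*% frame$axis)
  rad2 <- rowSums(d^2) - t_ax^2
  inside_r <- rad2 <= frame$R^2 + 1e-15
  el <- (t_ax <= 0 & rowSums(d^2) <= frame$R^2 + 1e-15) |
    (t_ax > 0 & t_ax <= frame$cyl_len & inside_r)
  sh <- !el & t_ax > frame$cyl_len &
    t_ax <= frame$cyl_len + frame$shaft_len & inside_r
  reg <- ifelse(pts[, 3] < 0, 1L, 2L)
  reg[el] <- 3L
  reg[sh] <- 4L
  reg
}

#' Electrode-tissue contact area
#'
#' Numerically integrates the electrode surface (hemispherical tip plus
#' cylindrical side) lying below the undisturbed tissue plane. Used to check
#' that the three orientation-specific insertion depths produce the same
#' contact area.
#'
#' @param cat a [catheter_spec()].
#' @param n quadrature resolution per parametric direction.
#' @return contact area in mm^2.
#' @export
electrode_contact_area <- function(cat, n = 400) {
  fr <- catheter_frame(cat)
  R <- fr$R
  # orthonormal frame around the axis
  a <- fr$axis
  n1 <- c(0, 1, 0)
  n2 <- c(-a[3], 0, a[1])
  # tip hemisphere: points c + R * u with dot(u, a) <= 0
  th <- (seq_len(n) - 0.5) / n * pi / 2 + pi / 2   # polar angle from +a in [pi/2, pi]
  ph <- (seq_len(2 * n) - 0.5) / (2 * n) * 2 * pi
  grid <- expand.grid(th = th, ph = ph)
  u <- cos(grid$th)
  w <- sin(grid$th)
  pz <- fr$centre[3] + R * (u * a[3] + w * (cos(grid$ph) * n1[3] +
                                              sin(grid$ph) * n2[3]))
  dA <- R^2 * sin(grid$th) * (pi / 2 / n) * (2 * pi / (2 * n))
  sph <- sum(dA[pz < 0])
  # cylindrical side: c + t a + R(cos f n1 + sin f n2), t in [0, cyl_len]
  tt <- (seq_len(n) - 0.5) / n * fr$cyl_len
  ff <- (seq_len(2 * n) - 0.5) / (2 * n) * 2 * pi
  g2 <- expand.grid(t = tt, f = ff)
  pz2 <- fr$centre[3] + g2$t * a[3] + R * (cos(g2$f) * n1[3] + sin(g2$f) * n2[3])
  dA2 <- R * (fr$cyl_len / n) * (2 * pi / (2 * n))
  cyl <- sum(rep(dA2, nrow(g2))[pz2 < 0])
  sph + cyl
}
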