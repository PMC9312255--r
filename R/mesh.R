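# Mesh construction: graded structured grids classified into tagged regions.
# Axisymmetric mode meshes the (r, z) meridian plane with linear triangles
# (exact for the perpendicular catheter); 3D_half mode meshes the y >= 0 half
# domain with linear tetrahedra for tilted catheters. Node coordinates are
# stored in metres; geometry inputs are in mm.

REGION_LEVELS <- c("tissue", "blood", "electrode", "shaft")
TAG_LEVELS <- c("dispersive_0V", "air_blood_zero_current", "symmetry",
                "irrigated_dirichlet", "electrode_blood_convective",
                "tissue_blood_convective", "outer_body_37C")

#' Build a tagged simulation mesh
#'
#' Meshes a [scenario_geometry()] with a graded structured grid, classifies
#' elements into tissue / blood / electrode / shaft regions and tags every
#' exterior facet and every interface between the thermal domain and blood.
#' The perpendicular (90 degree) catheter is meshed in the axisymmetric
#' meridian plane; tilted catheters require the half-domain tetrahedral mode.
#'
#' @param scenario a [scenario_geometry()].
#' @param resolution a [mesh_resolution()].
#' @param mode `"axisymmetric"` (90 degrees only) or `"3d_half"`.
#' @return an object of class `rf_mesh`.
#' @export
build_geometry <- function(scenario, resolution = mesh_resolution(),
                           mode = if (scenario$orientation == 90)
                             "axisymmetric" else "3d_half") {
  mode <- match.arg(mode, c("axisymmetric", "3d_half"))
  if (mode == "axisymmetric" && scenario$orientation != 90)
    stop("axisymmetric mode requires the perpendicular (90 degree) catheter",
         call. = FALSE)
  if (mode == "axisymmetric") build_mesh_axi(scenario, resolution)
  else build_mesh_3d(scenario, resolution)
}

mesh_extents <- function(scenario) {
  cat <- scenario$catheter
  margin <- scenario$domain_margin
  r_max <- margin + cat$electrode_radius
  z_min <- -margin - cat$insertion_depth
  z_top <- if (scenario$model == "BH") margin else scenario$blood_height
  list(r_max = r_max, z_min = z_min, z_top = z_top)
}

build_mesh_axi <- function(scenario, resolution) {
  cat <- scenario$catheter
  res <- resolution
  ext <- mesh_extents(scenario)
  fr <- catheter_frame(cat)
  zc <- fr$centre[3]
  z_cyl_top <- zc + fr$cyl_len
  z_shaft_top <- min(z_cyl_top + fr$shaft_len, ext$z_top - 1)
  rs <- graded_axis(0, ext$r_max, 0, min(2.1, ext$r_max), res$h_tip,
                    res$growth, res$h_max, mid_hi = 6, h_mid = res$h_lesion,
                    snap = fr$R)
  zs <- graded_axis(ext$z_min, ext$z_top, -1.7, 3.3, res$h_tip,
                    res$growth, res$h_max, mid_lo = -7, h_mid = res$h_lesion,
                    snap = c(-cat$insertion_depth, 0, zc, z_cyl_top,
                             z_shaft_top))
  nr <- length(rs); nz <- length(zs)
  nodes <- cbind(r = rep(rs, times = nz), z = rep(zs, each = nr))
  idx <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nr - 1L)
  n00 <- idx(i, j); n10 <- idx(i + 1L, j)
  n11 <- idx(i + 1L, j + 1L); n01 <- idx(i, j + 1L)
  elem <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  cent <- (nodes[elem[, 1], ] + nodes[elem[, 2], ] + nodes[elem[, 3], ]) / 3
  frame3 <- list(axis = fr$axis, centre = fr$centre, cyl_len = fr$cyl_len,
                 R = fr$R, shaft_len = z_shaft_top - z_cyl_top)
  region <- classify_points3(cbind(cent[, 1], 0, cent[, 2]), frame3, ext$z_top)
  finish_mesh(scenario, resolution, mode = "axisymmetric",
              nodes = nodes, elem = elem, region = region, frame = frame3,
              ext = ext)
}

build_mesh_3d <- function(scenario, resolution) {
  cat <- scenario$catheter
  res <- resolution
  ext <- mesh_extents(scenario)
  fr <- catheter_frame(cat)
  shaft_end <- fr$centre + (fr$cyl_len + fr$shaft_len) * fr$axis
  cyl_top <- fr$centre + fr$cyl_len * fr$axis
  x_hi <- max(ext$r_max, shaft_end[1] + 2)
  # fine x band around the electrode footprint
  ex_lo <- min(-fr$R, fr$centre[1] - fr$R) - 1.2
  ex_hi <- max(fr$R, cyl_top[1] + fr$R) + 1.2
  xs_pos <- graded_axis(0, x_hi, 0, ex_hi, res$h_tip, res$growth, res$h_max,
                        mid_hi = ex_hi + 3.5, h_mid = res$h_lesion,
                        snap = c(fr$R, shaft_end[1]))
  xs_neg <- graded_axis(0, ext$r_max, 0, -ex_lo, res$h_tip, res$growth,
                        res$h_max, mid_hi = -ex_lo + 3.5, h_mid = res$h_lesion)
  xs <- sort(unique(c(-rev(xs_neg), xs_pos)))
  xs <- xs[c(TRUE, diff(xs) > 1e-8)]
  ys <- graded_axis(0, ext$r_max, 0, 2, res$h_tip, res$growth, res$h_max,
                    mid_hi = 5, h_mid = res$h_lesion)
  zs <- graded_axis(ext$z_min, ext$z_top, -1.7,
                    max(3.3, cyl_top[3] + fr$R + 0.5), res$h_tip,
                    res$growth, res$h_max, mid_lo = -7, h_mid = res$h_lesion,
                    snap = c(-cat$insertion_depth, 0, shaft_end[3]))
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- cbind(x = rep(xs, times = ny * nz),
                 y = rep(rep(ys, each = nx), times = nz),
                 z = rep(zs, each = nx * ny))
  idx <- function(i, j, k) ((k - 1L) * ny + (j - 1L)) * nx + i
  i <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  j <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  k <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  v0 <- idx(i, j, k);         v1 <- idx(i + 1L, j, k)
  v2 <- idx(i + 1L, j + 1L, k); v3 <- idx(i, j + 1L, k)
  v4 <- idx(i, j, k + 1L);     v5 <- idx(i + 1L, j, k + 1L)
  v6 <- idx(i + 1L, j + 1L, k + 1L); v7 <- idx(i, j + 1L, k + 1L)
  # six tetrahedra sharing the v0-v6 diagonal (face-compatible decomposition)
  elem <- rbind(cbind(v0, v1, v2, v6), cbind(v0, v2, v3, v6),
                cbind(v0, v3, v7, v6), cbind(v0, v7, v4, v6),
                cbind(v0, v4, v5, v6), cbind(v0, v5, v1, v6))
  cent <- (nodes[elem[, 1], ] + nodes[elem[, 2], ] +
             nodes[elem[, 3], ] + nodes[elem[, 4], ]) / 4
  region <- classify_points3(cent, fr, ext$z_top)
  finish_mesh(scenario, resolution, mode = "3d_half",
              nodes = nodes, elem = elem, region = region, frame = fr,
              ext = ext)
}

# Shared finishing: facet extraction + tagging, unit conversion, validation.
finish_mesh <- function(scenario, resolution, mode, nodes, elem, region,
                        frame, ext) {
  dim_k <- ncol(elem)
  nn <- nrow(nodes)
  fac <- extract_facets(elem, nn)
  tag <- tag_facets(fac, nodes, region, scenario, frame, ext, mode)
  keep <- !is.na(tag)
  mesh <- structure(list(
    mode = mode,
    nodes = nodes * 1e-3,
    elem = fac$elem,
    region = region,
    facets = fac$facets[keep, , drop = FALSE],
    facet_tag = tag[keep],
    frame = list(axis = frame$axis, centre = frame$centre * 1e-3,
                 cyl_len = frame$cyl_len * 1e-3, R = frame$R * 1e-3,
                 shaft_len = frame$shaft_len * 1e-3),
    blood_top = ext$z_top * 1e-3,
    extents = lapply(ext, function(v) v * 1e-3),
    scenario = scenario,
    resolution = resolution,
    sym_factor = if (mode == "3d_half") 2 else 1), class = "rf_mesh")
  validate_mesh(mesh)
  mesh
}

# Exterior facets (count 1) and thermal-domain/blood interface facets
# (count 2 with discordant regions). Returns facets with their adjacent
# element regions.
extract_facets <- function(elem, nn) {
  k <- ncol(elem)
  if (k == 3L) {
    loc <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  } else {
    loc <- list(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  }
  ne <- nrow(elem)
  faces <- do.call(rbind, lapply(loc, function(l) elem[, l, drop = FALSE]))
  owner <- rep(seq_len(ne), times = length(loc))
  if (k == 3L) {
    a <- pmin(faces[, 1], faces[, 2])
    b <- pmax(faces[, 1], faces[, 2])
    key <- a * (nn + 1) + b
  } else {
    lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
    hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
    mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
    key <- (lo * (nn + 1) + mid) * (nn + 1) + hi
  }
  ord <- order(key)
  key <- key[ord]; faces <- faces[ord, , drop = FALSE]; owner <- owner[ord]
  first <- !duplicated(key)
  i1 <- which(first)
  n_per <- diff(c(i1, length(key) + 1L))
  if (any(n_per > 2L)) stop("non-manifold mesh", call. = FALSE)
  facets <- faces[i1, , drop = FALSE]
  e1 <- owner[i1]
  e2 <- ifelse(n_per == 2L, owner[pmin(i1 + 1L, length(owner))], NA_integer_)
  list(facets = facets, e1 = e1, e2 = e2, elem = elem)
}

tag_facets <- function(fac, nodes, region, scenario, frame, ext, mode) {
  nf <- nrow(fac$facets)
  k <- ncol(fac$facets)
  cent <- matrix(0, nf, ncol(nodes))
  for (c_i in seq_len(k)) cent <- cent + nodes[fac$facets[, c_i], , drop = FALSE]
  cent <- cent / k
  if (mode == "axisymmetric") {
    cx <- cent[, 1]; cy <- rep(0, nf); cz <- cent[, 2]
  } else {
    cx <- cent[, 1]; cy <- cent[, 2]; cz <- cent[, 3]
  }
  tol <- 1e-9
  r1 <- region[fac$e1]
  r2 <- ifelse(is.na(fac$e2), 0L, region[fac$e2])
  tag <- rep(NA_integer_, nf)
  ext_f <- r2 == 0L
  tm_like <- scenario$model != "BH"
  # exterior facets
  if (mode == "axisymmetric") {
    on_sym <- ext_f & abs(cx) < tol
  } else {
    on_sym <- ext_f & abs(cy) < tol
  }
  on_top <- ext_f & abs(cz - ext$z_top) < 1e-6
  tag[ext_f & r1 == 1L] <- 7L                               # outer body, 37 C
  tag[ext_f & r1 == 2L] <- 1L                               # dispersive patch
  if (tm_like) tag[on_top & r1 == 2L] <- 2L                 # air-blood
  tag[ext_f & r1 %in% c(3L, 4L)] <- 1L
  tag[on_sym] <- 3L
  # interfaces between the thermal domain and blood
  pair <- function(a, b) (!ext_f) & ((r1 == a & r2 == b) | (r1 == b & r2 == a))
  tb <- pair(1L, 2L)
  tag[tb] <- 6L
  eb <- pair(3L, 2L)
  if (any(eb)) {
    t_ax <- (cx - frame$centre[1]) * frame$axis[1] +
      (cy - frame$centre[2]) * frame$axis[2] +
      (cz - frame$centre[3]) * frame$axis[3]
    tag[eb & t_ax > 0] <- 4L                                # irrigated cylinder
    tag[eb & t_ax <= 0] <- 5L                               # free tip
  }
  tag[pair(4L, 2L)] <- 5L                                   # shaft in blood
  tag
}

validate_mesh <- function(mesh) {
  if (mesh$mode == "axisymmetric" && any(mesh$nodes[, 1] < -1e-12))
    stop("axisymmetric mesh has nodes at negative radius", call. = FALSE)
  if (!all(mesh$region %in% 1:4))
    stop("unclassified elements present", call. = FALSE)
  if (!any(mesh$region == 1L) || !any(mesh$region == 2L) ||
      !any(mesh$region == 3L))
    stop("mesh must contain tissue, blood and electrode regions",
         call. = FALSE)
  invisible(mesh)
}

#' @export
print.rf_mesh <- function(x, ...) {
  cat(sprintf("<rf_mesh> %s %s, %d nodes, %d elements\n",
              x$scenario$model, x$mode, nrow(x$nodes), nrow(x$elem)))
  tab <- table(factor(REGION_LEVELS[x$region], levels = REGION_LEVELS))
  cat("  elements: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  tabf <- table(factor(TAG_LEVELS[x$facet_tag], levels = TAG_LEVELS))
  cat("  facets:   ", paste(names(tabf)[tabf > 0], tabf[tabf > 0],
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Element measures: triangle areas (m^2) or tet volumes (m^3), plus the
# full-domain measure weight (revolved 2*pi*r for axisymmetric, doubled for
# the half domain).
element_measures <- function(mesh) {
  el <- mesh$elem
  nd <- mesh$nodes
  if (mesh$mode == "axisymmetric") {
    r1 <- nd[el[, 1], 1]; z1 <- nd[el[, 1], 2]
    r2 <- nd[el[, 2], 1]; z2 <- nd[el[, 2], 2]
    r3 <- nd[el[, 3], 1]; z3 <- nd[el[, 3], 2]
    A <- 0.5 * abs((r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1))
    rbar <- (r1 + r2 + r3) / 3
    list(size = A, weight = 2 * pi * rbar * A, rbar = rbar)
  } else {
    a <- nd[el[, 2], ] - nd[el[, 1], ]
    b <- nd[el[, 3], ] - nd[el[, 1], ]
    c3 <- nd[el[, 4], ] - nd[el[, 1], ]
    det <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
    V <- abs(det) / 6
    list(size = V, weight = 2 * V, rbar = NULL)
  }
}

#' Region volumes of a mesh
#'
#' Full-domain volume of each region (the axisymmetric meridian section is
#' revolved; the half domain is doubled).
#'
#' @param mesh an `rf_mesh`.
#' @return named numeric vector of volumes in mm^3.
#' @export
region_volumes <- function(mesh) {
  w <- element_measures(mesh)$weight
  v <- vapply(1:4, function(r) sum(w[mesh$region == r]), 0)
  names(v) <- REGION_LEVELS
  v * 1e9
}

#' Export a mesh and nodal fields as a legacy VTK unstructured grid
#'
#' Writes an ASCII VTK file with region and boundary tags as cell data and
#' any number of nodal fields as point data, for inspection in ParaView.
#' Axisymmetric meshes are written as their meridian section in the x-z
#' plane.
#'
#' @param mesh an `rf_mesh`.
#' @param file output path.
#' @param point_data named list of nodal vectors.
#' @return `file`, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list()) {
  nd <- mesh$nodes
  if (ncol(nd) == 2) nd <- cbind(nd[, 1], 0, nd[, 2])
  el <- mesh$elem
  k <- ncol(el)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "rfablate mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nd))), con)
  utils::write.table(format(nd, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nrow(el), nrow(el) * (k + 1)), con)
  utils::write.table(cbind(k, el - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(as.character(rep(if (k == 3) 5L else 10L, nrow(el))), con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(el)),
               "SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$region), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nd)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      v <- point_data[[nm]]
      v[!is.finite(v)] <- 0
      writeLines(format(v, digits = 9, trim = TRUE), con)
    }
  }
  invisible(file)
}
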