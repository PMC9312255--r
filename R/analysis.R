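# Lesion analysis: Arrhenius damage accumulation, iso-contour extraction of
# the damage (or temperature) field and lesion geometry metrics, and the
# tissue/blood power and energy accounting.

#' Arrhenius thermal damage integral
#'
#' Accumulates the first-order damage index
#' `Omega(t) = integral of A exp(-Ea / (R T(tau))) dtau` (temperature in
#' Kelvin) by trapezoidal quadrature over a per-node temperature history.
#'
#' @param T_history numeric matrix, nodes x time points (degrees C), or a
#'   vector for a single node.
#' @param times strictly increasing time points (s), `ncol(T_history)` long.
#' @param params an [arrhenius_params()].
#' @param cumulative return the full damage time series (matrix) instead of
#'   only the final column.
#' @return damage index per node: vector, or nodes x times matrix when
#'   `cumulative = TRUE`. Time zero contributes nothing; a single time point
#'   yields zero damage.
#' @export
arrhenius_integrate <- function(T_history, times, params = arrhenius_params(),
                                cumulative = FALSE) {
  if (is.vector(T_history)) T_history <- matrix(T_history, nrow = 1)
  if (ncol(T_history) != length(times))
    stop("T_history must have one column per time point", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(T_history)))
    stop("temperatures must be finite", call. = FALSE)
  if (any(T_history < -273.15))
    stop("temperatures below absolute zero", call. = FALSE)
  rate <- params$A * exp(-params$Ea / (params$R * (T_history + 273.15)))
  nt <- length(times)
  if (nt < 2) {
    out <- matrix(0, nrow(T_history), nt)
  } else {
    dt <- diff(times)
    seg <- (rate[, -nt, drop = FALSE] + rate[, -1, drop = FALSE]) / 2
    seg <- sweep(seg, 2, dt, `*`)
    out <- cbind(0, t(apply(seg, 1, cumsum)))
    if (nrow(T_history) == 1) out <- matrix(out, nrow = 1)
  }
  if (cumulative) out else out[, nt]
}

# Collect the point cloud of the `field >= level` region boundary and
# interior corners restricted to tissue elements: tissue nodes at or above
# the level plus linear edge crossings. Coordinates in metres, as 3-column
# matrices (axisymmetric: (r, 0, z)).
level_region_points <- function(mesh, field, level) {
  tis <- mesh$region == 1L
  el <- mesh$elem[tis, , drop = FALSE]
  nodes_t <- sort(unique(as.integer(el)))
  above <- nodes_t[which(field[nodes_t] >= level)]
  k <- ncol(el)
  eg <- if (k == 3L) list(c(1L, 2L), c(2L, 3L), c(3L, 1L)) else
    list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
  a_idx <- integer(0); b_idx <- integer(0)
  for (e in eg) {
    a_idx <- c(a_idx, el[, e[1]])
    b_idx <- c(b_idx, el[, e[2]])
  }
  fa <- field[a_idx]; fb <- field[b_idx]
  cross <- (fa - level) * (fb - level) < 0
  pts <- mesh$nodes[above, , drop = FALSE]
  if (any(cross)) {
    w <- (level - fa[cross]) / (fb[cross] - fa[cross])
    pa <- mesh$nodes[a_idx[cross], , drop = FALSE]
    pb <- mesh$nodes[b_idx[cross], , drop = FALSE]
    pts <- rbind(pts, pa + w * (pb - pa))
  }
  if (nrow(pts) == 0) return(matrix(0, 0, 3))
  if (ncol(pts) == 2) pts <- cbind(pts[, 1], 0, pts[, 2])
  pts
}

# Volume of the tissue region where a nodal field exceeds `level`,
# by exact clipping of the linear interpolant within each element.
# Full-domain volume (revolved / doubled), m^3.
level_region_volume <- function(mesh, field, level) {
  tis <- which(mesh$region == 1L)
  el <- mesh$elem[tis, , drop = FALSE]
  k <- ncol(el)
  f <- matrix(field[el], nrow(el), k)
  n_above <- rowSums(f >= level)
  meas <- element_measures(mesh)
  vol <- 0
  full <- n_above == k
  vol <- vol + sum(meas$weight[tis][full])
  part <- which(n_above > 0 & n_above < k)
  if (!length(part)) return(vol)
  nd <- mesh$nodes
  if (k == 3L) {
    for (e in part) {
      v <- el[e, ]
      fv <- f[e, ]
      vol <- vol + tri_clip_revolved(nd[v, , drop = FALSE], fv, level)
    }
  } else {
    for (e in part) {
      v <- el[e, ]
      fv <- f[e, ]
      vol <- vol + 2 * tet_clip_volume(nd[v, , drop = FALSE], fv, level)
    }
  }
  vol
}

# Revolved (2*pi*rbar*A) volume of the f >= level part of a meridian
# triangle with nodal values fv; linear interpolation on edges.
tri_clip_revolved <- function(p, fv, level) {
  above <- fv >= level
  na <- sum(above)
  if (na == 0L) return(0)
  if (na == 3L) {
    A <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
               (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    return(2 * pi * mean(p[, 1]) * A)
  }
  ip <- function(i, j) {
    w <- (level - fv[i]) / (fv[j] - fv[i])
    p[i, ] + w * (p[j, ] - p[i, ])
  }
  poly_rev <- function(q) {
    # polygon given in order; shoelace area and centroid radius
    x <- q[, 1]; y <- q[, 2]
    n <- nrow(q)
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    crossp <- x * yn - xn * y
    A <- sum(crossp) / 2
    if (abs(A) < 1e-30) return(0)
    cx <- sum((x + xn) * crossp) / (6 * A)
    2 * pi * cx * abs(A)
  }
  if (na == 1L) {
    i <- which(above)
    o <- which(!above)
    poly_rev(rbind(p[i, ], ip(i, o[1]), ip(i, o[2])))
  } else {
    o <- which(!above)
    i <- which(above)
    poly_rev(rbind(p[i[1], ], p[i[2], ], ip(i[2], o), ip(i[1], o)))
  }
}

# Volume of the f >= level part of a tetrahedron (linear field).
tet_clip_volume <- function(p, fv, level) {
  above <- fv >= level
  na <- sum(above)
  tet_vol <- function(a, b, c, d) abs(det(rbind(b - a, c - a, d - a))) / 6
  V <- tet_vol(p[1, ], p[2, ], p[3, ], p[4, ])
  if (na == 0L) return(0)
  if (na == 4L) return(V)
  ip <- function(i, j) {
    w <- (level - fv[i]) / (fv[j] - fv[i])
    p[i, ] + w * (p[j, ] - p[i, ])
  }
  if (na == 1L) {
    i <- which(above); o <- which(!above)
    return(tet_vol(p[i, ], ip(i, o[1]), ip(i, o[2]), ip(i, o[3])))
  }
  if (na == 3L) {
    i <- which(!above); o <- which(above)
    return(V - tet_vol(p[i, ], ip(i, o[1]), ip(i, o[2]), ip(i, o[3])))
  }
  # two above (A, B), two below (C, D): convex wedge with vertices
  # A, B and the four edge crossings; fan triangulation from A.
  iA <- which(above)[1]; iB <- which(above)[2]
  o <- which(!above)
  pac <- ip(iA, o[1]); pad <- ip(iA, o[2])
  pbc <- ip(iB, o[1]); pbd <- ip(iB, o[2])
  A <- p[iA, ]; B <- p[iB, ]
  tet_vol(A, pac, pad, pbd) + tet_vol(A, pac, pbd, pbc) +
    tet_vol(A, pbc, pbd, B)
}

#' Lesion geometry metrics from a damage field
#'
#' Extracts the `Omega >= threshold` region in the tissue: depth is the
#' maximum distance of the region below the undisturbed tissue surface
#' plane, maximum width the largest horizontal extent (diameter) at any
#' depth, and volume the full-lesion volume (axisymmetric revolution /
#' doubled half domain). The boundary is located by linear interpolation
#' along element edges.
#'
#' @param mesh an `rf_mesh`.
#' @param Omega nodal damage field.
#' @param threshold damage threshold taken as the lesion boundary
#'   (1 corresponds to 63 percent cell-death probability).
#' @return an object of class `lesion_metrics` with fields `depth`,
#'   `max_width`, `ratio`, `volume` (mm, mm, -, mm3), directional widths
#'   `width_x`/`width_y` in 3-D mode, and `empty`.
#' @export
extract_lesion <- function(mesh, Omega, threshold = 1) {
  pts <- level_region_points(mesh, Omega, threshold)
  if (!nrow(pts)) {
    return(structure(list(depth = 0, max_width = 0, ratio = NA_real_,
                          volume = 0, width_x = 0, width_y = 0,
                          empty = TRUE), class = "lesion_metrics"))
  }
  depth <- max(0, -min(pts[, 3])) * 1e3
  if (mesh$mode == "axisymmetric") {
    width_x <- width_y <- 2 * max(pts[, 1]) * 1e3
  } else {
    width_x <- (max(pts[, 1]) - min(pts[, 1])) * 1e3
    width_y <- 2 * max(abs(pts[, 2])) * 1e3
  }
  max_width <- max(width_x, width_y)
  vol <- level_region_volume(mesh, Omega, threshold) * 1e9
  structure(list(depth = depth, max_width = max_width,
                 ratio = if (depth > 0) max_width / depth else NA_real_,
                 volume = vol, width_x = width_x, width_y = width_y,
                 empty = FALSE), class = "lesion_metrics")
}

#' @export
print.lesion_metrics <- function(x, ...) {
  if (x$empty) cat("<lesion_metrics> empty lesion\n")
  else cat(sprintf(
    "<lesion_metrics> depth %.2f mm, width %.2f mm, ratio %.2f, volume %.1f mm3\n",
    x$depth, x$max_width, x$ratio, x$volume))
  invisible(x)
}

#' Isotherm contour extraction
#'
#' Applies the same edge-interpolation contouring machinery as
#' [extract_lesion()] to a temperature field, for diagnostics such as
#' comparing the damage boundary with the 72 degree isotherm after 5 s of
#' heating.
#'
#' @param mesh an `rf_mesh`.
#' @param T_field nodal temperatures (degrees C).
#' @param level isotherm level (degrees C).
#' @return list with the contour/region `points` (mm, matrix with columns
#'   x, y, z) and the same `depth`/`max_width` summary as a lesion; `empty`
#'   when the level is nowhere reached in tissue.
#' @export
isotherm_contour <- function(mesh, T_field, level) {
  pts <- level_region_points(mesh, T_field, level)
  if (!nrow(pts))
    return(list(points = matrix(0, 0, 3), depth = 0, max_width = 0,
                empty = TRUE))
  w <- if (mesh$mode == "axisymmetric") 2 * max(pts[, 1]) else
    max(max(pts[, 1]) - min(pts[, 1]), 2 * max(abs(pts[, 2])))
  list(points = pts * 1e3, depth = max(0, -min(pts[, 3])) * 1e3,
       max_width = w * 1e3, empty = FALSE)
}

#' Power and energy accounting between tissue and blood
#'
#' `P_T` is the percentage of the applied power dissipated in the tissue at
#' the first in-pulse electrical solve; `E_T` the percentage of the total
#' delivered energy dissipated in the tissue at pulse end.
#'
#' @param run an `rf_run` from [run_simulation()].
#' @return list with `P_T` and `E_T` (percent).
#' @export
power_energy_accounting <- function(run) {
  in_pulse <- !is.na(run$log$P_tissue)
  if (!any(in_pulse)) stop("no in-pulse step was recorded", call. = FALSE)
  tot <- run$log$P_tissue + run$log$P_blood + run$log$P_shaft
  if (any(tot[in_pulse] <= 0)) stop("zero total power", call. = FALSE)
  list(P_T = run$P_T, E_T = run$E_T)
}

#' Lesion metrics of a run at a snapshot time
#'
#' @param run an `rf_run`.
#' @param time snapshot time (s); must be one of the stored snapshots.
#' @param threshold damage threshold.
#' @return [extract_lesion()] metrics.
#' @export
lesion_at <- function(run, time, threshold = 1) {
  key <- sprintf("%.6g", time)
  if (is.null(run$snapshots[[key]]))
    stop(sprintf("no snapshot at t = %g s (stored: %s)", time,
                 paste(names(run$snapshots), collapse = ", ")),
         call. = FALSE)
  extract_lesion(run$mesh, run$snapshots[[key]]$Omega, threshold)
}
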