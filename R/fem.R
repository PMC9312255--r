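# Linear finite-element machinery on tagged meshes: axisymmetric P1
# triangles (radius-weighted measures, full-revolution quantities) and P1
# tetrahedra (half-domain, reported quantities doubled). Capacity and Robin
# terms are mass-lumped; stiffness uses one-point (centroid-radius)
# quadrature in the axisymmetric case.

# Per-element geometry for a subset of elements. Returns shape-gradient
# coefficient arrays, element measures and lumped nodal weights (full-domain
# measure split between vertices).
fem_prep <- function(mesh, which_elem) {
  el <- mesh$elem[which_elem, , drop = FALSE]
  nd <- mesh$nodes
  k <- ncol(el)
  ne <- nrow(el)
  if (mesh$mode == "axisymmetric") {
    r <- matrix(nd[el, 1], ne, 3)
    z <- matrix(nd[el, 2], ne, 3)
    b <- cbind(z[, 2] - z[, 3], z[, 3] - z[, 1], z[, 1] - z[, 2])
    cc <- cbind(r[, 3] - r[, 2], r[, 1] - r[, 3], r[, 2] - r[, 1])
    A2 <- b[, 1] * cc[, 2] - b[, 2] * cc[, 1]      # 2A (signed)
    A <- abs(A2) / 2
    rbar <- rowMeans(r)
    # nodal weights of integral(N_i * 2*pi*r dA): 2*pi*A/12 * (2 r_i + r_j + r_k)
    wn <- 2 * pi * A / 12 * (2 * r + rowSums(r) - r)
    list(elem = el, ne = ne, k = 3L, b = b, c = cc, size = A,
         weight = 2 * pi * rbar * A, rbar = rbar, w_node = wn)
  } else {
    p1 <- nd[el[, 1], ]; p2 <- nd[el[, 2], ]
    p3 <- nd[el[, 3], ]; p4 <- nd[el[, 4], ]
    a <- p2 - p1; b <- p3 - p1; c3 <- p4 - p1
    det <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
    V <- abs(det) / 6
    # gradients of barycentric shape functions: solve per-element 3x3 via
    # cross products: grad N_2 = (b x c)/det etc., grad N_1 = -(sum others)
    cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                  u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                  u[, 1] * v[, 2] - u[, 2] * v[, 1])
    g2 <- cross(b, c3) / det
    g3 <- cross(c3, a) / det
    g4 <- cross(a, b) / det
    g1 <- -(g2 + g3 + g4)
    gx <- cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1])
    gy <- cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2])
    gz <- cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3])
    wn <- matrix(2 * V / 4, ne, 4)
    list(elem = el, ne = ne, k = 4L, gx = gx, gy = gy, gz = gz, size = V,
         weight = 2 * V, w_node = wn)
  }
}

# Triplet (i, j) index template plus per-pair geometric factors so stiffness
# values for a new per-element conductivity are a vectorized product.
stiffness_template <- function(prep) {
  k <- prep$k
  pairs <- expand.grid(a = seq_len(k), b = seq_len(k))
  I <- prep$elem[, pairs$a]
  J <- prep$elem[, pairs$b]
  if (k == 3L) {
    fac <- 2 * pi * prep$rbar / (4 * prep$size)
    gbb <- matrix(0, prep$ne, k * k)
    gcc <- matrix(0, prep$ne, k * k)
    for (q in seq_len(nrow(pairs))) {
      gbb[, q] <- fac * prep$b[, pairs$a[q]] * prep$b[, pairs$b[q]]
      gcc[, q] <- fac * prep$c[, pairs$a[q]] * prep$c[, pairs$b[q]]
    }
    list(I = as.integer(I), J = as.integer(J), gxx = gbb, gzz = gcc,
         gyy = NULL, k = k)
  } else {
    # half-domain factor 2 so assembled operators match reported
    # (full-domain) powers; the PDE solution is unaffected by the global
    # scaling since boundary data are Dirichlet/relative.
    gxx <- matrix(0, prep$ne, k * k)
    gyy <- matrix(0, prep$ne, k * k)
    gzz <- matrix(0, prep$ne, k * k)
    for (q in seq_len(nrow(pairs))) {
      gxx[, q] <- 2 * prep$size * prep$gx[, pairs$a[q]] * prep$gx[, pairs$b[q]]
      gyy[, q] <- 2 * prep$size * prep$gy[, pairs$a[q]] * prep$gy[, pairs$b[q]]
      gzz[, q] <- 2 * prep$size * prep$gz[, pairs$a[q]] * prep$gz[, pairs$b[q]]
    }
    list(I = as.integer(I), J = as.integer(J), gxx = gxx, gyy = gyy,
         gzz = gzz, k = k)
  }
}

# Assemble the stiffness matrix for per-element conductivity `kappa`:
# a vector (isotropic) or a list(x=, y=, z=) of diagonal-tensor entries
# (axisymmetric: x = radial, z = axial).
assemble_stiffness <- function(tmpl, kappa, nn) {
  if (is.list(kappa)) {
    vals <- kappa$x * tmpl$gxx + kappa$z * tmpl$gzz
    if (!is.null(tmpl$gyy)) vals <- vals + kappa$y * tmpl$gyy
  } else {
    vals <- kappa * tmpl$gxx + kappa * tmpl$gzz
    if (!is.null(tmpl$gyy)) vals <- vals + kappa * tmpl$gyy
  }
  Matrix::sparseMatrix(i = tmpl$I, j = tmpl$J, x = as.numeric(vals),
                       dims = c(nn, nn))
}

# Elemental squared gradient of a nodal field, optionally weighted by a
# diagonal tensor (returns kappa . |grad u|^2 per element).
elemental_grad_sq <- function(prep, u, kappa = 1) {
  if (prep$k == 3L) {
    gu_r <- rowSums(prep$b * matrix(u[prep$elem], prep$ne, 3)) / (2 * prep$size)
    gu_z <- rowSums(prep$c * matrix(u[prep$elem], prep$ne, 3)) / (2 * prep$size)
    if (is.list(kappa)) kappa$x * gu_r^2 + kappa$z * gu_z^2
    else kappa * (gu_r^2 + gu_z^2)
  } else {
    um <- matrix(u[prep$elem], prep$ne, 4)
    gu_x <- rowSums(prep$gx * um)
    gu_y <- rowSums(prep$gy * um)
    gu_z <- rowSums(prep$gz * um)
    if (is.list(kappa)) kappa$x * gu_x^2 + kappa$y * gu_y^2 + kappa$z * gu_z^2
    else kappa * (gu_x^2 + gu_y^2 + gu_z^2)
  }
}

# Lumped boundary-facet weights: integral of the shape function over the
# facet with the full-domain measure (revolved edge / doubled triangle).
facet_weights <- function(mesh, which_facet) {
  f <- mesh$facets[which_facet, , drop = FALSE]
  nd <- mesh$nodes
  if (mesh$mode == "axisymmetric") {
    r1 <- nd[f[, 1], 1]; z1 <- nd[f[, 1], 2]
    r2 <- nd[f[, 2], 1]; z2 <- nd[f[, 2], 2]
    len <- sqrt((r2 - r1)^2 + (z2 - z1)^2)
    w <- cbind(2 * pi * len / 6 * (2 * r1 + r2),
               2 * pi * len / 6 * (2 * r2 + r1))
  } else {
    a <- nd[f[, 2], ] - nd[f[, 1], ]
    b <- nd[f[, 3], ] - nd[f[, 1], ]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area <- 0.5 * sqrt(rowSums(cr^2))
    w <- matrix(2 * area / 3, nrow(f), 3)
  }
  list(facets = f, w = w)
}

# Accumulate per-facet-vertex or per-element-vertex weighted values onto
# nodes.
accumulate_nodal <- function(idx_mat, val_mat, nn) {
  v <- numeric(nn)
  acc <- rowsum(as.numeric(val_mat), as.integer(idx_mat), reorder = FALSE)
  v[as.integer(rownames(acc))] <- acc[, 1]
  v
}

# Solve A x = b with Dirichlet values on `fixed` (indices into 1..nn).
# Returns the full solution vector and, if requested, the reaction
# (A x - b) at the fixed nodes. The factorization of the free-free block is
# cached in `cache` (an environment) under `name` and updated in place when
# the sparsity pattern is unchanged.
solve_dirichlet <- function(A, b, fixed, fixed_val, active, cache = NULL,
                            name = "ch", reactions = FALSE,
                            skip_update = FALSE) {
  nn <- nrow(A)
  free <- setdiff(active, fixed)
  x <- numeric(nn)
  x[fixed] <- fixed_val
  Aff <- Matrix::forceSymmetric(A[free, free])
  rhs <- b[free] - as.numeric(A[free, fixed, drop = FALSE] %*% x[fixed])
  ch <- NULL
  if (!is.null(cache)) {
    ch <- cache[[name]]
    if (!is.null(ch) && !skip_update) {
      ch <- tryCatch(Matrix::update(ch, Aff), error = function(e) NULL)
    }
    if (is.null(ch)) {
      ch <- Matrix::Cholesky(Aff, LDL = FALSE, super = TRUE)
      ch <- Matrix::update(ch, Aff)
    }
    cache[[name]] <- ch
    x[free] <- as.numeric(Matrix::solve(ch, rhs))
  } else {
    x[free] <- as.numeric(Matrix::solve(Aff, rhs))
  }
  out <- list(x = x)
  if (reactions)
    out$reaction <- as.numeric(A[fixed, , drop = FALSE] %*% x) - b[fixed]
  out
}
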