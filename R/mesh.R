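#' Discrete closed tissue surfaces
#'
#' A `surface_mesh` represents the closed tissue sheet: either a closed planar
#' curve (`backend = "curve2d"`, vertices in cyclic order) or a closed
#' triangulated surface of sphere topology (`backend = "surface3d"`).  The
#' per-vertex reference measure (`ref_local_areas`, a length for curves and an
#' area for surfaces) is frozen at construction and defines the local
#' incompressibility target.
#'
#' @param vertices numeric matrix of vertex positions (n x 2 for `curve2d`,
#'   n x 3 for `surface3d`).
#' @param faces integer matrix (m x 3) of triangle corner indices for
#'   `surface3d`; `NULL` for `curve2d`, whose connectivity is the implicit
#'   cycle `1, 2, ..., n, 1`.
#' @param backend `"curve2d"` or `"surface3d"`.
#' @param ref_local_areas optional per-vertex reference measure; defaults to
#'   the local measure of the supplied geometry.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces = NULL,
                         backend = c("curve2d", "surface3d"),
                         ref_local_areas = NULL) {
  backend <- match.arg(backend)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (backend == "curve2d") {
    if (ncol(vertices) != 2L) mm_geometry_error("curve2d vertices must be n x 2")
    if (nrow(vertices) < 4L) mm_resolution_error("curve2d needs at least 4 vertices")
    faces <- NULL
  } else {
    if (ncol(vertices) != 3L) mm_geometry_error("surface3d vertices must be n x 3")
    if (is.null(faces)) mm_geometry_error("surface3d requires a triangle list")
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    if (ncol(faces) != 3L) mm_geometry_error("faces must be m x 3")
    check_sphere_topology(nrow(vertices), faces)
  }
  mesh <- structure(
    list(backend = backend, vertices = vertices, faces = faces,
         ref_local_areas = NULL),
    class = "surface_mesh"
  )
  a <- local_areas(mesh)
  if (any(a <= 0)) mm_geometry_error("non-positive local measure at construction")
  mesh$ref_local_areas <-
    if (is.null(ref_local_areas)) a else as.numeric(ref_local_areas)
  if (length(mesh$ref_local_areas) != nrow(vertices))
    mm_geometry_error("ref_local_areas length must match vertex count")
  if (any(mesh$ref_local_areas <= 0))
    mm_geometry_error("ref_local_areas must be strictly positive")
  mesh
}

check_sphere_topology <- function(nv, faces) {
  if (min(faces) < 1L || max(faces) > nv)
    mm_geometry_error("face indices out of range")
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  tab <- table(key)
  if (any(tab != 2L))
    mm_geometry_error("mesh is not a closed manifold: %d edge(s) not shared by exactly 2 triangles",
                      sum(tab != 2L))
  ne <- length(tab)
  chi <- nv - ne + nrow(faces)
  if (chi != 2L)
    mm_geometry_error("Euler characteristic V-E+F = %d, expected 2 (sphere topology)", chi)
  invisible(TRUE)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh backend=%s  vertices=%d  %s  total measure=%.6g>\n",
              x$backend, nrow(x$vertices),
              if (is.null(x$faces)) "closed curve" else sprintf("faces=%d", nrow(x$faces)),
              sum(local_areas(x))))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Build a near-uniform triangulated sphere
#'
#' Subdivided icosahedron projected onto the sphere: each subdivision level
#' splits every triangle in four and reprojects, so levels 2, 3, 4 give 162,
#' 642, 2562 vertices.
#'
#' @param n_subdiv number of subdivision passes (>= 2; fourth-order operators
#'   need this much resolution).
#' @param radius sphere radius (> 0).
#' @return a `surface_mesh` with `backend = "surface3d"`.
#' @export
build_sphere_mesh <- function(n_subdiv, radius = 1) {
  if (!is.numeric(n_subdiv) || length(n_subdiv) != 1L || n_subdiv != round(n_subdiv))
    mm_parameter_error("n_subdiv must be an integer")
  if (n_subdiv < 2)
    mm_resolution_error("n_subdiv >= 2 required: coarser icospheres cannot resolve the fourth-order bending operator")
  stopifnot_scalar(radius, "radius", positive = TRUE)

  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))

  for (lev in seq_len(n_subdiv)) {
    midkey <- new.env(hash = TRUE, size = 4L * nrow(F))
    nextV <- nrow(V)
    Vlist <- list(V)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- midkey[[k]]
      if (!is.null(id)) return(id)
      p <- (V[a, ] + V[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      nextV <<- nextV + 1L
      Vlist[[length(Vlist) + 1L]] <<- p
      midkey[[k]] <- nextV
      nextV
    }
    newF <- matrix(0L, nrow(F) * 4L, 3L)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF[(f - 1L) * 4L + 1L, ] <- c(a, ab, ca)
      newF[(f - 1L) * 4L + 2L, ] <- c(b, bc, ab)
      newF[(f - 1L) * 4L + 3L, ] <- c(c, ca, bc)
      newF[(f - 1L) * 4L + 4L, ] <- c(ab, bc, ca)
    }
    V <- do.call(rbind, c(list(V), Vlist[-1]))
    F <- newF
  }
  surface_mesh(V * radius, F, backend = "surface3d")
}

#' Build a closed circular curve
#'
#' Equally spaced nodes on a circle of the given radius, in counterclockwise
#' (outward-normal) order.  The reduced one-dimensional backend used for fast
#' simulation and stability analysis.
#'
#' @param n_nodes number of nodes (>= 16).
#' @param radius circle radius (> 0).
#' @return a `surface_mesh` with `backend = "curve2d"`.
#' @export
build_circle_curve <- function(n_nodes, radius = 1) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes != round(n_nodes))
    mm_parameter_error("n_nodes must be an integer")
  if (n_nodes < 16)
    mm_resolution_error("n_nodes >= 16 required for the fourth-order bending operator")
  stopifnot_scalar(radius, "radius", positive = TRUE)
  th <- 2 * pi * (seq_len(n_nodes) - 1L) / n_nodes
  surface_mesh(cbind(radius * cos(th), radius * sin(th)), backend = "curve2d")
}

# --- curve primitives (indices mod n; edge i joins vertex i to i+1) ---------

curve_edges <- function(V) {
  Vn <- V[c(2:nrow(V), 1L), , drop = FALSE]
  e <- Vn - V
  l <- sqrt(rowSums(e^2))
  if (any(l <= 0)) mm_geometry_error("degenerate curve segment (zero length)")
  list(e = e, l = l)
}

shift_prev <- function(x) if (is.matrix(x)) x[c(nrow(x), 1:(nrow(x) - 1L)), , drop = FALSE] else x[c(length(x), 1:(length(x) - 1L))]
shift_next <- function(x) if (is.matrix(x)) x[c(2:nrow(x), 1L), , drop = FALSE] else x[c(2:length(x), 1L)]

curve_turning <- function(V) {
  ce <- curve_edges(V)
  e <- ce$e
  ep <- shift_prev(e)
  atan2(ep[, 1] * e[, 2] - ep[, 2] * e[, 1], rowSums(ep * e))
}

#' Per-vertex local measure of the current geometry
#'
#' Length of the dual segment (curve2d) or barycentric area (surface3d).
#' Sums to the total perimeter/area of the mesh.
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector, one strictly positive entry per vertex.
#' @export
local_areas <- function(mesh) {
  if (mesh$backend == "curve2d") {
    l <- curve_edges(mesh$vertices)$l
    (shift_prev(l) + l) / 2
  } else {
    as.numeric(surf_quantities(mesh)$vertex_area)
  }
}

#' Signed mean curvature at every vertex
#'
#' Convention: H is the sum of the principal curvatures, positive for outward
#' bending, so the unit sphere has H = 2 and a counterclockwise circle of
#' radius R has H = 1/R.  On surfaces H comes from the integrated
#' mean-curvature vector (cotangent Laplacian applied to positions) with the
#' sign recovered from the outward vertex normal; on curves it is the turning
#' angle divided by the dual segment length.
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of per-vertex curvature (1/length).
#' @export
mean_curvature <- function(mesh) {
  if (mesh$backend == "curve2d") {
    curve_turning(mesh$vertices) / local_areas(mesh)
  } else {
    as.numeric(surf_quantities(mesh)$H)
  }
}

surf_quantities <- function(mesh) {
  tryCatch(cpp_surf_quantities(mesh$vertices, mesh$faces - 1L),
           error = function(e) mm_geometry_error("%s", conditionMessage(e)))
}

#' Outward unit normals at vertices
#'
#' @param mesh a `surface_mesh`.
#' @return n x 2 (curve2d) or n x 3 (surface3d) matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  if (mesh$backend == "curve2d") {
    ce <- curve_edges(mesh$vertices)
    t_ <- ce$e / ce$l
    tm <- shift_prev(t_)
    n <- (t_ + tm)
    n <- cbind(n[, 2], -n[, 1])  # rotate averaged tangent by -90 deg
    nn <- sqrt(rowSums(n^2))
    nn[nn == 0] <- 1
    n / nn
  } else {
    surf_quantities(mesh)$vertex_normal
  }
}

#' Laplace-Beltrami operator on per-vertex scalar fields
#'
#' Returns the sparse operator `-M^{-1} K` with `M` the lumped mass matrix
#' (local measures) and `K` the cotangent (surface3d) or 1D finite-element
#' (curve2d) stiffness matrix.  The operator annihilates constants, is
#' symmetric in the mass-weighted inner product, and is negative
#' semi-definite.
#'
#' @param mesh a `surface_mesh`.
#' @return a `dgCMatrix` acting on per-vertex fields.
#' @export
laplace_beltrami <- function(mesh) {
  m <- lb_matrices(mesh)
  -Matrix::Diagonal(x = 1 / m$mass) %*% m$stiffness
}

#' Mass and stiffness matrices of the surface Laplacian
#'
#' The weak form used by the morphogen solver: lumped mass vector `mass`
#' (= [local_areas()]) and positive semi-definite stiffness `stiffness` with
#' `laplace_beltrami = -diag(1/mass) %*% stiffness`.
#'
#' @param mesh a `surface_mesh`.
#' @return list with `mass` (numeric vector) and `stiffness` (`dgCMatrix`).
#' @export
lb_matrices <- function(mesh) {
  n <- n_vertices(mesh)
  if (mesh$backend == "curve2d") {
    l <- curve_edges(mesh$vertices)$l
    i <- seq_len(n); ip <- c(2:n, 1L)
    K <- Matrix::sparseMatrix(
      i = c(i, ip, i, i), j = c(ip, i, i, i),
      x = c(-1 / l, -1 / l, 1 / l + 1 / shift_prev(l), rep(0, n)),
      dims = c(n, n))
  } else {
    tr <- tryCatch(cpp_cotan_stiffness(mesh$vertices, mesh$faces - 1L),
                   error = function(e) mm_geometry_error("%s", conditionMessage(e)))
    K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$w, dims = c(n, n))
  }
  list(mass = local_areas(mesh), stiffness = K)
}

#' Worst element quality of a mesh
#'
#' For surfaces, the minimum over triangles of `4*sqrt(3)*A / sum(l^2)`
#' (equilateral = 1); for curves, the ratio of shortest to longest segment
#' damped by the largest turning angle.  The integrator refuses to continue
#' below a configured threshold instead of remeshing.
#'
#' @param mesh a `surface_mesh`.
#' @return scalar in (0, 1].
#' @export
mesh_quality <- function(mesh) {
  if (mesh$backend == "curve2d") {
    l <- curve_edges(mesh$vertices)$l
    theta <- abs(curve_turning(mesh$vertices))
    (min(l) / max(l)) * max(0, 1 - max(theta) / pi)
  } else {
    surf_quantities(mesh)$min_quality
  }
}

# replace vertex positions, keeping reference areas frozen
with_vertices <- function(mesh, V) {
  mesh$vertices <- V
  mesh
}
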