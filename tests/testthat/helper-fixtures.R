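# shared fixtures: all built in code, nothing read from disk

# central finite differences of a scalar function of vertex positions
fd_position_gradient <- function(f, V, h = 1e-6) {
  G <- V * 0
  for (i in seq_len(nrow(V))) {
    for (j in seq_len(ncol(V))) {
      Vp <- V; Vp[i, j] <- Vp[i, j] + h
      Vm <- V; Vm[i, j] <- Vm[i, j] - h
      G[i, j] <- (f(Vp) - f(Vm)) / (2 * h)
    }
  }
  G
}

# seeded perturbed curve mesh that keeps the reference measures of the circle
perturbed_curve <- function(n = 24, amp = 0.05, seed = 42) {
  set.seed(seed)
  base <- build_circle_curve(n)
  mesh <- surface_mesh(base$vertices + amp * matrix(rnorm(2 * n), ncol = 2),
                       backend = "curve2d")
  mesh$ref_local_areas <- base$ref_local_areas
  mesh
}

# seeded perturbed icosphere (radial + tangential noise)
perturbed_sphere <- function(level = 2, amp = 0.04, seed = 42) {
  set.seed(seed)
  base <- build_sphere_mesh(level)
  n <- nrow(base$vertices)
  mesh <- surface_mesh(base$vertices * (1 + amp * matrix(rnorm(3 * n), ncol = 3)),
                       base$faces, backend = "surface3d")
  mesh$ref_local_areas <- base$ref_local_areas
  mesh
}

random_rotation_3d <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

rotation_2d <- function(alpha) {
  matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2, 2)
}

# move vertices while keeping the frozen reference measures
with_vertices_test <- function(mesh, V) {
  out <- surface_mesh(V, mesh$faces, backend = mesh$backend)
  out$ref_local_areas <- mesh$ref_local_areas
  out
}

# small fast patterning configuration used by several dynamic tests
quick_pattern_config <- function(seed = 1, t_end = 80, ...) {
  simulation_config(backend = "curve2d", n = 48, d_star = 0.1, p_star = 6,
                    m_star = 0.3, xi_star = 20, t_end = t_end, seed = seed, ...)
}
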