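test_that("icosphere construction: area, topology, scaling", {
  m3 <- build_sphere_mesh(3)
  expect_lt(abs(sum(local_areas(m3)) - 4 * pi) / (4 * pi), 0.01)

  # Euler characteristic / closed-manifold checks run at construction; verify
  # the counts directly as well
  f <- m3$faces
  e <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
  expect_identical(nrow(m3$vertices) - nrow(e) + nrow(f), 2L)

  m1 <- build_sphere_mesh(2, radius = 1)
  m2 <- build_sphere_mesh(2, radius = 2)
  expect_lt(abs(sum(local_areas(m2)) / sum(local_areas(m1)) - 4), 1e-12)

  expect_error(build_sphere_mesh(1), class = "morphomech_resolution_error")
})

test_that("circle construction: perimeter, equal spacing, resolution guard", {
  m <- build_circle_curve(256, radius = 1)
  expect_lt(abs(sum(local_areas(m)) - 2 * pi) / (2 * pi), 0.001)
  l <- sqrt(rowSums((m$vertices[c(2:256, 1), ] - m$vertices)^2))
  expect_lt(diff(range(l)) / mean(l), 1e-12)
  expect_error(build_circle_curve(4), class = "morphomech_resolution_error")
})

test_that("mean curvature matches analytic values and converges", {
  # sphere: H = 2/R; the area-weighted L2 error halves per refinement level
  # (pointwise convergence fails only at the 12 irregular valence-5 vertices,
  # a known property of the cotangent/barycentric scheme)
  errs <- vapply(2:4, function(lev) {
    m <- build_sphere_mesh(lev)
    a <- local_areas(m)
    sqrt(sum(a * (mean_curvature(m) - 2)^2) / sum(a))
  }, numeric(1))
  expect_lt(errs[1], 0.07)
  expect_lt(errs[2], 0.6 * errs[1])
  expect_lt(errs[3], 0.6 * errs[2])

  # circle: H = 1/R
  errs_c <- vapply(c(32, 64, 128), function(n) {
    max(abs(mean_curvature(build_circle_curve(n, radius = 2)) - 0.5))
  }, numeric(1))
  expect_lt(errs_c[1], 0.01)
  expect_lt(errs_c[2], errs_c[1])
  expect_lt(errs_c[3], errs_c[2])
})

test_that("ellipsoid curvature matches the closed-form oracle", {
  # ellipsoid x^2 + y^2 + z^2/4 = 1 built by anisotropic scaling of the
  # icosphere; oracle: sum of principal curvatures of the implicit surface
  # F = x^2 + y^2 + z^2/4 - 1 via div(grad F / |grad F|)
  s <- build_sphere_mesh(3)
  V <- cbind(s$vertices[, 1], s$vertices[, 2], 2 * s$vertices[, 3])
  mesh <- surface_mesh(V, s$faces, backend = "surface3d")
  g <- cbind(2 * V[, 1], 2 * V[, 2], V[, 3] / 2)
  ng <- sqrt(rowSums(g^2))
  hess_diag <- c(2, 2, 0.5)
  quad <- 4 * V[, 1]^2 * 2 + 4 * V[, 2]^2 * 2 + (V[, 3] / 2)^2 * 0.5
  H_exact <- sum(hess_diag) / ng - quad / ng^3

  H <- mean_curvature(mesh)
  a <- local_areas(mesh)
  l2_rel <- sqrt(sum(a * (H - H_exact)^2) / sum(a * H_exact^2))
  expect_lt(l2_rel, 0.05)
  expect_lt(max(abs(H - H_exact) / abs(H_exact)), 0.35)  # worst vertices sit at valence-5 points
})

test_that("Laplace-Beltrami: annihilates constants, symmetric weak form, NSD", {
  for (mesh in list(perturbed_curve(32), perturbed_sphere(2))) {
    n <- nrow(mesh$vertices)
    L <- laplace_beltrami(mesh)
    expect_lt(max(abs(L %*% rep(1, n))), 1e-12)
    ml <- lb_matrices(mesh)
    K <- as.matrix(ml$stiffness)
    expect_lt(max(abs(K - t(K))), 1e-12)
    set.seed(7)
    for (k in 1:5) {
      u <- rnorm(n)
      expect_lte(-sum(u * (K %*% u)), 1e-10 * sum(u^2))
    }
  }
})

test_that("Laplace-Beltrami eigenvalues: circle Fourier modes, sphere l=1", {
  n <- 128; R <- 2
  mesh <- build_circle_curve(n, radius = R)
  ml <- lb_matrices(mesh)
  th <- atan2(mesh$vertices[, 2], mesh$vertices[, 1])
  for (m in c(1, 3, 5)) {
    u <- cos(m * th)
    lam <- -sum(u * as.numeric(ml$stiffness %*% u)) / sum(ml$mass * u^2)
    expect_lt(abs(lam + m^2 / R^2) / (m^2 / R^2), 0.01)
  }

  # Rayleigh quotient of the coordinate function x converges to -l(l+1) = -2
  rq <- vapply(2:3, function(lev) {
    s <- build_sphere_mesh(lev)
    ml <- lb_matrices(s)
    x <- s$vertices[, 1]
    -sum(x * as.numeric(ml$stiffness %*% x)) / sum(ml$mass * x^2)
  }, numeric(1))
  expect_lt(abs(rq[2] + 2), 0.01)
  expect_lte(abs(rq[2] + 2), abs(rq[1] + 2) + 1e-12)
})

test_that("local measures: partition, isometry invariance, scaling", {
  mesh <- perturbed_sphere(2)
  a <- local_areas(mesh)
  expect_true(all(a > 0))
  tot <- sum(cpp_area <- a)
  # partition of the total area
  fa <- sum(morphomech:::surf_quantities(mesh)$face_area)
  expect_lt(abs(tot - fa) / fa, 1e-12)

  Q <- random_rotation_3d(3)
  rot <- surface_mesh(mesh$vertices %*% Q, mesh$faces, backend = "surface3d")
  expect_lt(max(abs(local_areas(rot) - a)), 1e-10)

  sc <- surface_mesh(3 * mesh$vertices, mesh$faces, backend = "surface3d")
  expect_lt(max(abs(local_areas(sc) - 9 * a)) / max(a), 1e-10)

  cm <- perturbed_curve(20)
  ac <- local_areas(cm)
  sc2 <- surface_mesh(3 * cm$vertices, backend = "curve2d")
  expect_lt(max(abs(local_areas(sc2) - 3 * ac)) / max(ac), 1e-12)
})

test_that("operators are equivariant under rigid motions", {
  mesh <- perturbed_sphere(2)
  Q <- random_rotation_3d(11)
  shift <- c(0.3, -1.2, 0.7)
  rot <- surface_mesh(sweep(mesh$vertices %*% Q, 2, shift, "+"), mesh$faces,
                      backend = "surface3d")
  expect_lt(max(abs(mean_curvature(rot) - mean_curvature(mesh))), 1e-10)
  u <- sin(3 * mesh$vertices[, 1])
  expect_lt(max(abs(laplace_beltrami(rot) %*% u - laplace_beltrami(mesh) %*% u)), 1e-9)

  cm <- perturbed_curve(24)
  rotc <- surface_mesh(sweep(cm$vertices %*% rotation_2d(0.8), 2, c(1, 2), "+"),
                       backend = "curve2d")
  expect_lt(max(abs(mean_curvature(rotc) - mean_curvature(cm))), 1e-10)
})

test_that("invalid meshes are rejected with typed errors", {
  s <- build_sphere_mesh(2)
  expect_error(surface_mesh(s$vertices, s$faces[-1, ], backend = "surface3d"),
               class = "morphomech_geometry_error")
  V <- s$vertices
  V[s$faces[1, 2], ] <- V[s$faces[1, 1], ]  # collapse an edge: degenerate triangle
  expect_error(surface_mesh(V, s$faces, backend = "surface3d"),
               class = "morphomech_geometry_error")
})
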