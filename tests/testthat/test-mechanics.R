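test_that("bending energy closed forms on sphere and circle", {
  mech0 <- mechanical_params(kappa0 = 1, h0_base = 0, h0_coupling = 0)

  # unit sphere, H0 = 0: F -> (1/2) * 2^2 * 4pi = 8pi under refinement
  e <- vapply(2:3, function(lev)
    helfrich_energy(build_sphere_mesh(lev), 0, mech0), numeric(1))
  expect_lt(abs(e[2] - 8 * pi) / (8 * pi), 0.01)
  expect_lt(abs(e[2] - 8 * pi), abs(e[1] - 8 * pi))

  # unit circle, H0 = 0: F -> (1/2) * 1 * 2pi = pi
  ec <- helfrich_energy(build_circle_curve(256), 0, mech0)
  expect_lt(abs(ec - pi) / pi, 0.001)

  # sphere at its spontaneous curvature is a zero-energy ground state
  mech_sp <- mechanical_params(kappa0 = 1, h0_base = 2, h0_coupling = 0)
  s <- build_sphere_mesh(2)
  mech_sp$h0_base <- mean_curvature(s)  # discrete relaxed reference
  expect_lt(helfrich_energy(s, 0, mech_sp), 1e-10)
})

test_that("non-positive effective rigidity raises a parameter error", {
  m <- perturbed_curve(20)
  mech <- mechanical_params(kappa0 = 1, kappa1 = -2, h0_base = 1)
  expect_error(helfrich_energy(m, rep(1, 20), mech),
               class = "morphomech_parameter_error")
})

test_that("shape_gradient equals central finite differences of the energy", {
  mech <- mechanical_params(kappa0 = 1.3, kappa1 = 0.2, h0_base = 0.8,
                            h0_coupling = 0.7, area_stiffness = 5)

  cm <- perturbed_curve(24)
  set.seed(5); phi <- runif(24)
  g <- -shape_gradient(cm, phi, mech)
  gfd <- fd_position_gradient(function(V)
    helfrich_energy(surface_mesh(V, backend = "curve2d"), phi, mech),
    cm$vertices)
  expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-6)

  sm <- perturbed_sphere(2)   # 162 vertices
  set.seed(6); phis <- runif(nrow(sm$vertices))
  g3 <- -shape_gradient(sm, phis, mech)
  gfd3 <- fd_position_gradient(function(V)
    helfrich_energy(surface_mesh(V, sm$faces, backend = "surface3d"), phis, mech),
    sm$vertices, h = 1e-5)
  expect_lt(max(abs(g3 - gfd3)) / max(abs(gfd3)), 1e-6)
})

test_that("forces vanish at the relaxed configuration and are equivariant", {
  s <- build_sphere_mesh(2)
  mech <- mechanical_params(kappa0 = 1, h0_base = 0, h0_coupling = 0)
  mech$h0_base <- mean_curvature(s)
  expect_lt(max(abs(shape_gradient(s, 0, mech))), 1e-9)
  expect_lt(max(abs(incompressibility_forces(s, mech)$forces)), 1e-12)

  sm <- perturbed_sphere(2)
  set.seed(8); phi <- runif(nrow(sm$vertices))
  mech2 <- mechanical_params(kappa0 = 1, h0_base = 1, h0_coupling = 0.5,
                             area_stiffness = 10)
  Fr <- shape_gradient(sm, phi, mech2)
  Q <- random_rotation_3d(4)
  rot <- surface_mesh(sm$vertices %*% Q, sm$faces, backend = "surface3d")
  rot$ref_local_areas <- sm$ref_local_areas
  expect_lt(max(abs(shape_gradient(rot, phi, mech2) - Fr %*% Q)), 1e-10)

  # discrete Noether check: total force is zero (translation invariance)
  expect_lt(max(abs(colSums(Fr))), 1e-10)
  expect_lt(max(abs(colSums(incompressibility_forces(sm, mech2)$forces))), 1e-10)
})

test_that("incompressibility penalty: multiplier and finite differences", {
  s <- build_sphere_mesh(2)
  mech <- mechanical_params(area_stiffness = 7)

  at_ref <- incompressibility_forces(s, mech)
  expect_lt(max(abs(at_ref$forces)), 1e-12)
  expect_lt(max(abs(at_ref$lambda)), 1e-12)

  # uniform dilation: uniform positive multiplier, net inward restoring force
  dil <- surface_mesh(1.05 * s$vertices, s$faces, backend = "surface3d")
  dil$ref_local_areas <- s$ref_local_areas
  ic <- incompressibility_forces(dil, mech)
  expect_true(all(ic$lambda > 0))
  expect_lt(diff(range(ic$lambda)) / mean(ic$lambda), 0.15)
  radial <- rowSums(ic$forces * dil$vertices) / sqrt(rowSums(dil$vertices^2))
  expect_true(all(radial < 0))

  e_area <- function(V, mesh0) {
    m2 <- surface_mesh(V, mesh0$faces, backend = "surface3d")
    a <- local_areas(m2)
    sum(0.5 * mech$area_stiffness * (a - mesh0$ref_local_areas)^2 / mesh0$ref_local_areas)
  }
  gfd <- fd_position_gradient(function(V) e_area(V, dil), dil$vertices, h = 1e-5)
  expect_lt(max(abs(-ic$forces - gfd)) / max(abs(gfd)), 1e-6)

  # curve backend too
  cm <- perturbed_curve(20)
  icc <- incompressibility_forces(cm, mech)
  e_area_c <- function(V) {
    m2 <- surface_mesh(V, backend = "curve2d")
    a <- local_areas(m2)
    sum(0.5 * mech$area_stiffness * (a - cm$ref_local_areas)^2 / cm$ref_local_areas)
  }
  gfdc <- fd_position_gradient(e_area_c, cm$vertices)
  expect_lt(max(abs(-icc$forces - gfdc)) / max(abs(gfdc)), 1e-6)
})

test_that("explicit gradient steps decrease the mechanical energy", {
  mech <- mechanical_params(kappa0 = 1, h0_base = 1, h0_coupling = 0.5,
                            xi = 1, area_stiffness = 50)
  for (mesh in list(perturbed_curve(24, amp = 0.08),
                    perturbed_sphere(2, amp = 0.05))) {
    set.seed(9); phi <- runif(nrow(mesh$vertices), 0, 0.5)
    e0 <- mechanical_energy(mesh, phi, mech)
    F <- shape_gradient(mesh, phi, mech) +
      incompressibility_forces(mesh, mech)$forces
    vel <- F / (mech$xi * local_areas(mesh))
    for (dt in c(1e-6, 1e-5)) {
      e1 <- mechanical_energy(with_vertices_test(mesh, mesh$vertices + dt * vel),
                              phi, mech)
      expect_lt(e1, e0)
    }
  }
})

test_that("stiffer penalty monotonically reduces local-area drift", {
  drift_at <- function(k) {
    cfg <- simulation_config(backend = "curve2d", n = 48, d_star = 0.1,
                             p_star = 6, m_star = 0.3, xi_star = 20,
                             area_stiffness = k, t_end = 5, seed = 3,
                             area_drift_tol = Inf)
    max(run_simulation(cfg)$series$max_area_drift)
  }
  drifts <- vapply(c(20, 200, 2000), drift_at, numeric(1))
  expect_lt(drifts[2], drifts[1])
  expect_lt(drifts[3], drifts[2])
})
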