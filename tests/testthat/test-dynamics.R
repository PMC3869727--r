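test_that("relaxed sphere with dead couplings is a fixed point of the flow", {
  mesh <- build_sphere_mesh(2)
  h <- mean_curvature(mesh)
  mech <- mechanical_params(kappa0 = 1, h0_base = 2, h0_coupling = 0,
                            xi = 1, area_stiffness = 100)
  mech$h0_base <- h
  kin <- kinetic_params(diffusion = 0.1, production_max = 0, degradation = 1,
                        curvature_ref = h)
  phi <- rep(0.5, nrow(mesh$vertices))
  for (k in 1:5) {
    res <- coupled_step(mesh, phi, mech, kin, dt = 1e-3)
    expect_true(res$accepted)
    expect_lt(max(abs(res$mesh$vertices - mesh$vertices)), 1e-10)
    mesh <- res$mesh; phi <- res$phi
  }
  expect_lt(diff(range(phi)), 1e-12)  # uniform decay only
})

test_that("doubling xi with doubled dt gives the identical mechanical update", {
  mesh <- perturbed_curve(24)
  set.seed(13); phi <- runif(24)
  mech1 <- mechanical_params(kappa0 = 1, h0_base = 1, h0_coupling = 0.5,
                             xi = 1, area_stiffness = 20)
  mech2 <- mech1; mech2$xi <- 2
  kin <- kinetic_params(diffusion = 0, production_max = 0, degradation = 0,
                        curvature_ref = 1)
  r1 <- coupled_step(mesh, phi, mech1, kin, dt = 1e-4)
  r2 <- coupled_step(mesh, phi, mech2, kin, dt = 2e-4)
  expect_lt(max(abs(r1$mesh$vertices - r2$mesh$vertices)), 1e-12)
})

test_that("accepted steps never raise the mechanical energy beyond tolerance", {
  # seeded ensemble of random starts, production off
  for (seed in 1:10) {
    cfg <- simulation_config(backend = "curve2d", n = 32, seed = seed,
                             mech = mechanical_params(kappa0 = 1, h0_base = 1,
                                                      h0_coupling = 0, xi = 5,
                                                      area_stiffness = 100),
                             kin = kinetic_params(diffusion = 0.1,
                                                  production_max = 0,
                                                  degradation = 1),
                             geometry_perturbation = 0.08,
                             phi0_mean = 0.5, phi0_halfwidth = 0.25,
                             t_end = 2, output_every = 50)
    tr <- run_simulation(cfg)
    de <- diff(tr$series$total_energy)
    expect_lte(max(de), cfg$energy_increase_tol)
    expect_lt(tail(tr$series$total_energy, 1), tr$series$total_energy[1])
  }
})

test_that("simulations are deterministic given the seed", {
  cfg <- quick_pattern_config(seed = 5, t_end = 3)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$series, t2$series)
  expect_identical(t1$final$phi, t2$final$phi)
  t3 <- run_simulation(quick_pattern_config(seed = 6, t_end = 3))
  expect_false(identical(t1$final$phi, t3$final$phi))
})

test_that("compiled fast path agrees with the R reference step", {
  cfg <- quick_pattern_config(seed = 2, t_end = 0.5, output_every = 25)
  fast <- run_simulation(cfg)
  cfg$use_fast_path <- FALSE
  ref <- run_simulation(cfg)
  expect_equal(nrow(fast$series), nrow(ref$series))
  expect_lt(max(abs(fast$final$mesh$vertices - ref$final$mesh$vertices)), 1e-9)
  expect_lt(max(abs(fast$final$phi - ref$final$phi)), 1e-9)
  expect_lt(max(abs(fast$series$total_energy - ref$series$total_energy)), 1e-9)
})

test_that("unstable parameters produce patches and growing curvature excess", {
  # triple chosen inside the patterning region located by the Jacobian oracle
  st <- homogeneous_state(build_circle_curve(48), 0.1, 6, 0.3, xi_star = 20)
  gr <- jacobian_growth_rates(st, n_modes = 6)
  expect_gt(max(gr$growth_rate, na.rm = TRUE), 0)

  tr <- run_simulation(quick_pattern_config(seed = 1, t_end = 60))
  s <- tr$series
  expect_gte(tail(s$patch_count, 1), 1)
  exc <- s$max_curvature_excess
  mid <- exc[which.min(abs(s$time - 10))]
  expect_gt(mid, exc[1])                       # growth after onset
  expect_lt(tail(exc, 1), 1.2 * max(exc))      # saturation, no blow-up
})

test_that("morphogen variance first smooths, then grows (three-phase path)", {
  tr <- run_simulation(quick_pattern_config(seed = 4, t_end = 25))
  vars <- tr$series$morphogen_variance
  vmin_idx <- which.min(vars)
  expect_lt(vars[vmin_idx], 0.5 * vars[1])          # smoothing of initial noise
  expect_gt(max(vars[vmin_idx:length(vars)]), 4 * vars[vmin_idx])  # patch growth
  expect_gt(vmin_idx, 1)
  expect_lt(vmin_idx, length(vars))
})

test_that("equilibrium detection distinguishes settled, decaying and terminal runs", {
  # static relaxed state: detected immediately after the first window
  mech <- mechanical_params(kappa0 = 1, h0_base = 1, h0_coupling = 0, xi = 1,
                            area_stiffness = 100)
  kin_dead <- kinetic_params(diffusion = 0, production_max = 0, degradation = 1)
  cfg <- simulation_config(backend = "curve2d", n = 32, mech = mech,
                           kin = kin_dead, t_end = 50, phi0_mean = 0.5,
                           phi0_halfwidth = 0, output_every = 25,
                           dt_init = 1e-3, dt_max = 0.05)
  tr <- run_simulation(cfg)
  expect_identical(tr$status, "equilibrium")
  # pure decay settles once exp(-k t) flattens below tolerance; with the
  # 1e-3 floor in the relative drift this happens near t ~ log(phi0*L/tol)/k
  expect_lt(tr$equilibrium_time, 25)
  expect_gt(tr$equilibrium_time, 5)
  expect_true(detect_equilibrium(tr)$detected)

  # runaway budding: terminal event, never classified as equilibrium
  bud <- simulation_config(backend = "curve2d", n = 48, d_star = 0.01,
                           p_star = 25, m_star = 0.3, xi_star = 20,
                           t_end = 60, seed = 1, quality_min = 0.3)
  trb <- run_simulation(bud)
  expect_true(trb$status %in% c("dt_underflow", "mesh_degenerate"))
  expect_false(detect_equilibrium(trb)$detected)
  expect_identical(morphomech:::classify_run(trb), "budding")
})

test_that("trajectory series share a strictly increasing time axis", {
  tr <- run_simulation(quick_pattern_config(seed = 3, t_end = 5))
  expect_true(all(diff(tr$series$time) > 0))
  expect_true(all(tr$series$dt > 0))
})
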