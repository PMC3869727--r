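test_that("stochastic initial field: bounds, determinism, sampling error", {
  mesh <- build_sphere_mesh(4)  # 2562 vertices
  expect_identical(random_initial_morphogen(mesh, 0.5, 0, seed = 1),
                   rep(0.5, nrow(mesh$vertices)))
  f1 <- random_initial_morphogen(mesh, 0.5, 0.25, seed = 7)
  f2 <- random_initial_morphogen(mesh, 0.5, 0.25, seed = 7)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0.25 & f1 <= 0.75))
  # uniform(mean +- hw): sd = hw/sqrt(3); 99% CI on the sample mean
  hw <- 0.25; n <- nrow(mesh$vertices)
  expect_lt(abs(mean(f1) - 0.5), 2.58 * hw / sqrt(3 * n) * 2)
  expect_error(random_initial_morphogen(mesh, 0.1, 0.2, seed = 1),
               class = "morphomech_parameter_error")
})

test_that("cap forcing: window, taper, direction, zero magnitude", {
  mesh <- build_sphere_mesh(2)
  spec <- forcing_spec(c(0, 0, 1), 0.6, 2, "outward", t_on = 1, t_off = 2)
  expect_true(all(make_forcing(spec, mesh, t = 0.5) == 0))
  Fm <- make_forcing(spec, mesh, t = 1.5)
  inside <- cap_vertices(spec, mesh)
  expect_true(all(rowSums(Fm[inside, , drop = FALSE]^2) > 0))
  expect_true(all(Fm[-inside, ] == 0))
  # outward: positive radial component; inward flips the sign
  rad <- rowSums(Fm * mesh$vertices)[inside]
  expect_true(all(rad > 0))
  spec_in <- forcing_spec(c(0, 0, 1), 0.6, 2, "inward", t_on = 1, t_off = 2)
  expect_equal(make_forcing(spec_in, mesh, 1.5), -Fm)
  # cosine taper: magnitude decreases with angular distance
  psi <- acos(pmin(pmax(mesh$vertices[inside, 3], -1), 1))
  mag <- sqrt(rowSums(Fm[inside, , drop = FALSE]^2))
  expect_true(all(diff(mag[order(psi)]) <= 1e-9))

  zero <- forcing_spec(c(0, 0, 1), 0.6, 0, "outward")
  expect_true(all(make_forcing(zero, mesh, 1) == 0))
})

test_that("snapshot round-trips preserve state to 1e-12", {
  dir <- withr::local_tempdir()
  sm <- perturbed_sphere(2)
  set.seed(3); phi <- runif(nrow(sm$vertices))
  p <- file.path(dir, "state.vtk")
  write_snapshot(sm, phi, p)
  back <- read_snapshot(p)
  expect_lt(max(abs(back$mesh$vertices - sm$vertices)), 1e-12)
  expect_lt(max(abs(back$phi - phi)), 1e-12)
  f <- back$mesh$faces
  e <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
  expect_identical(nrow(back$mesh$vertices) - nrow(e) + nrow(f), 2L)

  cm <- perturbed_curve(20)
  phic <- runif(20)
  pc <- file.path(dir, "curve.csv")
  write_snapshot(cm, phic, pc)
  backc <- read_snapshot(pc)
  expect_lt(max(abs(backc$mesh$vertices - cm$vertices)), 1e-12)
  expect_lt(max(abs(backc$phi - phic)), 1e-12)

  # truncated file raises a typed format error naming the problem
  lines <- readLines(p)
  writeLines(lines[1:20], p)
  expect_error(read_snapshot(p), class = "morphomech_format_error")
  expect_error(read_snapshot(file.path(dir, "nope.vtk")),
               class = "morphomech_format_error")
})

test_that("OBJ round-trip preserves geometry", {
  dir <- withr::local_tempdir()
  sm <- perturbed_sphere(2)
  p <- file.path(dir, "mesh.obj")
  write_obj(sm, p)
  back <- read_obj(p)
  expect_lt(max(abs(back$vertices - sm$vertices)), 1e-12)
  expect_identical(back$faces, sm$faces)
})

test_that("config files round-trip; unknown keys and mixed blocks error", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(backend = "curve2d", n = 48, d_star = 0.1,
                           p_star = 6, m_star = 0.3, xi_star = 20,
                           t_end = 10, seed = 9,
                           forcing = forcing_spec(0.3, 0.5, 1, "inward",
                                                  t_on = 0, t_off = 5))
  p <- file.path(dir, "run.cfg")
  write_config(cfg, p)
  cfg2 <- read_config(p)
  for (k in c("backend", "n", "d_star", "p_star", "m_star", "seed", "t_end"))
    expect_equal(cfg2[[k]], cfg[[k]])
  expect_equal(cfg2$forcing$magnitude, 1)
  expect_equal(cfg2$forcing$direction, "inward")

  writeLines(c("run.backend = curve2d", "model.dstar_typo = 1"), p)
  expect_error(read_config(p), class = "morphomech_format_error")
  writeLines(c("run.backend = curve2d", "model.d_star = 1",
               "model.p_star = 1", "model.m_star = 1", "kin.diffusion = 1"), p)
  expect_error(read_config(p), class = "morphomech_parameter_error")
  expect_error(simulation_config(backend = "curve2d"),
               class = "morphomech_parameter_error")
})

test_that("trajectory CSV follows the documented schema", {
  dir <- withr::local_tempdir()
  tr <- run_simulation(quick_pattern_config(seed = 2, t_end = 1))
  p <- file.path(dir, "traj.csv")
  write_trajectory_csv(tr, p)
  df <- read.csv(p)
  expect_identical(names(df),
                   c("time", "total_energy", "total_morphogen",
                     "max_curvature_excess", "max_area_drift", "patch_count",
                     "dt", "accepted"))
  expect_true(all(diff(df$time) > 0))
})

test_that("experiment protocol: seed-matched arms, zero-magnitude control identity", {
  cfg <- quick_pattern_config(seed = 3, t_end = 2)
  pull <- forcing_spec(0, 0.6, 0.5, "outward", t_on = 0, t_off = 2)
  ex <- run_experiment(cfg, pull = pull)
  expect_identical(sort(unique(ex$summary$seed)), cfg$seed)
  expect_identical(ex$summary$arm, c("control", "pull", "press"))
  # the unforced control arm is bit-identical to a plain simulation
  plain <- run_simulation(cfg)
  expect_identical(ex$control$series, plain$series)
  expect_identical(ex$control$final$phi, plain$final$phi)
  # and a zero-magnitude "forced" run matches the control exactly
  cfg0 <- cfg; cfg0$forcing <- forcing_spec(0, 0.6, 0, "outward", 0, 2)
  tr0 <- run_simulation(cfg0)
  expect_identical(tr0$series, plain$series)
})

test_that("command-line interface: exit codes and stability output", {
  dir <- withr::local_tempdir()
  expect_identical(cli_main(character()), 1L)
  expect_identical(cli_main(c("simulate", "--config",
                              file.path(dir, "missing.cfg"))), 1L)
  expect_identical(cli_main(c("frobnicate")), 1L)

  out <- capture.output(
    code <- cli_main(c("stability", "--d-star", "0.2", "--p-star", "0",
                       "--m-star", "1", "--n", "32")),
    type = "message")
  expect_identical(code, 0L)
  rates <- as.numeric(sub(".*growth_rate\\s+", "", grep("mode", out, value = TRUE)))
  expect_true(all(rates <= 1e-6, na.rm = TRUE))

  cfgp <- file.path(dir, "run.cfg")
  write_config(quick_pattern_config(seed = 1, t_end = 0.5), cfgp)
  outdir <- file.path(dir, "out")
  expect_identical(cli_main(c("simulate", "--config", cfgp, "--out", outdir)), 0L)
  expect_true(file.exists(file.path(outdir, "trajectory.csv")))
  expect_true(file.exists(file.path(outdir, "final.csv")))

  snap <- file.path(dir, "snap.csv")
  tr <- run_simulation(quick_pattern_config(seed = 1, t_end = 0.5))
  write_snapshot(tr$final$mesh, tr$final$phi, snap)
  expect_identical(cli_main(c("analyze", "--snapshot", snap)), 0L)
})
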