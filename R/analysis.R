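#' Count morphogen patches
#'
#' Patches are connected components (mesh adjacency) of the super-threshold
#' vertex set; components of fewer than 3 vertices are discarded as noise.
#' The default threshold is `mean(phi) + 0.5 * (max(phi) - mean(phi))` —
#' halfway between the field mean and its maximum.
#'
#' @param mesh a `surface_mesh`.
#' @param phi per-vertex morphogen field.
#' @param threshold concentration threshold; `NULL` for the default.
#' @param curvature_ref reference curvature for the reported maximal
#'   curvature excess; defaults to the area-weighted mean curvature.
#' @return a `pattern_summary`: list with `n_patches`, `patch_areas`,
#'   `patch_mean_phi`, `patch_vertices`, `max_curvature_excess`,
#'   `threshold_used`.
#' @export
count_patches <- function(mesh, phi, threshold = NULL, curvature_ref = NULL) {
  phi <- check_field(mesh, phi)
  if (is.null(threshold)) threshold <- mean(phi) + 0.5 * (max(phi) - mean(phi))
  if (!is.finite(threshold)) mm_parameter_error("threshold must be finite")
  a <- local_areas(mesh)
  H <- mean_curvature(mesh)
  if (is.null(curvature_ref)) curvature_ref <- sum(H * a) / sum(a)

  above <- which(phi > threshold)
  comps <- list()
  if (length(above) >= 3L) {
    n <- n_vertices(mesh)
    if (mesh$backend == "curve2d") {
      edges <- cbind(seq_len(n), c(2:n, 1L))
    } else {
      f <- mesh$faces
      edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
    }
    keep <- edges[, 1] %in% above & edges[, 2] %in% above
    el <- cbind(match(edges[keep, 1], above), match(edges[keep, 2], above))
    g <- igraph::make_graph(edges = as.vector(t(el)), n = length(above),
                            directed = FALSE)
    cc <- igraph::components(g)
    comps <- split(above, cc$membership)
    comps <- Filter(function(v) length(v) >= 3L, comps)
  }
  structure(list(
    n_patches = length(comps),
    patch_areas = vapply(comps, function(v) sum(a[v]), numeric(1), USE.NAMES = FALSE),
    patch_mean_phi = vapply(comps, function(v) sum(phi[v] * a[v]) / sum(a[v]),
                            numeric(1), USE.NAMES = FALSE),
    patch_vertices = unname(comps),
    max_curvature_excess = max(H - curvature_ref),
    threshold_used = threshold), class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("<pattern_summary patches=%d  areas=%s  threshold=%.4g>\n",
              x$n_patches, paste(signif(x$patch_areas, 3), collapse = ", "),
              x$threshold_used))
  invisible(x)
}

#' Total morphogen content
#'
#' `sum(phi_v * a_v)` over the current local measures: the observable whose
#' time series characterizes the approach to equilibrium.
#'
#' @param mesh a `surface_mesh`.
#' @param phi per-vertex field.
#' @return scalar.
#' @export
total_morphogen <- function(mesh, phi) {
  phi <- check_field(mesh, phi)
  sum(phi * local_areas(mesh))
}

# right-hand side of the full semi-discrete system at a given state,
# independent of the time integrator (used by the stability oracle)
system_rhs <- function(mesh, phi, mech, kin, ops = NULL) {
  a <- local_areas(mesh)
  F <- shape_gradient(mesh, phi, mech) +
    incompressibility_forces(mesh, mech)$forces
  vel <- F / (mech$xi * a)
  if (is.null(ops)) ops <- lb_matrices(mesh)
  H <- mean_curvature(mesh)
  dphi <- -kin$diffusion * as.numeric(ops$stiffness %*% phi) / ops$mass -
    kin$degradation * phi + production_rate(H, kin)
  c(as.numeric(vel), dphi)
}

#' Numerical linear-stability oracle
#'
#' Assembles the Jacobian of the full semi-discrete system (vertex positions
#' and morphogen values) at a homogeneous steady state by forward finite
#' differences of the right-hand side, then reports the leading eigenvalue
#' restricted to each symmetry mode: Fourier index on the circle, spherical-
#' harmonic degree on the sphere (by projection of the eigenvector's
#' morphogen and radial components).  A positive leading growth rate at some
#' mode predicts spontaneous patterning at that wavelength.
#'
#' @param state a homogeneous state from [homogeneous_state()] (or a list
#'   with `mesh`, `phi`, `mech`, `kin`).
#' @param n_modes highest symmetry mode to report.
#' @param fd_step forward-difference step, scaled by `max(1, |state|)`
#'   component-wise.
#' @return data.frame with columns `mode` and `growth_rate` (max real part of
#'   the eigenvalues dominated by that mode); the full eigenvalue set is
#'   attached as attribute `eigenvalues`.
#' @export
jacobian_growth_rates <- function(state, n_modes = 8, fd_step = 1e-6) {
  mesh <- state$mesh
  phi <- check_field(mesh, state$phi)
  mech <- state$mech; kin <- state$kin
  n <- n_vertices(mesh)
  d <- ncol(mesh$vertices)
  ops <- lb_matrices(mesh)

  pack <- function(V, p) c(as.numeric(V), p)
  s0 <- pack(mesh$vertices, phi)
  rhs <- function(s) {
    V <- matrix(s[seq_len(n * d)], n, d)
    p <- s[n * d + seq_len(n)]
    system_rhs(with_vertices(mesh, V), p, mech, kin, ops = NULL)
  }
  f0 <- rhs(s0)
  m <- length(s0)
  J <- matrix(0, m, m)
  for (k in seq_len(m)) {
    h <- fd_step * max(1, abs(s0[k]))
    sk <- s0; sk[k] <- sk[k] + h
    J[, k] <- (rhs(sk) - f0) / h
  }
  ev <- tryCatch(eigen(J), error = function(e)
    mm_numerical_error("eigen decomposition failed: %s", conditionMessage(e)))

  mode_of <- if (mesh$backend == "curve2d") {
    th <- atan2(mesh$vertices[, 2], mesh$vertices[, 1])
    ord <- order(th)
    function(w) {
      wp <- w[n * d + seq_len(n)]
      wr <- rowSums(matrix(w[seq_len(n * d)], n, d) * mesh$vertices) /
        sqrt(rowSums(mesh$vertices^2))
      u <- if (sum(Mod(wp)^2) > 1e-12 * sum(Mod(w)^2)) wp else wr
      spec <- Mod(fft(u[ord]))[seq_len(min(n_modes + 1L, floor(n / 2)))]
      which.max(spec) - 1L
    }
  } else {
    Y <- sphere_harmonic_basis(mesh, n_modes)  # list per degree: n x (2l+1)
    a <- local_areas(mesh)
    function(w) {
      wp <- w[n * d + seq_len(n)]
      wr <- rowSums(matrix(w[seq_len(n * d)], n, d) * mesh$vertices) /
        sqrt(rowSums(mesh$vertices^2))
      u <- if (sum(Mod(wp)^2) > 1e-12 * sum(Mod(w)^2)) wp else wr
      pw <- vapply(Y, function(B) sum(Mod(crossprod(B, a * u))^2), numeric(1))
      which.max(pw) - 1L
    }
  }

  modes <- vapply(seq_len(m), function(i) mode_of(ev$vectors[, i]), integer(1))
  out <- data.frame(mode = 0:n_modes, growth_rate = NA_real_)
  for (mm in 0:n_modes) {
    sel <- modes == mm
    if (any(sel)) out$growth_rate[out$mode == mm] <- max(Re(ev$values[sel]))
  }
  attr(out, "eigenvalues") <- ev$values
  out
}

# real spherical harmonics evaluated at mesh vertices, mass-orthonormalized
# per degree; returns list indexed by degree 0..lmax
sphere_harmonic_basis <- function(mesh, lmax) {
  V <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  theta <- acos(pmin(pmax(V[, 3], -1), 1))
  phi_az <- atan2(V[, 2], V[, 1])
  ct <- cos(theta)
  lapply(0:lmax, function(l) {
    P <- pracma::legendre(l, ct)  # (l+1) x n, orders m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    cols <- list(P[1, ])
    if (l >= 1) for (mo in 1:l) {
      cols[[length(cols) + 1L]] <- P[mo + 1, ] * cos(mo * phi_az)
      cols[[length(cols) + 1L]] <- P[mo + 1, ] * sin(mo * phi_az)
    }
    B <- do.call(cbind, cols)
    sweep(B, 2, sqrt(colSums(B^2) + 1e-300), "/")
  })
}

#' Measured growth rate of a seeded symmetry mode
#'
#' Runs the full nonlinear simulator from the homogeneous state plus a small
#' single-mode perturbation of the morphogen field and fits the exponential
#' growth (or decay) rate of that mode's amplitude during the linear phase.
#' Together with [jacobian_growth_rates()] this provides a two-route check of
#' the dispersion behavior: simulation vs. eigenvalue.
#'
#' @param state a homogeneous state from [homogeneous_state()] (curve2d).
#' @param mode Fourier index of the seeded perturbation (>= 2).
#' @param amplitude initial perturbation amplitude.
#' @param dt fixed step size.
#' @param t_max integration horizon for the fit.
#' @param settle fraction of the horizon discarded as transient.
#' @return list with `rate` (fitted log-slope), `times`, `amplitudes`.
#' @export
mode_growth_rate <- function(state, mode, amplitude = 1e-4, dt = 2e-4,
                             t_max = 2, settle = 0.3) {
  mesh <- state$mesh
  if (mesh$backend != "curve2d")
    mm_parameter_error("mode_growth_rate is defined for the curve2d backend")
  n <- n_vertices(mesh)
  th <- atan2(mesh$vertices[, 2], mesh$vertices[, 1])
  phi <- check_field(mesh, state$phi) + amplitude * cos(mode * th)

  n_steps <- ceiling(t_max / dt)
  record_every <- max(1L, floor(n_steps / 400))
  times <- amps <- numeric(0)
  par_flat <- c(state$mech[c("kappa0", "kappa1", "h0_base", "h0_coupling",
                             "xi", "area_stiffness")],
                state$kin[c("diffusion", "production_max", "michaelis_k",
                            "degradation", "curvature_ref")])
  Vcur <- mesh$vertices; pcur <- phi; t <- 0
  while (t < t_max) {
    chunk <- cpp_curve_steps(Vcur, pcur, mesh$ref_local_areas, par_flat,
                             t, dt, t_max, numeric(7),
                             list(dt_min = dt * 0.999, dt_max = dt,
                                  energy_increase_tol = Inf,
                                  quality_min = 0, grow = 1,
                                  chunk = record_every))
    Vcur <- chunk$V; pcur <- as.numeric(chunk$phi); t <- chunk$t
    if (chunk$status == "dt_underflow" || length(chunk$time) == 0) break
    dphi <- pcur - mean(pcur)
    amp <- sqrt((2 / n * sum(dphi * cos(mode * th)))^2 +
                (2 / n * sum(dphi * sin(mode * th)))^2)
    times <- c(times, t); amps <- c(amps, amp)
  }
  keep <- times > settle * t_max & amps > 0
  if (sum(keep) < 5)
    mm_numerical_error("too few samples for a growth-rate fit")
  fit <- lm(log(amps[keep]) ~ times[keep])
  list(rate = unname(coef(fit)[2]), times = times, amplitudes = amps)
}

#' Sweep the reduced parameter space
#'
#' Runs [run_simulation()] on every grid point x seed, summarizes each run's
#' final pattern, and classifies each grid point: `"homogeneous"` (no
#' patches), `"patterned"` (stable patches), `"budding"` (terminal step-size
#' underflow or mesh degeneration before equilibrium, the operational
#' signature of runaway budding).  Individual run failures are recorded and
#' the sweep continues.
#'
#' @param grid data.frame with columns `d_star`, `p_star`, `m_star`.
#' @param seeds integer vector of seeds (>= 3 recommended).
#' @param config base [simulation_config()] whose triple/seed are overridden.
#' @return list with `runs` (one row per run) and `summary` (one row per grid
#'   point: median patch count, median patch area, classification).
#' @export
parameter_sweep <- function(grid, seeds, config) {
  grid <- as.data.frame(grid)
  if (!all(c("d_star", "p_star", "m_star") %in% names(grid)))
    mm_parameter_error("grid needs columns d_star, p_star, m_star")
  runs <- list()
  for (gi in seq_len(nrow(grid))) {
    for (seed in seeds) {
      cfg <- config
      cfg$d_star <- grid$d_star[gi]; cfg$p_star <- grid$p_star[gi]
      cfg$m_star <- grid$m_star[gi]; cfg$seed <- as.integer(seed)
      cfg$mech <- cfg$kin <- NULL
      row <- data.frame(point = gi, d_star = cfg$d_star, p_star = cfg$p_star,
                        m_star = cfg$m_star, seed = seed,
                        n_patches = NA_integer_, median_patch_area = NA_real_,
                        total_morphogen = NA_real_, status = "failed",
                        class = "failed", stringsAsFactors = FALSE)
      tr <- tryCatch(run_simulation(cfg), error = function(e) e)
      if (!inherits(tr, "error")) {
        ps <- count_patches(tr$final$mesh, tr$final$phi)
        row$n_patches <- ps$n_patches
        row$median_patch_area <- if (ps$n_patches) median(ps$patch_areas) else 0
        row$total_morphogen <- total_morphogen(tr$final$mesh, tr$final$phi)
        row$status <- tr$status
        row$class <- classify_run(tr, ps)
      }
      runs[[length(runs) + 1L]] <- row
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$point), function(r) {
    cl <- table(r$class)
    data.frame(point = r$point[1], d_star = r$d_star[1], p_star = r$p_star[1],
               m_star = r$m_star[1],
               median_patch_count = median(r$n_patches, na.rm = TRUE),
               median_patch_area = median(r$median_patch_area, na.rm = TRUE),
               median_total_morphogen = median(r$total_morphogen, na.rm = TRUE),
               class = names(cl)[which.max(cl)], stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ)
}

classify_run <- function(traj, patches = NULL) {
  if (traj$status %in% c("dt_underflow", "mesh_degenerate")) return("budding")
  # a field that has decayed to a negligible level (relative to the unit
  # concentration scale of the reduced model) is homogeneous no matter how
  # its residual noise is distributed
  if (max(traj$final$phi) < 1e-2) return("homogeneous")
  if (is.null(patches))
    patches <- count_patches(traj$final$mesh, traj$final$phi)
  if (patches$n_patches >= 1) "patterned" else "homogeneous"
}

#' Write sweep results to CSV + JSON summary
#'
#' @param sweep result of [parameter_sweep()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs_path <- file.path(dir, "sweep_runs.csv")
  summary_path <- file.path(dir, "sweep_summary.json")
  write.csv(sweep$runs, runs_path, row.names = FALSE)
  jsonlite::write_json(sweep$summary, summary_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(runs_path, summary_path))
}
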