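#' Mechanical parameters of the tissue sheet
#'
#' The modified Helfrich energy uses morphogen-dependent moduli
#' `kappa(phi) = kappa0 + kappa1 * phi` (bending rigidity) and
#' `H0(phi) = h0_base + h0_coupling * phi` (spontaneous curvature).  Local
#' incompressibility is enforced by a quadratic penalty of stiffness
#' `area_stiffness` on the per-vertex measure relative to its frozen
#' reference, whose derivative is reported as the pressure-like multiplier.
#'
#' @param kappa0 baseline bending rigidity (energy, > 0).
#' @param kappa1 rigidity-morphogen coupling (energy per unit concentration).
#'   Defaults to 0: morphogens influence preferred curvature, not stiffness.
#' @param h0_base spontaneous curvature of the relaxed tissue (1/length).
#' @param h0_coupling spontaneous-curvature-morphogen coupling (1/length per
#'   unit concentration); positive values make the morphogen induce outward
#'   bending.
#' @param xi kinetic drag coefficient per unit measure (> 0); sets the time
#'   scale of the overdamped shape relaxation only.
#' @param area_stiffness incompressibility penalty coefficient (>= 0).
#' @return an object of class `mechanical_params`.
#' @export
mechanical_params <- function(kappa0 = 1, kappa1 = 0, h0_base = 2,
                              h0_coupling = 1, xi = 1, area_stiffness = 100) {
  stopifnot_scalar(kappa0, "kappa0", positive = TRUE)
  stopifnot_scalar(kappa1, "kappa1")
  # h0_base may be per-vertex: the relaxed reference of a discrete mesh is a
  # field (discretization of the curvature operator is not exactly uniform)
  if (!is.numeric(h0_base) || !all(is.finite(h0_base)))
    mm_parameter_error("'h0_base' must be finite numeric (scalar or per-vertex)")
  stopifnot_scalar(h0_coupling, "h0_coupling")
  stopifnot_scalar(xi, "xi", positive = TRUE)
  stopifnot_scalar(area_stiffness, "area_stiffness", nonneg = TRUE)
  structure(list(kappa0 = kappa0, kappa1 = kappa1, h0_base = h0_base,
                 h0_coupling = h0_coupling, xi = xi,
                 area_stiffness = area_stiffness),
            class = "mechanical_params")
}

effective_moduli <- function(mech, phi) {
  kappa <- mech$kappa0 + mech$kappa1 * phi
  if (any(kappa <= 0))
    mm_parameter_error("non-positive effective bending rigidity (kappa0 + kappa1*phi <= 0 at %d vertices)",
                       sum(kappa <= 0))
  list(kappa = kappa, c0 = mech$h0_base + mech$h0_coupling * phi)
}

#' Discrete modified Helfrich bending energy
#'
#' `F = sum_v 1/2 * kappa(phi_v) * (H_v - H0(phi_v))^2 * a_v` over the current
#' geometry, with `H` the signed mean curvature ([mean_curvature()]) and `a`
#' the current local measures.
#'
#' @param mesh a `surface_mesh`.
#' @param phi per-vertex morphogen concentration.
#' @param mech a `mechanical_params`.
#' @return scalar energy (>= 0 whenever the effective rigidity is positive).
#' @export
helfrich_energy <- function(mesh, phi, mech) {
  phi <- check_field(mesh, phi)
  em <- effective_moduli(mech, phi)
  if (mesh$backend == "curve2d") {
    a <- local_areas(mesh)
    H <- curve_turning(mesh$vertices) / a
    sum(0.5 * em$kappa * (H - em$c0)^2 * a)
  } else {
    surf_energy(mesh, em, want_grad = FALSE)$energy_bend
  }
}

surf_energy <- function(mesh, em, want_grad, area_stiffness = 0) {
  tryCatch(
    cpp_surface_energy(mesh$vertices, mesh$faces - 1L, em$kappa, em$c0,
                       mesh$ref_local_areas, area_stiffness, want_grad),
    error = function(e) mm_geometry_error("%s", conditionMessage(e)))
}

check_field <- function(mesh, phi) {
  if (length(phi) == 1L) phi <- rep(as.numeric(phi), n_vertices(mesh))
  if (length(phi) != n_vertices(mesh))
    mm_parameter_error("field length %d does not match vertex count %d",
                       length(phi), n_vertices(mesh))
  as.numeric(phi)
}

#' Elastic force: exact negative gradient of the discrete bending energy
#'
#' Differentiates [helfrich_energy()] exactly with respect to vertex
#' positions, holding the per-vertex morphogen values fixed (Lagrangian
#' transport).  The sum of the returned force vectors vanishes (translation
#' invariance of the discrete energy).
#'
#' @inheritParams helfrich_energy
#' @return n x 2 or n x 3 matrix of per-vertex force vectors.
#' @export
shape_gradient <- function(mesh, phi, mech) {
  phi <- check_field(mesh, phi)
  em <- effective_moduli(mech, phi)
  if (mesh$backend == "curve2d") {
    -curve_bending_gradient(mesh$vertices, em$kappa, em$c0)
  } else {
    -surf_energy(mesh, em, want_grad = TRUE)$grad_bend
  }
}

# gradient of sum_i 1/2 kappa_i (theta_i/a_i - c_i)^2 a_i  w.r.t. positions
curve_bending_gradient <- function(V, kappa, c0) {
  ce <- curve_edges(V)
  e <- ce$e; l <- ce$l
  t_ <- e / l
  a <- (shift_prev(l) + l) / 2
  theta <- curve_turning(V)
  H <- theta / a

  dF_dtheta <- kappa * (H - c0)
  dF_da <- 0.5 * kappa * (c0^2 - H^2)

  # perp(e_i)/l_i^2
  p <- cbind(-e[, 2], e[, 1]) / l^2

  # theta contributions: grad_{x_j} = p_j (D_{j+1} - D_j) + p_{j-1} (D_{j-1} - D_j)
  Dn <- shift_next(dF_dtheta); Dp <- shift_prev(dF_dtheta)
  gT <- p * (Dn - dF_dtheta) + shift_prev(p) * (Dp - dF_dtheta)

  # length contributions: coefficient of dl_i is g_i = (A_i + A_{i+1})/2
  g <- (dF_da + shift_next(dF_da)) / 2
  gL <- -g * t_ + shift_prev(g) * shift_prev(t_)
  gT + gL
}

#' Local incompressibility forces and multiplier estimate
#'
#' Exact negative gradient of the quadratic penalty
#' `E_area = sum_v 1/2 * area_stiffness * (a_v - a_v_ref)^2 / a_v_ref`
#' together with the per-vertex multiplier estimate
#' `lambda_v = area_stiffness * (a_v - a_v_ref) / a_v_ref`, which plays the
#' role of the local Lagrange multiplier (a pressure) in the stiff limit.
#'
#' @inheritParams helfrich_energy
#' @return list with `forces` (n x d matrix) and `lambda` (numeric vector).
#' @export
incompressibility_forces <- function(mesh, mech) {
  k <- mech$area_stiffness
  if (mesh$backend == "curve2d") {
    ce <- curve_edges(mesh$vertices)
    t_ <- ce$e / ce$l
    a <- (shift_prev(ce$l) + ce$l) / 2
    lambda <- k * (a - mesh$ref_local_areas) / mesh$ref_local_areas
    g <- (lambda + shift_next(lambda)) / 2
    list(forces = -(-g * t_ + shift_prev(g) * shift_prev(t_)), lambda = lambda)
  } else {
    em <- list(kappa = rep(1, n_vertices(mesh)), c0 = rep(0, n_vertices(mesh)))
    res <- surf_energy(mesh, em, want_grad = TRUE, area_stiffness = k)
    list(forces = -res$grad_area, lambda = as.numeric(res$lambda))
  }
}

# penalty energy (for step control / Lyapunov bookkeeping)
area_penalty_energy <- function(mesh, mech) {
  a <- local_areas(mesh)
  sum(0.5 * mech$area_stiffness * (a - mesh$ref_local_areas)^2 / mesh$ref_local_areas)
}

#' Total mechanical energy (bending + incompressibility penalty)
#'
#' The Lyapunov function of the shape flow at fixed morphogen field.
#'
#' @inheritParams helfrich_energy
#' @return scalar energy.
#' @export
mechanical_energy <- function(mesh, phi, mech) {
  helfrich_energy(mesh, phi, mech) + area_penalty_energy(mesh, mech)
}
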