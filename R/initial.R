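#' Stochastic initial morphogen field
#'
#' Independent per-vertex draws, uniform on
#' `[mean - halfwidth, mean + halfwidth]`.
#'
#' @param mesh a `surface_mesh`.
#' @param mean average initial concentration (>= halfwidth).
#' @param halfwidth half-width of the uniform interval (>= 0).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream
#'   (used internally so one config seed drives all randomness).
#' @return numeric per-vertex field.
#' @export
random_initial_morphogen <- function(mesh, mean, halfwidth, seed = NULL) {
  stopifnot_scalar(mean, "mean", nonneg = TRUE)
  stopifnot_scalar(halfwidth, "halfwidth", nonneg = TRUE)
  if (mean - halfwidth < 0)
    mm_parameter_error("mean - halfwidth must be >= 0 (concentrations are nonnegative)")
  if (!is.null(seed)) set.seed(seed)
  runif(n_vertices(mesh), mean - halfwidth, mean + halfwidth)
}

#' Homogeneous steady state of the coupled discrete system
#'
#' For a reduced triple on a relaxed mesh, returns the spatially uniform
#' state that is an exact fixed point of the discrete dynamics: the
#' production reference is anchored at the discrete relaxed curvature minus
#' `ref_offset`, the uniform concentration solves
#' `production(ref_offset) = degradation * phi`, and the spontaneous-curvature
#' baseline is shifted so the relaxed shape is mechanically stationary.  With
#' `ref_offset = 0` this is the relaxed shape with `phi = 0` (the production
#' gate sits exactly at its kink); with `ref_offset > 0` the state lies on the
#' smooth branch of the gate, which linear stability analysis requires.
#'
#' @param mesh a relaxed `surface_mesh` (exact circle or sphere).
#' @param d_star,p_star,m_star reduced triple.
#' @param xi_star,area_stiffness,ref_offset as in [params_from_triple()].
#' @return list with `mesh`, `phi` (uniform), `mech`, `kin`, `phi_star`.
#' @export
homogeneous_state <- function(mesh, d_star, p_star, m_star, xi_star = 10,
                              area_stiffness = 1000, ref_offset = 0) {
  pp <- params_from_triple(d_star, p_star, m_star, backend = mesh$backend,
                           xi_star = xi_star, area_stiffness = area_stiffness,
                           ref_offset = ref_offset)
  h_disc <- if (mesh$backend == "curve2d") mean(mean_curvature(mesh))
            else mean_curvature(mesh)
  pp$kin$curvature_ref <- h_disc - ref_offset
  pp$mech$h0_base <- h_disc - pp$phi_star
  list(mesh = mesh, phi = rep(pp$phi_star, n_vertices(mesh)),
       mech = pp$mech, kin = pp$kin, phi_star = pp$phi_star)
}
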