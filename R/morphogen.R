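#' Kinetic parameters of the morphogen
#'
#' Reaction-diffusion dynamics on the moving tissue: diffusion with constant
#' `diffusion`, linear degradation at rate `degradation`, and curvature-gated
#' Michaelis-Menten production
#' `rate = production_max * Hplus / (michaelis_k + Hplus)` with
#' `Hplus = max(H - curvature_ref, 0)`.  Only curvature above the reference
#' (relaxed) curvature induces expression; symmetric gating would produce
#' oscillations rather than stable patterns.
#'
#' @param diffusion diffusion constant (length^2/time, >= 0).
#' @param production_max maximal expression rate (concentration/time, >= 0).
#' @param michaelis_k half-saturation curvature excess (1/length, > 0).
#' @param degradation linear decay rate (1/time, > 0).
#' @param curvature_ref reference curvature above which production switches on
#'   (1/length); defaults to the curvature of the relaxed initial sphere/circle
#'   and is set from the initial mesh by [simulation_config()] when `NA`.
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(diffusion = 0.1, production_max = 1,
                           michaelis_k = 1, degradation = 1,
                           curvature_ref = NA_real_) {
  stopifnot_scalar(diffusion, "diffusion", nonneg = TRUE)
  stopifnot_scalar(production_max, "production_max", nonneg = TRUE)
  stopifnot_scalar(michaelis_k, "michaelis_k", positive = TRUE)
  stopifnot_scalar(degradation, "degradation", nonneg = TRUE)
  # curvature_ref may be per-vertex (the discrete relaxed curvature field)
  if (!(length(curvature_ref) == 1L && is.na(curvature_ref)) &&
      (!is.numeric(curvature_ref) || !all(is.finite(curvature_ref))))
    mm_parameter_error("'curvature_ref' must be finite numeric (scalar or per-vertex) or NA")
  structure(list(diffusion = diffusion, production_max = production_max,
                 michaelis_k = michaelis_k, degradation = degradation,
                 curvature_ref = curvature_ref),
            class = "kinetic_params")
}

#' Curvature-gated Michaelis-Menten production rate
#'
#' @param curvature per-vertex signed mean curvature (1/length).
#' @param kin a `kinetic_params` (with resolved `curvature_ref`).
#' @return per-vertex production rate (concentration/time).
#' @export
production_rate <- function(curvature, kin) {
  if (length(kin$curvature_ref) == 1L && is.na(kin$curvature_ref))
    mm_parameter_error("curvature_ref is unset; resolve it against the relaxed mesh first")
  hplus <- pmax(curvature - kin$curvature_ref, 0)
  kin$production_max * hplus / (kin$michaelis_k + hplus)
}

#' One semi-implicit morphogen substep on a frozen geometry
#'
#' Diffusion and degradation are treated implicitly, production explicitly at
#' the start-of-step curvature:
#' `(M + dt*(D*K + degradation*M)) phi' = M phi + dt * M * rate`,
#' with `M` the lumped mass matrix and `K` the stiffness form of the surface
#' Laplacian.  The system matrix is an M-matrix, so nonnegative input with
#' nonnegative production yields nonnegative output up to roundoff; values
#' below `-1e-12 * scale` would indicate a solver failure, tiny negatives are
#' clamped to zero and counted.
#'
#' @param mesh a `surface_mesh` (geometry frozen during the substep).
#' @param phi per-vertex concentration (>= 0).
#' @param kin a `kinetic_params`.
#' @param dt substep length (> 0).
#' @param ops optional precomputed [lb_matrices()] of `mesh`.
#' @param curvature optional precomputed [mean_curvature()] of `mesh`.
#' @return numeric vector `phi'` with attribute `clamped` (number of vertices
#'   clamped to zero).
#' @export
morphogen_step <- function(mesh, phi, kin, dt, ops = NULL, curvature = NULL) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  phi <- check_field(mesh, phi)
  if (is.null(ops)) ops <- lb_matrices(mesh)
  if (is.null(curvature)) curvature <- mean_curvature(mesh)
  m <- ops$mass
  rate <- production_rate(curvature, kin)
  rhs <- m * phi + dt * m * rate
  diag_part <- m * (1 + dt * kin$degradation)
  n <- length(m)
  phi_new <- tryCatch({
    if (kin$diffusion == 0) {
      rhs / diag_part
    } else if (n <= 400L) {
      A <- as.matrix(dt * kin$diffusion * ops$stiffness)
      diag(A) <- diag(A) + diag_part
      as.numeric(solve(A, rhs))
    } else {
      A <- dt * kin$diffusion * ops$stiffness +
        Matrix::Diagonal(x = diag_part)
      as.numeric(Matrix::solve(A, rhs))
    }
  }, error = function(e)
    mm_numerical_error("morphogen linear solve failed (n=%d, dt=%g): %s",
                       n, dt, conditionMessage(e)))
  if (any(!is.finite(phi_new)))
    mm_numerical_error("morphogen solve produced non-finite values")
  neg <- phi_new < 0
  out <- phi_new
  out[neg] <- 0
  attr(out, "clamped") <- sum(neg & phi_new < -1e-12 * max(1, max(abs(phi_new))))
  attr(out, "n_negative") <- sum(neg)
  out
}
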