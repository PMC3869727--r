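#' Localized external forcing (virtual micropipette)
#'
#' A circular cap of the tissue is pulled outward or pressed inward along the
#' local outward normal while `t` is in `[t_on, t_off]`, with a cosine taper
#' to zero at the cap edge.  Used for the virtual experiments probing whether
#' imposed curvature induces (outward) or suppresses (inward) morphogen
#' patches.
#'
#' @param center cap center: a unit 3-vector (surface3d) or a polar angle in
#'   radians (curve2d).
#' @param angular_radius cap half-opening angle in radians, in (0, pi).
#' @param magnitude force per unit measure (>= 0).
#' @param direction `"outward"` (pull) or `"inward"` (press).
#' @param t_on,t_off activation window (`t_on < t_off`).
#' @return an object of class `forcing_spec`.
#' @export
forcing_spec <- function(center, angular_radius, magnitude,
                         direction = c("outward", "inward"),
                         t_on = 0, t_off = Inf) {
  direction <- match.arg(direction)
  if (!(angular_radius > 0 && angular_radius < pi))
    mm_parameter_error("angular_radius must be in (0, pi)")
  stopifnot_scalar(magnitude, "magnitude", nonneg = TRUE)
  if (!(t_on < t_off)) mm_parameter_error("need t_on < t_off")
  if (length(center) == 3) center <- center / sqrt(sum(center^2))
  structure(list(center = center, angular_radius = angular_radius,
                 magnitude = magnitude, direction = direction,
                 t_on = t_on, t_off = t_off),
            class = "forcing_spec")
}

#' Evaluate a forcing specification on a mesh
#'
#' @param spec a [forcing_spec()].
#' @param mesh a `surface_mesh`.
#' @param t current time.
#' @return n x d matrix of per-vertex force vectors (zero outside the cap and
#'   outside the activation window).
#' @export
make_forcing <- function(spec, mesh, t) {
  d <- ncol(mesh$vertices)
  out <- matrix(0, n_vertices(mesh), d)
  if (t < spec$t_on || t > spec$t_off || spec$magnitude == 0) return(out)
  psi <- cap_angle(spec, mesh)
  inside <- psi < spec$angular_radius
  if (!any(inside)) return(out)
  taper <- 0.5 * (1 + cos(pi * psi[inside] / spec$angular_radius))
  sgn <- if (spec$direction == "outward") 1 else -1
  nrm <- vertex_normals(mesh)
  out[inside, ] <- sgn * spec$magnitude * taper * nrm[inside, , drop = FALSE]
  out
}

# angular distance of each vertex from the cap center
cap_angle <- function(spec, mesh) {
  V <- mesh$vertices
  if (mesh$backend == "curve2d") {
    ang <- atan2(V[, 2], V[, 1])
    d <- abs(ang - spec$center)
    pmin(d, 2 * pi - d)
  } else {
    u <- V / sqrt(rowSums(V^2))
    acos(pmin(pmax(as.numeric(u %*% spec$center), -1), 1))
  }
}

#' Vertices inside a forcing cap
#'
#' @inheritParams make_forcing
#' @return integer vector of vertex indices with angular distance below the
#'   cap radius.
#' @export
cap_vertices <- function(spec, mesh) {
  which(cap_angle(spec, mesh) < spec$angular_radius)
}

#' Run the virtual pull/press experiment protocol
#'
#' Three seed-matched runs — unforced control, outward pull, inward press —
#' differing only in the forcing term, so any difference in the outcome is
#' attributable to the imposed deformation.
#'
#' @param config base [simulation_config()] (its `forcing` is ignored).
#' @param pull,press [forcing_spec()]s for the two forced arms; defaults
#'   place both on the same cap.
#' @param out_dir optional directory for per-arm trajectory CSVs.
#' @return list with trajectories `control`, `pull`, `press`, the specs, and
#'   per-arm cap morphogen content + patch counts in `summary`.
#' @export
run_experiment <- function(config, pull = NULL, press = NULL, out_dir = NULL) {
  if (is.null(pull))
    pull <- forcing_spec(default_center(config), 0.6, 0.5, "outward",
                         t_on = 0, t_off = config$t_end)
  if (is.null(press))
    press <- forcing_spec(pull$center, pull$angular_radius, pull$magnitude,
                          "inward", t_on = pull$t_on, t_off = pull$t_off)
  arms <- list(control = NULL, pull = pull, press = press)
  out <- lapply(arms, function(f) {
    cfg <- config
    cfg$forcing <- f
    run_simulation(cfg)
  })
  summary <- do.call(rbind, lapply(names(out), function(nm) {
    tr <- out[[nm]]
    cap <- cap_vertices(pull, tr$final$mesh)
    ps <- count_patches(tr$final$mesh, tr$final$phi)
    in_cap <- if (ps$n_patches)
      sum(vapply(ps$patch_vertices, function(v) any(v %in% cap), logical(1)))
    else 0L
    a <- local_areas(tr$final$mesh)
    data.frame(arm = nm, seed = tr$config$seed, status = tr$status,
               cap_morphogen = sum(tr$final$phi[cap] * a[cap]),
               total_morphogen = total_morphogen(tr$final$mesh, tr$final$phi),
               n_patches = ps$n_patches, patches_in_cap = in_cap,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      write_trajectory_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  c(out, list(specs = list(pull = pull, press = press), summary = summary))
}

default_center <- function(config) {
  if (config$backend == "curve2d") 0 else c(0, 0, 1)
}
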