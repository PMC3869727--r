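#' Write a state snapshot
#'
#' Surface meshes are written as legacy ASCII VTK POLYDATA with the morphogen
#' as a per-vertex scalar field `phi`; curves as CSV with columns `x`, `y`,
#' `phi` in cyclic vertex order.  The format is chosen from the file
#' extension (`.vtk` or `.csv`).
#'
#' @param mesh a `surface_mesh`.
#' @param phi per-vertex morphogen field.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_snapshot <- function(mesh, phi, path) {
  phi <- check_field(mesh, phi)
  if (grepl("\\.csv$", path, ignore.case = TRUE) || mesh$backend == "curve2d") {
    if (mesh$backend != "curve2d")
      mm_format_error("CSV snapshots are only defined for curve2d states")
    df <- data.frame(x = mesh$vertices[, 1], y = mesh$vertices[, 2], phi = phi)
    write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
              quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    V <- mesh$vertices
    F <- mesh$faces
    writeLines(c("# vtk DataFile Version 3.0",
                 "morphomech snapshot", "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", nrow(V))), con)
    writeLines(apply(format(V, digits = 17, trim = TRUE, scientific = TRUE),
                     1, paste, collapse = " "), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(F), 4L * nrow(F)), con)
    writeLines(paste(3L, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
    writeLines(c(sprintf("POINT_DATA %d", nrow(V)),
                 "SCALARS phi double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(phi, digits = 17, trim = TRUE, scientific = TRUE), con)
  }
  invisible(path)
}

#' Read a state snapshot
#'
#' Inverse of [write_snapshot()]; round-trips vertices and field to within
#' 1e-12.  Malformed or truncated files raise a format error naming the
#' offending record.
#'
#' @param path `.vtk` (surface3d) or `.csv` (curve2d) snapshot.
#' @return list with `mesh` and `phi`.
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) mm_format_error("snapshot file '%s' does not exist", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- tryCatch(read.csv(path), error = function(e)
      mm_format_error("cannot parse curve CSV '%s': %s", path, conditionMessage(e)))
    if (!all(c("x", "y", "phi") %in% names(df)))
      mm_format_error("curve CSV '%s' must have columns x, y, phi", path)
    if (anyNA(df$x) || anyNA(df$y) || anyNA(df$phi))
      mm_format_error("curve CSV '%s' contains missing values", path)
    mesh <- surface_mesh(cbind(df$x, df$y), backend = "curve2d")
    return(list(mesh = mesh, phi = as.numeric(df$phi)))
  }
  lines <- readLines(path, warn = FALSE)
  need <- function(cond, what)
    if (!cond) mm_format_error("malformed VTK snapshot '%s': %s", path, what)
  need(length(lines) >= 5, "missing header")
  need(grepl("DATASET POLYDATA", lines[4]), "DATASET POLYDATA record missing")
  ip <- grep("^POINTS ", lines)
  need(length(ip) == 1, "POINTS record missing")
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  need(is.finite(np) && np > 0, "bad POINTS count")
  need(length(lines) >= ip + np, "truncated POINTS block")
  V <- matrix(scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE),
              ncol = 3, byrow = TRUE)
  need(nrow(V) == np, "POINTS block has wrong shape")
  ig <- grep("^POLYGONS ", lines)
  need(length(ig) == 1, "POLYGONS record missing")
  nf <- as.integer(strsplit(lines[ig], "\\s+")[[1]][2])
  need(length(lines) >= ig + nf, "truncated POLYGONS block")
  Fm <- matrix(scan(text = lines[(ig + 1):(ig + nf)], quiet = TRUE),
               ncol = 4, byrow = TRUE)
  need(all(Fm[, 1] == 3), "non-triangle polygon found")
  is <- grep("^SCALARS phi", lines)
  need(length(is) == 1, "SCALARS phi record missing")
  need(length(lines) >= is + 1 + np, "truncated scalar block")
  phi <- scan(text = lines[(is + 2):(is + 1 + np)], quiet = TRUE)
  need(length(phi) == np, "scalar block has wrong length")
  mesh <- surface_mesh(V, Fm[, 2:4] + 1L, backend = "surface3d")
  list(mesh = mesh, phi = phi)
}

#' Write / read OBJ geometry (surface3d, geometry only)
#'
#' @param mesh a surface3d `surface_mesh`.
#' @param path file path.
#' @return `write_obj` returns `path` invisibly; `read_obj` a `surface_mesh`.
#' @export
write_obj <- function(mesh, path) {
  if (mesh$backend != "surface3d") mm_format_error("OBJ output is surface3d only")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", apply(format(mesh$vertices, digits = 17, trim = TRUE),
                              1, paste, collapse = " ")), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) mm_format_error("OBJ file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl) || !length(fl))
    mm_format_error("OBJ file '%s' has no vertices or faces", path)
  V <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3, byrow = TRUE)
  Fm <- matrix(as.integer(scan(text = gsub("/[0-9/]*", "",
                                           sub("^f ", "", fl)), quiet = TRUE)),
               ncol = 3, byrow = TRUE)
  surface_mesh(V, Fm, backend = "surface3d")
}

#' Write the trajectory time series as CSV
#'
#' Columns: time, total_energy, total_morphogen, max_curvature_excess,
#' max_area_drift, patch_count, dt, accepted (all recorded rows are accepted
#' steps; rejected attempts only adapt the step size).
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  s <- traj$series
  out <- data.frame(time = s$time, total_energy = s$total_energy,
                    total_morphogen = s$total_morphogen,
                    max_curvature_excess = s$max_curvature_excess,
                    max_area_drift = s$max_area_drift,
                    patch_count = s$patch_count, dt = s$dt, accepted = TRUE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write flat key-value configuration files
#'
#' The configuration format is flat `section.key = value` lines (`#`
#' comments allowed); sections mirror [simulation_config()] argument groups.
#' Unknown keys are errors, so typos cannot silently fall back to defaults.
#' Model parameters may be given either as the reduced triple
#' (`model.d_star`, ...) or as dimensional blocks (`mech.*`, `kin.*`), not
#' both.
#'
#' @param path configuration file path.
#' @return a [simulation_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) mm_format_error("config file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      mm_format_error("cannot parse config line: '%s'", ln)
    kv[[m[2]]] <- m[3]
  }
  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) mm_format_error("expected a number, got '%s'", x)
    v
  }
  cfg_args <- list()
  mech_args <- list(); kin_args <- list(); forcing_args <- list()
  scalar_map <- c(run.n = "n", run.radius = "radius", run.t_end = "t_end",
                  run.seed = "seed", run.output_every = "output_every",
                  run.dt_init = "dt_init", run.dt_min = "dt_min",
                  run.dt_max = "dt_max",
                  model.d_star = "d_star", model.p_star = "p_star",
                  model.m_star = "m_star", model.xi_star = "xi_star",
                  model.area_stiffness = "area_stiffness",
                  model.ref_offset = "ref_offset",
                  init.phi0_mean = "phi0_mean",
                  init.phi0_halfwidth = "phi0_halfwidth",
                  init.geometry_perturbation = "geometry_perturbation",
                  control.energy_increase_tol = "energy_increase_tol",
                  control.equilibrium_velocity_tol = "equilibrium_velocity_tol",
                  control.equilibrium_morphogen_tol = "equilibrium_morphogen_tol",
                  control.equilibrium_window = "equilibrium_window",
                  control.quality_min = "quality_min",
                  control.area_drift_tol = "area_drift_tol",
                  control.max_steps = "max_steps")
  for (key in names(kv)) {
    val <- kv[[key]]
    if (key == "run.backend") {
      cfg_args$backend <- val
    } else if (key == "run.snapshot_dir") {
      cfg_args$snapshot_dir <- val
    } else if (key %in% names(scalar_map)) {
      cfg_args[[scalar_map[[key]]]] <- num(val)
    } else if (grepl("^mech\\.", key)) {
      mech_args[[sub("^mech\\.", "", key)]] <- num(val)
    } else if (grepl("^kin\\.", key)) {
      kin_args[[sub("^kin\\.", "", key)]] <- num(val)
    } else if (key == "forcing.direction") {
      forcing_args$direction <- val
    } else if (grepl("^forcing\\.", key)) {
      nm <- sub("^forcing\\.", "", key)
      forcing_args[[nm]] <- if (nm == "center")
        num(strsplit(val, ",")[[1]][1]) else num(val)
    } else {
      mm_format_error("unknown config key '%s'", key)
    }
  }
  if (length(mech_args) || length(kin_args)) {
    if (!is.null(cfg_args$d_star) || !is.null(cfg_args$p_star) ||
        !is.null(cfg_args$m_star))
      mm_parameter_error("config mixes the reduced triple with dimensional mech/kin blocks")
    cfg_args$mech <- do.call(mechanical_params, mech_args)
    cfg_args$kin <- do.call(kinetic_params, kin_args)
  }
  if (length(forcing_args)) cfg_args$forcing <- do.call(forcing_spec, forcing_args)
  do.call(simulation_config, cfg_args)
}

#' @rdname read_config
#' @param config a [simulation_config()] to serialize.
#' @export
write_config <- function(config, path) {
  ln <- c(sprintf("run.backend = %s", config$backend),
          sprintf("run.n = %d", config$n),
          sprintf("run.radius = %.17g", config$radius),
          sprintf("run.t_end = %.17g", config$t_end),
          sprintf("run.seed = %d", config$seed),
          sprintf("run.output_every = %d", as.integer(config$output_every)),
          sprintf("run.dt_init = %.17g", config$dt_init),
          sprintf("run.dt_max = %.17g", config$dt_max))
  if (!is.null(config$d_star)) {
    ln <- c(ln, sprintf("model.d_star = %.17g", config$d_star),
            sprintf("model.p_star = %.17g", config$p_star),
            sprintf("model.m_star = %.17g", config$m_star),
            sprintf("model.xi_star = %.17g", config$xi_star),
            sprintf("model.area_stiffness = %.17g", config$area_stiffness),
            sprintf("model.ref_offset = %.17g", config$ref_offset))
  } else {
    m <- unlist(unclass(config$mech))
    k <- unlist(unclass(config$kin))
    k <- k[!is.na(k)]  # an unresolved curvature_ref is re-derived on read
    ln <- c(ln, sprintf("mech.%s = %.17g", names(m), m),
            sprintf("kin.%s = %.17g", names(k), k))
  }
  ln <- c(ln, sprintf("init.phi0_mean = %.17g", config$phi0_mean),
          sprintf("init.phi0_halfwidth = %.17g", config$phi0_halfwidth),
          sprintf("init.geometry_perturbation = %.17g", config$geometry_perturbation))
  if (!is.null(config$forcing)) {
    f <- config$forcing
    ln <- c(ln, sprintf("forcing.center = %.17g", f$center[1]),
            sprintf("forcing.angular_radius = %.17g", f$angular_radius),
            sprintf("forcing.magnitude = %.17g", f$magnitude),
            sprintf("forcing.direction = %s", f$direction),
            sprintf("forcing.t_on = %.17g", f$t_on),
            sprintf("forcing.t_off = %.17g", f$t_off))
  }
  writeLines(ln, path)
  invisible(path)
}
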