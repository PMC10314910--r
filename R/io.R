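## full-precision float formatting: 17 significant digits round-trips
## IEEE doubles bit-exactly through strtod
.fmt <- function(x) sprintf("%.17g", x)

#' Write / read a profile curve as CSV
#'
#' One row per s node with columns `s`, `rho`, `z`, `theta`, `C1`, `C2`,
#' `H`, `K`, written at full double precision; the Fourier description
#' (`theta0`, `Ls`, amplitudes) rides along in `#`-comment header lines so
#' the profile object itself round-trips.
#'
#' @param grid a [surface_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(grid, path) {
  stopifnot(inherits(grid, "surface_grid"))
  p <- grid$profile
  hdr <- c(sprintf("# theta0 %s", .fmt(p$theta0)),
           sprintf("# Ls %s", .fmt(p$Ls)),
           sprintf("# amplitudes %s", paste(.fmt(p$amplitudes),
                                            collapse = " ")))
  df <- data.frame(s = .fmt(grid$s), rho = .fmt(grid$rho), z = .fmt(grid$z),
                   theta = .fmt(grid$theta), C1 = .fmt(grid$C1),
                   C2 = .fmt(grid$C2), H = .fmt(grid$H), K = .fmt(grid$K))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(unname(df), sep = ",")), con)
  invisible(path)
}

#' @rdname write_profile_csv
#' @param n_phi azimuthal resolution of the reconstructed grid.
#' @return for the reader: a list with `profile` (a [shape_profile()]) and
#'   `table` (the numeric node table).
#' @export
read_profile_csv <- function(path, n_phi = 3L) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  gv <- function(key) {
    ln <- sub(paste0("^# ", key, " "), "",
              grep(paste0("^# ", key, " "), hdr, value = TRUE)[1L])
    as.numeric(strsplit(trimws(ln), " +")[[1L]])
  }
  profile <- shape_profile(gv("amplitudes"), Ls = gv("Ls"),
                           theta0 = gv("theta0"))
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  list(profile = profile, table = tab)
}

#' Write / read a nematic texture container
#'
#' Plain-text tab-separated container: `#`-comment attribute lines
#' (dimensions, arc-length and azimuth nodes) followed by the `q0` block
#' and the `qm` block, one grid row per line at full double precision, so
#' textures round-trip bit-exactly.
#'
#' @param texture a [nematic_texture()].
#' @param grid the [surface_grid()] it lives on.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_texture <- function(texture, grid, path) {
  stopifnot(inherits(texture, "nematic_texture"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dims %d %d", texture$n_s, texture$n_phi),
    sprintf("# s_nodes %s", paste(.fmt(grid$s), collapse = " ")),
    sprintf("# phi_nodes %s", paste(.fmt(grid$phi), collapse = " ")),
    "# block q0"), con)
  writeLines(apply(texture$q0, 1L, function(r)
    paste(.fmt(r), collapse = "\t")), con)
  writeLines("# block qm", con)
  writeLines(apply(texture$qm, 1L, function(r)
    paste(.fmt(r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_texture
#' @return for the reader: a list with `texture`, `s_nodes`, `phi_nodes`.
#' @export
read_texture <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(sub("^# dims ", "",
                                  lines[grepl("^# dims", lines)]), " ")[[1L]])
  s_nodes <- as.numeric(strsplit(sub("^# s_nodes ", "",
                                     lines[grepl("^# s_nodes", lines)]),
                                 " ")[[1L]])
  phi_nodes <- as.numeric(strsplit(sub("^# phi_nodes ", "",
                                       lines[grepl("^# phi_nodes", lines)]),
                                   " ")[[1L]])
  blk <- which(grepl("^# block", lines))
  parse_block <- function(from, n) {
    t(vapply(lines[from + seq_len(n)],
             function(l) as.numeric(strsplit(l, "\t")[[1L]]),
             numeric(dims[2L]), USE.NAMES = FALSE))
  }
  list(texture = nematic_texture(parse_block(blk[1L], dims[1L]),
                                 parse_block(blk[2L], dims[1L])),
       s_nodes = s_nodes, phi_nodes = phi_nodes)
}

#' Write a defect table as CSV
#'
#' @param defects a `defect_set` from [detect_defects()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_defects_csv <- function(defects, path) {
  stopifnot(inherits(defects, "defect_set"))
  utils::write.csv(as.data.frame(defects), path, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration (and model parameters) from YAML
#'
#' Reads a flat YAML mapping, validates it, and fills documented defaults
#' (test-preset discretization unless `preset: production`).  Recognized
#' keys: the [model_params()] arguments (`v`, `cp`, `ke`, `kappa`, `c0`,
#' `r_over_xi`, `ki`, `nematic`, `alpha`, `beta`, `extrinsic`) and the
#' [run_config()] arguments (`preset`, `n_s`, `n_phi`, `n_modes`,
#' `mc_sweeps`, `mc_sweeps_later`, `shape_passes`, `shape_maxit`,
#' `max_iter`, `tol`, `patience`, `seed`, `h_min`, `branch`).  Unknown
#' keys are rejected by name (typo safety), as are out-of-range values.
#'
#' @param path YAML file.
#' @return list with `params` ([model_params()]) and `config`
#'   ([run_config()]).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  par_keys <- c("v", "cp", "ke", "kappa", "c0", "r_over_xi", "ki",
                "nematic", "alpha", "beta", "extrinsic")
  cfg_keys <- c("preset", "n_s", "n_phi", "n_modes", "mc_sweeps",
                "mc_sweeps_later", "shape_passes", "shape_maxit",
                "max_iter", "tol", "patience", "seed", "h_min", "branch")
  unknown <- setdiff(names(raw), c(par_keys, cfg_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$v) && (raw$v <= 0 || raw$v > 1))
    stop("config key 'v': reduced volume must lie in (0, 1]")
  params <- model_params(
    v_target = raw$v %||% 0.4, Cp = raw$cp %||% 0,
    ke = raw$ke %||% (1 / 5), kappa = raw$kappa %||% (1 / 60),
    C0 = raw$c0 %||% 0, R_over_xi = raw$r_over_xi %||% 10,
    ki = raw$ki %||% 1, nematic = raw$nematic %||% TRUE,
    alpha = raw$alpha, beta = raw$beta,
    extrinsic = raw$extrinsic %||% FALSE)
  config <- run_config(
    preset = raw$preset %||% "test",
    n_s = raw$n_s, n_phi = raw$n_phi, n_modes = raw$n_modes,
    mc_sweeps = raw$mc_sweeps, mc_sweeps_later = raw$mc_sweeps_later,
    shape_passes = raw$shape_passes, shape_maxit = raw$shape_maxit,
    max_iter = raw$max_iter, tol = raw$tol %||% 1e-3,
    patience = raw$patience %||% 2L, seed = raw$seed %||% 1L,
    h_min = raw$h_min %||% 0, branch = raw$branch %||% "prolate")
  list(params = params, config = config)
}

#' Save a configuration back to YAML
#'
#' Writes the subset of keys [load_config()] understands; a saved and
#' re-loaded configuration reproduces the run bit-identically (same seed).
#'
#' @param params a [model_params()].
#' @param config a [run_config()].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, config, path) {
  yaml::write_yaml(list(
    v = params$v_target, cp = params$Cp, ke = params$ke,
    kappa = params$kappa, c0 = params$C0, r_over_xi = params$R_over_xi,
    ki = params$ki, nematic = params$alpha > 0,
    alpha = params$alpha, beta = params$beta, extrinsic = params$extrinsic,
    preset = config$preset, n_s = config$n_s, n_phi = config$n_phi,
    n_modes = config$n_modes, mc_sweeps = config$mc_sweeps,
    mc_sweeps_later = config$mc_sweeps_later,
    shape_passes = config$shape_passes, shape_maxit = config$shape_maxit,
    max_iter = config$max_iter, tol = config$tol,
    patience = config$patience, seed = config$seed, h_min = config$h_min,
    branch = config$branch), path, precision = 15)
  invisible(path)
}

#' Save / load a complete run archive
#'
#' A run archive is a directory holding the config snapshot
#' (`config.yaml`), the profile curve (`profile.csv`), the texture
#' container (`texture.tsv`), the defect table (`defects.csv`), the
#' energy report (`energy.json`), the iteration trace (`trace.csv`) and
#' the visualization mesh (`shape.vtk`).  Re-loading an archive and
#' recomputing the total free energy reproduces the stored value to
#' 1e-10 relative (everything is serialized at full double precision).
#'
#' @param run a `shell_run` from [alternate_minimize()].
#' @param dir archive directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_run <- function(run, dir) {
  stopifnot(inherits(run, "shell_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_config(run$params, run$config, file.path(dir, "config.yaml"))
  write_profile_csv(run$grid, file.path(dir, "profile.csv"))
  write_texture(run$texture, run$grid, file.path(dir, "texture.tsv"))
  if (!is.null(run$defects))
    write_defects_csv(run$defects, file.path(dir, "defects.csv"))
  jsonlite::write_json(
    list(Fb = run$energy$Fb, Fc = run$energy$Fc, Fi = run$energy$Fi,
         Fe = run$energy$Fe, Ftot = run$energy$Ftot,
         shape_class = run$shape_class$class,
         v = run$measures$reduced_volume, closure = run$measures$closure,
         height = run$measures$height, converged = run$converged,
         seed = run$config$seed, branch = run$config$branch),
    file.path(dir, "energy.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(iteration = seq_along(run$trace),
                              Ftot = .fmt(run$trace)),
                   file.path(dir, "trace.csv"), row.names = FALSE,
                   quote = FALSE)
  export_vtk(run$grid, run$texture, file.path(dir, "shape.vtk"),
             lambda0 = equilibrium_lambda(run$params))
  invisible(dir)
}

#' @rdname save_run
#' @return for the loader: list with `params`, `config`, `profile`,
#'   `grid`, `texture`, `energy` (stored values) -- sufficient to
#'   recompute every reported quantity.
#' @export
load_run <- function(dir) {
  cf <- load_config(file.path(dir, "config.yaml"))
  pr <- read_profile_csv(file.path(dir, "profile.csv"))
  tx <- read_texture(file.path(dir, "texture.tsv"))
  grid <- surface_grid(pr$profile, cf$config$n_s, cf$config$n_phi)
  energy <- jsonlite::read_json(file.path(dir, "energy.json"),
                                simplifyVector = TRUE)
  list(params = cf$params, config = cf$config, profile = pr$profile,
       grid = grid, texture = tx$texture, energy = energy)
}

#' Export the shell surface as legacy VTK PolyData
#'
#' Surface-of-revolution triangulation with per-vertex scalars
#' `lambda_rel` (\eqn{\lambda/\lambda_0}) and per-vertex 3D director
#' vectors (tangent plane, from the director angle), viewable in ParaView
#' or any VTK reader.  Pole rings are merged to single apex vertices.  A
#' non-closed profile is exported anyway with a warning comment in the
#' header.
#'
#' @param grid a [surface_grid()].
#' @param texture optional [nematic_texture()] for the point data.
#' @param path output `.vtk` file.
#' @param lambda0 normalization for the order-parameter scalar.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(grid, texture = NULL, path, lambda0 = 0.5) {
  stopifnot(inherits(grid, "surface_grid"))
  n_s <- grid$n_s; n_phi <- grid$n_phi
  closed <- abs(grid$rho[n_s]) < 1e-3
  inner <- 2:(n_s - 1L)

  # vertices: interior rings (n_s-2)*n_phi, then the two apexes
  px <- outer(grid$rho[inner], cos(grid$phi))
  py <- outer(grid$rho[inner], sin(grid$phi))
  pz <- matrix(grid$z[inner], length(inner), n_phi)
  pts <- cbind(as.vector(t(px)), as.vector(t(py)), as.vector(t(pz)))
  apex1 <- c(0, 0, grid$z[1L]); apex2 <- c(0, 0, grid$z[n_s])
  pts <- rbind(pts, apex1, apex2)
  n_ring <- length(inner)
  vid <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L

  tri <- list()
  for (i in seq_len(n_ring - 1L)) for (j in seq_len(n_phi)) {
    tri[[length(tri) + 1L]] <- c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
    tri[[length(tri) + 1L]] <- c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
  }
  a1 <- n_ring * n_phi + 1L; a2 <- n_ring * n_phi + 2L
  for (j in seq_len(n_phi)) {
    tri[[length(tri) + 1L]] <- c(a1, vid(1L, j + 1L), vid(1L, j))
    tri[[length(tri) + 1L]] <- c(a2, vid(n_ring, j), vid(n_ring, j + 1L))
  }
  tri <- do.call(rbind, tri) - 1L          # VTK is 0-based

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("nemshell surface",
                      if (!closed) "  WARNING: profile not closed" else ""),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(pts))), con)
  writeLines(apply(pts, 1L, function(r) paste(.fmt(r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tri), 4L * nrow(tri)), con)
  writeLines(apply(tri, 1L, function(r)
    paste(c(3L, r), collapse = " ")), con)

  if (!is.null(texture)) {
    od <- order_director(texture)
    lam_rel <- od$lambda[inner, , drop = FALSE] / max(lambda0, 1e-12)
    eta <- od$eta[inner, , drop = FALSE]
    eta[is.na(eta)] <- 0
    th <- matrix(grid$theta[inner], n_ring, n_phi)
    ph <- matrix(grid$phi, n_ring, n_phi, byrow = TRUE)
    # director = cos(eta) e1 + sin(eta) e2 in ambient coordinates
    e1x <- cos(th) * cos(ph); e1y <- cos(th) * sin(ph); e1z <- sin(th)
    dx <- cos(eta) * e1x - sin(eta) * sin(ph)
    dy <- cos(eta) * e1y + sin(eta) * cos(ph)
    dz <- cos(eta) * e1z
    flat <- function(m) as.vector(t(m))
    writeLines(c(sprintf("POINT_DATA %d", nrow(pts)),
                 "SCALARS lambda_rel double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(.fmt(c(flat(lam_rel), 0, 0)), con)
    writeLines("VECTORS director double", con)
    vecs <- cbind(c(flat(dx), 0, 0), c(flat(dy), 0, 0), c(flat(dz), 0, 0))
    writeLines(apply(vecs, 1L, function(r) paste(.fmt(r), collapse = " ")),
               con)
  }
  invisible(path)
}
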