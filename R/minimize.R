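## geometry + parameter lists handed to the compiled Monte Carlo core
.mc_geom <- function(grid, params) {
  inv_rho <- ifelse(grid$interior & abs(grid$rho) > 1e-10, 1 / grid$rho, 0)
  kg2 <- ifelse(is.na(grid$kg2), 0, grid$kg2)
  n <- grid$n_s
  # s-link areas (link i: rows i, i+1, 1-based): midpoint rho; links
  # touching a pole row are excluded, matching the R-side lattice energy
  As <- numeric(n - 1L)
  i <- 2:(n - 2L)
  As[i] <- grid$ds * grid$dphi * (grid$rho[i] + grid$rho[i + 1L]) / 2
  list(n_s = n, n_phi = grid$n_phi, ds = grid$ds,
       inv_rho = inv_rho, kg2 = kg2, H = grid$H, D = grid$D,
       W = grid$w_s * grid$J * grid$dphi, As = As,
       ext = if (isTRUE(params$extrinsic))
         params$ki * (grid$C1^2 + grid$C2^2) else numeric(n))
}

.mc_par <- function(params) {
  list(alpha = params$alpha, beta = params$beta, ki = params$ki,
       ke = params$ke, Cp = params$Cp,
       lam0 = equilibrium_lambda(params),
       lam_iso = params$lambda_iso, lam_blend = params$lambda_blend)
}

#' Texture-dependent part of the free energy (compiled path)
#'
#' \eqn{F_c + F_i + F_e} evaluated by the same compiled kernel that drives
#' the Monte Carlo updates; used internally and cross-checked against the
#' vectorized R densities in the test suite.
#'
#' @inheritParams total_free_energy
#' @return scalar energy (units of ki).
#' @export
texture_energy <- function(texture, grid, params) {
  cpp_texture_energy(texture$q0, texture$qm, .mc_geom(grid, params),
                     .mc_par(params))
}

#' Monte Carlo relaxation of the nematic texture on a fixed shape
#'
#' Annealed single-site Metropolis updates of \eqn{(q_0, q_m)} with
#' Gaussian proposals: the temperature starts at a value calibrated so the
#' initial acceptance is moderate (from the mean proposal energy change),
#' cools geometrically (factor `cool` per stage of `stage` sweeps), and the
#' final `quench_frac` of the sweeps run greedily at T = 0, so the energy
#' is non-increasing there.  The proposal width adapts between stages
#' toward a target acceptance; the amplitude cap \eqn{\lambda \le 1/2} is
#' enforced by rejection.  The whole trajectory is a deterministic
#' function of `seed`.
#'
#' @param texture starting [nematic_texture()].
#' @param grid fixed [surface_grid()].
#' @param params a [model_params()].
#' @param sweeps total number of lattice sweeps.
#' @param seed integer seed for the compiled RNG stream.
#' @param sigma initial Gaussian proposal width.
#' @param t_start starting temperature, or `"auto"` for calibration.
#' @param t_scale factor applied to the (calibrated) starting temperature;
#'   re-relaxations after small shape updates use a reduced reheat.
#' @param cool geometric cooling factor per stage.
#' @param stage sweeps per annealing stage (adaptation interval).
#' @param quench_frac fraction of `sweeps` run at T = 0 at the end.
#' @return list with `texture` (relaxed), `accept` (per-sweep acceptance),
#'   `energy` (per-sweep texture-energy trace), `sigma` (final width),
#'   `t_start` (temperature used), `energy_drift` (tracked vs recomputed).
#' @export
mc_relax_texture <- function(texture, grid, params, sweeps = 200L,
                             seed = 1L, sigma = 0.08, t_start = "auto",
                             t_scale = 1, cool = 0.9, stage = 10L,
                             quench_frac = 0.2) {
  stopifnot(inherits(texture, "nematic_texture"),
            inherits(grid, "surface_grid"))
  geom <- .mc_geom(grid, params)
  par <- .mc_par(params)

  n_quench <- max(1L, round(quench_frac * sweeps))
  n_anneal <- max(0L, sweeps - n_quench)

  if (identical(t_start, "auto")) {
    probe <- cpp_mc_run(texture$q0, texture$qm, geom, par,
                        temps = 1e300, sigma = sigma,
                        seed = as.double(seed) + 2^31)
    t_start <- max(probe$mean_abs_de[1], 1e-12)
  }
  t_start <- t_start * t_scale

  # Exact greedy line search over the global gauge rotation
  # (q0, qm) -> (q0 cos(chi) - qm sin(chi), q0 sin(chi) + qm cos(chi)):
  # the condensation and intrinsic terms are exactly invariant, so only
  # the deviatoric energy changes.  Single-site moves order this mode
  # logarithmically slowly (the deviatoric scale is far below the
  # condensation scale), while the line search equilibrates it exactly.
  gauge_polish <- function(q0, qm) {
    tx <- nematic_texture(q0, qm)
    fe <- function(chi) {
      txr <- nematic_texture(cos(chi) * q0 - sin(chi) * qm,
                             sin(chi) * q0 + cos(chi) * qm)
      integrate_field(grid, deviatoric_density(txr, grid, params))
    }
    chis <- seq(0, 2 * pi, length.out = 25L)[-25L]
    vals <- vapply(chis, fe, 0)
    best <- which.min(vals)
    if (vals[best] < vals[1L] - 1e-12) {
      opt <- stats::optimize(fe, chis[best] + c(-0.3, 0.3))
      chi <- if (opt$objective < vals[best]) opt$minimum else chis[best]
      list(q0 = cos(chi) * q0 - sin(chi) * qm,
           qm = sin(chi) * q0 + cos(chi) * qm)
    } else list(q0 = q0, qm = qm)
  }

  q0 <- texture$q0; qm <- texture$qm
  acc <- numeric(0); etr <- numeric(0)
  done <- 0L; k <- 0L
  while (done < n_anneal) {
    nsw <- min(stage, n_anneal - done)
    temps <- t_start * cool^k * rep(1, nsw)
    run <- cpp_mc_run(q0, qm, geom, par, temps = temps, sigma = sigma,
                      seed = as.double(seed) + done)
    q0 <- run$q0; qm <- run$qm
    acc <- c(acc, run$accept); etr <- c(etr, run$energy)
    a_bar <- mean(run$accept)
    if (a_bar < 0.2) sigma <- max(sigma * 0.7, 1e-3)
    if (a_bar > 0.6) sigma <- min(sigma * 1.3, 0.25)
    gp <- gauge_polish(q0, qm)
    q0 <- gp$q0; qm <- gp$qm
    done <- done + nsw; k <- k + 1L
  }
  run <- cpp_mc_run(q0, qm, geom, par, temps = rep(0, n_quench),
                    sigma = sigma, seed = as.double(seed) + n_anneal + 1)
  gp <- gauge_polish(run$q0, run$qm)
  if (!identical(gp$q0, run$q0)) {
    run2 <- cpp_mc_run(gp$q0, gp$qm, geom, par,
                       temps = rep(0, max(10L, n_quench %/% 4L)),
                       sigma = sigma, seed = as.double(seed) + n_anneal + 2)
    run <- run2
  }
  acc <- c(acc, run$accept); etr <- c(etr, run$energy)

  a_all <- mean(acc[seq_len(max(1L, n_anneal))])
  if (n_anneal > 0L && (a_all < 0.05 || a_all > 0.95))
    warning(sprintf("MC acceptance %.2f outside [0.05, 0.95] after adaptation",
                    a_all))

  list(texture = nematic_texture(run$q0, run$qm),
       accept = acc, energy = etr, sigma = sigma, t_start = t_start,
       energy_drift = abs(run$energy_tracked - run$energy_final))
}

## objective for the shape step: texture held fixed on grid indices,
## area normalized exactly, volume/closure/self-intersection/height by
## quadratic penalty
.shape_objective <- function(amplitudes, texture, params, n_s, n_phi,
                             v_target, weights, h_min) {
  p <- tryCatch(
    normalize_area(shape_profile(amplitudes, Ls = pi), n_s = n_s),
    error = function(e) NULL)
  if (is.null(p)) return(1e10)
  g <- tryCatch(surface_grid(p, n_s, n_phi), error = function(e) NULL)
  if (is.null(g)) return(1e10)
  m <- surface_measures(g)
  # self-intersecting trials (rho < 0) carry a negative area element that
  # would make positive densities lower the integral without bound; they
  # are rejected outright, with a slope guiding the optimizer back
  viol <- sum(pmin(g$rho + 1e-4, 0)^2)
  if (viol > 0) return(1e5 * (1 + 1e4 * viol))
  e <- tryCatch(total_free_energy(texture, g, params)$Ftot,
                error = function(e) NULL)
  if (is.null(e) || !is.finite(e)) return(1e10)
  pen <- weights$closure * m$closure^2 +
    weights$volume * (m$reduced_volume - v_target)^2 +
    weights$rho_neg * sum(pmin(g$rho, 0)^2) * g$ds
  if (h_min > 0) pen <- pen + weights$height * max(0, h_min - m$height)^2
  e + pen
}

#' Constrained shape optimization at fixed texture
#'
#' Minimizes the total free energy over the Fourier amplitudes with the
#' texture held fixed on the \eqn{(s/L_s, \varphi)} grid.  The surface
#' area is enforced exactly by rescaling every trial profile to
#' \eqn{A = 4\pi} (which also removes \eqn{L_s} as an independent degree
#' of freedom); the closure \eqn{\rho(L_s)=0}, the reduced-volume target,
#' the \eqn{\rho \ge 0} barrier and the optional minimal pole-to-pole
#' height `h_min` (the stretching-force constraint) are quadratic
#' penalties whose weights escalate over the optimization passes.
#' Derivative-free Nelder-Mead is applied to blocks of amplitudes from
#' low to high frequency (the objective is noisy through the MC-relaxed
#' texture, so gradients are unreliable); a block move is kept only if it
#' lowered the penalized objective.
#'
#' @param profile starting [shape_profile()] (area-normalized internally).
#' @param texture fixed [nematic_texture()] on the `n_s x n_phi` grid.
#' @param params a [model_params()].
#' @param n_s,n_phi grid resolution used for energies and constraints.
#' @param h_min minimal pole-to-pole height (0 disables the constraint).
#' @param passes number of escalation passes over all blocks.
#' @param block_size amplitudes per Nelder-Mead block.
#' @param maxit Nelder-Mead iteration cap per block.
#' @param weights list of penalty weights (`closure`, `volume`,
#'   `rho_neg`, `height`); escalated tenfold per pass.
#' @param step initial simplex scale for block moves.
#' @return list with `profile` (optimized, area-normalized), `objective`,
#'   `measures`, `converged` flag.
#' @export
optimize_shape <- function(profile, texture, params, n_s = 41L, n_phi = 41L,
                           h_min = 0, passes = 2L, block_size = 10L,
                           maxit = 150L,
                           weights = list(closure = 1e4, volume = 1e4,
                                          rho_neg = 1e4, height = 1e3),
                           step = 0.05) {
  stopifnot(inherits(profile, "shape_profile"))
  a <- profile$amplitudes
  N <- length(a)
  blocks <- split(seq_len(N), ceiling(seq_len(N) / block_size))
  w <- weights
  for (pass in seq_len(passes)) {
    for (blk in blocks) {
      obj_blk <- function(x) {
        aa <- a; aa[blk] <- x
        .shape_objective(aa, texture, params, n_s, n_phi,
                         params$v_target, w, h_min)
      }
      f0 <- obj_blk(a[blk])
      opt <- stats::optim(a[blk], obj_blk, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-10,
                                         ndeps = rep(step, length(blk)),
                                         parscale = rep(step, length(blk))))
      if (opt$value < f0) a[blk] <- opt$par
    }
    w <- lapply(w, `*`, 10)
  }
  p <- normalize_area(shape_profile(a, Ls = pi), n_s = n_s)
  g <- surface_grid(p, n_s, n_phi)
  m <- surface_measures(g)
  list(profile = p, objective =
         .shape_objective(a, texture, params, n_s, n_phi,
                          params$v_target, w, h_min),
       measures = m,
       converged = abs(m$reduced_volume - params$v_target) < 1e-3 &&
         abs(m$closure) < 1e-3)
}

#' Run configuration for the alternating minimization
#'
#' Collects the discretization and schedule knobs of a full equilibrium
#' search.  The production preset mirrors the model's reference
#' discretization (101 x 101 grid, 80 Fourier modes); the `"test"` preset
#' scales everything down for desk-scale runs.
#'
#' @param preset `"production"` or `"test"`.
#' @param n_s,n_phi grid dimensions (>= 11, `n_s` odd).
#' @param n_modes number of Fourier amplitudes.
#' @param mc_sweeps sweeps for the first (annealed) texture relaxation.
#' @param mc_sweeps_later sweeps for subsequent relaxations (reheated to a
#'   fraction of the calibrated starting temperature).
#' @param shape_passes escalation passes inside each shape step.
#' @param shape_maxit Nelder-Mead cap per amplitude block.
#' @param max_iter maximal number of texture/shape alternations.
#' @param tol absolute convergence tolerance on Ftot between alternations.
#' @param patience alternations the tolerance must hold before stopping.
#' @param seed integer seed driving every stochastic element of the run.
#' @param h_min minimal pole-to-pole height (stretching-force constraint).
#' @param branch initial-condition branch tag: `"oblate"`, `"prolate"`,
#'   `"stomatocyte"`, `"sphere"`, `"dumbbell"` or `"custom"`.
#' @param profile starting profile when `branch = "custom"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = c("test", "production"),
                       n_s = NULL, n_phi = NULL, n_modes = NULL,
                       mc_sweeps = NULL, mc_sweeps_later = NULL,
                       shape_passes = NULL, shape_maxit = NULL,
                       max_iter = NULL, tol = 1e-3, patience = 2L,
                       seed = 1L, h_min = 0,
                       branch = "prolate", profile = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "production")
    list(n_s = 101L, n_phi = 101L, n_modes = 80L, mc_sweeps = 400L,
         mc_sweeps_later = 120L, shape_passes = 2L, shape_maxit = 200L,
         max_iter = 12L)
  else
    list(n_s = 41L, n_phi = 41L, n_modes = 16L, mc_sweeps = 150L,
         mc_sweeps_later = 60L, shape_passes = 2L, shape_maxit = 120L,
         max_iter = 6L)
  cfg <- list(
    preset = preset,
    n_s = as.integer(n_s %||% def$n_s),
    n_phi = as.integer(n_phi %||% def$n_phi),
    n_modes = as.integer(n_modes %||% def$n_modes),
    mc_sweeps = as.integer(mc_sweeps %||% def$mc_sweeps),
    mc_sweeps_later = as.integer(mc_sweeps_later %||% def$mc_sweeps_later),
    shape_passes = as.integer(shape_passes %||% def$shape_passes),
    shape_maxit = as.integer(shape_maxit %||% def$shape_maxit),
    max_iter = as.integer(max_iter %||% def$max_iter),
    tol = tol, patience = as.integer(patience),
    seed = as.integer(seed), h_min = h_min,
    branch = branch, profile = profile)
  if (cfg$n_s < 11L || cfg$n_phi < 11L) stop("grid dimensions must be >= 11")
  if (cfg$n_s %% 2L == 0L) stop("n_s must be odd")
  if (cfg$h_min < 0) stop("h_min must be >= 0")
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Alternating minimization of texture and shape
#'
#' The equilibrium search: starting from a seed shape for the requested
#' branch and a random texture, alternate (i) Monte Carlo relaxation of
#' the texture on the current shape and (ii) constrained optimization of
#' the Fourier amplitudes at the current texture, until the total free
#' energy changes by less than `tol` over `patience` consecutive
#' alternations.  The result records the final state, energy breakdown,
#' detected defects, shape class and convergence trace.
#'
#' @param config a [run_config()].
#' @param params a [model_params()].
#' @return object of class `shell_run`: list with `profile`, `texture`,
#'   `grid`, `energy` ([total_free_energy()] breakdown), `defects`,
#'   `shape_class`, `measures`, `trace` (per-alternation Ftot),
#'   `converged`, `config`, `params`.
#' @export
alternate_minimize <- function(config, params) {
  stopifnot(inherits(config, "run_config"), inherits(params, "model_params"))
  profile <- config$profile %||%
    seed_profile(config$branch, v_target = params$v_target,
                 n_modes = config$n_modes, n_s = config$n_s)
  profile <- normalize_area(profile, n_s = config$n_s)
  grid <- surface_grid(profile, config$n_s, config$n_phi)
  lam0 <- equilibrium_lambda(params)
  texture <- if (lam0 > 0)
    random_texture(grid, amplitude = 0.9 * lam0, seed = config$seed)
  else
    nematic_texture(matrix(0, config$n_s, config$n_phi),
                    matrix(0, config$n_s, config$n_phi))

  trace <- numeric(0)
  best <- Inf; stall <- 0L; converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    sweeps <- if (it == 1L) config$mc_sweeps else config$mc_sweeps_later
    # in the isotropic phase (alpha < 0) the texture relaxes to zero:
    # greedy sweeps only, no annealing noise
    rel <- if (lam0 > 0)
      mc_relax_texture(texture, grid, params, sweeps = sweeps,
                       seed = config$seed + 1000L * it,
                       t_scale = 1)
    else
      mc_relax_texture(texture, grid, params,
                       sweeps = max(10L, sweeps %/% 10L),
                       seed = config$seed + 1000L * it,
                       t_start = 0, quench_frac = 1)
    texture <- rel$texture
    opt <- optimize_shape(profile, texture, params,
                          n_s = config$n_s, n_phi = config$n_phi,
                          h_min = config$h_min,
                          passes = config$shape_passes,
                          maxit = config$shape_maxit)
    profile <- opt$profile
    grid <- surface_grid(profile, config$n_s, config$n_phi)
    f <- total_free_energy(texture, grid, params)$Ftot
    trace <- c(trace, f)
    if (abs(best - f) < config$tol) stall <- stall + 1L else stall <- 0L
    best <- min(best, f)
    if (stall >= config$patience) { converged <- TRUE; break }
  }
  # final greedy polish of the texture on the final shape
  rel <- mc_relax_texture(texture, grid, params,
                          sweeps = max(20L, config$mc_sweeps_later),
                          seed = config$seed + 999L,
                          t_start = 0, quench_frac = 1)
  texture <- rel$texture
  energy <- total_free_energy(texture, grid, params)
  defects <- if (lam0 > 0)
    tryCatch(detect_defects(texture, grid, lambda0 = lam0),
             warning = function(w) suppressWarnings(
               detect_defects(texture, grid, lambda0 = lam0)))
  else NULL

  structure(list(
    profile = profile, texture = texture, grid = grid,
    energy = energy, defects = defects,
    shape_class = classify_shape(profile, n_s = config$n_s),
    measures = surface_measures(grid),
    trace = trace, converged = converged,
    config = config, params = params),
    class = "shell_run")
}

#' @export
print.shell_run <- function(x, ...) {
  cat(sprintf("shell_run [%s seed]: class = %s, converged = %s\n",
              x$config$branch, x$shape_class$class, x$converged))
  cat(sprintf("  Ftot = %.6g (Fb %.4g, Fc %.4g, Fi %.4g, Fe %.4g)\n",
              x$energy$Ftot, x$energy$Fb, x$energy$Fc, x$energy$Fi,
              x$energy$Fe))
  cat(sprintf("  v = %.4f (target %.4f), closure = %.2g, defects: %s\n",
              x$measures$reduced_volume, x$params$v_target,
              x$measures$closure,
              if (is.null(x$defects)) "isotropic phase" else
                paste0(nrow(x$defects), " (total m = ",
                       sum(x$defects$m), ")")))
  invisible(x)
}

#' Classify the shape of a closed profile
#'
#' Deterministic rules on the profile curve, mirroring the standard
#' vesicle shape classes: `stomatocyte` when the tangent angle exceeds
#' \eqn{\pi} in the interior with an inward fold (non-monotone z, i.e. an
#' invagination); otherwise `oblate` when the equatorial radius exceeds
#' the pole-to-pole half-height; otherwise the prolate family, sub-labeled
#' `phi_shape` when the radius has two interior necks flanking a wider
#' central bulge, `necklace` when it has interior necks in any other
#' arrangement, and `prolate` when it has none.  Profiles with reduced
#' volume above 0.99 are labeled `sphere`.  Borderline calls within 5%
#' of a rule boundary carry `confident = FALSE`.
#'
#' @param profile a [shape_profile()].
#' @param n_s grid resolution for the rule evaluation.
#' @param neck_frac a neck is an interior minimum of \eqn{\rho} below this
#'   fraction of the maximal radius.
#' @return list with `class`, `confident`, `necks`, `v`.
#' @export
classify_shape <- function(profile, n_s = 101L, neck_frac = 0.6) {
  g <- surface_grid(profile, n_s, 3L)
  m <- surface_measures(g)
  v <- m$reduced_volume
  conf <- TRUE
  if (v > 0.99)
    return(list(class = "sphere", confident = TRUE, necks = 0L, v = v))

  # an invagination is a fold (theta beyond pi) that re-opens inside: rho
  # grows again after the neck (inner cap wider than the neck).  Biconcave
  # discocytes also carry theta > pi at their pole dimples, but there rho
  # shrinks monotonically to the pole, so they are not caught here.
  fold <- which(g$theta > pi + 0.05)
  if (length(fold) > 0L) {
    i_fold <- fold[1L]
    r_max <- max(g$rho)
    # neck: first local minimum of rho after the fold that is not a pole
    tail_rho <- g$rho[i_fold:n_s]
    j <- which(diff(tail_rho) > 0)[1L]
    if (!is.na(j) && tail_rho[j] > 0.05 * r_max) {
      reexp <- max(tail_rho[j:length(tail_rho)]) - tail_rho[j]
      if (reexp > 0.04 * r_max) {
        conf <- reexp > 0.10 * r_max && max(g$theta) > pi + 0.15
        return(list(class = "stomatocyte", confident = conf,
                    necks = 0L, v = v))
      }
    }
  }

  r_eq <- max(g$rho)
  half_h <- m$height / 2
  if (r_eq > half_h) {
    conf <- r_eq > 1.05 * half_h
    return(list(class = "oblate", confident = conf, necks = 0L, v = v))
  }

  # interior necks: prominence-filtered local minima of rho below
  # neck_frac * max(rho).  Minima in the same basin (no intermediate rise
  # of at least `prom`) are merged, so Fourier ringing along a thin tube
  # does not masquerade as extra necks.
  rho <- g$rho
  prom <- 0.10 * r_eq
  i <- 3:(n_s - 2L)
  is_min <- rho[i] < rho[i - 1L] & rho[i] <= rho[i + 1L] &
    rho[i] < neck_frac * r_eq & rho[i] > 1e-6
  cands <- i[is_min][order(rho[i[is_min]])]
  necks_idx <- integer(0)
  for (c_idx in cands) {
    separated <- vapply(necks_idx, function(a) {
      rng <- if (a < c_idx) a:c_idx else c_idx:a
      max(rho[rng]) >= max(rho[c_idx], rho[a]) + prom
    }, TRUE)
    if (all(separated)) necks_idx <- c(necks_idx, c_idx)
  }
  necks_idx <- sort(necks_idx)
  n_neck <- length(necks_idx)
  cls <- if (n_neck == 0L) "prolate"
  else if (n_neck == 2L) {
    mid <- max(rho[necks_idx[1L]:necks_idx[2L]])
    outer_max <- max(rho[2:necks_idx[1L]], rho[necks_idx[2L]:(n_s - 1L)])
    if (mid > 1.2 * outer_max) "phi_shape" else "necklace"
  } else "necklace"
  conf <- if (cls == "prolate") half_h > 1.05 * r_eq else TRUE
  list(class = cls, confident = conf, necks = n_neck, v = v)
}

#' Select the equilibrium branch among multi-start results
#'
#' Implements the multi-initial-condition protocol: candidate equilibria
#' from different seed branches are compared by total free energy; the
#' minimum is the equilibrium, and a runner-up within `tol_rel * |Ftot|`
#' marks coexistence -- the signature of a discontinuous (first-order)
#' morphological transition.
#'
#' @param results list of `shell_run` objects sharing parameters.
#' @param tol_rel relative energy tolerance declaring a tie.
#' @return list with `best` (the winning run), `margin` (energy gap to the
#'   runner-up; `Inf` for a single candidate), `coexistence` flag, and a
#'   `ranking` data frame (branch, class, Ftot).
#' @export
branch_compare <- function(results, tol_rel = 1e-3) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "shell_run")))
  key <- function(r) {
    p <- r$params
    paste(p$kappa, p$C0, p$alpha, p$beta, p$ki, p$ke, p$Cp, p$v_target)
  }
  if (length(unique(vapply(results, key, ""))) != 1L)
    stop("cannot compare runs with different model parameters")
  f <- vapply(results, function(r) r$energy$Ftot, 0)
  ord <- order(f)
  margin <- if (length(f) > 1L) f[ord[2L]] - f[ord[1L]] else Inf
  list(best = results[[ord[1L]]],
       margin = margin,
       coexistence = is.finite(margin) &&
         margin < tol_rel * max(1, abs(f[ord[1L]])),
       ranking = data.frame(
         branch = vapply(results, function(r) r$config$branch, ""),
         class = vapply(results, function(r) r$shape_class$class, ""),
         Ftot = f)[ord, ])
}
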