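#' Synthetic texture with prescribed defects
#'
#' Builds a nematic texture whose director field carries topological
#' defects of prescribed winding numbers at prescribed positions, for
#' testing detection and energy code.  The construction maps the surface
#' to the complex plane through the reference colatitude
#' \eqn{u = \pi s/L_s} and the stereographic coordinate
#' \eqn{\zeta = \tan(u/2) e^{i\varphi}}, places each defect's phase field
#' \eqn{m_k \arg(\zeta - \zeta_k)} there, and converts the chart angle to
#' the director angle relative to the meridian frame (which itself winds
#' once around each pole).  Charges must sum to 2 on a closed shell of
#' spherical topology; defects requested at the far pole (\eqn{s = L_s})
#' are realized automatically by the residual winding of the chart and are
#' therefore excluded from the explicit sum.
#'
#' The amplitude is `lambda_bg` away from the cores and rises from zero
#' over a core radius of `core_cells` grid cells (tanh profile).
#'
#' @param grid a [surface_grid()].
#' @param defects data frame with columns `s`, `phi`, `m` (winding numbers,
#'   multiples of 1/2, summing to 2).
#' @param lambda_bg background ordering amplitude in (0, 1/2].
#' @param core_cells core radius in units of the s grid spacing.
#' @param eta_offset constant added to the director angle (gauge freedom).
#' @return a [nematic_texture()].
#' @export
defect_texture <- function(grid, defects, lambda_bg = 0.5, core_cells = 2,
                           eta_offset = 0) {
  stopifnot(inherits(grid, "surface_grid"),
            all(c("s", "phi", "m") %in% names(defects)))
  if (abs(sum(defects$m) - 2) > 1e-9)
    stop("topology error: defect charges must sum to 2 on a closed shell")
  if (any(abs(defects$m * 2 - round(defects$m * 2)) > 1e-9))
    stop("winding numbers must be multiples of 1/2")
  if (lambda_bg <= 0 || lambda_bg > 0.5)
    stop("lambda_bg must lie in (0, 1/2]")

  n_s <- grid$n_s; n_phi <- grid$n_phi
  u <- pmin(pi * grid$s / grid$Ls, pi - 1e-8)
  zeta <- outer(tan(u / 2), exp(1i * grid$phi))

  at_far_pole <- defects$s > grid$Ls * (1 - 1e-6)
  psi <- matrix(0, n_s, n_phi)
  for (k in which(!at_far_pole)) {
    uk <- pi * defects$s[k] / grid$Ls
    zk <- tan(uk / 2) * exp(1i * defects$phi[k])
    psi <- psi + defects$m[k] * Arg(zeta - zk)
  }
  eta <- psi - matrix(grid$phi, n_s, n_phi, byrow = TRUE) + eta_offset

  # amplitude suppression near every core (including far-pole defects);
  # quadratic-in-distance tanh core, ~zero within the innermost cell and
  # back to background beyond ~2 core radii
  xyz <- function(s_val, phi_val) {
    rr <- stats::approx(grid$s, grid$rho, xout = s_val)$y
    zz <- stats::approx(grid$s, grid$z, xout = s_val)$y
    c(rr * cos(phi_val), rr * sin(phi_val), zz)
  }
  px <- outer(grid$rho, cos(grid$phi))
  py <- outer(grid$rho, sin(grid$phi))
  pz <- matrix(grid$z, n_s, n_phi)
  lam <- matrix(lambda_bg, n_s, n_phi)
  r_core <- core_cells * grid$ds
  for (k in seq_len(nrow(defects))) {
    ck <- xyz(defects$s[k], defects$phi[k])
    d <- sqrt((px - ck[1])^2 + (py - ck[2])^2 + (pz - ck[3])^2)
    lam <- lam * tanh((d / r_core)^2)
  }
  nematic_texture(lam * cos(2 * eta), lam * sin(2 * eta))
}

#' Random isotropic-phase texture
#'
#' Independent uniform draws of \eqn{(q_0, q_m)} in the disc of radius
#' `amplitude`, the standard disordered start for Monte Carlo relaxation.
#'
#' @param grid a [surface_grid()].
#' @param amplitude maximal ordering amplitude, at most 1/2.
#' @param seed optional integer seed (uses and restores the R RNG stream).
#' @return a [nematic_texture()].
#' @export
random_texture <- function(grid, amplitude = 0.25, seed = NULL) {
  stopifnot(amplitude <= 0.5, amplitude >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  n <- grid$n_s * grid$n_phi
  r <- amplitude * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  nematic_texture(matrix(r * cos(a), grid$n_s, grid$n_phi),
                  matrix(r * sin(a), grid$n_s, grid$n_phi))
}
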