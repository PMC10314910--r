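#' Shape profile of an axisymmetric closed shell
#'
#' A closed, axially symmetric surface is generated by rotating a profile
#' curve around the z axis.  The curve is described by the angle
#' \eqn{\theta(s)} between its tangent and the plane perpendicular to the
#' rotation axis, expanded as
#' \deqn{\theta(s) = \theta_0 s/L_s + \sum_{i=1}^N a_i \sin(\pi i s/L_s),}
#' where \eqn{s \in [0, L_s]} is the arc length of the profile curve.  For a
#' smooth closed surface of spherical topology \eqn{\theta(0)=0} and
#' \eqn{\theta(L_s)=\theta_0=\pi} hold identically by construction; the
#' closure condition \eqn{\rho(L_s)=0} is a separate constraint (see
#' [closure_residual()]).  All lengths are measured in units of
#' \eqn{R=\sqrt{A/4\pi}}.
#'
#' @param amplitudes numeric vector of Fourier amplitudes \eqn{a_1..a_N}
#'   (dimensionless).
#' @param Ls length of the profile curve (units of R), positive.
#' @param theta0 tangent angle at the end of the curve; \eqn{\pi} for closed
#'   smooth shells.
#' @return An object of class `shape_profile` with fields `amplitudes`,
#'   `Ls`, `theta0` and `N`.
#' @examples
#' p <- shape_profile(numeric(20), Ls = pi)   # the unit sphere
#' eval_theta(p, pi / 2)$theta                # pi/2
#' @export
shape_profile <- function(amplitudes, Ls, theta0 = pi) {
  stopifnot(is.numeric(amplitudes), is.numeric(Ls), length(Ls) == 1L)
  if (!is.finite(Ls) || Ls <= 0) stop("Ls must be positive and finite")
  if (any(!is.finite(amplitudes))) stop("non-finite Fourier amplitude")
  structure(
    list(amplitudes = as.numeric(amplitudes), Ls = as.numeric(Ls),
         theta0 = as.numeric(theta0), N = length(amplitudes)),
    class = "shape_profile")
}

#' @export
print.shape_profile <- function(x, ...) {
  cat(sprintf("shape_profile: N = %d modes, Ls = %.6g, theta0 = %.6g\n",
              x$N, x$Ls, x$theta0))
  cat(sprintf("  max |a_i| = %.4g, closure residual (n_s = 201) = %.3g\n",
              if (x$N) max(abs(x$amplitudes)) else 0,
              closure_residual(x, n_s = 201L)))
  invisible(x)
}

#' Evaluate the tangent angle and its derivative
#'
#' Evaluates \eqn{\theta(s)} and the analytic derivative
#' \eqn{d\theta/ds} (term-by-term differentiation of the Fourier series) at
#' arbitrary arc-length positions.  The derivative is never obtained by
#' finite differences: \eqn{C_1 = d\theta/ds} is one of the principal
#' curvatures and is kept free of discretization error.
#'
#' @param profile a [shape_profile()].
#' @param s numeric vector of arc-length positions, all within `[0, Ls]`.
#' @return list with components `theta` and `dtheta`.
#' @export
eval_theta <- function(profile, s) {
  stopifnot(inherits(profile, "shape_profile"))
  Ls <- profile$Ls
  if (any(s < -1e-12 * Ls | s > Ls * (1 + 1e-12)))
    stop("arc-length positions outside [0, Ls]")
  s <- pmin(pmax(s, 0), Ls)
  th <- profile$theta0 * s / Ls
  dth <- rep(profile$theta0 / Ls, length(s))
  N <- profile$N
  if (N > 0L) {
    k <- pi * seq_len(N) / Ls              # mode wavenumbers
    arg <- outer(s, k)                     # length(s) x N
    th <- th + drop(sin(arg) %*% profile$amplitudes)
    dth <- dth + drop(cos(arg) %*% (profile$amplitudes * k))
  }
  list(theta = th, dtheta = dth)
}

## 4-point Gauss-Legendre nodes/weights on [0,1]
.gl4 <- local({
  x <- c(-0.861136311594053, -0.339981043584856,
         0.339981043584856, 0.861136311594053)
  w <- c(0.347854845137454, 0.652145154862546,
         0.652145154862546, 0.347854845137454)
  list(x = (x + 1) / 2, w = w / 2)
})

## Cumulative integrals of cos(theta) and sin(theta) on the uniform s grid.
## theta is analytic, so each interval is integrated with 4-point
## Gauss-Legendre; values at the grid nodes are then exact to ~1e-12 for
## smooth profiles, which keeps the closure constraint free of quadrature
## noise.
.integrate_profile_curve <- function(profile, s_nodes) {
  n <- length(s_nodes)
  h <- s_nodes[2L] - s_nodes[1L]
  mid <- rep(s_nodes[-n], each = 4L) + h * rep(.gl4$x, times = n - 1L)
  th <- eval_theta(profile, mid)$theta
  wt <- h * rep(.gl4$w, times = n - 1L)
  dcos <- colSums(matrix(cos(th) * wt, nrow = 4L))
  dsin <- colSums(matrix(sin(th) * wt, nrow = 4L))
  list(rho = c(0, cumsum(dcos)), z = c(0, cumsum(dsin)))
}

#' Discretized surface of revolution
#'
#' Builds the discretized geometry of the surface generated by a shape
#' profile: profile-curve coordinates \eqn{\rho(s), z(s)} (by quadrature of
#' \eqn{\cos\theta, \sin\theta}), principal curvatures
#' \eqn{C_1 = d\theta/ds} and \eqn{C_2 = \sin\theta/\rho}, mean curvature
#' \eqn{H=(C_1+C_2)/2}, Gaussian curvature \eqn{K=C_1 C_2}, curvature
#' deviator \eqn{D=(C_1-C_2)/2}, geodesic curvature of the parallels
#' \eqn{\kappa_{g2} = \cos\theta/\rho}, and the Jacobian \eqn{J=\rho}
#' (arc-length parameterization, so the first fundamental form has
#' \eqn{E=\rho^2}, \eqn{F=0}, \eqn{G=1}).
#'
#' Both ends of the s grid are pole nodes.  At the poles \eqn{C_2} is
#' assigned its limit \eqn{C_1} (umbilic pole of a smooth axisymmetric
#' surface) and \eqn{\kappa_{g2}}, which diverges, is set to `NA`; pole
#' rings never enter \eqn{\kappa_{g2}}-weighted integrands because the area
#' element \eqn{J=\rho} vanishes there.
#'
#' @param profile a [shape_profile()].
#' @param n_s number of arc-length nodes (odd, >= 3; Simpson weights are
#'   attached to the grid).
#' @param n_phi number of azimuthal nodes covering \eqn{[0, 2\pi)} without
#'   repetition of the seam.
#' @return An object of class `surface_grid`: list with fields `s`, `phi`,
#'   `rho`, `z`, `theta`, `C1`, `C2`, `H`, `K`, `D`, `kg2`, `J`, `ds`,
#'   `dphi`, `w_s` (Simpson weights including `ds`), `interior` (logical,
#'   rows that are not poles), `rho_negative` (self-intersection flag),
#'   `Ls`, `n_s`, `n_phi`.
#' @export
surface_grid <- function(profile, n_s = 101L, n_phi = 101L) {
  stopifnot(inherits(profile, "shape_profile"))
  n_s <- as.integer(n_s); n_phi <- as.integer(n_phi)
  if (n_s < 3L) stop("n_s must be at least 3")
  if (n_s %% 2L == 0L) stop("n_s must be odd (composite Simpson weights)")
  if (n_phi < 3L) stop("n_phi must be at least 3")
  Ls <- profile$Ls
  s <- seq(0, Ls, length.out = n_s)
  ev <- eval_theta(profile, s)
  cur <- .integrate_profile_curve(profile, s)
  rho <- cur$rho; z <- cur$z
  theta <- ev$theta
  C1 <- ev$dtheta
  interior <- rep(TRUE, n_s); interior[c(1L, n_s)] <- FALSE

  rho_negative <- any(rho[interior] < -1e-12)
  tiny <- 1e-10
  if (any(abs(rho[interior]) < tiny & abs(sin(theta[interior])) > 1e-6))
    stop("degenerate shape: rho = 0 at a non-pole node")

  C2 <- numeric(n_s)
  safe <- interior & abs(rho) >= tiny
  C2[safe] <- sin(theta[safe]) / rho[safe]
  C2[!safe] <- C1[!safe]          # umbilic pole limit (and pinched nodes)

  kg2 <- rep(NA_real_, n_s)
  kg2[safe] <- cos(theta[safe]) / rho[safe]

  ds <- s[2L] - s[1L]
  w <- rep(c(2, 4), length.out = n_s); w[1L] <- 1; w[n_s] <- 1
  w_s <- w * ds / 3

  structure(list(
    s = s, phi = seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)],
    rho = rho, z = z, theta = theta,
    C1 = C1, C2 = C2, H = (C1 + C2) / 2, K = C1 * C2, D = (C1 - C2) / 2,
    kg2 = kg2, J = rho, ds = ds, dphi = 2 * pi / n_phi, w_s = w_s,
    interior = interior, rho_negative = rho_negative,
    Ls = Ls, n_s = n_s, n_phi = n_phi, profile = profile),
    class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  m <- surface_measures(x)
  cat(sprintf("surface_grid: %d x %d (s x phi), Ls = %.6g\n",
              x$n_s, x$n_phi, x$Ls))
  cat(sprintf("  area = %.6g (4pi = %.6g), volume = %.6g, v = %.6g\n",
              m$area, 4 * pi, m$volume, m$reduced_volume))
  cat(sprintf("  closure residual rho(Ls) = %.3g%s\n", m$closure,
              if (x$rho_negative) "  [rho < 0: self-intersecting]" else ""))
  invisible(x)
}

#' Integrated geometric measures of a surface grid
#'
#' Area \eqn{A = 2\pi\int \rho\, ds}, enclosed volume
#' \eqn{V = \pi\int \rho^2 \sin\theta\, ds}, reduced volume
#' \eqn{v = V/V_0} with \eqn{V_0 = \frac{4\pi}{3}(A/4\pi)^{3/2}} the volume
#' of the sphere with the same area, and the equivalent radius
#' \eqn{R_{\mathrm{eff}}=\sqrt{A/4\pi}}.  Composite Simpson quadrature on
#' the s grid.  A non-closed profile is reported through the `closure`
#' field but measures are still returned.
#'
#' @param grid a [surface_grid()].
#' @return An object of class `geometry_measures`: list with `area`,
#'   `volume`, `reduced_volume`, `R_eff`, `closure`, `height`.
#' @export
surface_measures <- function(grid) {
  stopifnot(inherits(grid, "surface_grid"))
  area <- 2 * pi * sum(grid$w_s * grid$rho)
  volume <- pi * sum(grid$w_s * grid$rho^2 * sin(grid$theta))
  R_eff <- sqrt(area / (4 * pi))
  structure(list(
    area = area, volume = volume,
    reduced_volume = volume / (4 * pi / 3 * R_eff^3),
    R_eff = R_eff, closure = grid$rho[grid$n_s],
    height = max(grid$z) - min(grid$z)),
    class = "geometry_measures")
}

#' @export
print.geometry_measures <- function(x, ...) {
  cat(sprintf(
    "area = %.6g, volume = %.6g, v = %.6g, R_eff = %.6g, height = %.6g\n",
    x$area, x$volume, x$reduced_volume, x$R_eff, x$height))
  invisible(x)
}

#' Closure residual of a profile
#'
#' \eqn{\rho(L_s) = \int_0^{L_s}\cos\theta\, ds}; zero for admissible closed
#' shapes, enforced by penalty during shape optimization.
#'
#' @inheritParams surface_grid
#' @param n_s number of grid nodes used for the cumulative quadrature.
#' @return scalar residual (units of R).
#' @export
closure_residual <- function(profile, n_s = 201L) {
  s <- seq(0, profile$Ls, length.out = as.integer(n_s))
  .integrate_profile_curve(profile, s)$rho[n_s]
}

#' Rescale a profile so the surface area is exactly 4*pi
#'
#' All lengths in the model are measured in units of
#' \eqn{R=\sqrt{A/4\pi}}; after every shape update the profile is rescaled
#' (amplitudes and theta0 unchanged, `Ls` multiplied by
#' \eqn{\sqrt{4\pi/A}}) so that the area is exactly \eqn{4\pi} and energies
#' are comparable across shapes.
#'
#' @inheritParams surface_grid
#' @param n_s nodes used to measure the area.
#' @return rescaled `shape_profile`.
#' @export
normalize_area <- function(profile, n_s = 101L) {
  g <- surface_grid(profile, n_s = n_s, n_phi = 3L)
  a <- surface_measures(g)$area
  if (!is.finite(a) || a <= 0) stop("cannot normalize: non-positive area")
  shape_profile(profile$amplitudes, Ls = profile$Ls * sqrt(4 * pi / a),
                theta0 = profile$theta0)
}

#' Surface integral of a scalar field over the grid
#'
#' \eqn{\int\!\!\int f\, J(s)\, ds\, d\varphi} with composite Simpson in s
#' and the (spectrally accurate) periodic trapezoid in phi.  `field` may be
#' an `n_s x n_phi` matrix or a length-`n_s` vector (axisymmetric field).
#'
#' @param grid a [surface_grid()].
#' @param field matrix or vector of point values.
#' @return scalar integral.
#' @export
integrate_field <- function(grid, field) {
  if (is.matrix(field)) {
    stopifnot(nrow(field) == grid$n_s, ncol(field) == grid$n_phi)
    sum((grid$w_s * grid$J) * rowSums(field)) * grid$dphi
  } else {
    stopifnot(length(field) == grid$n_s)
    2 * pi * sum(grid$w_s * grid$J * field)
  }
}
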