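# Shared test geometry: unit sphere and smooth random perturbations of it.

sphere_profile <- function(N = 12L) shape_profile(numeric(N), Ls = pi)

# Smooth random admissible profile: sphere plus decaying random amplitudes,
# rescaled to area 4*pi.  Not exactly closed; used for quadrature oracles.
random_profile <- function(seed, N = 12L, scale = 0.05) {
  set.seed(seed)
  a <- stats::rnorm(N, sd = scale / seq_len(N)^2)
  normalize_area(shape_profile(a, Ls = pi), n_s = 201L)
}

# As random_profile, but with a_1 adjusted so the curve actually closes
# (rho(Ls) = 0); needed for tests of properties that hold only for
# admissible closed shapes.
closed_random_profile <- function(seed, N = 12L, scale = 0.05) {
  p <- random_profile(seed, N = N, scale = scale)
  f <- function(a1) {
    a <- p$amplitudes; a[1] <- a1
    closure_residual(shape_profile(a, Ls = p$Ls), n_s = 201L)
  }
  a1 <- stats::uniroot(f, c(-1, 1), tol = 1e-12)$root
  a <- p$amplitudes; a[1] <- a1
  normalize_area(shape_profile(a, Ls = p$Ls), n_s = 201L)
}

# Finite-difference oracle for mean/Gaussian curvature from rho(s), z(s)
# (independent of the dtheta/ds route).  Interior nodes only.
curvature_fd_oracle <- function(grid) {
  s <- grid$s; rho <- grid$rho; z <- grid$z
  n <- length(s); h <- s[2] - s[1]
  i <- 2:(n - 1)
  rs <- (rho[i + 1] - rho[i - 1]) / (2 * h)
  zs <- (z[i + 1] - z[i - 1]) / (2 * h)
  rss <- (rho[i + 1] - 2 * rho[i] + rho[i - 1]) / h^2
  zss <- (z[i + 1] - 2 * z[i] + z[i - 1]) / h^2
  g <- rs^2 + zs^2
  K <- -zs * (zs * rss - zss * rs) / (rho[i] * g^2)
  # sign convention: outward normal, sphere has H = +1
  H <- -(rho[i] * (zs * rss - zss * rs) - zs * g) / (rho[i] * g^(3 / 2)) / 2
  list(idx = i, K = K, H = H)
}
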