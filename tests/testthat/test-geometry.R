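test_that("tangent angle series evaluates exactly at its endpoints and nodes", {
  p <- sphere_profile()
  expect_equal(eval_theta(p, pi / 2)$theta, pi / 2)
  expect_equal(eval_theta(p, c(0, p$Ls))$theta, c(0, pi))

  # single-mode case: theta(Ls/2) = theta0/2 + a_1
  p1 <- shape_profile(c(0.3), Ls = pi)
  expect_equal(eval_theta(p1, pi / 2)$theta, pi / 2 + 0.3)
  # derivative is the analytic term-by-term series
  expect_equal(eval_theta(p1, pi / 2)$dtheta, 1 + 0)  # cos(pi/2) kills mode 1
  expect_equal(eval_theta(p1, 0)$dtheta, 1 + 0.3 * 1)

  # endpoint angle holds for arbitrary amplitudes
  pr <- random_profile(1)
  expect_equal(eval_theta(pr, pr$Ls)$theta, pr$theta0)
  expect_error(eval_theta(p, -0.1), "outside")
  expect_error(eval_theta(p, pi + 0.1), "outside")
})

test_that("profile integration reproduces the unit sphere and refines correctly", {
  g <- surface_grid(sphere_profile(), n_s = 101L, n_phi = 11L)
  mid <- (g$n_s + 1L) / 2L
  expect_equal(g$rho[mid], 1, tolerance = 1e-10)
  expect_equal(g$z[g$n_s] - g$z[1], 2, tolerance = 1e-10)
  expect_lt(abs(g$rho[g$n_s]), 1e-10)          # sphere closes

  # refinement oracle: coarse-grid rho, z agree with a 10x finer quadrature
  pr <- random_profile(7)
  gc <- surface_grid(pr, n_s = 41L, n_phi = 5L)
  gf <- surface_grid(pr, n_s = 401L, n_phi = 5L)
  keep <- seq(1L, 401L, by = 10L)
  expect_equal(gc$rho, gf$rho[keep], tolerance = 1e-8)
  expect_equal(gc$z, gf$z[keep], tolerance = 1e-8)
})

test_that("principal curvatures: sphere, pole limits, and the rho-z oracle", {
  g <- surface_grid(sphere_profile(), n_s = 81L, n_phi = 7L)
  expect_equal(g$C1, rep(1, g$n_s), tolerance = 1e-9)
  expect_equal(g$C2, rep(1, g$n_s), tolerance = 1e-8)
  expect_equal(g$H, rep(1, g$n_s), tolerance = 1e-8)
  expect_equal(g$K, rep(1, g$n_s), tolerance = 1e-8)
  expect_equal(max(abs(g$D)), 0, tolerance = 1e-8)

  # pole nodes carry the umbilic limit C2 = C1, approached by the
  # neighbouring nodes (L'Hopital limit of sin(theta)/rho)
  pr <- random_profile(3)
  gp <- surface_grid(pr, n_s = 201L, n_phi = 5L)
  expect_identical(gp$C2[1], gp$C1[1])
  expect_identical(gp$C2[gp$n_s], gp$C1[gp$n_s])
  expect_lt(abs(gp$C2[2] - gp$C1[1]), 0.05 * max(1, abs(gp$C1[1])))

  # dual-formula oracle: H, K from finite differences of rho(s), z(s)
  fd <- curvature_fd_oracle(gp)
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 0.5))
  expect_lt(rel(gp$K[fd$idx], fd$K), 1e-3)
  expect_lt(rel(gp$H[fd$idx], fd$H), 1e-3)
})

test_that("surface measures: sphere closed forms and quadrature refinement", {
  g <- surface_grid(sphere_profile(), n_s = 101L, n_phi = 7L)
  m <- surface_measures(g)
  expect_equal(m$area, 4 * pi, tolerance = 1e-6)
  expect_equal(m$volume, 4 * pi / 3, tolerance = 1e-6)
  expect_equal(m$reduced_volume, 1, tolerance = 1e-6)
  expect_equal(m$R_eff, 1, tolerance = 1e-7)

  pr <- random_profile(11)
  vc <- surface_measures(surface_grid(pr, 41L, 5L))$reduced_volume
  vf <- surface_measures(surface_grid(pr, 401L, 5L))$reduced_volume
  expect_equal(vc, vf, tolerance = 1e-4)
})

test_that("geodesic curvature of parallels matches the sphere closed form", {
  g <- surface_grid(sphere_profile(), n_s = 81L, n_phi = 7L)
  i <- 2:(g$n_s - 1L)
  expect_equal(g$kg2[i], cos(g$s[i]) / sin(g$s[i]), tolerance = 1e-8)
  eq <- (g$n_s + 1L) / 2L
  expect_lt(abs(g$kg2[eq]), 1e-10)             # equator
  expect_true(all(is.na(g$kg2[c(1L, g$n_s)]))) # poles excluded
})

test_that("closure residual is the independent quadrature of cos(theta)", {
  expect_lt(abs(closure_residual(sphere_profile())), 1e-10)
  p <- shape_profile(c(0.1), Ls = pi)
  oracle <- stats::integrate(function(s) cos(eval_theta(p, s)$theta),
                             0, pi, rel.tol = 1e-12)$value
  expect_equal(closure_residual(p), oracle, tolerance = 1e-9)
  expect_gt(abs(closure_residual(p)), 1e-3)    # perturbation breaks closure
})

test_that("arc-length identity and area normalization contract hold", {
  pr <- random_profile(5)
  g <- surface_grid(pr, n_s = 201L, n_phi = 5L)
  # d rho/ds = cos(theta), d z/ds = sin(theta) by construction
  h <- g$ds; i <- 2:(g$n_s - 1L)
  rs <- (g$rho[i + 1] - g$rho[i - 1]) / (2 * h)
  zs <- (g$z[i + 1] - g$z[i - 1]) / (2 * h)
  expect_equal(rs^2 + zs^2, rep(1, length(i)), tolerance = 1e-3)

  # rescaling to A = 4*pi is exact and leaves the reduced volume invariant
  p2 <- shape_profile(pr$amplitudes, Ls = pr$Ls * 1.7)
  m2 <- surface_measures(surface_grid(normalize_area(p2, 201L), 201L, 5L))
  m1 <- surface_measures(surface_grid(pr, 201L, 5L))
  expect_equal(m2$area, 4 * pi, tolerance = 1e-10)
  expect_equal(m2$reduced_volume, m1$reduced_volume, tolerance = 1e-8)
})

test_that("the sphere is the unique v = 1 shape", {
  for (seed in 1:5) {
    pr <- closed_random_profile(seed, scale = 0.2)
    v <- surface_measures(surface_grid(pr, 201L, 5L))$reduced_volume
    expect_lte(v, 1 + 1e-9)
  }
  # near-spherical reduced volume forces a near-spherical profile
  pr <- random_profile(2, scale = 1e-5)
  g <- surface_grid(pr, 101L, 5L)
  expect_gt(surface_measures(g)$reduced_volume, 1 - 1e-6)
  expect_lt(max(abs(g$theta - pi * g$s / g$Ls)), 1e-3)
})
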