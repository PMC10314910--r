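zero_texture <- function(g)
  nematic_texture(matrix(0, g$n_s, g$n_phi), matrix(0, g$n_s, g$n_phi))

test_that("bending density reproduces the Helfrich sphere closed forms", {
  g <- surface_grid(sphere_profile(), 101L, 11L)
  p <- model_params(kappa = 1, C0 = 0, ke = 0)
  fb <- bending_density(g, p)
  expect_equal(fb, rep(2, g$n_s), tolerance = 1e-7)       # (1/2) * 2^2
  expect_equal(integrate_field(g, fb), 8 * pi, tolerance = 1e-6)
  # C0 = 2 matches the sphere's total curvature exactly
  p2 <- model_params(kappa = 1, C0 = 2)
  expect_lt(max(abs(bending_density(g, p2))), 1e-14)
})

test_that("condensation density: minimizer value and scan oracle", {
  g <- surface_grid(sphere_profile(), 21L, 8L)
  p <- model_params()           # alpha = 100, beta = 200
  expect_equal(condensation_density(zero_texture(g), p)[5, 5], 0)

  lam0 <- equilibrium_lambda(p)
  expect_equal(lam0, 0.5)       # alpha = 100, beta = 2 alpha
  tx <- nematic_texture(matrix(lam0, 21, 8), matrix(0, 21, 8))
  expect_equal(condensation_density(tx, p)[5, 5],
               -p$alpha^2 / (2 * p$beta), tolerance = 1e-12)

  # 1D scan over lambda finds the same minimizer as the closed form
  set.seed(1)
  for (k in 1:10) {
    a <- runif(1, 0.5, 200); b <- runif(1, 0.5, 400)
    fc <- function(l) -a * 2 * l^2 + b / 2 * (2 * l^2)^2
    scan <- optimize(fc, c(0, 5))$minimum
    expect_equal(sqrt(a / (2 * b)), scan, tolerance = 1e-4)
  }
  expect_equal(equilibrium_lambda(model_params(nematic = FALSE)), 0)
})

test_that("Euler relation gives the curvature seen at angle eta", {
  # cylinder wall: C1 = 0 along the axis, C2 = 1/r around it
  r <- 2; H <- (0 + 1 / r) / 2; D <- (0 - 1 / r) / 2
  expect_equal(euler_curvature(H, D, pi / 2), 1 / r)
  expect_equal(euler_curvature(H, D, 0), 0)
  # sphere: D = 0, any angle sees H
  eta <- seq(0, pi, by = 0.1)
  expect_equal(euler_curvature(1, 0, eta), rep(1, length(eta)))
  # saddle with C1 = -C2: H = 0, C = D cos(2 eta)
  expect_equal(euler_curvature(0, 0.7, eta), 0.7 * cos(2 * eta))
})

test_that("deviatoric density: director form, isotropic average, blending", {
  # the eta-average of (H + D cos 2eta - Cp)^2 equals (H - Cp)^2 + D^2/2
  H <- 0.8; D <- -1.3; Cp <- 0.5
  avg <- integrate(function(e) (euler_curvature(H, D, e) - Cp)^2,
                   0, pi)$value / pi
  expect_equal(avg, (H - Cp)^2 + D^2 / 2, tolerance = 1e-9)

  pr <- closed_random_profile(4, scale = 0.15)
  g <- surface_grid(pr, 41L, 13L)
  p <- model_params(Cp = 0.7, ke = 0.4)

  # fully ordered uniform texture: matches the Euler-relation closed form
  lam0 <- equilibrium_lambda(p)
  eta0 <- 0.3
  tx <- nematic_texture(matrix(lam0 * cos(2 * eta0), 41, 13),
                        matrix(lam0 * sin(2 * eta0), 41, 13))
  fe <- deviatoric_density(tx, g, p)
  ref <- p$ke / 2 * (euler_curvature(g$H, g$D, eta0) - p$Cp)^2
  i <- 3:39
  expect_equal(fe[i, 1], ref[i], tolerance = 1e-12)

  # zero texture: orientation-averaged form everywhere
  fe0 <- deviatoric_density(zero_texture(g), g, p)
  ref0 <- p$ke / 2 * ((g$H - p$Cp)^2 + g$D^2 / 2)
  expect_equal(fe0[i, 1], ref0[i], tolerance = 1e-12)

  # isotropic phase (alpha < 0): averaged form regardless of the fields
  p_iso <- model_params(Cp = 0.7, ke = 0.4, nematic = FALSE)
  expect_equal(deviatoric_density(tx, g, p_iso)[i, 1], ref0[i],
               tolerance = 1e-12)

  # continuity across the blend window: no jump larger than the window
  lam_seq <- seq(0, 0.25 * lam0, length.out = 60)
  vals <- vapply(lam_seq, function(l) {
    t2 <- nematic_texture(matrix(l * cos(2 * eta0), 41, 13),
                          matrix(l * sin(2 * eta0), 41, 13))
    deviatoric_density(t2, g, p)[20, 1]
  }, 0)
  expect_lt(max(abs(diff(vals))), 0.1 * (max(vals) - min(vals) + 1e-12) + 1e-9)
})

test_that("total free energy: breakdown, closed forms, refinement, additivity", {
  g <- surface_grid(sphere_profile(), 101L, 21L)
  p <- model_params(kappa = 1, C0 = 0, ke = 0.2, Cp = 0.5, nematic = FALSE)
  e <- total_free_energy(zero_texture(g), g, p)
  expect_equal(e$Ftot, e$Fb + e$Fc + e$Fi + e$Fe, tolerance = 1e-12)
  expect_equal(e$Fb, 8 * pi, tolerance = 1e-5)
  expect_equal(e$Fc, 0)
  expect_equal(e$Fi, 0)
  expect_equal(e$Fe, p$ke / 2 * (1 - p$Cp)^2 * 4 * pi, tolerance = 1e-5)

  # zeroing ke removes exactly Fe
  p0 <- model_params(kappa = 1, C0 = 0, ke = 0, Cp = 0.5, nematic = FALSE)
  e0 <- total_free_energy(zero_texture(g), g, p0)
  expect_equal(e$Ftot - e0$Ftot, e$Fe, tolerance = 1e-12)

  # grid refinement changes Ftot of a fixed smooth configuration < 0.1%
  pr <- closed_random_profile(9, scale = 0.1)
  p1 <- model_params(Cp = 1, ke = 0.2, kappa = 1 / 60)
  conf <- function(n_s, n_phi) {
    gg <- surface_grid(pr, n_s, n_phi)
    # fixed physical core radius (0.1 R) so the configuration itself does
    # not change with the grid
    tt <- defect_texture(gg, data.frame(s = c(0, gg$Ls), phi = 0, m = c(1, 1)),
                         core_cells = 0.1 / gg$ds)
    total_free_energy(tt, gg, p1)$Ftot
  }
  f1 <- conf(81L, 81L); f2 <- conf(161L, 161L)
  expect_equal(f1, f2, tolerance = 1e-3)
})

test_that("energies are invariant under the mirror reflection s -> Ls - s", {
  pr <- closed_random_profile(6, scale = 0.15)
  g <- surface_grid(pr, 61L, 31L)
  tx <- defect_texture(g, data.frame(s = c(0.3, 0.7) * g$Ls,
                                     phi = g$phi[c(1, 16)], m = c(1, 1)))
  p <- model_params(Cp = 1.2, ke = 0.3, kappa = 0.05, C0 = 0.4)

  # mirrored profile: a_i -> (-1)^i a_i; mirrored texture: rows reversed,
  # qm sign-flipped (eta -> -eta under the orientation flip)
  prm <- normalize_area(shape_profile(pr$amplitudes * (-1)^seq_len(pr$N),
                                      Ls = pr$Ls), 201L)
  gm <- surface_grid(prm, 61L, 31L)
  txm <- nematic_texture(tx$q0[61:1, ], -tx$qm[61:1, ])
  e <- total_free_energy(tx, g, p)
  em <- total_free_energy(txm, gm, p)
  for (f in c("Fb", "Fc", "Fi", "Fe", "Ftot"))
    expect_equal(em[[f]], e[[f]], tolerance = 1e-6)
})

test_that("with ke = 0 and no texture the model is exactly Helfrich's", {
  for (kap in c(0.02, 1, 7)) {
    g <- surface_grid(sphere_profile(), 81L, 7L)
    p <- model_params(kappa = kap, ke = 0, nematic = FALSE)
    e <- total_free_energy(zero_texture(g), g, p)
    expect_equal(e$Ftot, 8 * pi * kap, tolerance = 1e-5)
    expect_equal(e$Fc + e$Fi + e$Fe, 0)
  }
})
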