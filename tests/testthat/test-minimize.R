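test_that("compiled texture energy matches the vectorized R densities", {
  g <- surface_grid(seed_profile("prolate", 0.6, 12), 41L, 31L)
  p <- model_params(v_target = 0.6, Cp = 1.2)
  tx <- random_texture(g, 0.45, seed = 11)
  b <- total_free_energy(tx, g, p)
  expect_equal(texture_energy(tx, g, p), b$Fc + b$Fi + b$Fe,
               tolerance = 1e-12)
  # extrinsic variant agrees too
  p2 <- model_params(v_target = 0.6, Cp = 1.2, extrinsic = TRUE)
  b2 <- total_free_energy(tx, g, p2)
  expect_equal(texture_energy(tx, g, p2), b2$Fc + b2$Fi + b2$Fe,
               tolerance = 1e-12)
})

test_that("Monte Carlo relaxation: determinism, quench monotonicity, drift", {
  g <- surface_grid(sphere_profile(), 31L, 31L)
  p <- model_params(v_target = 1, Cp = 0.5)
  tx <- random_texture(g, 0.45, seed = 5)

  r1 <- mc_relax_texture(tx, g, p, sweeps = 120, seed = 9)
  r2 <- mc_relax_texture(tx, g, p, sweeps = 120, seed = 9)
  expect_identical(r1$texture$q0, r2$texture$q0)   # bit-identical trajectory
  expect_identical(r1$texture$qm, r2$texture$qm)

  # greedy quench sweeps never increase the energy
  n_q <- 24                                         # final 20% of sweeps
  quench_trace <- tail(r1$energy, n_q)
  expect_true(all(diff(quench_trace) <= 1e-9))

  # accumulated delta-E agrees with the recomputed total (no drift)
  expect_lt(r1$energy_drift, 1e-8)

  # the amplitude cap is respected
  lam <- sqrt(r1$texture$q0^2 + r1$texture$qm^2)
  expect_lte(max(lam), 0.5 + 1e-12)
})

test_that("relaxed textures on closed shells carry total charge 2", {
  p <- model_params(v_target = 1, Cp = 0)
  g <- surface_grid(sphere_profile(16L), 41L, 41L)
  for (sd in c(1L, 2L)) {
    rel <- mc_relax_texture(random_texture(g, 0.45, seed = sd), g, p,
                            sweeps = 800, seed = sd)
    d <- suppressWarnings(detect_defects(rel$texture, g, lambda0 = 0.5))
    expect_equal(total_charge(d), 2)
  }
})

test_that("shape optimization recovers the Helfrich sphere", {
  p <- model_params(v_target = 1, kappa = 1, ke = 0, nematic = FALSE)
  prof <- seed_profile("prolate", v_target = 0.85, n_modes = 20)
  tx <- nematic_texture(matrix(0, 41, 21), matrix(0, 41, 21))
  opt <- optimize_shape(prof, tx, p, n_s = 41L, n_phi = 21L,
                        passes = 4L, maxit = 300L)
  g <- surface_grid(opt$profile, 41L, 21L)
  e <- total_free_energy(tx, g, p)
  expect_equal(e$Fb, 8 * pi, tolerance = 0.01)
  expect_lt(abs(opt$measures$reduced_volume - 1), 1e-3)
  expect_lt(abs(opt$measures$closure), 1e-3)
  expect_equal(surface_measures(g)$area, 4 * pi, tolerance = 1e-10)
})

test_that("shape classification follows the profile-curve rules", {
  expect_equal(classify_shape(seed_profile("sphere"))$class, "sphere")
  expect_equal(classify_shape(seed_profile("oblate", 0.5))$class, "oblate")
  expect_equal(classify_shape(seed_profile("prolate", 0.5))$class, "prolate")
  expect_equal(classify_shape(seed_profile("stomatocyte", 0.5))$class,
               "stomatocyte")
  expect_equal(classify_shape(seed_profile("dumbbell", 0.72))$class,
               "necklace")
  phi_cl <- classify_shape(seed_profile("phi", 0.6))
  expect_equal(phi_cl$class, "phi_shape")
  expect_equal(phi_cl$necks, 2L)
})

test_that("branch comparison selects the energy minimum and flags ties", {
  p <- model_params(v_target = 0.7, Cp = 1.5, kappa = 0, nematic = FALSE)
  mk_run <- function(branch, seed) {
    cfg <- run_config("test", seed = seed, branch = branch, n_s = 21L,
                      n_phi = 21L, n_modes = 8L, mc_sweeps = 20L,
                      mc_sweeps_later = 10L, max_iter = 2L,
                      shape_maxit = 40L, shape_passes = 1L)
    suppressWarnings(alternate_minimize(cfg, p))
  }
  r1 <- mk_run("prolate", 1L)
  r2 <- mk_run("dumbbell", 1L)
  bc <- branch_compare(list(r1, r2))
  expect_equal(bc$best$energy$Ftot, min(r1$energy$Ftot, r2$energy$Ftot))
  expect_equal(bc$margin, abs(r1$energy$Ftot - r2$energy$Ftot))
  expect_equal(nrow(bc$ranking), 2L)

  bc1 <- branch_compare(list(r1))
  expect_identical(bc1$margin, Inf)
  expect_false(bc1$coexistence)

  # a duplicated run is an exact tie: coexistence
  bc2 <- branch_compare(list(r1, r1), tol_rel = 1e-3)
  expect_true(bc2$coexistence)

  # comparing across different parameters is refused
  r3 <- r2; r3$params <- model_params(v_target = 0.7, Cp = 9)
  expect_error(branch_compare(list(r1, r3)), "different model parameters")
})

test_that("alternating minimization honours its constraint contracts", {
  p <- model_params(v_target = 0.6, Cp = 1)
  cfg <- run_config("test", seed = 3, branch = "prolate", n_s = 31L,
                    n_phi = 31L, n_modes = 12L, mc_sweeps = 300L,
                    mc_sweeps_later = 150L, max_iter = 3L,
                    shape_maxit = 80L, shape_passes = 2L)
  r <- suppressWarnings(alternate_minimize(cfg, p))
  # area contract: exactly 4*pi after every accepted shape
  expect_equal(surface_measures(r$grid)$area, 4 * pi, tolerance = 1e-10)
  # volume constraint
  expect_lt(abs(r$measures$reduced_volume - 0.6), 1e-3)
  # the reported energy is reproducible from the stored state
  e <- total_free_energy(r$texture, r$grid, r$params)
  expect_equal(r$energy$Ftot, e$Ftot, tolerance = 1e-10)
  # topology of the final texture
  expect_equal(sum(r$defects$m), 2)
  # the trace never rises by more than the MC reheating noise between
  # alternations once shapes are accepted
  expect_true(all(is.finite(r$trace)))
})
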