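# independent ring-winding oracle used to cross-check detect_defects
ring_wind <- function(texture, r) {
  x <- atan2(texture$qm[r, ], texture$q0[r, ])
  d <- diff(c(x, x[1]))
  sum((d + pi) %% (2 * pi) - pi) / (4 * pi)
}

sphere_grid <- function(n_s = 61L, n_phi = 61L)
  surface_grid(sphere_profile(), n_s = n_s, n_phi = n_phi)

test_that("order and director extraction inverts the (q0, qm) parameterization", {
  g <- sphere_grid(21L, 8L)
  mk <- function(q0v, qmv)
    nematic_texture(matrix(q0v, 21, 8), matrix(qmv, 21, 8))
  od <- order_director(mk(0.3, 0))
  expect_equal(od$lambda[10, 1], 0.3)
  expect_equal(od$eta[10, 1], 0)                  # along the meridian
  od <- order_director(mk(0, 0.3))
  expect_equal(od$eta[10, 1], pi / 4)
  od <- order_director(mk(0, 0))
  expect_equal(od$lambda[10, 1], 0)
  expect_true(od$defect_flag[10, 1])
  expect_true(is.na(od$eta[10, 1]))
  # amplitude bound lambda <= 1/2 is enforced
  expect_error(mk(0.4, 0.4), "lambda")
})

test_that("intrinsic elastic density: positivity, scaling, gauge invariance", {
  g <- sphere_grid(41L, 41L)
  tx <- defect_texture(g, data.frame(s = c(0, g$Ls), phi = c(0, 0),
                                     m = c(1, 1)))
  f <- gradient_energy_density(tx, g)
  expect_true(all(f >= 0))
  expect_equal(f[c(1, 41), ], matrix(0, 2, 41))   # pole rows excluded

  # quadratic scaling in the order parameter
  tx2 <- nematic_texture(0.5 * tx$q0, 0.5 * tx$qm)
  expect_equal(gradient_energy_density(tx2, g), 0.25 * f, tolerance = 1e-12)

  # global gauge rotation of (q0, qm) leaves the density unchanged
  chi <- 0.7
  txr <- nematic_texture(cos(chi) * tx$q0 - sin(chi) * tx$qm,
                         sin(chi) * tx$q0 + cos(chi) * tx$qm)
  expect_equal(gradient_energy_density(txr, g), f, tolerance = 1e-12)

  expect_error(gradient_energy_density(tx, sphere_grid(21L, 8L)), "dimensions")
})

test_that("intrinsic elastic density matches the 3D embedding oracle", {
  g <- sphere_grid(101L, 101L)
  u <- matrix(pi * g$s / g$Ls, g$n_s, g$n_phi)
  ph <- matrix(g$phi, g$n_s, g$n_phi, byrow = TRUE)
  lam <- 0.3 + 0.1 * sin(u)^2 * cos(ph)
  ang <- 0.4 * sin(u) * sin(ph)
  tx <- nematic_texture(lam * cos(ang), lam * sin(ang))

  rows <- which(g$s > 0.2 * g$Ls & g$s < 0.8 * g$Ls)
  f_imp <- gradient_energy_density(tx, g, ki = 1)   # (1/2)|grad_s Q|^2, ki=1
  f_orc <- embed_oracle(tx, g, rows)
  expect_lt(max(abs(f_imp[rows, ] - f_orc[rows, ])) / max(f_orc[rows, ]),
            0.01)
})

test_that("uniform texture has zero intrinsic energy where parallels are geodesics", {
  # on any ring where kg2 = 0 (here: the equator of the sphere) a uniform
  # (q0, qm) field has no tangential gradient at all
  g <- sphere_grid(41L, 31L)
  tx <- nematic_texture(matrix(0.3, 41, 31), matrix(0.1, 41, 31))
  f <- gradient_energy_density(tx, g)
  eq <- (g$n_s + 1L) / 2L
  expect_lt(f[eq, 1], 1e-20)
  # everywhere else the frame spin (kg2) costs energy: 4 kg2^2 (q0^2+qm^2)
  i <- 10L
  expect_equal(f[i, 1], 4 * g$kg2[i]^2 * (0.3^2 + 0.1^2), tolerance = 1e-12)
})

test_that("defect textures round-trip through detection: poles and half-charges", {
  g <- sphere_grid(61L, 61L)

  # one m = +1 defect at each pole (prolate-like configuration)
  tx <- defect_texture(g, data.frame(s = c(0, g$Ls), phi = 0, m = c(1, 1)))
  d <- detect_defects(tx, g)
  expect_equal(nrow(d), 2L)
  expect_setequal(d$m, c(1, 1))
  expect_equal(total_charge(d), 2)

  # four m = +1/2 defects just outside the equator (oblate-like)
  pos <- data.frame(s = g$Ls * c(0.42, 0.42, 0.58, 0.58),
                    phi = g$phi[c(1, 31, 16, 46)], m = 0.5)
  tx <- defect_texture(g, pos, lambda_bg = 0.5)
  d <- detect_defects(tx, g)
  expect_equal(nrow(d), 4L)
  expect_equal(sort(d$m), rep(0.5, 4))
  expect_equal(total_charge(d), 2)
  # every prescribed core recovered within ~one grid cell
  for (k in seq_len(4)) {
    ds_gap <- abs(d$s - pos$s[k])
    dp_gap <- pmin(abs(d$phi - pos$phi[k]), 2 * pi - abs(d$phi - pos$phi[k]))
    expect_lt(min(ds_gap + dp_gap), 1.5 * g$ds + 1.5 * g$dphi)
  }

  # defects and antidefects plus pole charges sum to 2
  mixed <- data.frame(
    s = c(0.35, 0.35, 0.55, 0.55, 0, 1) * g$Ls,
    phi = g$phi[c(1, 31, 16, 46, 1, 1)],
    m = c(0.5, 0.5, -0.5, -0.5, 1, 1))
  tx <- detect_defects(defect_texture(g, mixed, core_cells = 1.5), g)
  expect_equal(total_charge(tx), 2)
  expect_equal(sum(tx$m == -0.5), 2L)
})

test_that("winding is stable across nested loops and merged cores sum charges", {
  g <- sphere_grid(81L, 81L)
  tx <- defect_texture(g, data.frame(s = g$Ls * c(0.5, 0.3, 0.7),
                                     phi = c(pi, 0, 0), m = c(1, 0.5, 0.5)))
  # multi-loop oracle: ring windings on three nested parallels bracketing
  # the equatorial defect are identical after charge bookkeeping
  w <- vapply(c(-6L, -8L, -10L), function(k)
    ring_wind(tx, (g$n_s + 1L) %/% 2L + k), 0)
  expect_equal(w, rep(w[1], 3), tolerance = 1e-12)

  # two half-defects closer than a core radius merge and report m = 1
  gm <- sphere_grid(41L, 41L)
  near <- data.frame(s = gm$Ls * c(0.50, 0.52, 0, 0),
                     phi = c(0, 0, 0, 0), m = c(0.5, 0.5, 0.5, 0.5))
  near$s[3:4] <- gm$Ls * c(0.2, 0.8)
  d <- detect_defects(defect_texture(gm, near, core_cells = 2.5), gm)
  expect_equal(total_charge(d), 2)
  expect_true(1 %in% d$m)          # merged pair carries the summed charge
})

test_that("texture generators respect topology and reproducibility contracts", {
  g <- sphere_grid(31L, 31L)
  expect_error(defect_texture(g, data.frame(s = 0, phi = 0, m = 1)),
               "topology")
  expect_error(defect_texture(g, data.frame(s = c(0, g$Ls), phi = 0,
                                            m = c(0.7, 1.3))),
               "multiples")
  t1 <- random_texture(g, amplitude = 0.25, seed = 42L)
  t2 <- random_texture(g, amplitude = 0.25, seed = 42L)
  expect_identical(t1, t2)
  expect_true(max(t1$q0^2 + t1$qm^2) <= 0.25^2 + 1e-12)
  t0 <- random_texture(g, amplitude = 0)
  expect_equal(max(abs(t0$q0)) + max(abs(t0$qm)), 0)
})
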