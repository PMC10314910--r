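#' Model parameters for the coupled shape-texture free energy
#'
#' Collects the physical coefficients of the four energy densities.  All
#' lengths are in units of the equivalent sphere radius
#' \eqn{R=\sqrt{A/4\pi}} and all energies in units of the intrinsic
#' elastic constant \eqn{k_i}.  The Landau coefficients are closed from
#' the correlation length \eqn{\xi = \sqrt{k_i/|\alpha|}}: given
#' `R_over_xi`, \eqn{|\alpha| = k_i (R/\xi)^2}, and \eqn{\beta = 2|\alpha|}
#' so that the equilibrium ordering amplitude [equilibrium_lambda()] sits
#' at the upper bound 1/2 of \eqn{\lambda} (the amplitude only scales the
#' reported \eqn{\lambda/\lambda_0} maps).  The sign of \eqn{\alpha}
#' encodes the phase: positive below the transition temperature (nematic),
#' negative above it (isotropic); a temperature quench is a sign flip of
#' \eqn{\alpha} alone.
#'
#' @param v_target reduced volume constraint, in (0, 1].
#' @param Cp intrinsic (spontaneous) curvature of the curved rod-like
#'   molecules, units 1/R.
#' @param ke deviatoric coupling constant (units of ki).
#' @param kappa Helfrich bending rigidity (units of ki).
#' @param C0 isotropic spontaneous curvature (1/R).
#' @param R_over_xi ratio of shell radius to nematic correlation length.
#' @param ki intrinsic elastic constant; the energy unit, default 1.
#' @param nematic logical; `TRUE` for the ordered phase (alpha > 0).
#' @param alpha,beta optional explicit Landau coefficients overriding the
#'   `R_over_xi` closure.
#' @param lambda_iso,lambda_blend relative amplitudes (fractions of
#'   lambda0) delimiting the linear blend between the orientation-averaged
#'   and the director form of the deviatoric density.
#' @param extrinsic include the normal components of the frame gradients
#'   in the intrinsic elastic term (see [gradient_energy_density()]).
#' @return object of class `model_params`.
#' @export
model_params <- function(v_target = 0.4, Cp = 0, ke = 1 / 5, kappa = 1 / 60,
                         C0 = 0, R_over_xi = 10, ki = 1, nematic = TRUE,
                         alpha = NULL, beta = NULL,
                         lambda_iso = 0.05, lambda_blend = 0.15,
                         extrinsic = FALSE) {
  if (is.null(alpha)) alpha <- (if (nematic) 1 else -1) * ki * R_over_xi^2
  if (is.null(beta)) beta <- 2 * abs(alpha)
  stopifnot(beta > 0, ki > 0, ke >= 0, kappa >= 0,
            v_target > 0, v_target <= 1,
            lambda_iso >= 0, lambda_blend >= lambda_iso)
  structure(list(kappa = kappa, C0 = C0, alpha = alpha, beta = beta,
                 ki = ki, ke = ke, Cp = Cp, v_target = v_target,
                 R_over_xi = R_over_xi, lambda_iso = lambda_iso,
                 lambda_blend = lambda_blend, extrinsic = extrinsic),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: v = %.3g, Cp = %.3g, ke = %.3g ki, kappa = %.4g ki\n",
    x$v_target, x$Cp, x$ke / x$ki, x$kappa / x$ki))
  cat(sprintf("  C0 = %.3g, alpha = %.4g (%s phase), beta = %.4g, lambda0 = %.3g\n",
              x$C0, x$alpha, if (x$alpha > 0) "nematic" else "isotropic",
              x$beta, equilibrium_lambda(x)))
  invisible(x)
}

#' Equilibrium ordering amplitude
#'
#' The minimizer of the condensation density
#' \eqn{f_c = -\alpha\,\mathrm{Tr}Q^2 + \frac{\beta}{2}(\mathrm{Tr}Q^2)^2}
#' under \eqn{\mathrm{Tr}Q^2 = 2\lambda^2}:
#' \eqn{\lambda_0 = \sqrt{\alpha/2\beta}} for \eqn{\alpha > 0}, zero in
#' the isotropic phase.  (The often-quoted \eqn{\sqrt{\alpha/\beta}}
#' corresponds to the alternative convention
#' \eqn{\mathrm{Tr}Q^2 = \lambda^2}; only the ratio \eqn{\lambda/\lambda_0}
#' enters reported maps, so the choice of convention is cosmetic, but the
#' self-consistent minimizer is used throughout.)
#'
#' @param params a [model_params()].
#' @return scalar \eqn{\lambda_0 \in [0, 1/2]}.
#' @export
equilibrium_lambda <- function(params) {
  if (params$alpha <= 0) return(0)
  sqrt(params$alpha / (2 * params$beta))
}

#' Helfrich bending energy density
#'
#' \eqn{f_b = \frac{\kappa}{2}(C_1 + C_2 - C_0)^2}: the classical
#' spontaneous-curvature bending density of the bare shell.
#'
#' @param grid a [surface_grid()].
#' @param params a [model_params()].
#' @return numeric vector over the s nodes (the density is axisymmetric).
#' @export
bending_density <- function(grid, params) {
  params$kappa / 2 * (grid$C1 + grid$C2 - params$C0)^2
}

#' Landau condensation energy density
#'
#' \eqn{f_c = -\alpha\,\mathrm{Tr}Q^2 + \frac{\beta}{2}(\mathrm{Tr}Q^2)^2}
#' with \eqn{\mathrm{Tr}Q^2 = 2(q_0^2+q_m^2)}.  Negative below the
#' transition (\eqn{\alpha>0}), where it condenses the nematic order
#' towards [equilibrium_lambda()]; bounded below by
#' \eqn{-\alpha^2/2\beta} per unit area.
#'
#' @param texture a [nematic_texture()].
#' @param params a [model_params()].
#' @return `n_s x n_phi` matrix of densities.
#' @export
condensation_density <- function(texture, params) {
  trq2 <- 2 * (texture$q0^2 + texture$qm^2)
  -params$alpha * trq2 + params$beta / 2 * trq2^2
}

#' Normal curvature seen by a molecule (Euler relation)
#'
#' \eqn{C = H + D\cos 2\eta}: the curvature of the surface along the
#' direction at angle \eqn{\eta} from the first principal direction, with
#' \eqn{H} the mean curvature and \eqn{D} the curvature deviator.
#'
#' @param H,D mean curvature and curvature deviator (any conforming
#'   shapes).
#' @param eta in-plane angle from the first principal direction (radians).
#' @return normal curvature, elementwise.
#' @export
euler_curvature <- function(H, D, eta) H + D * cos(2 * eta)

#' Deviatoric bending energy density of the curved molecules
#'
#' \eqn{f_e = \frac{k_e}{2}(C - C_p)^2} with the Euler curvature
#' \eqn{C = H + D\cos 2\eta} evaluated at the local director angle where
#' the texture is ordered.  Where the order is (near-)isotropic all
#' molecular orientations are equally probable and the density becomes the
#' uniform average over \eqn{\eta},
#' \eqn{f_e^{iso} = \frac{k_e}{2}\big[(H-C_p)^2 + D^2/2\big]}
#' -- randomly oriented curved molecules act like an isotropic spontaneous
#' curvature.  The two forms are blended linearly in
#' \eqn{\lambda/\lambda_0} over `[lambda_iso, lambda_blend]` so the
#' density is continuous through defect cores and through the
#' order-disorder transition.
#'
#' @param texture a [nematic_texture()].
#' @param grid matching [surface_grid()].
#' @param params a [model_params()].
#' @return `n_s x n_phi` matrix of densities.
#' @export
deviatoric_density <- function(texture, grid, params) {
  if (texture$n_s != grid$n_s || texture$n_phi != grid$n_phi)
    stop("texture and grid dimensions differ")
  H <- grid$H; D <- grid$D
  iso <- (H - params$Cp)^2 + D^2 / 2
  lam0 <- equilibrium_lambda(params)
  lam <- sqrt(texture$q0^2 + texture$qm^2)
  if (lam0 == 0) {
    f <- matrix(params$ke / 2 * iso, grid$n_s, grid$n_phi)
    return(f)
  }
  cos2eta <- ifelse(lam > 0, texture$q0 / pmax(lam, 1e-300), 1)
  ord <- (H + D * cos2eta - params$Cp)^2
  t <- pmin(pmax((lam / lam0 - params$lambda_iso) /
                   (params$lambda_blend - params$lambda_iso), 0), 1)
  params$ke / 2 * ((1 - t) * iso + t * ord)
}

#' Total free energy of a configuration
#'
#' Integrates the four densities over the shell surface,
#' \eqn{F = \int\!\!\int f\, J(s)\, ds\, d\varphi}, and returns the
#' breakdown \eqn{F_{tot} = F_b + F_c + F_i + F_e}.
#'
#' @param texture a [nematic_texture()].
#' @param grid matching [surface_grid()].
#' @param params a [model_params()].
#' @param keep_fields retain the per-node density fields in the result.
#' @return object of class `energy_breakdown`: list with `Fb`, `Fc`, `Fi`,
#'   `Fe`, `Ftot` (units of ki) and optionally `fields`.
#' @export
total_free_energy <- function(texture, grid, params, keep_fields = FALSE) {
  fb <- bending_density(grid, params)
  fc <- condensation_density(texture, params)
  fi <- gradient_energy_density(texture, grid, ki = params$ki,
                                extrinsic = params$extrinsic)
  fe <- deviatoric_density(texture, grid, params)
  if (any(!is.finite(fb)) || any(!is.finite(fc)) ||
      any(!is.finite(fi)) || any(!is.finite(fe))) {
    bad <- c(Fb = any(!is.finite(fb)), Fc = any(!is.finite(fc)),
             Fi = any(!is.finite(fi)), Fe = any(!is.finite(fe)))
    stop("non-finite energy density in: ",
         paste(names(bad)[bad], collapse = ", "))
  }
  out <- list(Fb = integrate_field(grid, fb),
              Fc = integrate_field(grid, fc),
              Fi = integrate_field(grid, fi),
              Fe = integrate_field(grid, fe))
  out$Ftot <- out$Fb + out$Fc + out$Fi + out$Fe
  if (keep_fields)
    out$fields <- list(fb = fb, fc = fc, fi = fi, fe = fe)
  structure(out, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "free energy (units of ki): Ftot = %.6g\n  Fb = %.6g  Fc = %.6g  Fi = %.6g  Fe = %.6g\n",
    x$Ftot, x$Fb, x$Fc, x$Fi, x$Fe))
  invisible(x)
}
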