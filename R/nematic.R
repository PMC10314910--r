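#' In-plane nematic texture on a surface grid
#'
#' The surface order tensor
#' \eqn{Q = q_0(e_1\otimes e_1 - e_2\otimes e_2) + q_m(e_1\otimes e_2 + e_2\otimes e_1)}
#' is stored through the two scalar fields \eqn{q_0(s,\varphi)} and
#' \eqn{q_m(s,\varphi)} on the `n_s x n_phi` grid, with \eqn{e_1} along the
#' meridians and \eqn{e_2} along the parallels.  The ordering amplitude is
#' \eqn{\lambda = \sqrt{q_0^2+q_m^2} \in [0, 1/2]} and the director angle
#' \eqn{\eta} (measured from the meridian direction) satisfies
#' \eqn{\cos 2\eta = q_0/\lambda}, \eqn{\sin 2\eta = q_m/\lambda}.
#'
#' The two pole rows carry no orientational degrees of freedom (the surface
#' frame is singular there); they are stored as zeros and excluded from
#' energies and Monte Carlo updates.
#'
#' @param q0,qm numeric `n_s x n_phi` matrices.
#' @return object of class `nematic_texture` (list with `q0`, `qm`, `n_s`,
#'   `n_phi`).
#' @export
nematic_texture <- function(q0, qm) {
  stopifnot(is.matrix(q0), is.matrix(qm), all(dim(q0) == dim(qm)))
  if (any(!is.finite(q0)) || any(!is.finite(qm)))
    stop("non-finite texture values")
  lam2 <- q0^2 + qm^2
  if (any(lam2 > 0.25 + 1e-9))
    stop("ordering amplitude exceeds the bound lambda <= 1/2")
  q0[c(1L, nrow(q0)), ] <- 0
  qm[c(1L, nrow(qm)), ] <- 0
  structure(list(q0 = q0, qm = qm, n_s = nrow(q0), n_phi = ncol(q0)),
            class = "nematic_texture")
}

#' @export
print.nematic_texture <- function(x, ...) {
  lam <- sqrt(x$q0^2 + x$qm^2)
  cat(sprintf("nematic_texture: %d x %d, lambda in [%.4g, %.4g], mean %.4g\n",
              x$n_s, x$n_phi, min(lam), max(lam),
              mean(lam[-c(1L, x$n_s), ])))
  invisible(x)
}

#' Ordering amplitude and director angle of a texture
#'
#' Inverts the \eqn{(q_0, q_m)} parameterization:
#' \eqn{\lambda = \sqrt{q_0^2 + q_m^2}} and
#' \eqn{\eta = \frac{1}{2}\mathrm{atan2}(q_m, q_0)}, reported in
#' \eqn{[0,\pi)} (the director is headless).  Where \eqn{\lambda = 0} the
#' angle is undefined: `eta` is `NA` there and the `defect_flag` matrix is
#' set (isotropic points signal defect cores).
#'
#' @param texture a [nematic_texture()].
#' @param tol amplitude below which a node is flagged as isotropic.
#' @return list with matrices `lambda`, `eta`, `defect_flag`.
#' @export
order_director <- function(texture, tol = 1e-12) {
  stopifnot(inherits(texture, "nematic_texture"))
  lam <- sqrt(texture$q0^2 + texture$qm^2)
  eta <- 0.5 * atan2(texture$qm, texture$q0)
  eta <- eta %% pi
  flag <- lam <= tol
  eta[flag] <- NA_real_
  list(lambda = lam, eta = eta, defect_flag = flag)
}

## Link-based (staggered) energies of the intrinsic elastic term.
## Derivatives live on lattice links -- s-links between interior rows,
## periodic phi-links within each interior row -- with geometric factors
## at the link midpoint.  A one-sided (link) scheme is used deliberately:
## centered differences are blind to site-alternating (checkerboard)
## modes, which a Metropolis sampler then populates freely wherever the
## frame-spin term is large (near the poles); link differences penalize
## them, and remain O(h^2) accurate at midpoints.
.fi_link_energies <- function(texture, grid, ki, w_node) {
  q0 <- texture$q0; qm <- texture$qm
  n <- grid$n_s; np <- grid$n_phi
  inv_rho <- ifelse(grid$interior & abs(grid$rho) > 1e-10, 1 / grid$rho, 0)
  kg2 <- ifelse(is.na(grid$kg2), 0, grid$kg2)

  # s-links between interior rows i = 2..n-2 (1-based), midpoint area
  i <- 2:(n - 2L)
  A_s <- grid$ds * grid$dphi * (grid$rho[i] + grid$rho[i + 1L]) / 2
  e_s <- ki * ((q0[i + 1L, , drop = FALSE] - q0[i, , drop = FALSE])^2 +
                 (qm[i + 1L, , drop = FALSE] - qm[i, , drop = FALSE])^2) /
    grid$ds^2 * A_s

  # phi-links within interior rows; gauge term at the link midpoint
  jp <- c(2:np, 1L)
  d0 <- (q0[, jp, drop = FALSE] - q0) / grid$dphi
  dm <- (qm[, jp, drop = FALSE] - qm) / grid$dphi
  q0m <- (q0[, jp, drop = FALSE] + q0) / 2
  qmm <- (qm[, jp, drop = FALSE] + qm) / 2
  g0 <- d0 * inv_rho - 2 * kg2 * qmm
  gm <- dm * inv_rho + 2 * kg2 * q0m
  e_p <- ki * (g0^2 + gm^2) * w_node     # link area = w_s * rho * dphi
  e_p[c(1L, n), ] <- 0
  list(e_s = e_s, idx_s = i, e_p = e_p)
}

#' Intrinsic elastic energy density of the texture
#'
#' The density \eqn{f_i = \frac{k_i}{2}\,|\nabla_s Q|^2} penalizes spatial
#' variation of the in-plane order.  Expanding the surface gradient in the
#' principal frame (with \eqn{\kappa_{g1}=0} for meridians) and keeping the
#' tangential components only gives
#' \deqn{f_i = k_i\Big[ q_{0,s}^2 + q_{m,s}^2
#'   + \big(\tfrac{q_{0,\varphi}}{\rho} - 2\kappa_{g2} q_m\big)^2
#'   + \big(\tfrac{q_{m,\varphi}}{\rho} + 2\kappa_{g2} q_0\big)^2 \Big].}
#' The normal components generated by the frame derivatives
#' (\eqn{-C_1 v\otimes e_1}, \eqn{-C_2 v\otimes e_2}) couple the order
#' amplitude to the curvature; they are excluded by default because that
#' coupling is carried by the deviatoric term of the model, and including
#' both would count it twice.  Setting `extrinsic = TRUE` adds their exact
#' contribution \eqn{k_i (C_1^2 + C_2^2)(q_0^2+q_m^2)}.
#'
#' The discretization is link-based (derivatives on lattice links with
#' midpoint geometric factors), which suppresses the checkerboard modes a
#' centered scheme leaves unpenalized; the returned node field shares
#' each link's energy equally between its endpoints, so integrating it
#' with [integrate_field()] reproduces the lattice energy exactly.
#'
#' @param texture a [nematic_texture()].
#' @param grid the [surface_grid()] the texture lives on.
#' @param ki intrinsic elastic constant (energy unit).
#' @param extrinsic also include the normal (curvature-coupling) components
#'   of the frame derivatives.  Default `FALSE`.
#' @return `n_s x n_phi` matrix of non-negative densities.
#' @export
gradient_energy_density <- function(texture, grid, ki = 1, extrinsic = FALSE) {
  stopifnot(inherits(texture, "nematic_texture"),
            inherits(grid, "surface_grid"))
  if (texture$n_s != grid$n_s || texture$n_phi != grid$n_phi)
    stop("texture and grid dimensions differ")
  n <- grid$n_s; np <- grid$n_phi
  w_node <- grid$w_s * grid$J * grid$dphi       # node area weights
  le <- .fi_link_energies(texture, grid, ki, w_node)

  shares <- matrix(0, n, np)
  shares[le$idx_s, ] <- shares[le$idx_s, ] + le$e_s / 2
  shares[le$idx_s + 1L, ] <- shares[le$idx_s + 1L, ] + le$e_s / 2
  jm <- c(np, 1:(np - 1L))
  shares <- shares + le$e_p / 2 + le$e_p[, jm, drop = FALSE] / 2

  f <- matrix(0, n, np)
  pos <- w_node > 0
  f[pos, ] <- shares[pos, ] / w_node[pos]
  if (extrinsic)
    f <- f + ki * (grid$C1^2 + grid$C2^2) * (texture$q0^2 + texture$qm^2)
  f[c(1L, n), ] <- 0
  f
}

## phi winding of 2*eta along the ring at row r: sum of wrapped increments
## of 2*eta around the parallel, in units of 4*pi (so a ring enclosing a
## polar cap of total charge m gives w = m - 1).
.ring_winding <- function(two_eta, r) {
  x <- two_eta[r, ]
  d <- diff(c(x, x[1L]))
  d <- (d + pi) %% (2 * pi) - pi
  list(w = sum(d) / (4 * pi), max_jump = max(abs(d)))
}

## accumulate wrapped increments of 2*eta along an arbitrary node path
.path_winding <- function(two_eta, rows, cols) {
  idx <- cbind(rows, cols)
  x <- two_eta[idx]
  d <- diff(c(x, x[1L]))
  d <- (d + pi) %% (2 * pi) - pi
  list(w = sum(d) / (4 * pi), max_jump = max(abs(d)))
}

## connected components of a logical mask on interior rows, periodic in phi
.label_components <- function(mask) {
  n_s <- nrow(mask); n_phi <- ncol(mask)
  lab <- matrix(0L, n_s, n_phi)
  cur <- 0L
  for (i0 in seq_len(n_s)) for (j0 in seq_len(n_phi)) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0), ncol = 2L)
    lab[i0, j0] <- cur
    while (nrow(queue) > 0L) {
      i <- queue[1L, 1L]; j <- queue[1L, 2L]
      queue <- queue[-1L, , drop = FALSE]
      nb <- rbind(c(i - 1L, j), c(i + 1L, j),
                  c(i, if (j == 1L) n_phi else j - 1L),
                  c(i, if (j == n_phi) 1L else j + 1L))
      nb <- nb[nb[, 1L] >= 1L & nb[, 1L] <= n_s, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        ii <- nb[k, 1L]; jj <- nb[k, 2L]
        if (mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

#' Detect topological defects of a texture
#'
#' Defect cores are connected grid regions where the ordering amplitude
#' falls below `threshold * lambda0` (cores are signalled by
#' \eqn{\lambda \to 0}), plus the two poles, whose charge is measured on
#' the adjacent parallel ring.  Around every core the winding number is
#' accumulated from the unwrapped increments of \eqn{2\eta} along an
#' enclosing grid loop and snapped to the nearest multiple of 1/2:
#' rectangle loops for off-pole cores, parallel rings for cores adjacent
#' to a pole or wrapping the full azimuth (there the loop also picks up
#' the +1 winding of the meridian frame around the pole).  Merged cores
#' report their summed charge.  An angle jump of at least \eqn{\pi/2}
#' between adjacent loop nodes marks the result as low-confidence
#' (`confident = FALSE`) and triggers a refinement warning.
#'
#' On a closed shell of spherical topology the charges must sum to 2
#' (Poincare-Hopf); see [total_charge()].
#'
#' @param texture a [nematic_texture()].
#' @param grid matching [surface_grid()].
#' @param lambda0 equilibrium ordering amplitude used to scale the core
#'   threshold (see [equilibrium_lambda()]).
#' @param threshold relative amplitude below which a node belongs to a
#'   core; default 0.2.
#' @param escalate if the detected charges do not sum to the topological
#'   total 2 (cores shallower than the threshold on coarse grids), retry
#'   with the threshold raised in steps of 25% up to 0.7; warn if the sum
#'   never closes.
#' @return object of class `defect_set`: data frame with columns `s`,
#'   `phi`, `m`, `core_rows`, `confident`, plus attribute `total`.
#' @export
detect_defects <- function(texture, grid, lambda0 = 0.5, threshold = 0.2,
                           escalate = TRUE) {
  stopifnot(inherits(texture, "nematic_texture"),
            inherits(grid, "surface_grid"))
  out <- .detect_defects_at(texture, grid, lambda0, threshold)
  if (escalate && abs(sum(out$m) - 2) > 1e-9) {
    thr <- threshold
    best <- out
    while (thr < 0.7) {
      thr <- thr * 1.25
      cand <- .detect_defects_at(texture, grid, lambda0, thr)
      if (abs(sum(cand$m) - 2) < 1e-9) { best <- cand; break }
      # keep the candidate whose total is closest to the topological 2,
      # preferring the lower threshold on ties
      if (abs(sum(cand$m) - 2) < abs(sum(best$m) - 2) - 1e-9) best <- cand
    }
    out <- best
    if (abs(sum(out$m) - 2) > 1e-9)
      warning("detected charges do not sum to 2 at any core threshold; ",
              "texture under-resolved")
  }
  if (attr(out, "low_conf"))
    warning("defect winding low-confidence: angle jump >= pi/2 on a loop; ",
            "refine the grid")
  attr(out, "low_conf") <- NULL
  class(out) <- c("defect_set", "data.frame")
  attr(out, "total") <- sum(out$m)
  out
}

.detect_defects_at <- function(texture, grid, lambda0, threshold) {
  od <- order_director(texture)
  two_eta <- atan2(texture$qm, texture$q0)    # = 2*eta, continuous rep
  n_s <- grid$n_s; n_phi <- grid$n_phi
  lam_cut <- threshold * lambda0

  mask <- od$lambda < lam_cut
  mask[c(1L, n_s), ] <- FALSE                 # poles handled separately
  lab <- .label_components(mask)
  # merge components whose enclosing loops would overlap: each rectangle
  # would otherwise report the total charge of all cores it encloses
  repeat {
    ids <- setdiff(unique(as.vector(lab)), 0L)
    if (length(ids) < 2L) break
    cells_of <- lapply(ids, function(k) which(lab == k, arr.ind = TRUE))
    merged <- FALSE
    for (a in seq_along(ids)) {
      for (b in seq_len(a - 1L)) {
        ca <- cells_of[[a]]; cb <- cells_of[[b]]
        drow <- min(abs(outer(ca[, 1L], cb[, 1L], "-")))
        dcol <- min(outer(ca[, 2L], cb[, 2L], function(x, y) {
          d <- abs(x - y); pmin(d, n_phi - d)
        }))
        if (drow <= 6L && dcol <= 6L) {
          lab[lab == ids[a]] <- ids[b]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  # all components reaching into a polar cap share that cap's enclosing
  # ring; they must be measured as one object or each would report the
  # whole cap charge
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) > 1L) {
    touch_n <- touch_s <- integer(0)
    for (k in ids) {
      rows_k <- which(lab == k, arr.ind = TRUE)[, 1L]
      if (min(rows_k) <= 3L) touch_n <- c(touch_n, k)
      if (max(rows_k) >= n_s - 2L) touch_s <- c(touch_s, k)
    }
    if (length(touch_n) > 1L) lab[lab %in% touch_n] <- touch_n[1L]
    if (length(touch_s) > 1L) lab[lab %in% touch_s] <- touch_s[1L]
  }
  ids <- setdiff(unique(as.vector(lab)), 0L)
  for (k in seq_along(ids)) lab[lab == ids[k]] <- -k
  lab <- -lab
  ncomp <- length(ids)

  res <- list()
  low_conf <- FALSE
  north_taken <- FALSE; south_taken <- FALSE

  for (k in seq_len(ncomp)) {
    cells <- which(lab == k, arr.ind = TRUE)
    r0 <- min(cells[, 1L]); r1 <- max(cells[, 1L])
    cols <- sort(unique(cells[, 2L]))
    touches_north <- r0 <= 2L
    touches_south <- r1 >= n_s - 1L
    wraps <- length(cols) > n_phi - 3L
    conf <- TRUE

    if (touches_north && touches_south) {
      # core band spans the whole surface: charge is the total, 2
      m <- 2
    } else if (touches_north) {
      ring <- min(r1 + 1L, n_s - 1L)
      wnd <- .ring_winding(two_eta, ring)
      m <- wnd$w + 1
      conf <- wnd$max_jump < pi / 2
      north_taken <- TRUE
    } else if (touches_south) {
      ring <- max(r0 - 1L, 2L)
      wnd <- .ring_winding(two_eta, ring)
      m <- 1 - wnd$w
      conf <- wnd$max_jump < pi / 2
      south_taken <- TRUE
    } else if (wraps) {
      wa <- .ring_winding(two_eta, r0 - 1L)
      wb <- .ring_winding(two_eta, r1 + 1L)
      m <- wb$w - wa$w
      conf <- max(wa$max_jump, wb$max_jump) < pi / 2
    } else {
      j0 <- min(cols); j1 <- max(cols)
      # column window with phi wraparound if the component crosses the seam
      if (any(diff(cols) > 1L)) {      # wraps the seam
        gap <- which(diff(cols) > 1L)[1L]
        j0 <- cols[gap + 1L]; j1 <- cols[gap] + n_phi
      }
      # loop margin: as wide as the grid allows (more nodes -> smaller
      # per-step angle jumps), up to 3 cells
      mar <- max(1L, min(3L, r0 - 2L, n_s - 1L - r1))
      jj <- ((j0 - 1L - mar):(j1 + mar - 1L)) %% n_phi + 1L
      ra <- r0 - mar; rb <- r1 + mar
      # positive (counterclockwise) boundary of the (s, phi) rectangle:
      # outer-s edge traversed with increasing phi, inner-s edge decreasing
      rows <- c(rep(rb, length(jj)),            # outer edge, +phi
                (rb:ra),                        # down the last column
                rep(ra, length(jj)),            # inner edge, -phi
                (ra:rb))                        # up the first column
      colseq <- c(jj, rep(jj[length(jj)], rb - ra + 1L),
                  rev(jj), rep(jj[1L], rb - ra + 1L))
      wnd <- .path_winding(two_eta, rows, colseq)
      m <- wnd$w
      conf <- wnd$max_jump < pi / 2
    }
    lamw <- pmax(lam_cut - od$lambda[cells], 0)
    if (sum(lamw) == 0) lamw <- rep(1, nrow(cells))
    phi_cells <- grid$phi[cells[, 2L]]
    phic <- atan2(sum(lamw * sin(phi_cells)), sum(lamw * cos(phi_cells))) %% (2 * pi)
    m_snap <- round(2 * m) / 2
    if (abs(m - m_snap) > 0.2) conf <- FALSE
    low_conf <- low_conf || !conf
    res[[length(res) + 1L]] <- data.frame(
      s = sum(lamw * grid$s[cells[, 1L]]) / sum(lamw),
      phi = phic, m = m_snap,
      core_rows = paste0(r0, ":", r1), confident = conf)
  }

  # poles without an adjacent core region: measure the cap charge on the
  # first interior ring
  if (!north_taken) {
    wnd <- .ring_winding(two_eta, 2L)
    m <- round(2 * (wnd$w + 1)) / 2
    if (m != 0) {
      conf <- wnd$max_jump < pi / 2
      low_conf <- low_conf || !conf
      res[[length(res) + 1L]] <- data.frame(
        s = 0, phi = 0, m = m, core_rows = "pole:1", confident = conf)
    }
  }
  if (!south_taken) {
    wnd <- .ring_winding(two_eta, n_s - 1L)
    m <- round(2 * (1 - wnd$w)) / 2
    if (m != 0) {
      conf <- wnd$max_jump < pi / 2
      low_conf <- low_conf || !conf
      res[[length(res) + 1L]] <- data.frame(
        s = grid$Ls, phi = 0, m = m,
        core_rows = paste0("pole:", n_s), confident = conf)
    }
  }

  out <- if (length(res)) do.call(rbind, res) else
    data.frame(s = numeric(0), phi = numeric(0), m = numeric(0),
               core_rows = character(0), confident = logical(0))
  attr(out, "low_conf") <- low_conf
  out
}

#' Total topological charge of a defect set
#'
#' Sum of the winding numbers.  For any texture with isolated zeros on a
#' closed surface of spherical topology the total is 2 (Gauss-Bonnet /
#' Poincare-Hopf).
#'
#' @param defects a `defect_set` from [detect_defects()].
#' @return half-integer total charge.
#' @export
total_charge <- function(defects) {
  stopifnot(inherits(defects, "defect_set"))
  sum(defects$m)
}

#' @export
print.defect_set <- function(x, ...) {
  cat(sprintf("defect_set: %d core(s), total charge %.1f\n",
              nrow(x), sum(x$m)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
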