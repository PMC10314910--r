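# Brute-force oracle for the intrinsic elastic density: embed Q as a 3x3
# ambient tensor field via the local frames, finite-difference along the
# surface directions, project tangentially, and take the squared norm --
# fully independent of the kg2/gauge route used by the implementation.
  # brute force: embed Q as a 3x3 ambient tensor via the local frames,
  # finite-difference along the surface directions, project tangentially,
  # and take the squared norm -- fully independent of the kg2 route.
  embed_oracle <- function(tx, g, rows) {
    n_s <- g$n_s; n_phi <- g$n_phi
    th <- matrix(g$theta, n_s, n_phi)
    ph <- matrix(g$phi, n_s, n_phi, byrow = TRUE)
    e1 <- list(cos(th) * cos(ph), cos(th) * sin(ph), sin(th))
    e2 <- list(-sin(ph), cos(ph), matrix(0, n_s, n_phi))
    nv <- list(e1[[2]] * e2[[3]] - e1[[3]] * e2[[2]],
               e1[[3]] * e2[[1]] - e1[[1]] * e2[[3]],
               e1[[1]] * e2[[2]] - e1[[2]] * e2[[1]])
    Qc <- vector("list", 9)    # 3x3 ambient components, row-major
    for (a in 1:3) for (b in 1:3) {
      Qc[[3 * (a - 1) + b]] <-
        tx$q0 * (e1[[a]] * e1[[b]] - e2[[a]] * e2[[b]]) +
        tx$qm * (e1[[a]] * e2[[b]] + e2[[a]] * e1[[b]])
    }
    dds <- function(f) {
      d <- f * NA
      i <- 2:(n_s - 1)
      d[i, ] <- (f[i + 1, ] - f[i - 1, ]) / (2 * g$ds)
      d
    }
    ddp <- function(f)
      (f[, c(2:n_phi, 1)] - f[, c(n_phi, 1:(n_phi - 1))]) / (2 * g$dphi)
    out <- matrix(0, n_s, n_phi)
    for (dir in 1:2) {
      Dq <- lapply(Qc, if (dir == 1) dds else
        function(f) ddp(f) / matrix(g$rho, n_s, n_phi))
      # tangential projection P Dq P with P = I - v v^T, done per node
      for (i in rows) for (j in 1:n_phi) {
        M <- matrix(vapply(Dq, function(f) f[i, j], 0), 3, 3, byrow = TRUE)
        v <- c(nv[[1]][i, j], nv[[2]][i, j], nv[[3]][i, j])
        P <- diag(3) - tcrossprod(v)
        out[i, j] <- out[i, j] + sum((P %*% M %*% P)^2)
      }
    }
    out / 2      # (1/2)|grad_s Q|^2 with k_i = 1
  }

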