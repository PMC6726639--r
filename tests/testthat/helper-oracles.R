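# Independent numerical oracles used across the test files.

# Finite-difference Cauchy stress 2 F (dPsi/dC) t(F): central differences
# of the strain energy with respect to the (symmetrised) entries of C.
fd_cauchy_stress <- function(law, F, a0, eps = 1e-6) {
  C0 <- crossprod(F)
  G <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Cp <- C0; Cm <- C0
    Cp[i, j] <- Cp[i, j] + eps
    Cm[i, j] <- Cm[i, j] - eps
    if (i != j) {
      Cp[j, i] <- Cp[j, i] + eps
      Cm[j, i] <- Cm[j, i] - eps
    }
    wp <- strain_energy(law, sum(diag(Cp)), drop(a0 %*% Cp %*% a0))
    wm <- strain_energy(law, sum(diag(Cm)), drop(a0 %*% Cm %*% a0))
    G[i, j] <- (wp - wm) / (if (i == j) 2 else 4) / eps
  }
  2 * F %*% G %*% t(F)
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Random incompressible deformation gradient R %*% diag(l1, l2, 1/(l1 l2))
# with the fiber invariant kept away from the tension switch at I4 = 1.
random_incompressible_F <- function(tension = TRUE) {
  if (tension) {
    l1 <- runif(1, 1.05, 1.3)
  } else {
    l1 <- runif(1, 0.8, 0.95)
  }
  l2 <- runif(1, 0.9, 1.2)
  random_rotation() %*% diag(c(l1, l2, 1 / (l1 * l2)))
}

# Central-difference gradient of the assembled elastic energy.
fd_energy_gradient <- function(struct, pos, eps = 1e-6) {
  g <- matrix(0, nrow(pos), 2)
  for (i in seq_len(nrow(pos))) for (j in 1:2) {
    pp <- pos; pm <- pos
    pp[i, j] <- pp[i, j] + eps
    pm[i, j] <- pm[i, j] - eps
    g[i, j] <- (elastic_energy(struct, pp) - elastic_energy(struct, pm)) /
      (2 * eps)
  }
  g
}

# Small helper: a laminar channel grid and its analytic steady profile.
poiseuille_exact <- function(grid, dp) {
  y <- (seq_len(grid$ny) - 0.5) * grid$h
  dp * y * (grid$Ly - y) / (2 * grid$mu * grid$Lx)
}
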