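## Independent oracles used across the test files. All are deliberately
## naive (dense arithmetic, finite differences) and share no code with the
## implementation paths they check.

## Random symmetric matrix with entries in [-1, 1].
rand_sym <- function() {
  A <- matrix(stats::runif(9, -1, 1), 3, 3)
  (A + t(A)) / 2
}

## Random symmetric positive definite matrix, comfortably conditioned.
rand_spd <- function() {
  A <- matrix(stats::runif(9, -1, 1), 3, 3)
  crossprod(A) + diag(3)
}

## Random deformation gradient with det > 0 near the identity.
rand_F <- function(spread = 0.3) {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -spread, spread), 3, 3)
    if (det(F) > 0.1) return(F)
  }
}

## Brute-force invariant set computed by direct trace/determinant
## arithmetic, term by term.
oracle_invariants <- function(A, Ad) {
  tr <- function(M) M[1, 1] + M[2, 2] + M[3, 3]
  A2 <- A %*% A
  Ad2 <- Ad %*% Ad
  c(I1 = tr(A),
    I2 = 0.5 * (tr(A)^2 - tr(A2)),
    I3 = det(A),
    J1 = tr(Ad),
    J2 = tr(Ad2),
    J3 = det(Ad),
    J4 = tr(A %*% Ad),
    J5 = tr(A %*% Ad2),
    J6 = tr(A2 %*% Ad),
    J7 = tr(A2 %*% Ad2))
}

## Central finite difference of t -> Cbar(C(t)) along a matrix path C(t),
## used as the independent oracle for the chain-rule rate.
oracle_cbar_rate_fd <- function(Cfun, t, h = 1e-6) {
  cb <- function(tt) {
    C <- Cfun(tt)
    det(C)^(-1 / 3) * C
  }
  (cb(t + h) - cb(t - h)) / (2 * h)
}

## Numerical stress 2 * dW/dC by full-matrix central differences, treating
## each of the nine entries of C as independent (invariant-based energies
## yield a symmetric gradient automatically).
oracle_stress_from_energy <- function(W, C, h = 1e-6) {
  G <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Cp <- C; Cm <- C
    Cp[i, j] <- Cp[i, j] + h
    Cm[i, j] <- Cm[i, j] - h
    G[i, j] <- (W(Cp) - W(Cm)) / (2 * h)
  }
  2 * G
}

## Same for viscous potentials: 2 * dW/dCdot at fixed C.
oracle_stress_from_potential <- function(W, C, Cdot, h = 1e-6) {
  G <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Dp <- Cdot; Dm <- Cdot
    Dp[i, j] <- Dp[i, j] + h
    Dm[i, j] <- Dm[i, j] - h
    G[i, j] <- (W(C, Dp) - W(C, Dm)) / (2 * h)
  }
  2 * G
}

## Barred invariants of a (C, Cdot) pair, needed by the energy oracles.
oracle_barred <- function(C, Cdot = matrix(0, 3, 3)) {
  J <- sqrt(det(C))
  Cb <- J^(-2 / 3) * C
  tr <- function(M) sum(diag(M))
  Cbd <- J^(-2 / 3) * (Cdot - tr(solve(C) %*% Cdot) / 3 * C)
  list(J = J, Cbar = Cb, Cbardot = Cbd,
       I1b = tr(Cb), I2b = 0.5 * (tr(Cb)^2 - tr(Cb %*% Cb)),
       J2b = tr(Cbd %*% Cbd), J5b = tr(Cb %*% Cbd %*% Cbd))
}

## Dense multivariate-normal log density, computed with solve() and
## determinant() rather than a Cholesky factor.
oracle_mvn_logdens <- function(y, K) {
  n <- length(y)
  -0.5 * drop(t(y) %*% solve(K) %*% y) -
    0.5 * as.numeric(determinant(K, logarithm = TRUE)$modulus) -
    n / 2 * log(2 * pi)
}

## Uniaxial isochoric state at stretch lam and rate lamdot (closed forms).
uniaxial_point <- function(lam, lamdot = NULL) {
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  Fdot <- if (is.null(lamdot)) NULL else
    diag(c(lamdot, -lamdot / (2 * lam^1.5), -lamdot / (2 * lam^1.5)))
  deformation_point(F, Fdot)
}

shear_point <- function(gam, gamdot = NULL) {
  F <- diag(3); F[1, 2] <- gam
  Fdot <- if (is.null(gamdot)) NULL else {
    Fd <- matrix(0, 3, 3); Fd[1, 2] <- gamdot; Fd
  }
  deformation_point(F, Fdot)
}
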