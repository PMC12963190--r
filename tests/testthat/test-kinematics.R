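test_that("right Cauchy-Green tensor matches closed forms and rejects inverted states", {
  expect_equal(right_cauchy_green(diag(3)), diag(3))
  expect_equal(right_cauchy_green(diag(c(2, 1, 1))), diag(c(4, 1, 1)))
  ## isochoric uniaxial stretch at lambda = 1.25
  lam <- 1.25
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  expect_equal(right_cauchy_green(F), diag(c(1.5625, 0.8, 0.8)))
  expect_error(right_cauchy_green(diag(c(-1, 1, 1))), "det")
  expect_error(right_cauchy_green(matrix(0, 3, 3)), "det")
})

test_that("isochoric split yields unit-determinant Cbar and the right J", {
  sp <- isochoric_split(diag(3))
  expect_equal(sp$J, 1)
  expect_equal(sp$Cbar, diag(3))

  sp <- isochoric_split(diag(c(4, 1, 1)))
  expect_equal(sp$J, 2)
  expect_equal(sp$Cbar, 2^(-2 / 3) * diag(c(4, 1, 1)))
  expect_equal(det(sp$Cbar), 1, tolerance = 1e-12)

  C <- right_cauchy_green(diag(c(0.75, 1, 1)))
  expect_equal(isochoric_split(C)$J, 0.75)

  set.seed(11)
  for (i in 1:100) {
    sp <- isochoric_split(rand_spd())
    expect_lt(abs(det(sp$Cbar) - 1), 1e-10)
  }
  expect_error(isochoric_split(diag(c(-1, 1, 1))), "positive definite")
})

test_that("Cbar rate matches its special cases and the finite-difference oracle", {
  ## isochoric motion: J = 1 and tr(C^-1 Cdot) = 0, so the rate passes through
  p <- uniaxial_point(1.2, 10)
  expect_equal(cbar_rate(p$C, p$Cdot), p$Cdot, tolerance = 1e-12)

  ## pure dilation has no isochoric part
  expect_equal(cbar_rate(2 * diag(3), 0.7 * diag(3)), matrix(0, 3, 3),
               tolerance = 1e-12)

  ## random smooth SPD paths against central differences
  set.seed(21)
  for (i in 1:20) {
    A <- rand_sym(); B <- rand_sym()
    Cfun <- function(t) diag(3) + 0.5 * sin(t) * A + 0.25 * t * B +
      0.1 * t^2 * diag(3)
    t0 <- stats::runif(1, 0.2, 1)
    C <- Cfun(t0)
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < 0.2) next
    h <- 1e-5
    Cdot <- (Cfun(t0 + h) - Cfun(t0 - h)) / (2 * h)
    got <- cbar_rate(C, Cdot)
    want <- oracle_cbar_rate_fd(Cfun, t0)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("invariants match the undeformed state and brute-force arithmetic", {
  p0 <- deformation_point(diag(3))
  inv0 <- invariants(p0)
  expect_equal(unname(inv0[c("I1bar", "I2bar")]), c(3, 3))
  expect_equal(unname(inv0[paste0("Jbar", 1:7)]), rep(0, 7))

  ## Jbar1, Jbar4, Jbar6 vanish at C = I for any rate tensor
  set.seed(31)
  for (i in 1:100) {
    Cd <- rand_sym()
    inv <- invariants(diag(3), Cbardot = cbar_rate(diag(3), Cd), J = 1)
    expect_lt(abs(inv["Jbar1"]), 1e-12)
    expect_lt(abs(inv["Jbar4"]), 1e-12)
    expect_lt(abs(inv["Jbar6"]), 1e-12)
  }

  ## dynamic uniaxial state at lambda = 1.2, lamdot = 10 vs direct arithmetic
  p <- uniaxial_point(1.2, 10)
  inv <- invariants(p)
  want <- oracle_invariants(p$Cbar, p$Cbardot)
  expect_equal(unname(inv[c("I1bar", "I2bar")]),
               unname(want[c("I1", "I2")]), tolerance = 1e-12)
  expect_equal(unname(inv[paste0("Jbar", 1:7)]),
               unname(want[paste0("J", 1:7)]), tolerance = 1e-12)

  ## random states
  set.seed(32)
  for (i in 1:100) {
    C <- rand_spd(); Cd <- rand_sym()
    sp <- isochoric_split(C)
    Cbd <- cbar_rate(C, Cd)
    inv <- invariants(sp$Cbar, Cbardot = Cbd, J = sp$J)
    want <- oracle_invariants(sp$Cbar, Cbd)
    expect_equal(unname(inv[-1]),
                 unname(want[c("I1", "I2", paste0("J", 1:7))]),
                 tolerance = 1e-10)
  }
})

test_that("Lagrangian deviatoric operator is C-orthogonal", {
  expect_equal(Dev(diag(3), diag(3)), matrix(0, 3, 3))
  ## hand arithmetic: I : C = 6, C^-1 = diag(1/4, 1, 1)
  expect_equal(Dev(diag(3), diag(c(4, 1, 1))), diag(c(0.5, -1, -1)))
  set.seed(41)
  for (i in 1:50) {
    Z <- rand_sym(); C <- rand_spd()
    expect_lt(abs(ddot(Dev(Z, C), C)), 1e-10)
  }
})

test_that("integrity basis handles reference, dynamic and singular-rate states", {
  ## undeformed quasi-static state: G1 = I, everything else zero
  b <- integrity_basis(deformation_point(diag(3)))
  expect_equal(b$G$G1, diag(3))
  for (k in 2:8) expect_equal(b$G[[k]], matrix(0, 3, 3))
  expect_false(b$g6_valid)

  ## dynamic uniaxial: all eight finite, G6 valid, each Gi (i >= 2) C-orthogonal
  p <- uniaxial_point(1.2, 10)
  b <- integrity_basis(p)
  expect_true(b$g6_valid)
  for (k in 1:8) expect_true(all(is.finite(b$G[[k]])))
  for (k in 2:8) expect_lt(abs(ddot(b$G[[k]], p$C)), 1e-8)

  ## simple shear: det(Cbardot) = 0, G6 flagged invalid and zeroed
  p <- shear_point(0.3, 55)
  expect_lt(abs(det(p$Cbardot)), 1e-10)
  b <- integrity_basis(p)
  expect_false(b$g6_valid)
  expect_equal(b$G$G6, matrix(0, 3, 3))
})

test_that("Voigt vectorisation round-trips without shear weighting", {
  expect_equal(voigt(diag(3)), c(1, 1, 1, 0, 0, 0))
  set.seed(51)
  for (i in 1:20) {
    Z <- rand_sym()
    expect_identical(unvoigt(voigt(Z)), Z)
  }
  ## simple shear at gamma = 0.5: C = t(F) F with F12 = 0.5
  C <- right_cauchy_green(shear_point(0.5)$F)
  expect_equal(voigt(C), c(1, 1.25, 1, 0, 0, 0.5))
})

test_that("deformation points derive consistent kinematics from (F, Fdot)", {
  p <- uniaxial_point(1.3, 20)
  expect_equal(p$C, crossprod(p$F))
  expect_equal(p$J, 1, tolerance = 1e-12)
  ## Cdot = d/dt (t(F) F) by finite differences on the path
  h <- 1e-6
  lam2 <- 1.3 + 20 * h
  Cfd <- (crossprod(uniaxial_point(lam2)$F) -
            crossprod(uniaxial_point(1.3 - 20 * h)$F)) / (2 * h)
  expect_equal(p$Cdot, Cfd, tolerance = 1e-5)
  ## quasi-static states carry exactly zero rates
  q <- uniaxial_point(1.3)
  expect_identical(q$Cdot, matrix(0, 3, 3))
  expect_identical(q$Cbardot, matrix(0, 3, 3))
})
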