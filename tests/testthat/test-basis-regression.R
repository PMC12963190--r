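test_that("per-point solves recover the closed-form coefficients", {
  ## Simo-Miehe: zeta1 = kappa/2 * (J^2 - 1), an exact 1-column system
  kap <- 10
  for (J in c(0.75, 0.9, 1)) {
    p <- deformation_point(diag(c(J, 1, 1)))
    sol <- solve_point(simo_miehe_stress(p$C, kap), integrity_basis(p),
                       "vol", J = p$J)
    expect_equal(unname(sol$coef["zeta1"]), kap / 2 * (J^2 - 1),
                 tolerance = 1e-10)
    expect_lt(sol$residual, 1e-10)
  }

  ## Mooney-Rivlin: Gamma1 = 2(A10 + I1bar A01), Gamma2 = -2 A01.
  ## The coefficients are identifiable wherever Dev(I) and Dev(Cbar) are
  ## linearly independent -- true for shear and general states. (On purely
  ## uniaxial paths the two generators are parallel, the system is rank 1,
  ## and only the reconstructed stress is unique; see below.)
  A10 <- 1; A01 <- 0.5
  for (gam in c(0.1, 0.3, 0.5)) {
    p <- shear_point(gam)
    I1b <- sum(diag(p$Cbar))
    sol <- solve_point(mooney_rivlin_stress(p$C, A10, A01),
                       integrity_basis(p), "h_iso", J = p$J)
    expect_equal(unname(sol$coef["Gamma1"]), 2 * (A10 + I1b * A01),
                 tolerance = 1e-8)
    expect_equal(unname(sol$coef["Gamma2"]), -2 * A01, tolerance = 1e-8)
    expect_lt(sol$residual, 1e-10)
  }

  ## uniaxial record: rank-1 system, min-norm solution, exact reconstruction
  p <- uniaxial_point(1.15)
  basis <- integrity_basis(p)
  S <- mooney_rivlin_stress(p$C, A10, A01)
  sol <- solve_point(S, basis, "h_iso", J = p$J)
  expect_lt(sol$residual, 1e-10)
  expect_equal(reconstruct_stress(sol$coef, basis, "h_iso", J = p$J), S,
               tolerance = 1e-10)

  ## zero stress at the reference: the min-norm solution of the homogeneous
  ## system is identically zero
  p0 <- deformation_point(diag(3))
  sol <- solve_point(matrix(0, 3, 3), integrity_basis(p0), "vol", J = 1)
  expect_equal(unname(sol$coef), 0)
  p0r <- uniaxial_point(1, 10)
  sol <- solve_point(matrix(0, 3, 3), integrity_basis(p0r), "v_iso", J = 1)
  expect_equal(unname(sol$coef), rep(0, 7))
})

test_that("stress reconstruction round-trips even on rank-deficient systems", {
  ## dynamic uniaxial: the 7-column system has rank <= 2, yet the
  ## reconstructed stress is unique
  for (lam in c(1.1, 1.3, 1.5)) for (r in c(10, 100)) {
    p <- uniaxial_point(lam, r)
    S <- uss_stress(p$C, p$Cdot, 1, 1, 0.75)
    basis <- integrity_basis(p)
    sol <- solve_point(S, basis, "v_iso", J = p$J)
    A <- vapply(basis$G[2:8], voigt, numeric(6))
    expect_lte(qr(A)$rank, 2)
    S_rec <- reconstruct_stress(sol$coef, basis, "v_iso", J = p$J)
    expect_equal(S_rec, S, tolerance = 1e-8)
  }

  ## shear with singular Cbardot: Phi5 forced to zero, round trip still exact
  p <- shear_point(0.3, 55)
  S <- uss_stress(p$C, p$Cdot, 1, 1, 0.75)
  basis <- integrity_basis(p)
  sol <- solve_point(S, basis, "v_iso", J = p$J)
  expect_false(sol$g6_valid)
  expect_equal(unname(sol$coef["Phi5"]), 0)
  expect_equal(reconstruct_stress(sol$coef, basis, "v_iso", J = p$J), S,
               tolerance = 1e-8)
})

test_that("the invariant/coefficient dataset has the right shape and inputs", {
  vol <- generate_dataset(protocol_spec("confined_uniaxial", c(0.75, 1, 26)),
                          "simo_miehe")
  ds <- build_dstar(vol)
  expect_equal(nrow(ds), 26)
  expect_true(all(c("J", "zeta1", "residual") %in% names(ds)))
  expect_equal(ds$zeta1, 10 / 2 * (ds$J^2 - 1), tolerance = 1e-10)

  dyn <- generate_dataset(protocol_spec("uniaxial_isochoric", c(1, 1.5, 7),
                                        rates = c(10, 100)), "uss")
  dsv <- build_dstar(dyn)
  expect_equal(nrow(dsv), 14)
  expect_true(all(c("I1bar", "I2bar", "Jbar1", "Jbar4", "Jbar6",
                    paste0("Phi", 1:7)) %in% names(dsv)))
  ## omitted invariants never appear as inputs
  expect_false(any(c("Jbar2", "Jbar3", "Jbar5", "Jbar7") %in% names(dsv)))
  expect_lt(max(dsv$residual), 1e-8)
})

test_that("per-point solving is invariant to record order", {
  dyn <- generate_dataset(protocol_spec("uniaxial_isochoric", c(1, 1.4, 5),
                                        rates = c(10, 55)), "uss")
  ds1 <- build_dstar(dyn)
  perm <- c(7, 3, 10, 1, 5, 9, 2, 8, 4, 6)
  dyn2 <- dyn
  dyn2$points <- dyn$points[perm]
  dyn2$S <- dyn$S[perm]
  ds2 <- build_dstar(dyn2)
  num <- names(ds1)[names(ds1) != "g6_valid"]
  m1 <- as.matrix(ds1[, num]); rownames(m1) <- NULL
  m2 <- as.matrix(ds2[, num]); rownames(m2) <- NULL
  expect_identical(m1[perm, ], m2)   # bit-identical under permutation
})

test_that("inconsistent all-zero systems are rejected", {
  p0 <- deformation_point(diag(3))
  basis <- integrity_basis(p0)   # G2..G8 all vanish at the reference
  S <- diag(c(1, 1, 1))
  expect_error(solve_point(S, basis, "h_iso", J = 1), "inconsistent")
})
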