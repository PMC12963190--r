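test_that("protocol grids match the benchmark study designs", {
  spec <- protocol_spec("confined_uniaxial", c(0.75, 1, 26))
  pts <- generate_protocol(spec)
  expect_length(pts, 26)
  strains <- vapply(pts, attr, numeric(1), "strain")
  expect_equal(diff(strains)[1], 0.01, tolerance = 1e-12)
  expect_equal(pts[[26]]$F, diag(3))

  spec <- protocol_spec("uniaxial_isochoric", c(1, 1.5, 31),
                        rates = c(10, 32.5, 55, 77.5, 100))
  expect_length(generate_protocol(spec), 155)

  pts <- generate_protocol(protocol_spec("simple_shear", c(0, 0.5, 6)))
  expect_equal(pts[[1]]$F, diag(3))

  expect_error(protocol_spec("uniaxial_isochoric", c(-0.1, 1, 5)), "positive")
  expect_error(protocol_spec("confined_uniaxial", c(0.75, 1, 26), rates = 10),
               "quasi-static")
  expect_error(protocol_spec("confined_uniaxial", c(0.75, 1, 1)), "count")
})

test_that("volumetric laws match hand arithmetic and vanish at J = 1", {
  expect_equal(simo_miehe_stress(diag(3), 10), matrix(0, 3, 3))
  expect_equal(simo_miehe_stress(diag(c(4, 1, 1)), 0), matrix(0, 3, 3))
  C <- right_cauchy_green(diag(c(0.75, 1, 1)))
  S <- simo_miehe_stress(C, 10)
  expect_equal(S[1, 1], 5 * (0.5625 - 1) / 0.5625, tolerance = 1e-12)
  expect_equal(S[2, 2], -2.1875)
  expect_equal(S[3, 3], -2.1875)

  expect_equal(neo_hookean_vol_stress(diag(3), 10), matrix(0, 3, 3))
  S <- neo_hookean_vol_stress(C, 10)
  expect_equal(S[2, 2], 10 * 0.75 * (0.75 - 1))

  ## small-strain limit: S_NH / S_SM -> kappa_NH / kappa
  kap <- 10; kapNH <- 7
  for (J in c(1 + 1e-4, 1 - 1e-4)) {
    C <- diag(c(J^2, 1, 1))
    r <- neo_hookean_vol_stress(C, kapNH)[1, 1] /
      simo_miehe_stress(C, kap)[1, 1]
    expect_equal(r, kapNH / kap, tolerance = 1e-3)
  }
})

test_that("isochoric hyperelastic laws match their energy derivatives", {
  expect_equal(mooney_rivlin_stress(diag(3), 1, 0.5), matrix(0, 3, 3))
  expect_equal(yeoh_stress(diag(3), 1.46, -0.21), matrix(0, 3, 3))

  ## A01 = 0 leaves only the Dev(I) direction
  p <- uniaxial_point(1.2)
  S <- mooney_rivlin_stress(p$C, 2, 0)
  D <- Dev(diag(3), p$C)
  expect_equal(S / S[1, 1], D / D[1, 1], tolerance = 1e-12)

  ## C2 = 0 gives a constant coefficient 2*C1 on Dev(I)
  S <- yeoh_stress(p$C, 1.5, 0)
  expect_equal(S, 3 * D, tolerance = 1e-12)

  W_mr <- function(C) {
    b <- oracle_barred(C)
    1 * (b$I1b - 3) + 0.5 * (b$I2b - 3)
  }
  W_y <- function(C) {
    b <- oracle_barred(C)
    1.46 * (b$I1b - 3) - 0.21 * (b$I1b - 3)^2
  }
  C <- right_cauchy_green(uniaxial_point(1.25)$F)
  expect_equal(mooney_rivlin_stress(C, 1, 0.5),
               oracle_stress_from_energy(W_mr, C), tolerance = 1e-6)
  expect_equal(yeoh_stress(C, 1.46, -0.21),
               oracle_stress_from_energy(W_y, C), tolerance = 1e-6)

  ## random states
  set.seed(61)
  for (i in 1:20) {
    C <- rand_spd()
    expect_equal(mooney_rivlin_stress(C, 1, 0.5),
                 oracle_stress_from_energy(W_mr, C), tolerance = 1e-5)
  }
})

test_that("viscous overstress laws match their potential derivatives", {
  ## zero at the reference state for any rate (both sqrt factors vanish)
  set.seed(71)
  for (i in 1:10) {
    Cd <- rand_sym()
    expect_equal(uss_stress(diag(3), Cd, 1, 1, 0.75), matrix(0, 3, 3),
                 tolerance = 1e-12)
    expect_equal(pioletti_stress(diag(3), Cd, 6.94), matrix(0, 3, 3),
                 tolerance = 1e-12)
  }

  ## k21 = 0 leaves a term linear in k11
  p <- uniaxial_point(1.3, 55)
  expect_equal(uss_stress(p$C, p$Cdot, 2, 0, 0.75),
               2 * uss_stress(p$C, p$Cdot, 1, 0, 0.75), tolerance = 1e-12)
  ## Pioletti is linear in eta_prime
  expect_equal(pioletti_stress(p$C, p$Cdot, 13.88),
               2 * pioletti_stress(p$C, p$Cdot, 6.94), tolerance = 1e-12)

  W_uss <- function(C, Cdot) {
    b <- oracle_barred(C, Cdot)
    1 * b$J2b * sqrt(b$I1b - 3) + (1 / 0.75) * b$J5b^0.75 * sqrt(b$I2b - 3)
  }
  W_pl <- function(C, Cdot) {
    b <- oracle_barred(C, Cdot)
    6.94 / 4 * (b$I1b - 3) * b$J2b
  }
  p <- uniaxial_point(1.5, 100)
  expect_equal(uss_stress(p$C, p$Cdot, 1, 1, 0.75),
               oracle_stress_from_potential(W_uss, p$C, p$Cdot),
               tolerance = 1e-5)
  p <- uniaxial_point(1.2, 55)
  expect_equal(pioletti_stress(p$C, p$Cdot, 6.94),
               oracle_stress_from_potential(W_pl, p$C, p$Cdot),
               tolerance = 1e-6)

  ## the generating USS law is dissipative on tension and shear paths
  for (lam in seq(1.05, 1.5, by = 0.05)) for (r in c(10, 55, 100)) {
    p <- uniaxial_point(lam, r)
    expect_gte(ddot(uss_stress(p$C, p$Cdot, 1, 1, 0.75), p$Cdot), 0)
  }
  for (gam in seq(0.05, 0.5, by = 0.05)) for (r in c(10, 55, 145)) {
    p <- shear_point(gam, r)
    expect_gte(ddot(uss_stress(p$C, p$Cdot, 1, 1, 0.75), p$Cdot), 0)
  }
})

test_that("dataset generation enforces law/mode pairing and reproducible noise", {
  vol_spec <- protocol_spec("confined_uniaxial", c(0.75, 1, 26))
  ds <- generate_dataset(vol_spec, "simo_miehe")
  expect_length(ds, 26)
  expect_identical(ds$label, "vol")
  expect_equal(ds$S[[26]], matrix(0, 3, 3))

  dyn_spec <- protocol_spec("uniaxial_isochoric", c(1, 1.5, 31),
                            rates = c(10, 32.5, 55, 77.5, 100))
  expect_length(generate_dataset(dyn_spec, "uss"), 155)

  expect_error(generate_dataset(vol_spec, "mooney_rivlin"), "isochoric")
  expect_error(generate_dataset(dyn_spec, "simo_miehe"), "confined")
  expect_error(generate_dataset(protocol_spec("uniaxial_isochoric",
                                              c(1, 1.25, 5)), "uss"),
               "rated")

  ## noise: seeded, multiplicative, reference state exempt
  uni <- protocol_spec("uniaxial_isochoric", c(1, 1.25, 6))
  clean <- generate_dataset(uni, "mooney_rivlin")
  n1 <- generate_dataset(uni, "mooney_rivlin",
                         noise = list(sigma_rel = 0.05, seed = 7))
  n2 <- generate_dataset(uni, "mooney_rivlin",
                         noise = list(sigma_rel = 0.05, seed = 7))
  n3 <- generate_dataset(uni, "mooney_rivlin",
                         noise = list(sigma_rel = 0, seed = 7))
  expect_identical(n1$S, n2$S)
  expect_identical(n3$S, clean$S)
  expect_identical(n1$S[[1]], clean$S[[1]])     # reference record untouched
  expect_false(identical(n1$S[[3]], clean$S[[3]]))
})
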