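## Phenomenological material laws and loading protocols used to generate
## synthetic training/testing datasets: Simo-Miehe and neo-Hookean volumetric
## responses, Mooney-Rivlin and Yeoh isochoric hyperelasticity, and the USS
## and Pioletti viscous dissipation potentials.

#' Loading protocol specification
#'
#' Describes a uniform grid of deformation states for one of three standard
#' experimental modes:
#' \describe{
#'   \item{`confined_uniaxial`}{`F = diag(J, 1, 1)` with volumetric strain
#'     `J = det(F)`; quasi-static (confined compression/tension).}
#'   \item{`uniaxial_isochoric`}{`F = diag(lambda, 1/sqrt(lambda),
#'     1/sqrt(lambda))`; volume-preserving uniaxial stretch, quasi-static
#'     when `rates` is empty, otherwise one state per (stretch, rate) pair
#'     with the closed-form `Fdot`.}
#'   \item{`simple_shear`}{`F = I + gamma e1 (x) E2`; quasi-static when
#'     `rates` is empty.}
#' }
#'
#' @param mode One of `"confined_uniaxial"`, `"uniaxial_isochoric"`,
#'   `"simple_shear"`.
#' @param strain Numeric `c(start, stop, count)` defining a uniform strain
#'   grid (volumetric strain `J`, stretch `lambda`, or shear strain `gamma`).
#' @param rates Numeric vector of strain rates (`lambdadot` or `gammadot`);
#'   empty for quasi-static loading.
#' @return An object of class `"protocol_spec"`.
#' @export
protocol_spec <- function(mode = c("confined_uniaxial", "uniaxial_isochoric",
                                   "simple_shear"),
                          strain, rates = numeric(0)) {
  mode <- match.arg(mode)
  if (length(strain) != 3L || !is.numeric(strain) || strain[3] < 2)
    stop("strain must be c(start, stop, count) with count >= 2", call. = FALSE)
  grid <- seq(strain[1], strain[2], length.out = strain[3])
  if (mode %in% c("confined_uniaxial", "uniaxial_isochoric") && any(grid <= 0))
    stop("invalid grid: stretches/volume ratios must be positive",
         call. = FALSE)
  if (mode == "confined_uniaxial" && length(rates) > 0)
    stop("confined_uniaxial is a quasi-static protocol; rates must be empty",
         call. = FALSE)
  structure(list(mode = mode, strain = strain, grid = grid,
                 rates = as.numeric(rates)),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("Protocol:", x$mode, "\n")
  cat("  strain grid:", x$strain[1], "to", x$strain[2], "in", x$strain[3],
      "points\n")
  if (length(x$rates)) cat("  rates:", paste(x$rates, collapse = ", "), "\n")
  else cat("  quasi-static\n")
  invisible(x)
}

.protocol_F <- function(mode, s) {
  switch(mode,
    confined_uniaxial = diag(c(s, 1, 1)),
    uniaxial_isochoric = diag(c(s, 1 / sqrt(s), 1 / sqrt(s))),
    simple_shear = { F <- diag(3); F[1, 2] <- s; F })
}

.protocol_Fdot <- function(mode, s, rate) {
  switch(mode,
    uniaxial_isochoric = diag(c(rate, -rate / (2 * s^1.5),
                                -rate / (2 * s^1.5))),
    simple_shear = { Fd <- matrix(0, 3, 3); Fd[1, 2] <- rate; Fd })
}

#' Generate the deformation states of a protocol
#'
#' For quasi-static specs, one state per strain value with exactly zero rate
#' tensors; for rated specs, one state per (strain, rate) pair with the
#' closed-form deformation gradient rate.
#'
#' @param spec A `"protocol_spec"`.
#' @return A list of `"deformation_point"` objects; each carries `strain`,
#'   `rate` and `mode` attributes for bookkeeping.
#' @export
generate_protocol <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  quasi <- length(spec$rates) == 0
  combos <- if (quasi) {
    data.frame(strain = spec$grid, rate = 0)
  } else {
    expand.grid(strain = spec$grid, rate = spec$rates,
                KEEP.OUT.ATTRS = FALSE)
  }
  lapply(seq_len(nrow(combos)), function(i) {
    s <- combos$strain[i]; r <- combos$rate[i]
    F <- .protocol_F(spec$mode, s)
    Fdot <- if (quasi) NULL else .protocol_Fdot(spec$mode, s, r)
    pt <- deformation_point(F, Fdot)
    attr(pt, "strain") <- s
    attr(pt, "rate") <- r
    attr(pt, "mode") <- spec$mode
    pt
  })
}

#' Simo-Miehe volumetric stress
#'
#' `S_vol = kappa/2 * (J^2 - 1) * solve(C)`, the stress derived from the
#' volumetric energy `U(J) = kappa/2 * ((J^2 - 1)/2 - log(J))`.
#'
#' @param C Symmetric positive definite 3x3 matrix.
#' @param kappa Bulk modulus (> 0).
#' @return A symmetric 3x3 stress matrix.
#' @export
simo_miehe_stress <- function(C, kappa) {
  C <- .check_spd(C)
  J2 <- det(C)
  kappa / 2 * (J2 - 1) * solve(C)
}

#' Volumetric neo-Hookean stress
#'
#' `S_vol = kappa_NH * J * (J - 1) * solve(C)`, from
#' `U(J) = kappa_NH/2 * (J - 1)^2`.
#'
#' @param C Symmetric positive definite 3x3 matrix.
#' @param kappa_NH Bulk modulus (> 0).
#' @return A symmetric 3x3 stress matrix.
#' @export
neo_hookean_vol_stress <- function(C, kappa_NH) {
  C <- .check_spd(C)
  J <- sqrt(det(C))
  kappa_NH * J * (J - 1) * solve(C)
}

#' Mooney-Rivlin isochoric hyperelastic stress
#'
#' `S = J^(-2/3) * (2*(A10 + I1bar*A01) * Dev(I) - 2*A01 * Dev(Cbar))`, from
#' the energy `A10*(I1bar - 3) + A01*(I2bar - 3)`.
#'
#' @param C Symmetric positive definite 3x3 matrix.
#' @param A10,A01 Material parameters.
#' @return A symmetric 3x3 stress matrix.
#' @export
mooney_rivlin_stress <- function(C, A10, A01) {
  C <- .check_spd(C)
  sp <- isochoric_split(C)
  I1b <- sum(diag(sp$Cbar))
  sp$J^(-2 / 3) *
    (2 * (A10 + I1b * A01) * Dev(diag(3), C) - 2 * A01 * Dev(sp$Cbar, C))
}

#' Yeoh (2-parameter) isochoric hyperelastic stress
#'
#' `S = J^(-2/3) * (2*C1 + 4*C2*(I1bar - 3)) * Dev(I)`, from the energy
#' `C1*(I1bar - 3) + C2*(I1bar - 3)^2`.
#'
#' @param C Symmetric positive definite 3x3 matrix.
#' @param C1,C2 Material parameters.
#' @return A symmetric 3x3 stress matrix.
#' @export
yeoh_stress <- function(C, C1, C2) {
  C <- .check_spd(C)
  sp <- isochoric_split(C)
  I1b <- sum(diag(sp$Cbar))
  sp$J^(-2 / 3) * (2 * C1 + 4 * C2 * (I1b - 3)) * Dev(diag(3), C)
}

#' Upadhyay-Subhash-Spearot (USS) viscous overstress
#'
#' `S = J^(-2/3) * (4*k11*sqrt(I1bar - 3) * Dev(Cbardot)
#'   + 2*k21*Jbar5^(c21 - 1)*sqrt(I2bar - 3) * Dev(Cbar Cbardot + Cbardot
#'   Cbar))`, the stress of the dissipation potential
#' `k11*Jbar2*sqrt(I1bar - 3) + (k21/c21)*Jbar5^c21*sqrt(I2bar - 3)`.
#' At `C = I` both square-root factors vanish, so the overstress is zero for
#' any rate.
#'
#' @param C Symmetric positive definite 3x3 matrix.
#' @param Cdot Symmetric 3x3 rate matrix.
#' @param k11,k21 Linear and nonlinear rate-sensitivity parameters.
#' @param c21 Rate-sensitivity index (> 0).
#' @return A symmetric 3x3 stress matrix.
#' @export
uss_stress <- function(C, Cdot, k11, k21, c21) {
  C <- .check_spd(C)
  Cdot <- .check_sym(Cdot, "Cdot")
  sp <- isochoric_split(C)
  Cb <- sp$Cbar
  Cbd <- cbar_rate(C, Cdot)
  inv <- tensor_invariants(Cb, Cbd)
  I1b <- inv["I1"]; I2b <- inv["I2"]; J5b <- inv["J5"]
  ## det(Cbar)=1 guarantees I1bar,I2bar >= 3; clamp tiny negative round-off
  t1 <- sqrt(max(I1b - 3, 0))
  t2 <- sqrt(max(I2b - 3, 0))
  term1 <- 4 * k11 * t1 * Dev(Cbd, C)
  if (t2 == 0) return(term1)  # second term vanishes with its sqrt factor
  if (J5b < 0 && c21 != round(c21))
    stop("domain error: Jbar5 = ", format(J5b),
         " < 0 with non-integer exponent c21 = ", c21, call. = FALSE)
  M <- .sym(Cb %*% Cbd + Cbd %*% Cb)
  sp$J^(-2 / 3) * (term1 + 2 * k21 * J5b^(c21 - 1) * t2 * Dev(M, C))
}

#' Pioletti viscous overstress
#'
#' `S = J^(-2/3) * eta_prime * (I1bar - 3) * Dev(Cbardot)`, from the
#' dissipation potential `eta_prime/4 * (I1bar - 3) * Jbar2`.
#'
#' @param C Symmetric positive definite 3x3 matrix.
#' @param Cdot Symmetric 3x3 rate matrix.
#' @param eta_prime Viscosity parameter.
#' @return A symmetric 3x3 stress matrix.
#' @export
pioletti_stress <- function(C, Cdot, eta_prime) {
  C <- .check_spd(C)
  Cdot <- .check_sym(Cdot, "Cdot")
  sp <- isochoric_split(C)
  Cbd <- cbar_rate(C, Cdot)
  I1b <- sum(diag(sp$Cbar))
  sp$J^(-2 / 3) * eta_prime * (I1b - 3) * Dev(Cbd, C)
}

.law_registry <- list(
  simo_miehe    = list(label = "vol",   rated = FALSE,
                       fn = function(p, par) simo_miehe_stress(p$C, par$kappa)),
  neo_hookean   = list(label = "vol",   rated = FALSE,
                       fn = function(p, par) neo_hookean_vol_stress(p$C, par$kappa_NH)),
  mooney_rivlin = list(label = "h_iso", rated = FALSE,
                       fn = function(p, par) mooney_rivlin_stress(p$C, par$A10, par$A01)),
  yeoh          = list(label = "h_iso", rated = FALSE,
                       fn = function(p, par) yeoh_stress(p$C, par$C1, par$C2)),
  uss           = list(label = "v_iso", rated = TRUE,
                       fn = function(p, par) uss_stress(p$C, p$Cdot, par$k11, par$k21, par$c21)),
  pioletti      = list(label = "v_iso", rated = TRUE,
                       fn = function(p, par) pioletti_stress(p$C, p$Cdot, par$eta_prime))
)

#' Default material parameters
#'
#' The parameter values used throughout the benchmark studies: Simo-Miehe
#' `kappa = 10`, Mooney-Rivlin `A10 = 1`, `A01 = 0.5`, and USS `k11 = 1`,
#' `k21 = 1`, `c21 = 0.75` (in consistent stress/time units).
#'
#' @return A named list of parameters.
#' @export
default_material_params <- function() {
  list(kappa = 10, kappa_NH = 10, A10 = 1, A01 = 0.5,
       C1 = 1, C2 = 1, k11 = 1, k21 = 1, c21 = 0.75, eta_prime = 1)
}

#' Generate a synthetic stress-strain(-rate) dataset
#'
#' Evaluates a phenomenological law on every state of a protocol, producing
#' one of the three constituent datasets (`vol`, `h_iso` or `v_iso`) used to
#' train the surrogates. Volumetric laws require the confined mode; isochoric
#' hyperelastic laws a quasi-static isochoric mode; viscous laws a rated
#' mode. Optional multiplicative Gaussian noise `S * (1 + sigma_rel * eps)`
#' is applied component-wise, never at stress-free reference states.
#'
#' @param spec A `"protocol_spec"`.
#' @param law One of `"simo_miehe"`, `"neo_hookean"`, `"mooney_rivlin"`,
#'   `"yeoh"`, `"uss"`, `"pioletti"`.
#' @param params Named list of material parameters; missing entries take the
#'   defaults of [default_material_params()].
#' @param noise Optional `list(sigma_rel =, seed =)`.
#' @return An object of class `"vh_dataset"`: fields `points` (list of
#'   deformation states), `S` (list of stress matrices), `label`, `law`,
#'   `params`, `spec`, `noise`.
#' @export
generate_dataset <- function(spec, law, params = list(), noise = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  law <- match.arg(law, names(.law_registry))
  reg <- .law_registry[[law]]
  rated <- length(spec$rates) > 0
  if (reg$label == "vol" && spec$mode != "confined_uniaxial")
    stop("volumetric laws require the confined_uniaxial protocol",
         call. = FALSE)
  if (reg$label == "h_iso" && (spec$mode == "confined_uniaxial" || rated))
    stop("isochoric hyperelastic laws require a quasi-static isochoric protocol",
         call. = FALSE)
  if (reg$label == "v_iso" && !rated)
    stop("viscous overstress laws require a rated protocol", call. = FALSE)
  par <- utils::modifyList(default_material_params(), params)
  points <- generate_protocol(spec)
  S <- lapply(points, reg$fn, par = par)
  if (!is.null(noise) && noise$sigma_rel > 0) {
    S <- .apply_noise(S, noise$sigma_rel, noise$seed)
  }
  structure(list(points = points, S = S, label = reg$label, law = law,
                 params = par, spec = spec, noise = noise),
            class = "vh_dataset")
}

.apply_noise <- function(S, sigma_rel, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  lapply(S, function(Si) {
    if (max(abs(Si)) == 0) return(Si)  # reference state stays exact
    eps <- unvoigt(stats::rnorm(6))
    .sym(Si * (1 + sigma_rel * eps))
  })
}

#' @export
print.vh_dataset <- function(x, ...) {
  cat("Visco-hyperelastic dataset (", x$label, "): ",
      length(x$points), " records\n", sep = "")
  cat("  law:", x$law, " protocol:", x$spec$mode, "\n")
  if (!is.null(x$noise))
    cat("  noise: sigma_rel =", x$noise$sigma_rel,
        "seed =", x$noise$seed, "\n")
  invisible(x)
}

#' @export
length.vh_dataset <- function(x) length(x$points)
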