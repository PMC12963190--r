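## Finite-strain kinematics: right Cauchy-Green tensor, volumetric/isochoric
## split, scalar invariants, the Lagrangian deviatoric operator, and the
## isotropic integrity basis used by the surrogate stress representation.
## All tensors are 3x3 matrices in a fixed reference (Lagrangian) frame.

.sym <- function(Z) (Z + t(Z)) / 2

.check_sym <- function(Z, name = "Z", tol = 1e-8) {
  if (!is.matrix(Z) || !all(dim(Z) == c(3L, 3L)) || !is.numeric(Z))
    stop(name, " must be a numeric 3x3 matrix", call. = FALSE)
  if (!all(is.finite(Z)))
    stop(name, " has non-finite entries", call. = FALSE)
  scale <- max(abs(Z), 1)
  if (max(abs(Z - t(Z))) > tol * scale)
    stop(name, " must be symmetric", call. = FALSE)
  invisible(.sym(Z))
}

.check_spd <- function(C, name = "C") {
  C <- .check_sym(C, name)
  ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
  if (!ok) stop(name, " must be symmetric positive definite", call. = FALSE)
  C
}

#' Double contraction of two tensors
#'
#' Computes `A : B = sum_ij A_ij B_ij`.
#'
#' @param A,B 3x3 matrices.
#' @return A scalar.
#' @export
ddot <- function(A, B) sum(A * B)

#' Right Cauchy-Green deformation tensor
#'
#' Computes `C = t(F) %*% F` from a deformation gradient with positive
#' determinant.
#'
#' @param F A 3x3 deformation gradient matrix, `det(F) > 0`.
#' @return A symmetric 3x3 matrix.
#' @export
right_cauchy_green <- function(F) {
  if (!is.matrix(F) || !all(dim(F) == c(3L, 3L)) || !all(is.finite(F)))
    stop("F must be a finite numeric 3x3 matrix", call. = FALSE)
  if (det(F) <= 0)
    stop("invalid deformation: det(F) must be positive", call. = FALSE)
  .sym(crossprod(F))
}

#' Volumetric/isochoric split of the right Cauchy-Green tensor
#'
#' Splits `C = J^(2/3) * Cbar` with `J = sqrt(det(C))` and `det(Cbar) = 1`.
#'
#' @param C Symmetric positive definite 3x3 matrix.
#' @return A list with elements `J` (scalar) and `Cbar` (unit-determinant
#'   symmetric matrix).
#' @export
isochoric_split <- function(C) {
  C <- .check_spd(C)
  J <- sqrt(det(C))
  list(J = J, Cbar = J^(-2 / 3) * C)
}

#' Rate of the isochoric right Cauchy-Green tensor
#'
#' Exact chain-rule time derivative of `Cbar = J^(-2/3) C`:
#' `Cbardot = J^(-2/3) * (Cdot - tr(solve(C) %*% Cdot)/3 * C)`.
#' For isochoric motions (`tr(solve(C) %*% Cdot) = 0`, `J = 1`) this returns
#' `Cdot` unchanged; for pure dilations it returns zero.
#'
#' @param C Symmetric positive definite 3x3 matrix.
#' @param Cdot Symmetric 3x3 matrix, the material time derivative of `C`.
#' @return A symmetric 3x3 matrix.
#' @export
cbar_rate <- function(C, Cdot) {
  C <- .check_spd(C)
  Cdot <- .check_sym(Cdot, "Cdot")
  J <- sqrt(det(C))
  trace_term <- sum(diag(solve(C, Cdot)))
  J^(-2 / 3) * (Cdot - trace_term / 3 * C)
}

#' Construct a deformation state
#'
#' Bundles a deformation gradient (and optional rate) with all derived
#' kinematic quantities: `C`, `Cdot`, `J`, `Cbar`, `Cbardot`. When `Fdot` is
#' absent the state is quasi-static and the rate tensors are exactly zero.
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @param Fdot Optional 3x3 deformation gradient rate.
#' @return An object of class `"deformation_point"`.
#' @export
deformation_point <- function(F, Fdot = NULL) {
  C <- right_cauchy_green(F)
  if (is.null(Fdot)) {
    Cdot <- matrix(0, 3, 3)
  } else {
    if (!is.matrix(Fdot) || !all(dim(Fdot) == c(3L, 3L)) || !all(is.finite(Fdot)))
      stop("Fdot must be a finite numeric 3x3 matrix", call. = FALSE)
    Cdot <- .sym(crossprod(Fdot, F) + crossprod(F, Fdot))
  }
  .deformation_point_from_C(C, Cdot, F = F, Fdot = Fdot)
}

## Internal constructor used when only (C, Cdot) are known (e.g. file input).
.deformation_point_from_C <- function(C, Cdot, F = NULL, Fdot = NULL) {
  split <- isochoric_split(C)
  structure(
    list(F = F, Fdot = Fdot, C = C, Cdot = Cdot,
         J = split$J, Cbar = split$Cbar,
         Cbardot = cbar_rate(C, Cdot)),
    class = "deformation_point")
}

#' @export
print.deformation_point <- function(x, ...) {
  cat("Deformation state: J =", format(x$J, digits = 6),
      if (all(x$Cdot == 0)) "(quasi-static)" else "(rate-dependent)", "\n")
  cat("C:\n"); print(x$C)
  if (!all(x$Cdot == 0)) { cat("Cdot:\n"); print(x$Cdot) }
  invisible(x)
}

#' Scalar invariants of a strain/strain-rate pair
#'
#' The nine invariants of a tensor pair `(A, Adot)`: the principal invariants
#' `I1 = tr(A)`, `I2 = (tr(A)^2 - tr(A^2))/2`, `I3 = det(A)` and the rate
#' invariants `J1 = tr(Adot)`, `J2 = tr(Adot^2)`, `J3 = det(Adot)`,
#' `J4 = tr(A Adot)`, `J5 = tr(A Adot^2)`, `J6 = tr(A^2 Adot)`,
#' `J7 = tr(A^2 Adot^2)`.
#'
#' @param A,Adot Symmetric 3x3 matrices.
#' @return A named numeric vector `I1, I2, I3, J1, ..., J7`.
#' @export
tensor_invariants <- function(A, Adot = matrix(0, 3, 3)) {
  A2 <- A %*% A
  Ad2 <- Adot %*% Adot
  c(I1 = sum(diag(A)),
    I2 = 0.5 * (sum(diag(A))^2 - sum(diag(A2))),
    I3 = det(A),
    J1 = sum(diag(Adot)),
    J2 = sum(diag(Ad2)),
    J3 = det(Adot),
    J4 = sum(A * Adot),
    J5 = sum(diag(A %*% Ad2)),
    J6 = sum(A2 * Adot),
    J7 = sum(diag(A2 %*% Ad2)))
}

#' Barred (isochoric) invariant set of a deformation state
#'
#' Evaluates the invariants of `(Cbar, Cbardot)` together with the volume
#' ratio `J`. At the undeformed state (`Cbar = I`, `Cbardot = 0`) the set is
#' `I1bar = I2bar = 3` with all rate invariants zero; `Jbar1`, `Jbar4` and
#' `Jbar6` vanish at `C = I` for any rate tensor, which is what pins the
#' stress-free reference state to a single surrogate input.
#'
#' @param point A `"deformation_point"`, or a unit-determinant symmetric
#'   matrix `Cbar` (then `Cbardot` and `J` must be supplied).
#' @param Cbardot,J Used only when `point` is a plain matrix.
#' @param tol Relative tolerance on `det(Cbar) = 1`.
#' @return A named numeric vector
#'   `J, I1bar, I2bar, Jbar1, Jbar2, Jbar3, Jbar4, Jbar5, Jbar6, Jbar7`.
#' @export
invariants <- function(point, Cbardot = NULL, J = NULL, tol = 1e-8) {
  if (inherits(point, "deformation_point")) {
    Cbar <- point$Cbar; Cbardot <- point$Cbardot; J <- point$J
  } else {
    Cbar <- point
    if (is.null(Cbardot) || is.null(J))
      stop("Cbardot and J are required when passing a bare Cbar matrix",
           call. = FALSE)
  }
  if (abs(det(Cbar) - 1) > tol)
    stop("det(Cbar) must equal 1", call. = FALSE)
  inv <- tensor_invariants(Cbar, Cbardot)
  c(J = J,
    I1bar = unname(inv["I1"]), I2bar = unname(inv["I2"]),
    Jbar1 = unname(inv["J1"]), Jbar2 = unname(inv["J2"]),
    Jbar3 = unname(inv["J3"]), Jbar4 = unname(inv["J4"]),
    Jbar5 = unname(inv["J5"]), Jbar6 = unname(inv["J6"]),
    Jbar7 = unname(inv["J7"]))
}

#' Lagrangian deviatoric operator
#'
#' `Dev(Z) = Z - (Z : C)/3 * solve(C)`. The result is C-orthogonal:
#' `Dev(Z) : C = 0`.
#'
#' @param Z Symmetric 3x3 matrix.
#' @param C Symmetric positive definite 3x3 metric tensor.
#' @return A symmetric 3x3 matrix.
#' @export
Dev <- function(Z, C) {
  Z - ddot(Z, C) / 3 * solve(C)
}

#' Integrity basis of the stress representation
#'
#' The eight symmetric tensor generators whose linear combinations represent
#' every isotropic stress function of `(Cbar, Cbardot)`:
#' `G1 = solve(C)`, `G2 = Dev(I)`, `G3 = Dev(Cbar)`, `G4 = Dev(solve(Cbar))`,
#' `G5 = Dev(Cbardot)`, `G6 = Dev(solve(Cbardot))`,
#' `G7 = Dev(Cbar Cbardot + Cbardot Cbar)`,
#' `G8 = Dev(Cbar^2 Cbardot + Cbardot Cbar^2)`.
#'
#' `G6` requires inverting `Cbardot`; when `det(Cbardot)` is below `det_tol`
#' (relative to its magnitude), e.g. in simple shear or quasi-statics, `G6`
#' is returned as the zero tensor and flagged via `g6_valid = FALSE` so that
#' its coefficient can be dropped consistently at solve and predict time.
#'
#' @param point A `"deformation_point"`.
#' @param det_tol Relative tolerance below which `Cbardot` is treated as
#'   singular.
#' @return A list with elements `G` (list of eight 3x3 matrices) and
#'   `g6_valid` (logical).
#' @export
integrity_basis <- function(point, det_tol = 1e-10) {
  stopifnot(inherits(point, "deformation_point"))
  C <- point$C; Cb <- point$Cbar; Cbd <- point$Cbardot
  I3 <- diag(3)
  scale <- max(abs(Cbd))
  g6_valid <- scale > 0 && abs(det(Cbd)) > det_tol * scale^3
  Cb2 <- Cb %*% Cb
  G <- list(
    G1 = solve(C),
    G2 = Dev(I3, C),
    G3 = Dev(Cb, C),
    G4 = Dev(solve(Cb), C),
    G5 = Dev(Cbd, C),
    G6 = if (g6_valid) Dev(solve(Cbd), C) else matrix(0, 3, 3),
    G7 = Dev(.sym(Cb %*% Cbd + Cbd %*% Cb), C),
    G8 = Dev(.sym(Cb2 %*% Cbd + Cbd %*% Cb2), C))
  list(G = lapply(G, .sym), g6_valid = g6_valid)
}

#' Voigt vectorisation of a symmetric tensor
#'
#' Orders the six independent components as
#' `[Z11, Z22, Z33, Z23, Z13, Z12]`, with no engineering-shear doubling, so
#' `unvoigt(voigt(Z))` is a lossless round trip.
#'
#' @param Z Symmetric 3x3 matrix.
#' @return A numeric vector of length 6.
#' @export
voigt <- function(Z) {
  c(Z[1, 1], Z[2, 2], Z[3, 3], Z[2, 3], Z[1, 3], Z[1, 2])
}

#' @rdname voigt
#' @param v Numeric vector of length 6 in Voigt order.
#' @export
unvoigt <- function(v) {
  stopifnot(length(v) == 6L)
  matrix(c(v[1], v[6], v[5],
           v[6], v[2], v[4],
           v[5], v[4], v[3]), 3, 3, byrow = TRUE)
}
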