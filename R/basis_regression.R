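## Per-point conversion of stress-strain(-rate) records into integrity-basis
## coefficients: each data point yields a 6-row linear system relating the
## Voigt stress vector to the Voigt forms of the relevant basis tensors.

#' Minimum-norm least squares with singular-value thresholding
#'
#' Solves `min ||A x - b||_2`, returning the minimum-norm minimiser when the
#' system is rank deficient. Singular values below `rcond * max(d)` are
#' truncated.
#'
#' @param A Numeric matrix.
#' @param b Numeric vector.
#' @param rcond Relative singular-value threshold.
#' @return A list with `x` (coefficients) and `residual` (`||Ax - b||_2`).
#' @keywords internal
.min_norm_lstsq <- function(A, b, rcond = 1e-10) {
  sv <- svd(A)
  d <- sv$d
  keep <- d > rcond * max(d, 0)
  if (!any(keep)) {
    x <- rep(0, ncol(A))
  } else {
    dinv <- ifelse(keep, 1 / d, 0)
    x <- sv$v %*% (dinv * crossprod(sv$u, b))
  }
  x <- drop(x)
  list(x = x, residual = sqrt(sum((A %*% x - b)^2)))
}

.variant_info <- list(
  vol   = list(cols = 1L,   coef = "zeta1",
               inputs = "J"),
  h_iso = list(cols = 2:3,  coef = c("Gamma1", "Gamma2"),
               inputs = c("I1bar", "I2bar")),
  v_iso = list(cols = 2:8,  coef = paste0("Phi", 1:7),
               inputs = c("I1bar", "I2bar", "Jbar1", "Jbar4", "Jbar6"))
)

#' Solve the per-point coefficient system
#'
#' Inverts the linear relation between a stress tensor and the integrity
#' basis evaluated at the same deformation state. The volumetric variant
#' solves `vec(S) = vec(G1) * zeta1`; the isochoric variants first divide
#' the `J^(-2/3)` prefactor out of the stress and use columns
#' `[vec(G2) vec(G3)]` (hyperelastic) or `[vec(G2) ... vec(G8)]` (viscous).
#' Rank-deficient systems (typical for the 7-column viscous solve on
#' uniaxial data) return the minimum-norm solution; an invalid `G6` enters
#' as a zero column, forcing `Phi5 = 0`.
#'
#' @param S Symmetric 3x3 stress matrix.
#' @param basis Output of [integrity_basis()] at the same state.
#' @param variant `"vol"`, `"h_iso"` or `"v_iso"`.
#' @param J Volume ratio of the state (used for the `J^(-2/3)` scaling).
#' @param rcond Relative singular-value threshold.
#' @return A list with `coef` (named vector), `residual`, and `g6_valid`.
#' @export
solve_point <- function(S, basis, variant = c("vol", "h_iso", "v_iso"),
                        J = 1, rcond = 1e-10) {
  variant <- match.arg(variant)
  info <- .variant_info[[variant]]
  A <- vapply(basis$G[info$cols], voigt, numeric(6))
  b <- voigt(S)
  if (variant != "vol") b <- b * J^(2 / 3)
  if (max(abs(A)) == 0) {
    if (max(abs(b)) > 0)
      stop("inconsistent system: zero basis with non-zero stress",
           call. = FALSE)
    return(list(coef = stats::setNames(rep(0, length(info$coef)), info$coef),
                residual = 0, g6_valid = basis$g6_valid))
  }
  sol <- .min_norm_lstsq(A, b, rcond)
  list(coef = stats::setNames(sol$x, info$coef),
       residual = sol$residual, g6_valid = basis$g6_valid)
}

#' Build the invariant/coefficient training set
#'
#' Applies [solve_point()] to every record of a dataset, pairing each
#' record's invariant subset with its recovered coefficients. The inputs are
#' `J` (volumetric), `(I1bar, I2bar)` (hyperelastic), or
#' `(I1bar, I2bar, Jbar1, Jbar4, Jbar6)` (viscous; the remaining rate
#' invariants are omitted so that the undeformed state maps to the single
#' input `[3, 3, 0, 0, 0]` regardless of rate). Stress-free reference
#' records are solved like any other (giving zero coefficients) and kept.
#'
#' @param dataset A `"vh_dataset"`.
#' @param rcond Relative singular-value threshold for the per-point solves.
#' @return A data frame (class `"dstar"`) with the variant's input columns,
#'   coefficient columns, `residual`, and bookkeeping columns `strain`,
#'   `rate`, `g6_valid`; the variant is stored in `attr(, "variant")`.
#' @export
build_dstar <- function(dataset, rcond = 1e-10) {
  stopifnot(inherits(dataset, "vh_dataset"))
  variant <- dataset$label
  info <- .variant_info[[variant]]
  n <- length(dataset$points)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pt <- dataset$points[[i]]
    inv <- invariants(pt)
    basis <- integrity_basis(pt)
    sol <- solve_point(dataset$S[[i]], basis, variant, J = pt$J,
                       rcond = rcond)
    rows[[i]] <- c(inv[info$inputs], sol$coef,
                   residual = sol$residual,
                   strain = attr(pt, "strain") %||% NA_real_,
                   rate = attr(pt, "rate") %||% NA_real_,
                   g6_valid = as.numeric(sol$g6_valid))
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$g6_valid <- as.logical(out$g6_valid)
  attr(out, "variant") <- variant
  class(out) <- c("dstar", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct a stress tensor from integrity-basis coefficients
#'
#' Assembles `S = zeta1 * G1` (volumetric) or
#' `S = J^(-2/3) * sum_i x_i * G_i` (isochoric variants) from a coefficient
#' vector and a basis. Terms whose basis tensor is flagged invalid (`G6`
#' when `Cbardot` is singular) are dropped.
#'
#' @param coef Named or ordered coefficient vector for the variant.
#' @param basis Output of [integrity_basis()].
#' @param variant `"vol"`, `"h_iso"` or `"v_iso"`.
#' @param J Volume ratio of the state.
#' @return A symmetric 3x3 stress matrix.
#' @export
reconstruct_stress <- function(coef, basis, variant = c("vol", "h_iso", "v_iso"),
                               J = 1) {
  variant <- match.arg(variant)
  info <- .variant_info[[variant]]
  S <- matrix(0, 3, 3)
  for (k in seq_along(info$cols)) {
    S <- S + coef[[k]] * basis$G[[info$cols[k]]]
  }
  if (variant != "vol") S <- J^(-2 / 3) * S
  S
}
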