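## The three surrogate constitutive mappings -- volumetric, isochoric
## hyperelastic, and isochoric viscous overstress -- and the classed model
## object that assembles them into a full stress predictor.

.reference_input <- list(
  vol   = c(J = 1),
  h_iso = c(I1bar = 3, I2bar = 3),
  v_iso = c(I1bar = 3, I2bar = 3, Jbar1 = 0, Jbar4 = 0, Jbar6 = 0)
)

#' Default per-point noise policy
#'
#' The stabilisation noise assigned to each training record: the volumetric
#' surrogate uses `1e-4` at every point; the isochoric surrogates use `1e-5`
#' at stress-free reference records (to pin the normalization condition via
#' exact inference) and `1e-2` elsewhere (for fitting flexibility).
#'
#' @param variant `"vol"`, `"h_iso"` or `"v_iso"`.
#' @param is_reference Logical vector marking reference records.
#' @return A numeric vector of noise values.
#' @export
alpha_policy_default <- function(variant, is_reference) {
  if (variant == "vol") rep(1e-4, length(is_reference))
  else ifelse(is_reference, 1e-5, 1e-2)
}

## Rows whose inputs coincide with the reference input of the variant.
.is_reference_row <- function(X, variant, tol = 1e-9) {
  ref <- .reference_input[[variant]]
  apply(X, 1, function(r) all(abs(r - ref) <= tol))
}

## Constraint functionals for the dissipation inequality: at each point,
## Xi = sum_i Phi_i * (J^(-2/3) G_{i+1} : Cdot), a linear functional of the
## predicted coefficient vector.
.dissipation_constraints <- function(points) {
  Xc <- t(vapply(points, function(p)
    invariants(p)[.variant_info$v_iso$inputs], numeric(5)))
  W <- t(vapply(points, function(p) {
    basis <- integrity_basis(p)
    vapply(basis$G[.variant_info$v_iso$cols], function(G)
      p$J^(-2 / 3) * ddot(G, p$Cdot), numeric(1))
  }, numeric(7)))
  list(Xc = Xc, W = W)
}

#' Train one surrogate mapping
#'
#' Fits the GP regression from a variant's invariant inputs to its
#' integrity-basis coefficients. The stress-free reference record is
#' appended (with zero outputs) if absent, duplicated reference inputs are
#' collapsed to a single record to keep the covariance matrix invertible,
#' and the viscous variant is fitted with the dissipation inequality
#' enforced at the supplied constraint points (by default, all training
#' deformation states).
#'
#' @param dstar A `"dstar"` data frame from [build_dstar()].
#' @param variant `"vol"`, `"h_iso"` or `"v_iso"`; defaults to the variant
#'   recorded on `dstar`.
#' @param alpha Optional per-point noise vector (after reference collapsing);
#'   defaults to [alpha_policy_default()].
#' @param constraint_points List of `"deformation_point"` objects at which
#'   the dissipation inequality is enforced (viscous variant only).
#' @param config A [gp_config()].
#' @return An object of class `"surrogate_model"`.
#' @export
train_surrogate <- function(dstar, variant = attr(dstar, "variant"),
                            alpha = NULL, constraint_points = NULL,
                            config = gp_config()) {
  variant <- match.arg(variant, c("vol", "h_iso", "v_iso"))
  info <- .variant_info[[variant]]
  X <- as.matrix(dstar[, info$inputs, drop = FALSE])
  Y <- as.matrix(dstar[, info$coef, drop = FALSE])
  is_ref <- .is_reference_row(X, variant)
  if (!any(is_ref)) {
    X <- rbind(X, .reference_input[[variant]])
    Y <- rbind(Y, rep(0, ncol(Y)))
    is_ref <- c(is_ref, TRUE)
  }
  ## collapse duplicated reference inputs: all map to the same invariant
  ## vector, so keep the first occurrence only (K stays invertible)
  keep <- !(is_ref & cumsum(is_ref) > 1)
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  is_ref <- is_ref[keep]
  if (is.null(alpha)) alpha <- alpha_policy_default(variant, is_ref)
  stopifnot(length(alpha) == nrow(X))
  if (variant == "v_iso" && !is.null(constraint_points)) {
    constraints <- .dissipation_constraints(constraint_points)
    gp <- gp_fit_constrained(X, Y, alpha, constraints, config)
  } else {
    gp <- gp_fit(X, Y, alpha, config)
  }
  structure(list(variant = variant, gp = gp, inputs = info$inputs,
                 coef_names = info$coef, n_train = nrow(X)),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat("Surrogate mapping (", x$variant, "): [",
      paste(x$inputs, collapse = ", "), "] -> [",
      paste(x$coef_names, collapse = ", "), "]\n", sep = "")
  print(x$gp)
  invisible(x)
}

#' Predict integrity-basis coefficients from a surrogate
#'
#' @param object A `"surrogate_model"`.
#' @param points A list of `"deformation_point"` objects (or a single one).
#' @param ... Unused.
#' @return A matrix of predicted coefficients (one row per point).
#' @export
predict.surrogate_model <- function(object, points, ...) {
  if (inherits(points, "deformation_point")) points <- list(points)
  X <- t(vapply(points, function(p) invariants(p)[object$inputs],
                numeric(length(object$inputs))))
  pred <- gp_predict(object$gp, X)$mean
  colnames(pred) <- object$coef_names
  pred
}

#' Fit a physics-informed data-driven constitutive model
#'
#' The main fitting entry point. Takes one dataset per stress component
#' (volumetric, isochoric hyperelastic, isochoric viscous overstress),
#' converts each to its invariant/coefficient form, and trains the
#' corresponding GP surrogate. The viscous surrogate is trained with the
#' dissipation inequality (second law) enforced at its own training states
#' unless `constrain = FALSE`.
#'
#' @param vol,h_iso,v_iso Optional `"vh_dataset"` objects, one per stress
#'   component. At least one must be given.
#' @param rcond Singular-value threshold for the per-point coefficient
#'   solves.
#' @param constrain Logical; enforce the dissipation inequality on the
#'   viscous surrogate.
#' @param config A [gp_config()].
#' @return An object of class `"constitutive_model"` with one trained
#'   `"surrogate_model"` per supplied component.
#' @export
fit_constitutive <- function(vol = NULL, h_iso = NULL, v_iso = NULL,
                             rcond = 1e-10, constrain = TRUE,
                             config = gp_config()) {
  datasets <- list(vol = vol, h_iso = h_iso, v_iso = v_iso)
  datasets <- datasets[!vapply(datasets, is.null, logical(1))]
  if (!length(datasets))
    stop("at least one dataset must be supplied", call. = FALSE)
  surrogates <- list()
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    stopifnot(inherits(ds, "vh_dataset"))
    if (ds$label != nm)
      stop("dataset passed as '", nm, "' is labelled '", ds$label, "'",
           call. = FALSE)
    dstar <- build_dstar(ds, rcond = rcond)
    cpts <- if (nm == "v_iso" && constrain) ds$points else NULL
    surrogates[[nm]] <- train_surrogate(dstar, variant = nm,
                                        constraint_points = cpts,
                                        config = config)
  }
  structure(list(surrogates = surrogates, config = config, rcond = rcond),
            class = "constitutive_model")
}

#' Predict the stress decomposition at a deformation state
#'
#' Predicts coefficients from each trained surrogate at the state's
#' invariants and assembles them against the state's integrity basis.
#' Components without a trained surrogate are returned as zero and flagged.
#' When `Cbardot` is singular the `Phi5 * G6` term is dropped, mirroring
#' training.
#'
#' @param model A `"constitutive_model"`.
#' @param point A `"deformation_point"`.
#' @return A list with `S_vol`, `S_h_iso`, `S_v_iso`, `S_total` (3x3
#'   matrices) and `available` (named logical vector).
#' @export
predict_stress <- function(model, point) {
  stopifnot(inherits(model, "constitutive_model"),
            inherits(point, "deformation_point"))
  basis <- integrity_basis(point)
  out <- list(S_vol = matrix(0, 3, 3), S_h_iso = matrix(0, 3, 3),
              S_v_iso = matrix(0, 3, 3))
  available <- c(vol = FALSE, h_iso = FALSE, v_iso = FALSE)
  for (nm in names(model$surrogates)) {
    coef <- drop(predict(model$surrogates[[nm]], point))
    out[[paste0("S_", nm)]] <- reconstruct_stress(coef, basis, nm,
                                                  J = point$J)
    available[nm] <- TRUE
  }
  out$S_total <- out$S_vol + out$S_h_iso + out$S_v_iso
  out$available <- available
  out
}

#' Internal viscous dissipation
#'
#' `Xi = S_v,iso : Cdot`, the Clausius-Planck internal dissipation of the
#' viscous overstress; equal to `2 (F S_v,iso) : Fdot`.
#'
#' @param S_v_iso Symmetric 3x3 viscous overstress matrix.
#' @param Cdot Symmetric 3x3 rate matrix.
#' @return A scalar.
#' @export
dissipation <- function(S_v_iso, Cdot) ddot(S_v_iso, Cdot)

#' @export
print.constitutive_model <- function(x, ...) {
  cat("Physics-informed data-driven constitutive model\n")
  cat("Components:", paste(names(x$surrogates), collapse = ", "), "\n")
  for (s in x$surrogates) print(s)
  invisible(x)
}

#' @export
summary.constitutive_model <- function(object, ...) {
  comp <- do.call(rbind, lapply(names(object$surrogates), function(nm) {
    s <- object$surrogates[[nm]]
    data.frame(component = nm, n_train = s$n_train,
               sigma_f = s$gp$theta[1], l = s$gp$theta[2],
               lml = s$gp$lml, constrained = s$gp$constrained)
  }))
  rownames(comp) <- NULL
  structure(list(components = comp), class = "summary.constitutive_model")
}

#' @export
print.summary.constitutive_model <- function(x, ...) {
  cat("Constitutive model summary\n")
  print(x$components)
  invisible(x)
}

#' @export
coef.constitutive_model <- function(object, ...) {
  sapply(object$surrogates, function(s) s$gp$theta)
}

#' Predict stresses for a set of deformation states
#'
#' @param object A `"constitutive_model"`.
#' @param newdata A `"deformation_point"`, a list of them, or a
#'   `"protocol_spec"` (expanded via [generate_protocol()]).
#' @param ... Unused.
#' @return A list of [predict_stress()] results, one per state.
#' @export
predict.constitutive_model <- function(object, newdata, ...) {
  if (inherits(newdata, "protocol_spec")) newdata <- generate_protocol(newdata)
  if (inherits(newdata, "deformation_point")) newdata <- list(newdata)
  lapply(newdata, function(p) predict_stress(object, p))
}
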