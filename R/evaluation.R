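## Error metrics, conventional-model calibration baselines, the classical
## black-box strain-to-stress GPR baseline, and benchmark case runners.

#' Percent relative stress error
#'
#' `err = 100 * ||vec(S_pred) - vec(S_true)|| / ||vec(S_true)||` using the
#' 6-entry Voigt norm (each distinct component counted once). The caller is
#' responsible for excluding stress-free reference states, where the
#' denominator vanishes.
#'
#' @param S_pred,S_true Symmetric 3x3 stress matrices.
#' @return A scalar percentage.
#' @export
percent_err <- function(S_pred, S_true) {
  denom <- sqrt(sum(voigt(S_true)^2))
  if (denom == 0)
    stop("percent_err is undefined at a zero true stress; exclude reference states",
         call. = FALSE)
  100 * sqrt(sum((voigt(S_pred) - voigt(S_true))^2)) / denom
}

## Mean percent error over paired stress lists, skipping zero-stress records.
.mean_err <- function(S_pred, S_true) {
  errs <- mapply(function(p, t) {
    if (max(abs(t)) == 0) NA_real_ else percent_err(p, t)
  }, S_pred, S_true)
  mean(errs, na.rm = TRUE)
}

#' Calibrate the volumetric neo-Hookean model
#'
#' Linear least squares for the single bulk modulus of
#' `S = kappa_NH * J * (J - 1) * solve(C)` against a volumetric dataset,
#' using all six Voigt stress rows of every record (the reference state
#' contributes a zero row and is retained).
#'
#' @param dataset A `"vh_dataset"` with label `"vol"`.
#' @return The fitted `kappa_NH`.
#' @export
calibrate_neo_hookean <- function(dataset) {
  stopifnot(inherits(dataset, "vh_dataset"), dataset$label == "vol")
  a <- c(); b <- c()
  for (i in seq_along(dataset$points)) {
    p <- dataset$points[[i]]
    a <- c(a, p$J * (p$J - 1) * voigt(solve(p$C)))
    b <- c(b, voigt(dataset$S[[i]]))
  }
  if (sum(a^2) == 0)
    stop("degenerate design: all records are at J = 1", call. = FALSE)
  sum(a * b) / sum(a^2)
}

#' Calibrate the 2-parameter Yeoh model
#'
#' Linear least squares of the Yeoh 11-stress-component against the
#' 11-component of a uniaxial hyperelastic dataset (only the loading-
#' direction component enters the fit).
#'
#' @param dataset A `"vh_dataset"` with label `"h_iso"`.
#' @return Named vector `c(C1, C2)`.
#' @export
calibrate_yeoh <- function(dataset) {
  stopifnot(inherits(dataset, "vh_dataset"), dataset$label == "h_iso")
  X <- NULL; y <- c()
  for (i in seq_along(dataset$points)) {
    p <- dataset$points[[i]]
    I1b <- sum(diag(p$Cbar))
    d11 <- Dev(diag(3), p$C)[1, 1] * p$J^(-2 / 3)
    X <- rbind(X, c(2 * d11, 4 * (I1b - 3) * d11))
    y <- c(y, dataset$S[[i]][1, 1])
  }
  if (qr(X)$rank < 2)
    stop("rank-deficient design for the Yeoh calibration", call. = FALSE)
  stats::setNames(drop(qr.solve(X, y)), c("C1", "C2"))
}

#' Calibrate the Pioletti model
#'
#' Least squares of the Pioletti 11-stress-component against the
#' 11-component of a dynamic uniaxial dataset across the full
#' stretch/stretch-rate grid. The model is linear in `eta_prime`, so the
#' closed-form linear solution is used (it coincides with an iterative
#' nonlinear solve).
#'
#' @param dataset A `"vh_dataset"` with label `"v_iso"`.
#' @return The fitted `eta_prime`.
#' @export
calibrate_pioletti <- function(dataset) {
  stopifnot(inherits(dataset, "vh_dataset"), dataset$label == "v_iso")
  num <- 0; den <- 0
  for (i in seq_along(dataset$points)) {
    p <- dataset$points[[i]]
    I1b <- sum(diag(p$Cbar))
    x <- p$J^(-2 / 3) * (I1b - 3) * Dev(p$Cbardot, p$C)[1, 1]
    num <- num + x * dataset$S[[i]][1, 1]
    den <- den + x^2
  }
  if (den == 0)
    stop("degenerate design: no rate-dependent records", call. = FALSE)
  num / den
}

#' Train the classical black-box mapping baseline
#'
#' Standard GPR from `[vec(C); vec(Cdot)]` (strain and strain rate) directly
#' to `vec(S)`, with the same Matern-3/2 kernel and noise policy as the
#' surrogates. For quasi-static datasets the `Cdot` block is omitted.
#'
#' @param dataset A `"vh_dataset"`.
#' @param config A [gp_config()].
#' @return An object of class `"classical_baseline"`.
#' @export
classical_baseline_train <- function(dataset, config = gp_config()) {
  stopifnot(inherits(dataset, "vh_dataset"))
  rated <- any(vapply(dataset$points, function(p) any(p$Cdot != 0),
                      logical(1)))
  X <- t(vapply(dataset$points, function(p)
    if (rated) c(voigt(p$C), voigt(p$Cdot)) else voigt(p$C),
    numeric(if (rated) 12 else 6)))
  Y <- t(vapply(dataset$S, voigt, numeric(6)))
  is_ref <- vapply(dataset$S, function(S) max(abs(S)) == 0, logical(1))
  alpha <- alpha_policy_default(dataset$label, is_ref)
  keep <- !duplicated(X)
  gp <- gp_fit(X[keep, , drop = FALSE], Y[keep, , drop = FALSE],
               alpha[keep], config)
  structure(list(gp = gp, rated = rated), class = "classical_baseline")
}

#' Predict stress from the classical baseline
#'
#' @param model A `"classical_baseline"`.
#' @param point A `"deformation_point"`.
#' @return A symmetric 3x3 stress matrix (symmetric by construction, since
#'   the model predicts the 6 Voigt components).
#' @export
classical_baseline_predict <- function(model, point) {
  stopifnot(inherits(model, "classical_baseline"))
  x <- if (model$rated) c(voigt(point$C), voigt(point$Cdot))
       else voigt(point$C)
  unvoigt(drop(gp_predict(model$gp, matrix(x, nrow = 1))$mean))
}

.case_setups <- list(
  vol = list(
    law = "simo_miehe", baseline_law = "neo_hookean",
    spec = function() protocol_spec("confined_uniaxial", c(0.75, 1, 26))),
  h_iso = list(
    law = "mooney_rivlin", baseline_law = "yeoh",
    spec = function() protocol_spec("uniaxial_isochoric", c(1, 1.25, 26))),
  v_iso = list(
    law = "uss", baseline_law = "pioletti",
    spec = function() protocol_spec("uniaxial_isochoric", c(1, 1.5, 31),
                                    rates = c(10, 32.5, 55, 77.5, 100)))
)

#' Run one benchmark study
#'
#' Reproduces one of the three benchmark cases end to end: generate the
#' training dataset from the case's phenomenological law on its printed
#' training grid, train the GP surrogate (with dissipation constraints for
#' the viscous case), calibrate the conventional comparison model, train
#' the classical black-box baseline, and evaluate training-regime mean
#' percent relative errors for all three (stress-free reference records
#' excluded; for the viscous case errors are averaged over all points and
#' rates).
#'
#' @param case `"vol"`, `"h_iso"` or `"v_iso"`.
#' @param config A [gp_config()].
#' @param include_classical Logical; train and score the classical mapping
#'   baseline.
#' @param noise Optional noise spec forwarded to [generate_dataset()].
#' @return A list of class `"case_report"`: the calibrated conventional
#'   parameters, the trained model(s), per-model training-regime mean
#'   errors, per-point error tables, and dissipation values at the training
#'   states (viscous case).
#' @export
run_case <- function(case = c("vol", "h_iso", "v_iso"),
                     config = gp_config(), include_classical = FALSE,
                     noise = NULL) {
  case <- match.arg(case)
  setup <- .case_setups[[case]]
  dataset <- generate_dataset(setup$spec(), setup$law, noise = noise)

  args <- list(rcond = 1e-10, config = config)
  args[[case]] <- dataset
  model <- do.call(fit_constitutive, args)

  preds <- predict(model, dataset$points)
  S_surr <- lapply(preds, function(p) p[[paste0("S_", case)]])

  calib <- switch(case,
    vol = list(kappa_NH = calibrate_neo_hookean(dataset)),
    h_iso = as.list(calibrate_yeoh(dataset)),
    v_iso = list(eta_prime = calibrate_pioletti(dataset)))
  S_conv <- lapply(dataset$points, function(p) switch(case,
    vol = neo_hookean_vol_stress(p$C, calib$kappa_NH),
    h_iso = yeoh_stress(p$C, calib$C1, calib$C2),
    v_iso = pioletti_stress(p$C, p$Cdot, calib$eta_prime)))

  errors <- list(surrogate = .mean_err(S_surr, dataset$S),
                 conventional = .mean_err(S_conv, dataset$S))

  classical <- NULL
  if (include_classical) {
    classical <- classical_baseline_train(dataset, config)
    S_cls <- lapply(dataset$points, classical_baseline_predict,
                    model = classical)
    errors$classical <- .mean_err(S_cls, dataset$S)
  }

  diss <- NULL
  if (case == "v_iso") {
    diss <- mapply(function(pred, p) dissipation(pred$S_v_iso, p$Cdot),
                   preds, dataset$points)
  }

  structure(list(case = case, dataset = dataset, model = model,
                 calibration = calib, errors = errors,
                 classical = classical, dissipation = diss,
                 seed = config$seed),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("Benchmark case:", x$case, "\n")
  cat("Calibrated conventional parameters:\n")
  for (nm in names(x$calibration))
    cat("  ", nm, "=", format(x$calibration[[nm]], digits = 6), "\n")
  cat("Training-regime mean percent relative errors:\n")
  for (nm in names(x$errors))
    cat("  ", nm, ":", format(x$errors[[nm]], digits = 4), "%\n")
  if (!is.null(x$dissipation))
    cat("Minimum dissipation at training states:",
        format(min(x$dissipation), digits = 4), "\n")
  invisible(x)
}
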