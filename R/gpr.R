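## Matern-3/2 Gaussian process regression with per-point noise, shared-kernel
## multi-output support, maximum-likelihood hyperparameter fitting, and an
## inequality-constrained variant (C-GPR) that restricts the hyperparameter
## search to kernels whose predictions satisfy linear functionals of the
## outputs (here: non-negative viscous dissipation) at chosen points.

#' Matern-3/2 covariance function
#'
#' `k(x, x') = sigma_f^2 * (1 + sqrt(3) r / l) * exp(-sqrt(3) r / l)
#'   + alpha * delta(x, x')` with `r = ||x - x'||_2`. The Kronecker delta
#' term adds the stabilisation noise only when the two inputs are identical.
#'
#' @param x,xp Numeric input vectors of equal length.
#' @param params `c(sigma_f, l)`, both positive.
#' @param alpha Non-negative stabilisation noise.
#' @return A scalar covariance value.
#' @export
matern32 <- function(x, xp, params, alpha = 0) {
  stopifnot(length(params) == 2L, all(params > 0))
  r <- sqrt(sum((x - xp)^2))
  s <- sqrt(3) * r / params[2]
  params[1]^2 * (1 + s) * exp(-s) + alpha * as.numeric(identical(x, xp))
}

## Dense Matern-3/2 kernel matrix between row sets X (n x d) and Xp (m x d).
.kernel_matrix <- function(X, Xp, sigma_f, l) {
  ## pairwise Euclidean distances
  xn <- rowSums(X^2)
  yn <- rowSums(Xp^2)
  D2 <- outer(xn, yn, "+") - 2 * tcrossprod(X, Xp)
  D2[D2 < 0] <- 0
  S <- sqrt(3) * sqrt(D2) / l
  sigma_f^2 * (1 + S) * exp(-S)
}

.as_input_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  X
}

## Standardisation transform fitted on training inputs (per-dimension
## shift/scale); constant dimensions get unit scale.
.fit_transform <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

## Per-column output scale (no centring: the zero-mean prior must keep
## far-field predictions at zero). The per-point noise alpha acts on this
## unit-variance scale, making it a relative noise level as in common GPR
## implementations.
.fit_yscale <- function(Y) {
  s <- apply(Y, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  s
}

.apply_transform <- function(X, tr) {
  sweep(sweep(X, 2, tr$center, "-"), 2, tr$scale, "/")
}

#' Log marginal likelihood of a Matern-3/2 GP
#'
#' For a shared kernel across `n_o` output columns,
#' `sum_j [ -1/2 y_j' K^-1 y_j - 1/2 log det K - N/2 log 2 pi ]` with
#' `K = K(X, X) + diag(alpha)`.
#'
#' @param params `c(sigma_f, l)`.
#' @param X Input matrix (`N x n_i`), already on the scale the kernel sees.
#' @param Y Output matrix (`N x n_o`) or vector.
#' @param alpha Per-point noise vector (length `N`) or scalar.
#' @return The scalar log marginal likelihood.
#' @export
gp_lml <- function(params, X, Y, alpha) {
  X <- .as_input_matrix(X)
  Y <- as.matrix(Y)
  N <- nrow(X)
  if (length(alpha) == 1L) alpha <- rep(alpha, N)
  K <- .kernel_matrix(X, X, params[1], params[2]) + diag(alpha, N)
  L <- tryCatch(chol(K), error = function(e)
    stop("covariance matrix not positive definite; ",
         "consider a larger stabilisation noise alpha", call. = FALSE))
  logdet <- 2 * sum(log(diag(L)))
  quad <- sum(vapply(seq_len(ncol(Y)), function(j) {
    v <- backsolve(L, forwardsolve(t(L), Y[, j]))
    sum(Y[, j] * v)
  }, numeric(1)))
  -0.5 * quad - ncol(Y) * (0.5 * logdet + N / 2 * log(2 * pi))
}

#' GPR fitting configuration
#'
#' @param restarts Number of seeded random restarts for the hyperparameter
#'   search (the first start is the data-driven initial value).
#' @param seed Integer seed controlling the restart draws.
#' @param bound_factor Multiplicative half-width of the log-space search box
#'   around the initial values.
#' @param constraint_tol Feasibility slack for constrained fits.
#' @param maxit_constrained Iteration cap per penalty round of the
#'   derivative-free constrained search.
#' @return A list of class `"gp_config"`.
#' @export
gp_config <- function(restarts = 5L, seed = 1L, bound_factor = 1e3,
                      constraint_tol = 1e-8, maxit_constrained = 500L) {
  structure(list(restarts = as.integer(restarts), seed = as.integer(seed),
                 bound_factor = bound_factor,
                 constraint_tol = constraint_tol,
                 maxit_constrained = as.integer(maxit_constrained)),
            class = "gp_config")
}

## Data-driven initial hyperparameters on standardised inputs:
## l0 = median pairwise distance, sigma_f0 = pooled output sd.
.gp_init <- function(Xs, Y) {
  n <- nrow(Xs)
  idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
  D <- as.matrix(stats::dist(Xs[idx, , drop = FALSE]))
  l0 <- stats::median(D[upper.tri(D)])
  if (!is.finite(l0) || l0 <= 0) l0 <- 1
  sf0 <- stats::sd(as.numeric(Y))
  if (!is.finite(sf0) || sf0 <= 0) sf0 <- 1
  c(sf0, l0)
}

## Shared optimisation driver: maximises LML over log(theta) within a box,
## multi-start; returns the best theta found.
.gp_optimise <- function(Xs, Y, alpha, config) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)
  init <- .gp_init(Xs, Y)
  lb <- log(init) - log(config$bound_factor)
  ub <- log(init) + log(config$bound_factor)
  obj <- function(lp) {
    val <- tryCatch(gp_lml(exp(lp), Xs, Y, alpha), error = function(e) -Inf)
    if (!is.finite(val)) return(1e12)
    -val
  }
  starts <- rbind(log(init),
                  matrix(stats::runif((config$restarts - 1L) * 2, lb, ub),
                         ncol = 2, byrow = TRUE))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lb, upper = ub),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("GPR fitting failed from every start; data may be degenerate",
         call. = FALSE)
  list(theta = exp(best$par), lml = -best$value, lb = lb, ub = ub,
       init = init)
}

## Assemble the trained-model object (cached Cholesky solve of K^-1 Ys,
## where Ys is the output-scaled training matrix).
.gp_finalize <- function(theta, Xs, Y, alpha, transform, config, lml,
                         y_scale = rep(1, ncol(as.matrix(Y))),
                         constrained = FALSE, n_constraints = 0L) {
  Y <- as.matrix(Y)
  N <- nrow(Xs)
  Ys <- sweep(Y, 2, y_scale, "/")
  K <- .kernel_matrix(Xs, Xs, theta[1], theta[2]) + diag(alpha, N)
  L <- chol(K)
  KinvY <- backsolve(L, forwardsolve(t(L), Ys))
  structure(list(theta = c(sigma_f = unname(theta[1]), l = unname(theta[2])),
                 X = Xs, Y = Y, y_scale = y_scale, alpha = alpha,
                 transform = transform,
                 L = L, KinvY = KinvY, lml = lml, config = config,
                 constrained = constrained, n_constraints = n_constraints),
            class = "gp_model")
}

#' Fit a Matern-3/2 Gaussian process regressor
#'
#' Standardises each input dimension to zero mean/unit variance (training
#' statistics), then maximises the log marginal likelihood over
#' `(sigma_f, l)` in log space with seeded multi-start L-BFGS-B. Outputs are
#' not centred: the zero-mean prior makes far-field predictions decay to
#' zero. One shared kernel serves all output columns.
#'
#' Each output column is scaled by its training standard deviation (without
#' centring), so the per-point noise `alpha` acts as a relative noise level
#' on unit-variance outputs; predictions are returned on the original
#' scale.
#'
#' @param X Input matrix (`N x n_i`), data frame, or vector.
#' @param Y Output matrix (`N x n_o`) or vector.
#' @param alpha Per-point noise vector (length `N`) or scalar.
#' @param config A [gp_config()].
#' @return An object of class `"gp_model"`.
#' @export
gp_fit <- function(X, Y, alpha, config = gp_config()) {
  X <- .as_input_matrix(X)
  Y <- as.matrix(Y)
  N <- nrow(X)
  if (N < 2) stop("at least 2 training points are required", call. = FALSE)
  if (length(alpha) == 1L) alpha <- rep(alpha, N)
  stopifnot(length(alpha) == N)
  tr <- .fit_transform(X)
  Xs <- .apply_transform(X, tr)
  ys <- .fit_yscale(Y)
  Ys <- sweep(Y, 2, ys, "/")
  opt <- .gp_optimise(Xs, Ys, alpha, config)
  .gp_finalize(opt$theta, Xs, Y, alpha, tr, config, opt$lml, y_scale = ys)
}

#' Predict from a fitted Gaussian process
#'
#' Posterior mean `K(X, x*)' K(X, X)^-1 Y` and variance
#' `k(x*, x*) - K(X, x*)' K(X, X)^-1 K(X, x*)`, the latter clipped at zero.
#' At a training point whose noise `alpha` is small the mean interpolates
#' the stored output (exact-inference property).
#'
#' @param model A `"gp_model"`.
#' @param Xstar New inputs (`N* x n_i` matrix, data frame, or vector).
#' @return A list with `mean` (`N* x n_o` matrix) and `variance`
#'   (length-`N*` vector).
#' @export
gp_predict <- function(model, Xstar) {
  stopifnot(inherits(model, "gp_model"))
  Xstar <- .as_input_matrix(Xstar)
  Xs <- .apply_transform(Xstar, model$transform)
  Ks <- .kernel_matrix(model$X, Xs, model$theta[1], model$theta[2])
  mean <- sweep(crossprod(Ks, model$KinvY), 2, model$y_scale, "*")
  v <- forwardsolve(t(model$L), Ks)
  variance <- pmax(model$theta[1]^2 - colSums(v^2), 0)
  list(mean = mean, variance = variance)
}

#' @export
print.gp_model <- function(x, ...) {
  cat("Matern-3/2 GP", if (x$constrained) "(constrained)" else "", "\n")
  cat("  N =", nrow(x$X), " inputs =", ncol(x$X),
      " outputs =", ncol(x$Y), "\n")
  cat("  sigma_f =", format(x$theta[1], digits = 6),
      " l =", format(x$theta[2], digits = 6),
      " lml =", format(x$lml, digits = 8), "\n")
  invisible(x)
}

#' Fit a Matern-3/2 GP under linear inequality constraints on predictions
#'
#' Restricts the hyperparameter search so that, at each constraint point,
#' a known linear functional of the predicted output vector is non-negative
#' (here: the viscous dissipation `S_v,iso : Cdot`). The constraint set is
#' `sum_j W[m, j] * ytilde_j(Xc[m, ]) >= 0` for every row `m`.
#'
#' The search starts from the unconstrained maximum-likelihood optimum; if
#' that is already feasible it is returned unchanged. Otherwise a
#' derivative-free penalised Nelder-Mead search (escalating quadratic
#' penalty on constraint violations) is run in log-hyperparameter space
#' until every constraint holds within `config$constraint_tol` slack.
#'
#' @param X,Y,alpha As in [gp_fit()].
#' @param constraints A list with `Xc` (constraint-point inputs, `M x n_i`)
#'   and `W` (weights, `M x n_o`).
#' @param config A [gp_config()].
#' @return A `"gp_model"` with `constrained = TRUE`.
#' @export
gp_fit_constrained <- function(X, Y, alpha, constraints,
                               config = gp_config()) {
  X <- .as_input_matrix(X)
  Y <- as.matrix(Y)
  N <- nrow(X)
  if (length(alpha) == 1L) alpha <- rep(alpha, N)
  Xc <- .as_input_matrix(constraints$Xc)
  W <- as.matrix(constraints$W)
  stopifnot(nrow(Xc) == nrow(W), ncol(W) == ncol(Y))
  tr <- .fit_transform(X)
  Xs <- .apply_transform(X, tr)
  Xcs <- .apply_transform(Xc, tr)
  ys <- .fit_yscale(Y)
  Ys <- sweep(Y, 2, ys, "/")

  eval_constraints <- function(theta) {
    K <- .kernel_matrix(Xs, Xs, theta[1], theta[2]) + diag(alpha, N)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(rep(-Inf, nrow(Xcs)))
    KinvY <- backsolve(L, forwardsolve(t(L), Ys))
    Ks <- .kernel_matrix(Xs, Xcs, theta[1], theta[2])
    pred <- sweep(crossprod(Ks, KinvY), 2, ys, "*")
    rowSums(W * pred)
  }

  opt <- .gp_optimise(Xs, Ys, alpha, config)
  tol <- config$constraint_tol
  g0 <- eval_constraints(opt$theta)
  if (all(g0 >= -tol)) {
    return(.gp_finalize(opt$theta, Xs, Y, alpha, tr, config, opt$lml,
                        y_scale = ys, constrained = TRUE,
                        n_constraints = nrow(Xcs)))
  }

  ## derivative-free penalised search, multi-started (the first start is the
  ## unconstrained optimum), with an escalating quadratic penalty on scaled
  ## constraint violations
  gscale <- max(abs(g0[is.finite(g0)]), 1)
  mu0 <- 10 * (1 + abs(opt$lml))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed + 1L)
  starts <- rbind(log(opt$theta),
                  matrix(stats::runif((config$restarts - 1L) * 2,
                                      opt$lb, opt$ub),
                         ncol = 2, byrow = TRUE))
  best <- NULL
  last_g <- g0
  for (s in seq_len(nrow(starts))) {
    par <- starts[s, ]
    mu <- mu0
    for (round in 1:4) {
      pen_obj <- function(lp) {
        lp <- pmin(pmax(lp, opt$lb), opt$ub)
        theta <- exp(lp)
        val <- tryCatch(gp_lml(theta, Xs, Ys, alpha),
                        error = function(e) -Inf)
        if (!is.finite(val)) return(1e12)
        g <- eval_constraints(theta)
        viol <- pmax(0, -(g / gscale))
        -val + mu * sum(viol^2)
      }
      fit <- stats::optim(par, pen_obj, method = "Nelder-Mead",
                          control = list(maxit = config$maxit_constrained,
                                         reltol = 1e-12))
      par <- pmin(pmax(fit$par, opt$lb), opt$ub)
      theta <- exp(par)
      g <- eval_constraints(theta)
      last_g <- g
      if (all(g >= -tol)) {
        lml <- gp_lml(theta, Xs, Ys, alpha)
        if (is.null(best) || lml > best$lml)
          best <- list(theta = theta, lml = lml)
        break
      }
      mu <- mu * 100
    }
  }
  if (is.null(best)) {
    bad <- which(last_g < -tol)
    stop("no feasible hyperparameters found; violated constraint points: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  .gp_finalize(best$theta, Xs, Y, alpha, tr, config, best$lml,
               y_scale = ys, constrained = TRUE, n_constraints = nrow(Xcs))
}
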