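#' Linear kernel with training-mean feature centering
#'
#' Computes the linear (dot-product) kernel after centering every feature by
#' the training-set mean, the only feature transform applied in this pipeline.
#' Centering parameters always come from the training data: when `X_other`
#' (e.g. test subjects) is supplied it is centered by the *training* means,
#' never its own.
#'
#' @param X_train Numeric matrix, training subjects in rows, voxels in columns.
#' @param X_other Optional numeric matrix with the same number of columns
#'   (test subjects); when given, the cross-kernel
#'   `centered(X_other) %*% t(centered(X_train))` is returned.
#' @param centering_mean Optional length-V vector of feature means to center
#'   by; defaults to `colMeans(X_train)`.
#' @return An object of class `kernel_matrix`: a list with `K` (the kernel
#'   matrix) and `centering_mean` (the training means used).
#' @examples
#' K <- linear_kernel(matrix(c(1, 3), ncol = 1))
#' K$K   # [[1, -1], [-1, 1]]
#' @export
linear_kernel <- function(X_train, X_other = NULL, centering_mean = NULL) {
  X_train <- as.matrix(X_train)
  if (is.null(centering_mean)) centering_mean <- colMeans(X_train)
  if (length(centering_mean) != ncol(X_train))
    stop("centering_mean must have one entry per feature column")
  Xc <- sweep(X_train, 2L, centering_mean, "-")
  if (is.null(X_other)) {
    K <- tcrossprod(Xc)
  } else {
    X_other <- as.matrix(X_other)
    if (ncol(X_other) != ncol(X_train))
      stop("X_other must have the same number of feature columns as X_train")
    K <- tcrossprod(sweep(X_other, 2L, centering_mean, "-"), Xc)
  }
  structure(list(K = K, centering_mean = centering_mean),
            class = "kernel_matrix")
}

as_kernel <- function(K) {
  if (inherits(K, "kernel_matrix")) K$K else as.matrix(K)
}

#' Fit a relevance vector regression model
#'
#' Sparse Bayesian kernel regression: each basis function (one per training
#' subject, plus a bias) carries its own Gaussian prior precision
#' `alpha_i`; type-II maximum likelihood re-estimates the `alpha_i` and the
#' noise precision `beta`, and bases whose precision diverges past
#' `prune_alpha` are pruned.  The training subjects that survive are the
#' relevance vectors.  The targets are centered by their training mean
#' internally; the mean is restored at prediction.
#'
#' With `max_iter = 0` no re-estimation is performed and the returned
#' posterior mean is the fixed-hyperparameter Bayesian linear regression
#' solution `(A + beta * Phi'Phi)^{-1} beta * Phi'y` at the supplied
#' `alpha_init`, `beta_init`.
#'
#' @param K_train Training kernel: a `kernel_matrix` from [linear_kernel()] or
#'   a plain square numeric matrix (n x n).
#' @param y Numeric response vector of length n (n >= 3).
#' @param max_iter Maximum number of re-estimation iterations.
#' @param tol Convergence tolerance on `max |delta log alpha|` across
#'   surviving bases.
#' @param prune_alpha Precision threshold above which a basis is pruned.
#' @param alpha_init Initial prior precisions, length n + 1 (bias first);
#'   default `1 / n^2` for every basis.
#' @param beta_init Initial noise precision; default `1 / var(y)`.
#' @param beta_max Ceiling on the re-estimated noise precision, default
#'   `1e6 / var(y)` (the conventional sparse-Bayesian control setting: the
#'   noise SD is not allowed below a thousandth of the target SD).  The
#'   type-II updates have a degenerate fixed point on full-rank kernels in
#'   which `beta` diverges and the fit collapses to exact interpolation of
#'   the training scores; the ceiling keeps the model in the regularized
#'   regime.  Set to `Inf` to allow the interpolation limit.
#' @param track_evidence If `TRUE`, record the log marginal likelihood after
#'   every iteration (used to check evidence monotonicity; slows the fit).
#' @return An object of class `rvr_model` with elements `alpha`, `beta`, `mu`,
#'   `sigma_diag`, `active_idx` (1 = bias, i + 1 = training subject i),
#'   `y_offset`, `n_train`, `n_iter`, `converged`, `offset_only`,
#'   `degenerate`, and `evidence`.
#' @seealso [predict_rvr()], [primal_weights()], [fit_krr()]
#' @export
fit_rvr <- function(K_train, y, max_iter = 1000, tol = 1e-3,
                    prune_alpha = 1e9, alpha_init = NULL, beta_init = NULL,
                    beta_max = NULL, track_evidence = FALSE) {
  K <- as_kernel(K_train)
  n <- length(y)
  if (nrow(K) != n || ncol(K) != n)
    stop("K_train must be a square n x n kernel matching length(y)")
  if (n < 3) stop("at least 3 training subjects are required")
  if (!all(is.finite(y))) stop("y must be finite")
  if (!all(is.finite(K))) stop("K_train must be finite")

  y_offset <- mean(y)
  yc <- y - y_offset

  if (stats::var(y) == 0) {
    # constant targets: nothing to learn, predict the offset everywhere
    return(structure(list(
      alpha = numeric(0), beta = Inf, mu = numeric(0),
      sigma_diag = numeric(0), active_idx = integer(0),
      y_offset = y_offset, n_train = n, n_iter = 0L, converged = TRUE,
      offset_only = TRUE, degenerate = FALSE, evidence = numeric(0)),
      class = "rvr_model"))
  }

  if (is.null(alpha_init)) alpha_init <- rep(1 / n^2, n + 1L)
  if (length(alpha_init) == 1L) alpha_init <- rep(alpha_init, n + 1L)
  if (length(alpha_init) != n + 1L)
    stop("alpha_init must have length n + 1 (bias first)")
  if (any(alpha_init <= 0)) stop("alpha_init must be positive")
  if (is.null(beta_init)) beta_init <- 1 / stats::var(y)
  if (beta_init <= 0) stop("beta_init must be positive")
  if (is.null(beta_max)) beta_max <- 1e6 / stats::var(y)
  if (beta_max < beta_init) stop("beta_max must be at least beta_init")

  Phi <- cbind(1, K)
  fit <- .rvm_em(Phi, yc, alpha_init, beta_init, beta_max,
                 as.integer(max_iter), tol, prune_alpha, track_evidence)

  structure(list(
    alpha = as.numeric(fit$alpha),
    beta = fit$beta,
    mu = as.numeric(fit$mu),
    sigma_diag = as.numeric(fit$sigma_diag),
    active_idx = as.integer(fit$active),
    y_offset = y_offset,
    n_train = n,
    n_iter = fit$n_iter,
    converged = fit$converged,
    offset_only = length(fit$active) == 0L,
    degenerate = fit$degenerate,
    evidence = as.numeric(fit$evidence)),
    class = "rvr_model")
}

#' @export
print.rvr_model <- function(x, ...) {
  cat("Relevance vector regression model\n")
  cat(sprintf("  training subjects: %d\n", x$n_train))
  if (x$offset_only) {
    cat(sprintf("  all bases pruned: predicts the training mean %.4g\n",
                x$y_offset))
  } else {
    nrv <- sum(x$active_idx != 1L)
    cat(sprintf("  relevance vectors: %d (bias %s)\n", nrv,
                if (1L %in% x$active_idx) "retained" else "pruned"))
    cat(sprintf("  noise precision beta: %.4g\n", x$beta))
  }
  cat(sprintf("  iterations: %d (%s)\n", x$n_iter,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Predict from a fitted RVR model
#'
#' @param model An `rvr_model` from [fit_rvr()].
#' @param K_cross Cross kernel (`kernel_matrix` or matrix), one row per test
#'   subject, one column per *training* subject in the order used at fit time.
#' @return Numeric vector of predicted scores.
#' @export
predict_rvr <- function(model, K_cross) {
  stopifnot(inherits(model, "rvr_model"))
  K <- as_kernel(K_cross)
  if (is.null(dim(K))) K <- matrix(K, nrow = 1L)
  if (ncol(K) != model$n_train)
    stop("K_cross must have one column per training subject (",
         model$n_train, ")")
  if (model$offset_only) return(rep(model$y_offset, nrow(K)))
  Phi_test <- cbind(1, K)
  as.numeric(Phi_test[, model$active_idx, drop = FALSE] %*% model$mu) +
    model$y_offset
}

#' Recover voxel-space (primal) weights of a linear-kernel RVR model
#'
#' For a linear kernel the dual solution is equivalent to a voxel-space
#' weight vector `w = sum_i mu_i * x_i` over the retained relevance vectors
#' (centered training patterns).  This is the per-fold weight vector that the
#' localization stage averages into the final weight map.
#'
#' @param model An `rvr_model` fitted on a linear kernel.
#' @param X_train_centered The centered (and, if used, confound-residualized)
#'   training matrix the kernel was built from, n x V.
#' @return Numeric length-V weight vector (all zeros when every non-bias
#'   basis was pruned).
#' @export
primal_weights <- function(model, X_train_centered) {
  stopifnot(inherits(model, "rvr_model"))
  X <- as.matrix(X_train_centered)
  if (nrow(X) != model$n_train)
    stop("X_train_centered must have one row per training subject")
  rv <- model$active_idx[model$active_idx != 1L]
  if (length(rv) == 0L) return(numeric(ncol(X)))
  mu_rv <- model$mu[model$active_idx != 1L]
  as.numeric(crossprod(X[rv - 1L, , drop = FALSE], mu_rv))
}

#' Kernel ridge regression (closed form)
#'
#' Baseline with the same linear-kernel plumbing as [fit_rvr()]: dual
#' coefficients `(K + lambda I)^{-1} (y - mean(y))`, intercept restored at
#' prediction.  Used as a comparison method and as an independent oracle in
#' tests.
#'
#' @param K_train Training kernel (`kernel_matrix` or square matrix).
#' @param y Numeric response vector.
#' @param ridge_lambda Positive ridge penalty.
#' @return Object of class `krr_model` with `coef`, `y_offset`, `n_train`,
#'   `lambda`.
#' @export
fit_krr <- function(K_train, y, ridge_lambda) {
  K <- as_kernel(K_train)
  n <- length(y)
  if (nrow(K) != n || ncol(K) != n) stop("K_train must be n x n")
  if (!is.numeric(ridge_lambda) || length(ridge_lambda) != 1L ||
      ridge_lambda <= 0)
    stop("ridge_lambda must be a positive scalar")
  y_offset <- mean(y)
  coef <- solve(K + diag(ridge_lambda, n), y - y_offset)
  structure(list(coef = as.numeric(coef), y_offset = y_offset,
                 n_train = n, lambda = ridge_lambda),
            class = "krr_model")
}

#' @rdname fit_krr
#' @param model A `krr_model`.
#' @param K_cross Cross kernel, test rows by training columns.
#' @export
predict_krr <- function(model, K_cross) {
  stopifnot(inherits(model, "krr_model"))
  K <- as_kernel(K_cross)
  if (is.null(dim(K))) K <- matrix(K, nrow = 1L)
  if (ncol(K) != model$n_train)
    stop("K_cross must have one column per training subject")
  as.numeric(K %*% model$coef) + model$y_offset
}

#' Serialize an RVR model to a single JSON archive
#'
#' Keys: `alpha`, `beta`, `mu`, `sigma_diag`, `active_idx`, `y_offset`,
#' `n_train`, `n_iter`, `converged`, `offset_only`, `degenerate`,
#' `evidence`, plus a free-form `config` echo.
#'
#' @param model An `rvr_model`.
#' @param path File path to write.
#' @param config Optional list echoed verbatim into the archive.
#' @return `path`, invisibly.
#' @export
write_rvr_model <- function(model, path, config = NULL) {
  stopifnot(inherits(model, "rvr_model"))
  obj <- unclass(model)
  obj$config <- config
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_rvr_model
#' @export
read_rvr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- obj$config
  obj$config <- NULL
  obj$active_idx <- as.integer(obj$active_idx)
  for (f in c("alpha", "mu", "sigma_diag", "evidence"))
    obj[[f]] <- as.numeric(obj[[f]])
  model <- structure(obj, class = "rvr_model")
  attr(model, "config") <- config
  model
}
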