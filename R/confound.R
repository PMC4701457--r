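#' Residual forming matrix
#'
#' `R = I - C (C'C)^+ C'`, the projector onto the orthogonal complement of
#' the column space of a confound design `C` (pseudo-inverse, so
#' rank-deficient designs are handled).  Multiplying data by `R` removes the
#' confound's linear effect; with a binary regressor plus intercept this is
#' the dummy-variable regression / ANCOVA adjustment.
#'
#' @param C Numeric matrix n x q (a vector is taken as one column).
#' @return n x n projection matrix satisfying `R C = 0` and `R R = R`.
#' @export
residual_forming_matrix <- function(C) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (n <= ncol(C)) stop("need more rows than confound columns")
  diag(n) - C %*% MASS::ginv(crossprod(C)) %*% t(C)
}

#' Fit the confound model on training data
#'
#' Estimates per-voxel confound coefficients `(C'C)^+ C' X` on the training
#' fold only, so they can be applied frozen to held-out subjects without
#' test-set leakage.  Training residuals have exactly zero per-voxel
#' correlation with the confound.
#'
#' @param X_train Numeric matrix n x V.
#' @param c_train Binary (0/1) confound vector of length n.
#' @param with_intercept Include an intercept column (default `TRUE`,
#'   matching the ANCOVA equivalence); requires both confound classes to be
#'   present in the training fold.
#' @return Object of class `confound_model` with `coef` (q x V) and
#'   `with_intercept`.
#' @export
fit_confound <- function(X_train, c_train, with_intercept = TRUE) {
  X_train <- as.matrix(X_train)
  if (length(c_train) != nrow(X_train))
    stop("c_train must have one entry per training row")
  if (!all(c_train %in% c(0, 1))) stop("confound must be binary 0/1")
  if (with_intercept && length(unique(c_train)) < 2)
    stop("confound coefficients are unidentifiable: only one class ",
         "present in the training fold")
  C <- if (with_intercept) cbind(1, c_train) else cbind(c_train)
  coef <- MASS::ginv(crossprod(C)) %*% crossprod(C, X_train)
  structure(list(coef = coef, with_intercept = isTRUE(with_intercept)),
            class = "confound_model")
}

#' Residualize a feature matrix by a fitted confound model
#'
#' `X - C coef` with coefficients frozen from the training fit; applying the
#' model to its own training data equals multiplication by the residual
#' forming matrix.
#'
#' @param model A `confound_model` from [fit_confound()].
#' @param X Numeric matrix (training or test subjects).
#' @param c Binary confound vector for the rows of `X`.
#' @return Residualized matrix of the same shape as `X`.
#' @export
apply_confound <- function(model, X, c) {
  stopifnot(inherits(model, "confound_model"))
  X <- as.matrix(X)
  if (length(c) != nrow(X)) stop("c must have one entry per row of X")
  if (!all(c %in% c(0, 1))) stop("confound must be binary 0/1")
  if (ncol(X) != ncol(model$coef))
    stop("X has ", ncol(X), " columns but the model was fitted on ",
         ncol(model$coef))
  C <- if (model$with_intercept) cbind(1, c) else cbind(c)
  X - C %*% model$coef
}

#' Two-sample t-test of confound-score association
#'
#' Equal-variance two-sample t-test (two-sided) of the scores between
#' confounded and unconfounded subjects, used to check whether the confound
#' is systematically related to the score being decoded.
#'
#' @param scores Numeric score vector.
#' @param c Binary confound vector.
#' @return List with `t`, `p`, `group_means`, `group_sds`, `group_n`
#'   (named `confound_1` / `confound_0`), and `degenerate` (TRUE when the
#'   pooled variance is zero).
#' @export
confound_score_ttest <- function(scores, c) {
  if (length(scores) != length(c)) stop("scores and c differ in length")
  if (!all(c %in% c(0, 1))) stop("confound must be binary 0/1")
  g1 <- scores[c == 1]
  g0 <- scores[c == 0]
  if (length(g1) < 2 || length(g0) < 2)
    stop("each confound class needs at least 2 subjects")
  out <- list(group_means = c(confound_1 = mean(g1), confound_0 = mean(g0)),
              group_sds = c(confound_1 = sd(g1), confound_0 = sd(g0)),
              group_n = c(confound_1 = length(g1), confound_0 = length(g0)))
  if (sd(g1) == 0 && sd(g0) == 0) {
    if (mean(g1) == mean(g0)) {
      warning("zero variance in both groups with equal means; t set to 0")
      return(c(list(t = 0, p = 1, degenerate = TRUE), out))
    }
    warning("zero variance in both groups with unequal means; p set to 0")
    return(c(list(t = sign(mean(g1) - mean(g0)) * Inf, p = 0,
                  degenerate = TRUE), out))
  }
  tt <- t.test(g1, g0, var.equal = TRUE)
  c(list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE), out)
}
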