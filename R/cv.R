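#' Leave-one-out cross-validation scheme
#'
#' @param n Number of subjects (>= 3).
#' @return Object of class `fold_scheme` with `n` singleton test folds in
#'   subject order.
#' @export
make_loo <- function(n) {
  if (n < 3) stop("leave-one-out needs at least 3 subjects")
  structure(list(kind = "loo", folds = as.list(seq_len(n)), k = as.integer(n),
                 n = as.integer(n), balance_pvalues = NULL,
                 attempts_used = 0L, seed = NA_integer_),
            class = "fold_scheme")
}

#' Balanced k-fold cross-validation scheme
#'
#' Randomly partitions subjects into `k` folds with sizes as equal as
#' possible (larger folds first), then checks that the to-be-predicted
#' scores do not differ between any fold and the remaining subjects
#' (two-sample t-test, each fold vs. rest).  A partition is accepted when
#' every fold's p-value exceeds `alpha_balance`; otherwise it is reshuffled
#' with an incremented seed, up to `max_attempts` times.
#'
#' @param scores Numeric score vector (one per subject).
#' @param k Number of folds (>= 2, <= n; `k = n` reproduces leave-one-out).
#' @param seed RNG seed for the shuffles.
#' @param alpha_balance Balance-test significance level (default 0.05).
#' @param max_attempts Maximum reshuffles before giving up (default 100).
#' @return Object of class `fold_scheme` with `folds` (test index sets),
#'   `balance_pvalues` (one per fold) and `attempts_used`.
#' @export
make_kfold <- function(scores, k, seed = 1, alpha_balance = 0.05,
                       max_attempts = 100) {
  n <- length(scores)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("cannot split ", n, " subjects into ", k, " folds")
  base <- n %/% k
  sizes <- rep(base, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- base + 1L
  fold_p <- function(test_scores, rest_scores) {
    if (length(test_scores) < 2 || length(rest_scores) < 2) return(1)
    if (sd(test_scores) == 0 && sd(rest_scores) == 0) return(1)
    tryCatch(t.test(test_scores, rest_scores, var.equal = TRUE)$p.value,
             error = function(e) 1)
  }
  worst <- Inf
  for (attempt in seq_len(max_attempts)) {
    perm <- with_seed(seed + attempt - 1L, sample.int(n))
    folds <- split(perm, rep(seq_len(k), times = sizes))
    folds <- lapply(folds, sort)
    pvals <- vapply(folds, function(f) fold_p(scores[f], scores[-f]),
                    numeric(1))
    if (all(pvals > alpha_balance)) {
      return(structure(list(kind = "kfold", folds = unname(folds),
                            k = as.integer(k), n = as.integer(n),
                            balance_pvalues = unname(pvals),
                            attempts_used = attempt,
                            seed = as.integer(seed)),
                       class = "fold_scheme"))
    }
    worst <- min(worst, min(pvals))
  }
  stop(sprintf(
    "no score-balanced %d-fold partition found in %d attempts (worst balance p-value %.4g <= %.3g)",
    k, max_attempts, worst, alpha_balance))
}

#' @export
print.fold_scheme <- function(x, ...) {
  sizes <- lengths(x$folds)
  cat(sprintf("%s cross-validation: %d folds over %d subjects (sizes %s)\n",
              if (x$kind == "loo") "Leave-one-out" else
                sprintf("%d-fold", x$k),
              length(x$folds), x$n,
              paste(sizes, collapse = "/")))
  if (!is.null(x$balance_pvalues))
    cat(sprintf("  balance p-values: %s (attempt %d)\n",
                paste(sprintf("%.3f", x$balance_pvalues), collapse = ", "),
                x$attempts_used))
  invisible(x)
}

#' Pearson correlation between true and decoded scores
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 3 with non-zero
#'   variance (predictions that collapse to a constant have no defined
#'   correlation and raise an error).
#' @return Product-moment correlation in \[-1, 1\].
#' @export
pearson_r <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("lengths differ")
  if (length(y_true) < 3) stop("need at least 3 pairs")
  if (sd(y_true) == 0 || sd(y_pred) == 0)
    stop("correlation undefined: zero variance (predictions may have ",
         "collapsed to the mean)")
  cor(y_true, y_pred)
}

#' Mean squared error between true and decoded scores
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return Mean of squared differences (>= 0).
#' @export
mse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("lengths differ")
  mean((y_true - y_pred)^2)
}

#' Joint significance decision
#'
#' A decoding model counts as significant only when the permutation p-values
#' of *both* agreement metrics (correlation and MSE) fall below `alpha`
#' (strict AND).
#'
#' @param p_r,p_mse Permutation p-values in \[0, 1\].
#' @param alpha Significance threshold (default 0.05).
#' @return Logical flag.
#' @export
decide_significance <- function(p_r, p_mse, alpha = 0.05) {
  stopifnot(p_r >= 0, p_r <= 1, p_mse >= 0, p_mse <= 1)
  p_r < alpha && p_mse < alpha
}

# Shared per-fold preparation: training-mean centering of features, optional
# within-fold confound residualization (coefficients frozen from the training
# fold), and linear kernels.  Only training rows are read before prediction.
prepare_fold <- function(dataset, train, test, control_confound) {
  X_tr <- dataset$X[train, , drop = FALSE]
  mu_feat <- colMeans(X_tr)
  Xc_tr <- sweep(X_tr, 2L, mu_feat, "-")
  if (control_confound) {
    c_tr <- dataset$confound[train]
    if (length(unique(c_tr)) < 2)
      stop("confound has a single class in a training fold ",
           "(test subjects: ", paste(test, collapse = ", "), ")")
    cm <- fit_confound(Xc_tr, c_tr, with_intercept = TRUE)
    Xc_tr <- apply_confound(cm, Xc_tr, c_tr)
  } else {
    cm <- NULL
  }
  Xc_te <- sweep(dataset$X[test, , drop = FALSE], 2L, mu_feat, "-")
  if (control_confound)
    Xc_te <- apply_confound(cm, Xc_te, dataset$confound[test])
  zeros <- rep(0, ncol(Xc_tr))
  list(Xc_tr = Xc_tr,
       K_tr = linear_kernel(Xc_tr, centering_mean = zeros),
       K_cross = linear_kernel(Xc_tr, Xc_te, centering_mean = zeros))
}

#' Run the cross-validated decoding loop
#'
#' For every fold: center features by the training mean, optionally remove
#' the binary confound (fitted on the training fold, applied frozen to the
#' test fold), build linear kernels, fit RVR, predict the held-out subjects,
#' and store the fold's voxel-space weights.  Out-of-fold predictions are
#' pooled over subjects before computing the agreement metrics; the final
#' weight map is the fold-average divided by its Euclidean norm.
#'
#' @param dataset A `subject_dataset`.
#' @param scheme A `fold_scheme` covering all subjects.
#' @param control_confound Remove the binary confound within folds.
#' @param rvr_options List of extra arguments passed to [fit_rvr()].
#' @param keep_weights Compute per-fold primal weights and the weight map
#'   (default `TRUE`; permutation replicates skip this).
#' @return Object of class `decoding_result`: `y_true`, `y_pred`, `r`,
#'   `mse`, `per_fold_weights`, `weight_map` (unit Euclidean norm),
#'   `fold_r` / `fold_mse` (per-fold metrics, NA where undefined, with their
#'   averages in `mean_fold_r` / `mean_fold_mse`), and a `settings` echo.
#' @export
run_decoding <- function(dataset, scheme, control_confound = FALSE,
                         rvr_options = list(), keep_weights = TRUE) {
  stopifnot(inherits(dataset, "subject_dataset"),
            inherits(scheme, "fold_scheme"))
  n <- nrow(dataset$X)
  idx <- sort(unlist(scheme$folds))
  if (!identical(idx, seq_len(n)))
    stop("fold scheme does not partition the ", n, " subjects")
  y <- dataset$scores
  y_pred <- rep(NA_real_, n)
  nf <- length(scheme$folds)
  per_fold_weights <- if (keep_weights) vector("list", nf) else NULL
  fold_r <- rep(NA_real_, nf)
  fold_mse <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    test <- scheme$folds[[f]]
    train <- setdiff(seq_len(n), test)
    if (length(train) < 3)
      stop("fold ", f, " leaves fewer than 3 training subjects")
    prep <- prepare_fold(dataset, train, test, control_confound)
    model <- do.call(fit_rvr, c(list(prep$K_tr, y[train]), rvr_options))
    y_pred[test] <- predict_rvr(model, prep$K_cross)
    if (keep_weights)
      per_fold_weights[[f]] <- primal_weights(model, prep$Xc_tr)
    fold_mse[f] <- mse(y[test], y_pred[test])
    if (length(test) >= 3 && sd(y[test]) > 0 && sd(y_pred[test]) > 0)
      fold_r[f] <- cor(y[test], y_pred[test])
  }
  structure(list(
    y_true = y, y_pred = y_pred,
    r = pearson_r(y, y_pred), mse = mse(y, y_pred),
    per_fold_weights = per_fold_weights,
    weight_map = if (keep_weights) average_weight_map(per_fold_weights)
                 else NULL,
    fold_r = fold_r, fold_mse = fold_mse,
    mean_fold_r = if (any(!is.na(fold_r))) mean(fold_r, na.rm = TRUE)
                  else NA_real_,
    mean_fold_mse = mean(fold_mse),
    settings = list(scheme = scheme$kind, k = scheme$k,
                    control_confound = control_confound,
                    rvr_options = rvr_options,
                    score_name = dataset$score_name)),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding result (%s, %s%s): r = %.3f, MSE = %.3f over %d subjects\n",
              x$settings$score_name,
              if (x$settings$scheme == "loo") "LOO" else
                sprintf("%d-fold", x$settings$k),
              if (x$settings$control_confound) ", confound-controlled" else "",
              x$r, x$mse, length(x$y_true)))
  invisible(x)
}
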