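# Precomputed per-fold kernels for leave-one-out permutation replicates.
# Folds, feature centering and confound residualization depend only on the
# features and confound, never on the labels, so under LOO they are shared
# across all label permutations.
build_loo_context <- function(dataset, control_confound) {
  n <- nrow(dataset$X)
  scheme <- make_loo(n)
  lapply(seq_len(n), function(f) {
    test <- scheme$folds[[f]]
    train <- setdiff(seq_len(n), test)
    prep <- prepare_fold(dataset, train, test, control_confound)
    list(train = train, test = test, K_tr = prep$K_tr,
         K_cross = prep$K_cross)
  })
}

decode_with_context <- function(ctx, y, rvr_options) {
  y_pred <- rep(NA_real_, length(y))
  for (fc in ctx) {
    model <- do.call(fit_rvr, c(list(fc$K_tr, y[fc$train]), rvr_options))
    y_pred[fc$test] <- predict_rvr(model, fc$K_cross)
  }
  list(r = pearson_r(y, y_pred), mse = mse(y, y_pred))
}

#' Label-permutation significance test of the decoding metrics
#'
#' Re-runs the entire cross-validated decoding with the scores shuffled
#' across participants (the confound stays attached to its participant
#' unless `permute_confound = TRUE`) and counts how many permutations reach
#' `|r|` at least as large as the observed `|r|`, or an MSE at least as
#' small as the observed MSE.  P-values are count / n_perm (the literal
#' rule, which can return 0), or (count + 1) / (n_perm + 1) with
#' `plus_one_correction`.  For k-fold schemes the balanced partition is
#' rebuilt against each permutation's labels, since the balance t-test
#' references them.
#'
#' Permutation replicates whose decoding fails (e.g. predictions collapse to
#' a constant, leaving the correlation undefined) are counted as beating the
#' observed statistic on both metrics — a conservative convention — with a
#' warning.
#'
#' @param dataset A `subject_dataset`.
#' @param scheme_spec Either a `fold_scheme` or a list such as
#'   `list(kind = "loo")` / `list(kind = "kfold", k = 4)`.
#' @param control_confound Remove the binary confound within folds.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the shuffles.
#' @param rvr_options Extra arguments for [fit_rvr()].
#' @param permute_confound Also shuffle the confound with the scores
#'   (default `FALSE`: the test targets the score-brain association under
#'   the fixed confound structure).
#' @param plus_one_correction Use (count + 1) / (n_perm + 1).
#' @param alpha_balance,max_attempts Passed to [make_kfold()] when
#'   rebuilding k-fold partitions.
#' @return Object of class `permutation_result`: `n_perm`, `observed_r`,
#'   `observed_mse`, `null_r`, `null_mse` (NA for failed replicates),
#'   `count_r`, `count_mse`, `p_r`, `p_mse`, `n_failed`, `seed`,
#'   `plus_one_correction`.
#' @export
permutation_test <- function(dataset, scheme_spec = list(kind = "loo"),
                             control_confound = FALSE, n_perm = 1000,
                             seed = 1, rvr_options = list(),
                             permute_confound = FALSE,
                             plus_one_correction = FALSE,
                             alpha_balance = 0.05, max_attempts = 100) {
  stopifnot(inherits(dataset, "subject_dataset"))
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (inherits(scheme_spec, "fold_scheme"))
    scheme_spec <- list(kind = scheme_spec$kind, k = scheme_spec$k,
                        seed = scheme_spec$seed)
  kind <- match.arg(scheme_spec$kind, c("loo", "kfold"))
  n <- nrow(dataset$X)

  run_one <- function(ds, perm_seed) {
    if (kind == "loo") {
      scheme <- make_loo(n)
    } else {
      scheme <- make_kfold(ds$scores, scheme_spec$k, seed = perm_seed,
                           alpha_balance = alpha_balance,
                           max_attempts = max_attempts)
    }
    res <- run_decoding(ds, scheme, control_confound = control_confound,
                        rvr_options = rvr_options, keep_weights = FALSE)
    list(r = res$r, mse = res$mse)
  }

  base_seed <- if (!is.null(scheme_spec$seed) && !is.na(scheme_spec$seed))
    scheme_spec$seed else seed
  obs <- run_one(dataset, base_seed)

  use_fast <- kind == "loo"
  if (use_fast)
    ctx <- build_loo_context(dataset, control_confound)

  null_r <- rep(NA_real_, n_perm)
  null_mse <- rep(NA_real_, n_perm)
  perms <- with_seed(seed, lapply(seq_len(n_perm),
                                  function(b) sample.int(n)))
  n_failed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- perms[[b]]
    y_b <- dataset$scores[perm]
    out <- tryCatch({
      if (use_fast && !permute_confound) {
        decode_with_context(ctx, y_b, rvr_options)
      } else {
        ds_b <- dataset
        ds_b$scores <- y_b
        if (permute_confound) ds_b$confound <- dataset$confound[perm]
        run_one(ds_b, seed + b)
      }
    }, error = function(e) e)
    if (inherits(out, "error")) {
      n_failed <- n_failed + 1L
    } else {
      null_r[b] <- out$r
      null_mse[b] <- out$mse
    }
  }
  if (n_failed > 0)
    warning(n_failed, " permutation(s) failed to decode; counted as ",
            "beating the observed statistic (conservative)")

  count_r <- sum(abs(null_r) >= abs(obs$r), na.rm = TRUE) + n_failed
  count_mse <- sum(null_mse <= obs$mse, na.rm = TRUE) + n_failed
  denom <- if (plus_one_correction) n_perm + 1 else n_perm
  add <- if (plus_one_correction) 1 else 0
  structure(list(
    n_perm = as.integer(n_perm),
    observed_r = obs$r, observed_mse = obs$mse,
    null_r = null_r, null_mse = null_mse,
    count_r = as.integer(count_r), count_mse = as.integer(count_mse),
    p_r = (count_r + add) / denom, p_mse = (count_mse + add) / denom,
    n_failed = n_failed, seed = as.integer(seed),
    plus_one_correction = isTRUE(plus_one_correction),
    scheme = kind, control_confound = control_confound),
    class = "permutation_result")
}

#' Summarize a permutation test
#'
#' @param result A `permutation_result`.
#' @param alpha Significance threshold for the joint decision (default 0.05).
#' @return List with the observed metrics, p-values, the joint
#'   [decide_significance()] flag, and quantiles (5/25/50/75/95%) of the
#'   null distributions.
#' @export
summarize_permutation <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "permutation_result"))
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  list(observed_r = result$observed_r, observed_mse = result$observed_mse,
       p_r = result$p_r, p_mse = result$p_mse,
       significant = decide_significance(result$p_r, result$p_mse, alpha),
       alpha = alpha, n_perm = result$n_perm, n_failed = result$n_failed,
       null_r_quantiles = quantile(result$null_r, qs, na.rm = TRUE),
       null_mse_quantiles = quantile(result$null_mse, qs, na.rm = TRUE))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations, %s):\n", x$n_perm,
              x$scheme))
  cat(sprintf("  r   = %.3f (p = %.4g)\n", x$observed_r, x$p_r))
  cat(sprintf("  MSE = %.3f (p = %.4g)\n", x$observed_mse, x$p_mse))
  if (x$n_failed > 0)
    cat(sprintf("  %d failed permutation(s) counted conservatively\n",
                x$n_failed))
  invisible(x)
}
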