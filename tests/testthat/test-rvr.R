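test_that("linear kernel centers by the training mean and matches dot products", {
  X <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(linear_kernel(X)$K, matrix(0, 4, 4))

  K <- linear_kernel(matrix(c(1, 3), ncol = 1))
  expect_equal(K$centering_mean, 2)
  expect_equal(K$K, matrix(c(1, -1, -1, 1), 2))

  withr::with_seed(2, {
    Xr <- matrix(rnorm(120), 6, 20)
    Xt <- matrix(rnorm(60), 3, 20)
  })
  mu <- colMeans(Xr)
  Kr <- linear_kernel(Xr)$K
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    oracle[i, j] <- sum((Xr[i, ] - mu) * (Xr[j, ] - mu))
  expect_equal(Kr, oracle, tolerance = 1e-12)
  expect_equal(Kr, t(Kr), tolerance = 1e-10)
  ev <- eigen(Kr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))

  Kc <- linear_kernel(Xr, Xt)$K
  oc <- matrix(0, 3, 6)
  for (i in 1:3) for (j in 1:6)
    oc[i, j] <- sum((Xt[i, ] - mu) * (Xr[j, ] - mu))
  expect_equal(Kc, oc, tolerance = 1e-12)

  expect_error(linear_kernel(Xr, Xt[, 1:5]), "columns")
})

test_that("constant targets give an offset-only model", {
  K <- linear_kernel(matrix(rnorm(40), 8, 5))
  m <- fit_rvr(K, rep(7, 8))
  expect_true(m$offset_only)
  expect_equal(predict_rvr(m, matrix(rnorm(24), 3, 8)), rep(7, 3))
  expect_equal(primal_weights(m, matrix(0, 8, 5)), rep(0, 5))
})

test_that("frozen hyperparameters reproduce the Bayesian closed form", {
  for (n in c(5, 12, 20)) {
    withr::with_seed(n, {
      X <- matrix(rnorm(n * 7), n, 7)
      y <- rnorm(n, sd = 3) + 10
    })
    K <- linear_kernel(X)
    m <- fit_rvr(K, y, max_iter = 0, alpha_init = 1, beta_init = 100)
    Phi <- cbind(1, K$K)
    yc <- y - mean(y)
    mu_oracle <- solve(diag(n + 1) + 100 * crossprod(Phi),
                       100 * crossprod(Phi, yc))
    expect_equal(m$active_idx, seq_len(n + 1))
    expect_equal(m$mu, as.numeric(mu_oracle), tolerance = 1e-8)
    expect_equal(m$beta, 100)
  }
})

test_that("held-out RVR predictions track the OLS oracle on low-dimensional data", {
  n <- 50; V <- 5
  withr::with_seed(7, {
    X <- matrix(rnorm(n * V), n, V)
    w <- rnorm(V)
    y <- as.numeric(X %*% w) + rnorm(n, sd = 0.01)
  })
  pred_rvr <- numeric(n); pred_ols <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    K <- linear_kernel(X[tr, ], centering_mean = colMeans(X[tr, ]))
    Kx <- linear_kernel(X[tr, ], X[i, , drop = FALSE])
    m <- fit_rvr(K, y[tr])
    pred_rvr[i] <- predict_rvr(m, Kx)
    fit <- lm(y ~ ., data = data.frame(y = y[tr], X[tr, ]))
    pred_ols[i] <- predict(fit, newdata = data.frame(t(X[i, ])))
  }
  expect_gt(cor(pred_rvr, pred_ols), 0.99)
})

test_that("noiseless training data is interpolated and dual/primal forms agree", {
  n <- 20; V <- 30
  withr::with_seed(3, {
    X <- matrix(rnorm(n * V), n, V)
    w <- rnorm(V)
    Xte <- matrix(rnorm(10 * V), 10, V)
  })
  y <- as.numeric(X %*% w)
  mu_feat <- colMeans(X)
  Xc <- sweep(X, 2, mu_feat)
  Xc_te <- sweep(Xte, 2, mu_feat)
  zeros <- rep(0, V)
  K <- linear_kernel(Xc, centering_mean = zeros)
  # beta_max = Inf releases the noise-precision ceiling so the fit can reach
  # the exact-interpolation limit on noiseless data
  m <- fit_rvr(K, y, beta_max = Inf)
  expect_lt(max(abs(predict_rvr(m, K) - y)), 1e-6)

  # primal identity: yhat - offset = x_c . w + mu_bias on test points
  wp <- primal_weights(m, Xc)
  K_cross <- linear_kernel(Xc, Xc_te, centering_mean = zeros)
  dual <- predict_rvr(m, K_cross)
  bias <- if (1L %in% m$active_idx) m$mu[m$active_idx == 1L] else 0
  primal <- as.numeric(Xc_te %*% wp) + bias + m$y_offset
  expect_equal(primal, dual, tolerance = 1e-8)
})

test_that("a three-subject toy prediction re-derives by hand", {
  K <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3)
  y <- c(1, 2, 4)
  m <- fit_rvr(K, y, max_iter = 5, alpha_init = 0.5, beta_init = 10)
  k_new <- matrix(c(1, 0.5, 0.25), 1)
  pred <- predict_rvr(m, k_new)
  phi_new <- c(1, as.numeric(k_new))[m$active_idx]
  expect_equal(pred, sum(phi_new * m$mu) + m$y_offset, tolerance = 1e-12)
})

test_that("primal weights are the relevance-vector-weighted pattern sum", {
  model <- structure(list(alpha = 1, beta = 1, mu = 2, sigma_diag = 1,
                          active_idx = 3L, y_offset = 0, n_train = 3L,
                          n_iter = 1L, converged = TRUE, offset_only = FALSE,
                          degenerate = FALSE, evidence = numeric(0)),
                     class = "rvr_model")
  X <- rbind(c(9, 9, 9), c(1, 0, -1), c(9, 9, 9))
  expect_equal(primal_weights(model, X), c(2, 0, -2))
})

test_that("re-estimation prunes, keeps the evidence non-decreasing, and ignores subject order", {
  n <- 100
  withr::with_seed(5, {
    X <- matrix(rnorm(n * 40), n, 40)
    w <- rnorm(40)
    y <- as.numeric(X %*% w) + rnorm(n, sd = 2)
    Xte <- matrix(rnorm(6 * 40), 6, 40)
  })
  K <- linear_kernel(X)
  m <- fit_rvr(K, y, track_evidence = TRUE)
  expect_lte(length(m$active_idx), n + 1)
  expect_lt(length(m$active_idx), n)  # strict pruning at this size
  expect_true(all(diff(m$evidence) > -1e-6))
  expect_true(all(m$alpha <= 1e9))
  expect_gt(m$beta, 0)

  # permuting training subjects permutes nothing observable
  perm <- withr::with_seed(6, sample.int(n))
  mu_feat <- colMeans(X)
  K_cross <- linear_kernel(X, Xte)
  Kp <- linear_kernel(X[perm, ])
  Kp_cross <- linear_kernel(X[perm, ], Xte)
  mp <- fit_rvr(Kp, y[perm])
  expect_equal(predict_rvr(mp, Kp_cross), predict_rvr(m, K_cross),
               tolerance = 1e-10)
})

test_that("kernel ridge regression matches hand solves and shrinks to the mean", {
  Kh <- matrix(c(4, 1, 0, 1, 3, 1, 0, 1, 2), 3)
  y <- c(2, 5, 11)
  m <- fit_krr(Kh, y, ridge_lambda = 1)
  oracle <- solve(Kh + diag(3), y - mean(y))
  expect_equal(m$coef, as.numeric(oracle), tolerance = 1e-12)
  expect_equal(predict_krr(m, Kh), as.numeric(Kh %*% oracle) + mean(y))

  big <- fit_krr(Kh, y, ridge_lambda = 1e12)
  expect_equal(predict_krr(big, Kh), rep(mean(y), 3), tolerance = 1e-6)

  expect_error(fit_krr(Kh, y, ridge_lambda = 0), "positive")
})

test_that("KRR and RVR agree on pooled accuracy for planted-signal data", {
  fx <- planted_dataset(n = 60, V = 80, noise_sd = 0.3, seed = 17)
  ds <- fx$dataset
  n <- nrow(ds$X)
  pred_rvr <- numeric(n); pred_krr <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    K <- linear_kernel(ds$X[tr, ])
    Kx <- linear_kernel(ds$X[tr, ], ds$X[i, , drop = FALSE])
    pred_rvr[i] <- predict_rvr(fit_rvr(K, ds$scores[tr]), Kx)
    pred_krr[i] <- predict_krr(fit_krr(K, ds$scores[tr], 1), Kx)
  }
  r_rvr <- pearson_r(ds$scores, pred_rvr)
  r_krr <- pearson_r(ds$scores, pred_krr)
  expect_lt(abs(r_rvr - r_krr), 0.1)
})

test_that("models serialize to a JSON archive and back", {
  withr::with_seed(9, {
    X <- matrix(rnorm(60), 12, 5)
    y <- rnorm(12)
  })
  m <- fit_rvr(linear_kernel(X), y)
  p <- withr::local_tempfile(fileext = ".json")
  write_rvr_model(m, p, config = list(kernel = "linear"))
  m2 <- read_rvr_model(p)
  expect_equal(m2$mu, m$mu)
  expect_equal(m2$active_idx, m$active_idx)
  expect_equal(m2$y_offset, m$y_offset)
  expect_equal(attr(m2, "config")$kernel, "linear")
  K_new <- matrix(rnorm(24), 2, 12)
  expect_equal(predict_rvr(m2, K_new), predict_rvr(m, K_new))
})

test_that("degenerate and invalid inputs are rejected or flagged", {
  K <- linear_kernel(matrix(rnorm(20), 4, 5))
  expect_error(fit_rvr(K, c(1, 2)), "square|match")
  expect_error(fit_rvr(K, c(1, 2, NA, 4)), "finite")
  expect_error(fit_rvr(linear_kernel(matrix(rnorm(4), 2, 2)), c(1, 2)),
               "at least 3")
  # everything pruned at initialization: offset-only, flagged not an error
  m <- fit_rvr(K, c(1, 3, 2, 5), prune_alpha = 1e-10)
  expect_true(m$offset_only)
  expect_equal(predict_rvr(m, matrix(0, 1, 4)), mean(c(1, 3, 2, 5)))
})
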