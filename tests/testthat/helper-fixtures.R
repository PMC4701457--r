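# Shared fixture builders.  Everything is generated in code at test time;
# nothing is read from disk except what the tests themselves write to
# tempdirs.

# Small planted-signal dataset built in memory: X = z * w + noise.
planted_dataset <- function(n, V, noise_sd = 0.1, seed = 1,
                            confound_prevalence = 0, confound_gain = 0) {
  withr::with_seed(seed, {
    w <- rnorm(V)
    z <- rnorm(n)
    cvec <- if (confound_prevalence > 0)
      rbinom(n, 1L, confound_prevalence) else rep(0L, n)
    wc <- rnorm(V)
    X <- outer(z, w) + confound_gain * outer(cvec, wc) +
      matrix(rnorm(n * V, sd = noise_sd), n, V)
    list(dataset = dataset_from_matrix(X, z, cvec), w = w, z = z,
         confound = cvec)
  })
}

# Pure-noise dataset (scores independent of features by construction).
null_dataset <- function(n, V, seed = 1) {
  withr::with_seed(seed, {
    dataset_from_matrix(matrix(rnorm(n * V), n, V), rnorm(n))
  })
}

# A tiny on-disk synthetic study; returns the generate_study() result.
tiny_study <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                       ...) {
  args <- utils::modifyList(
    list(grid_shape = c(6, 6, 4), n_subjects = 12, n_blobs = 1,
         blob_sigma_mm = 5, noise_sd = 0.3, nan_rate = 0.01,
         mask_kind = "full", seed = 42),
    list(...))
  generate_study(do.call(generator_config, args), dir)
}
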