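# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Separable 3D Gaussian convolution (truncated at 3 sigma, kernel sum 1 in
# the interior).  Returns the smoothed array plus the white-noise variance
# scale prod(sum(k^2)) so callers can restore a target interior noise SD.
smooth_gaussian_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  if (sigma_vox <= 0) return(list(arr = arr, var_scale = 1))
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  var_scale <- 1
  conv_mat <- function(d1) {
    M <- matrix(0, d1, d1)
    for (off in seq(-r, r)) {
      i <- seq_len(d1)
      j <- i + off
      ok <- j >= 1 & j <= d1
      M[cbind(i[ok], j[ok])] <- k[off + r + 1L]
    }
    M
  }
  # axis 1
  arr <- array(conv_mat(d[1]) %*% matrix(arr, d[1], d[2] * d[3]), dim = d)
  # axis 2
  a2 <- aperm(arr, c(2, 1, 3))
  a2 <- array(conv_mat(d[2]) %*% matrix(a2, d[2], d[1] * d[3]),
              dim = c(d[2], d[1], d[3]))
  arr <- aperm(a2, c(2, 1, 3))
  # axis 3
  a3 <- aperm(arr, c(3, 1, 2))
  a3 <- array(conv_mat(d[3]) %*% matrix(a3, d[3], d[1] * d[2]),
              dim = c(d[3], d[1], d[2]))
  arr <- aperm(a3, c(2, 3, 1))
  var_scale <- sum(k^2)^3
  list(arr = arr, var_scale = var_scale)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
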