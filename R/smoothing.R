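# Validity-aware separable Gaussian smoothing (normalized convolution):
# smooth(M) = conv(M * V) / conv(V), with V the 0/1 validity mask, so
# invalid pixels neither contribute nor contaminate their neighbours.

gaussian_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k / sum(k)
}

# 1-D convolution along columns with zero padding, C-speed via stats::filter
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  pad <- matrix(0, r, ncol(m))
  mp <- rbind(pad, m, pad)
  out <- stats::filter(mp, k, method = "convolution", sides = 2)
  matrix(out[(r + 1):(r + nrow(m)), ], nrow(m), ncol(m))
}

# Smooth a map with NA-invalid pixels; returns matrix with NA where the
# local kernel mass is (numerically) zero.
smooth_masked <- function(density, valid, sigma_px) {
  if (sigma_px <= 0) {
    out <- density
    out[!valid] <- NA_real_
    return(out)
  }
  k <- gaussian_kernel_1d(sigma_px)
  m0 <- density
  m0[!valid] <- 0
  v <- matrix(as.numeric(valid), nrow(valid), ncol(valid))
  num <- t(conv_cols(t(conv_cols(m0, k)), k))
  den <- t(conv_cols(t(conv_cols(v, k)), k))
  out <- num / den
  out[den < 1e-12] <- NA_real_
  out
}
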