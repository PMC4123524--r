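# Small 2-D filtering kernel machinery (direct evaluation, deterministic).
# Border handling throughout is edge-mirroring ("symmetric"/reflect) padding,
# and border rows/cols of gradient maps are kept, so every filter output is
# fully reproducible without a library convolution.

pad_symmetric <- function(x, pr, pc = pr) {
  M <- nrow(x)
  N <- ncol(x)
  if (pr >= M || pc >= N)
    stopf("padding (%d, %d) too large for a %d x %d image", pr, pc, M, N)
  ri <- c(rev(seq_len(pr)), seq_len(M), M + 1 - seq_len(pr))
  ci <- c(rev(seq_len(pc)), seq_len(N), N + 1 - seq_len(pc))
  x[ri, ci, drop = FALSE]
}

# cross-correlation of x with an odd-sized kernel k, symmetric padding
filter2_sym <- function(x, k) {
  kr <- nrow(k)
  kc <- ncol(k)
  if (kr %% 2 == 0 || kc %% 2 == 0) stopf("kernel must be odd-sized")
  pr <- (kr - 1) / 2
  pc <- (kc - 1) / 2
  xp <- pad_symmetric(x, pr, pc)
  M <- nrow(x)
  N <- ncol(x)
  out <- matrix(0, M, N)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      if (k[a, b] != 0)
        out <- out + k[a, b] * xp[a:(a + M - 1), b:(b + N - 1)]
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel_1d(sigma)
  x <- filter2_sym(x, matrix(k, nrow = 1))
  filter2_sym(x, matrix(k, ncol = 1))
}

# 3x3 Sobel derivative kernels; `scale` divides the raw stencil (1 for the
# classic unnormalized operator, 1/8 so a unit step responds with 0.5)
sobel_kx <- function(scale = 1) matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) * scale
sobel_ky <- function(scale = 1) t(sobel_kx(scale))

sobel_gradients <- function(x, scale = 1) {
  list(gx = filter2_sym(x, sobel_kx(scale)),
       gy = filter2_sym(x, sobel_ky(scale)))
}

prewitt_kx <- function(scale = 1) matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3) * scale

log_kernel <- function(sigma) {
  r <- max(2L, ceiling(3 * sigma))
  g <- expand.grid(y = -r:r, x = -r:r)
  rho2 <- g$x^2 + g$y^2
  k <- (rho2 - 2 * sigma^2) / sigma^4 * exp(-rho2 / (2 * sigma^2))
  k <- matrix(k, nrow = 2 * r + 1)
  k - mean(k) # zero net response on constants
}
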