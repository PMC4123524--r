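# Similarity between original and reconstruction: MSE/MAE, structural
# similarity (SSIM/MSSIM) and its gradient-domain variant (GSSIM/MGSSIM).
# SSIM-family statistics are computed on nonoverlapping window_size x
# window_size tiles; partial border tiles are dropped.

#' Similarity configuration
#'
#' @param window_size Side of the square nonoverlapping windows (default 8,
#'   the classic SSIM block size).
#' @param k1,k2 Relative stabilizing constants; `C1 = (k1 * L)^2`,
#'   `C2 = (k2 * L)^2`, `C3 = C2 / 2` with `L` the image dynamic range.
#'   Explicit `C1`/`C2`/`C3` override these.
#' @param C1,C2,C3 Optional absolute stabilizing constants.
#' @param alpha_g,beta_g,gamma_g Exponents on the luminance, gradient
#'   contrast and gradient structure factors of GSSIM (default all 1).
#' @return A `similarity_config` object.
#' @export
similarity_config <- function(window_size = 8L, k1 = 0.01, k2 = 0.03,
                              C1 = NULL, C2 = NULL, C3 = NULL,
                              alpha_g = 1, beta_g = 1, gamma_g = 1) {
  if (!is_scalar_num(window_size) || window_size < 2)
    stopf("`window_size` must be >= 2")
  for (nm in c("C1", "C2", "C3")) {
    v <- get(nm)
    if (!is.null(v) && (!is_scalar_num(v) || v <= 0))
      stopf("`%s` must be a positive scalar", nm)
  }
  structure(list(window_size = as.integer(window_size), k1 = k1, k2 = k2,
                 C1 = C1, C2 = C2, C3 = C3,
                 alpha_g = alpha_g, beta_g = beta_g, gamma_g = gamma_g),
            class = "similarity_config")
}

resolve_constants <- function(cfg, L) {
  C1 <- if (is.null(cfg$C1)) (cfg$k1 * L)^2 else cfg$C1
  C2 <- if (is.null(cfg$C2)) (cfg$k2 * L)^2 else cfg$C2
  C3 <- if (is.null(cfg$C3)) C2 / 2 else cfg$C3
  list(C1 = C1, C2 = C2, C3 = C3)
}

#' Mean square and mean absolute error
#'
#' @param x,y [gray_image]s (or matrices) of identical shape.
#' @return Named numeric vector `c(mse = ..., mae = ...)`.
#' @examples
#' mse_mae(matrix(c(0, 0)), matrix(c(3, 4)))
#' @export
mse_mae <- function(x, y) {
  x <- as_gray_image(x)$pixels
  y <- as_gray_image(y)$pixels
  if (!identical(dim(x), dim(y)))
    stopf("images must have identical shapes (%d x %d vs %d x %d)",
          nrow(x), ncol(x), nrow(y), ncol(y))
  d <- x - y
  c(mse = mean(d^2), mae = mean(abs(d)))
}

#' Sobel gradient magnitude
#'
#' `sqrt(gx^2 + gy^2)` with the classic (unnormalized) 3x3 Sobel stencils and
#' edge-mirroring padding; border rows/cols are kept.
#'
#' @param x A [gray_image] or numeric matrix.
#' @return Numeric matrix of the image's shape.
#' @export
gradient_magnitude <- function(x) {
  if (inherits(x, "gray_image")) x <- x$pixels
  g <- sobel_gradients(x, scale = 1)
  sqrt(g$gx^2 + g$gy^2)
}

#' Statistics of one window pair
#'
#' Means, standard deviations and covariance of an intensity window pair,
#' and optionally of the corresponding gradient-magnitude windows.
#' Variances are population (divide-by-n) moments.
#'
#' @param xw,yw Numeric intensity windows (equal size).
#' @param gxw,gyw Optional gradient-magnitude windows of the same size.
#' @return A list of class `window_stats` with fields `mu_x`, `mu_y`,
#'   `sigma_x`, `sigma_y`, `sigma_xy` and, when gradients are supplied,
#'   `gsigma_x`, `gsigma_y`, `gsigma_xy`.
#' @export
window_stats <- function(xw, yw, gxw = NULL, gyw = NULL) {
  xw <- as.numeric(xw)
  yw <- as.numeric(yw)
  if (length(xw) != length(yw)) stopf("windows must have equal size")
  st <- list(
    mu_x = mean(xw), mu_y = mean(yw),
    sigma_x = sqrt(max(0, mean(xw^2) - mean(xw)^2)),
    sigma_y = sqrt(max(0, mean(yw^2) - mean(yw)^2)),
    sigma_xy = mean(xw * yw) - mean(xw) * mean(yw)
  )
  if (!is.null(gxw)) {
    gxw <- as.numeric(gxw)
    gyw <- as.numeric(gyw)
    st$gsigma_x <- sqrt(max(0, mean(gxw^2) - mean(gxw)^2))
    st$gsigma_y <- sqrt(max(0, mean(gyw^2) - mean(gyw)^2))
    st$gsigma_xy <- mean(gxw * gyw) - mean(gxw) * mean(gyw)
  }
  class(st) <- "window_stats"
  st
}

luminance_factor <- function(st, C1) {
  (2 * st$mu_x * st$mu_y + C1) / (st$mu_x^2 + st$mu_y^2 + C1)
}

#' SSIM of one window pair
#'
#' The standard two-factor structural similarity
#' `l(x, y) * (2 * sigma_xy + C2) / (sigma_x^2 + sigma_y^2 + C2)`, i.e. the
#' luminance factor times the merged contrast-structure factor (equivalent to
#' the three-factor form with `C3 = C2 / 2`). Anticorrelated windows are
#' penalized through the covariance.
#'
#' @param stats A [window_stats()] object.
#' @param cfg A [similarity_config()].
#' @param dynamic_range Dynamic range used to resolve the constants.
#' @return Scalar SSIM value (<= 1).
#' @export
ssim_window <- function(stats, cfg = similarity_config(), dynamic_range = 255) {
  cc <- resolve_constants(cfg, dynamic_range)
  luminance_factor(stats, cc$C1) *
    (2 * stats$sigma_xy + cc$C2) / (stats$sigma_x^2 + stats$sigma_y^2 + cc$C2)
}

#' GSSIM of one window pair
#'
#' Gradient-domain structural similarity: the intensity luminance factor
#' combined with contrast and structure factors computed on the
#' gradient-magnitude windows,
#' `l(x, y)^alpha_g * c(x', y')^beta_g * s(x', y')^gamma_g`.
#'
#' @inheritParams ssim_window
#' @return Scalar GSSIM value (<= 1).
#' @export
gssim_window <- function(stats, cfg = similarity_config(), dynamic_range = 255) {
  if (is.null(stats$gsigma_x))
    stopf("`stats` must include gradient-window statistics")
  cc <- resolve_constants(cfg, dynamic_range)
  l <- luminance_factor(stats, cc$C1)
  cg <- (2 * stats$gsigma_x * stats$gsigma_y + cc$C2) /
    (stats$gsigma_x^2 + stats$gsigma_y^2 + cc$C2)
  sg <- (stats$gsigma_xy + cc$C3) / (stats$gsigma_x * stats$gsigma_y + cc$C3)
  signed_pow(l, cfg$alpha_g) * signed_pow(cg, cfg$beta_g) * signed_pow(sg, cfg$gamma_g)
}

window_grid <- function(M, N, ws) {
  nr <- floor(M / ws)
  nc <- floor(N / ws)
  if (nr < 1 || nc < 1)
    stopf("image (%d x %d) smaller than one %d x %d similarity window",
          M, N, ws, ws)
  list(nr = nr, nc = nc)
}

tile_values <- function(x, y, gx, gy, cfg, L, fun) {
  ws <- cfg$window_size
  g <- window_grid(nrow(x), ncol(x), ws)
  vals <- numeric(g$nr * g$nc)
  idx <- 0L
  for (a in seq_len(g$nr)) {
    rows <- ((a - 1L) * ws + 1L):(a * ws)
    for (b in seq_len(g$nc)) {
      cols <- ((b - 1L) * ws + 1L):(b * ws)
      st <- window_stats(x[rows, cols], y[rows, cols],
                         if (is.null(gx)) NULL else gx[rows, cols],
                         if (is.null(gy)) NULL else gy[rows, cols])
      idx <- idx + 1L
      vals[idx] <- fun(st, cfg, L)
    }
  }
  vals
}

check_pair <- function(x, y) {
  x <- as_gray_image(x)
  y <- as_gray_image(y, dynamic_range = x$dynamic_range)
  if (!identical(dim(x), dim(y)))
    stopf("images must have identical shapes (%d x %d vs %d x %d)",
          nrow(x$pixels), ncol(x$pixels), nrow(y$pixels), ncol(y$pixels))
  list(x = x, y = y)
}

#' Mean SSIM over nonoverlapping windows
#'
#' @param x,y [gray_image]s of identical shape, at least one full window.
#' @param cfg A [similarity_config()].
#' @return Scalar MSSIM.
#' @export
mssim <- function(x, y, cfg = similarity_config()) {
  p <- check_pair(x, y)
  mean(tile_values(p$x$pixels, p$y$pixels, NULL, NULL, cfg,
                   p$x$dynamic_range, ssim_window))
}

#' Mean GSSIM over nonoverlapping windows
#'
#' Gradient magnitudes are computed once on the full images; window
#' statistics then mix intensity luminance with gradient contrast/structure.
#'
#' @inheritParams mssim
#' @return Scalar MGSSIM.
#' @export
mgssim <- function(x, y, cfg = similarity_config()) {
  p <- check_pair(x, y)
  gx <- gradient_magnitude(p$x$pixels)
  gy <- gradient_magnitude(p$y$pixels)
  mean(tile_values(p$x$pixels, p$y$pixels, gx, gy, cfg,
                   p$x$dynamic_range, gssim_window))
}

#' Full similarity report for an image pair
#'
#' @inheritParams mssim
#' @return A list of class `similarity_report` with fields `mse`, `mae`,
#'   `mssim`, `mgssim` and `n_windows` (full nonoverlapping windows used).
#' @export
similarity_report <- function(x, y, cfg = similarity_config()) {
  p <- check_pair(x, y)
  err <- mse_mae(p$x, p$y)
  g <- window_grid(nrow(p$x$pixels), ncol(p$x$pixels), cfg$window_size)
  structure(list(mse = unname(err["mse"]), mae = unname(err["mae"]),
                 mssim = mssim(p$x, p$y, cfg), mgssim = mgssim(p$x, p$y, cfg),
                 n_windows = as.integer(g$nr * g$nc)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "<similarity_report> MSE %.4f | MAE %.4f | MSSIM %.4f | MGSSIM %.4f (%d windows)\n",
    x$mse, x$mae, x$mssim, x$mgssim, x$n_windows))
  invisible(x)
}
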