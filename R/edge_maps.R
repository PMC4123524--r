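# Candidate edge-map generation: built-in detectors, morphological dilation,
# and the grayscale edge map (dilated mask carrying original intensities).

#' Edge detector specification
#'
#' Describes one of the built-in detectors. Gradient detectors (sobel,
#' prewitt, roberts) threshold the gradient magnitude of the image scaled to
#' `[0, 1]`; the kernels are normalized so that a full-contrast step edge
#' responds with magnitude 0.5, the convention under which published
#' threshold grids such as 0.01--0.08 are stated.
#'
#' @param name One of `"sobel"`, `"prewitt"`, `"roberts"`, `"log"`,
#'   `"canny"`.
#' @param threshold Nonnegative threshold on the normalized response. For
#'   canny this is the high hysteresis threshold; for log it is the minimum
#'   zero-crossing slope.
#' @param sigma Gaussian scale: smoothing for canny (default `sqrt(2)`),
#'   kernel scale for log (default 2). Ignored by the gradient detectors.
#' @param low_ratio Canny low threshold as a fraction of `threshold`
#'   (default 0.4).
#' @return A `detector_spec` object.
#' @export
detector_spec <- function(name = c("sobel", "prewitt", "roberts", "log", "canny"),
                          threshold = 0.05, sigma = NULL, low_ratio = 0.4) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stopf("unknown detector name '%s'", name[1]))
  if (!is_scalar_num(threshold) || threshold < 0)
    stopf("`threshold` must be a nonnegative scalar")
  if (is.null(sigma)) sigma <- switch(name, log = 2, canny = sqrt(2), NA_real_)
  if (!is_scalar_num(low_ratio) || low_ratio <= 0 || low_ratio > 1)
    stopf("`low_ratio` must be in (0, 1]")
  structure(list(name = name, threshold = threshold, sigma = sigma,
                 low_ratio = low_ratio),
            class = "detector_spec")
}

roberts_magnitude <- function(z) {
  M <- nrow(z)
  N <- ncol(z)
  zp <- z[c(seq_len(M), M), c(seq_len(N), N), drop = FALSE] # replicate last row/col
  d1 <- (zp[seq_len(M), seq_len(N)] - zp[seq_len(M) + 1, seq_len(N) + 1]) / 2
  d2 <- (zp[seq_len(M), seq_len(N) + 1] - zp[seq_len(M) + 1, seq_len(N)]) / 2
  sqrt(d1^2 + d2^2)
}

canny_detect <- function(z, threshold, sigma, low_ratio) {
  zs <- gaussian_blur(z, sigma)
  g <- sobel_gradients(zs, scale = 1 / 8)
  mag <- sqrt(g$gx^2 + g$gy^2)
  # non-maximum suppression along the quantized gradient direction
  theta <- atan2(g$gy, g$gx) * 180 / pi
  bin <- (round(theta / 45) %% 4 + 4) %% 4
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nms <- matrix(FALSE, nrow(z), ncol(z))
  for (b in 0:3) {
    o <- offs[[b + 1]]
    fwd <- shift_matrix(mag, o[1], o[2], fill = -Inf)
    bwd <- shift_matrix(mag, -o[1], -o[2], fill = -Inf)
    nms <- nms | (bin == b & mag >= fwd & mag >= bwd)
  }
  mag_nms <- ifelse(nms, mag, 0)
  strong <- mag_nms > threshold
  weak <- mag_nms > threshold * low_ratio
  # hysteresis: grow strong pixels through 8-connected weak pixels
  repeat {
    grown <- dilate_edge_map(strong, 1L) & weak
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong
}

log_detect <- function(z, threshold, sigma) {
  r <- filter2_sym(z, log_kernel(sigma))
  M <- nrow(z)
  N <- ncol(z)
  edge <- matrix(FALSE, M, N)
  # zero crossings between 4-neighbors with slope above the threshold;
  # the pixel with the smaller absolute response is marked
  east <- shift_matrix(r, 0L, 1L, fill = NA_real_)
  south <- shift_matrix(r, 1L, 0L, fill = NA_real_)
  for (nb in list(east, south)) {
    cross <- !is.na(nb) & r * nb < 0 & abs(r - nb) > threshold
    here <- cross & abs(r) <= abs(nb)
    there <- cross & !here
    edge <- edge | here
    if (identical(nb, east)) {
      edge <- edge | shift_matrix(there, 0L, -1L) # mark the east partner
    } else {
      edge <- edge | shift_matrix(there, -1L, 0L)
    }
  }
  edge
}

#' Detect edges with a built-in detector
#'
#' Runs the detector described by `spec` over a grayscale image. The image is
#' scaled to `[0, 1]` before the response is computed, so thresholds are
#' comparable across bit depths. Borders are handled by edge-mirroring
#' padding and kept in the output.
#'
#' @param image A [gray_image] (or numeric matrix).
#' @param spec A [detector_spec()].
#' @return Logical edge map of the image's shape.
#' @examples
#' img <- gray_image(cbind(matrix(0, 16, 8), matrix(200, 16, 8)))
#' e <- detect_edges(img, detector_spec("sobel", threshold = 0.1))
#' sum(e)
#' @export
detect_edges <- function(image, spec) {
  image <- as_gray_image(image)
  if (!inherits(spec, "detector_spec")) stopf("`spec` must be a detector_spec")
  z <- image$pixels / image$dynamic_range
  mask <- switch(spec$name,
    sobel = {
      g <- sobel_gradients(z, scale = 1 / 8)
      sqrt(g$gx^2 + g$gy^2) > spec$threshold
    },
    prewitt = {
      gx <- filter2_sym(z, prewitt_kx(1 / 6))
      gy <- filter2_sym(z, t(prewitt_kx(1 / 6)))
      sqrt(gx^2 + gy^2) > spec$threshold
    },
    roberts = roberts_magnitude(z) > spec$threshold,
    log = log_detect(z, spec$threshold, spec$sigma),
    canny = canny_detect(z, spec$threshold, spec$sigma, spec$low_ratio)
  )
  mask
}

#' Dilate a binary edge map
#'
#' Binary morphological dilation with a square structuring element of side
#' `2 * selem_radius + 1`. Radius 0 is the identity. A 3x3 square (radius 1)
#' is the default throughout the package: it is the smallest element that
#' connects 8-neighbor edge chains into a continuous band.
#'
#' @param edges Logical edge map.
#' @param selem_radius Nonnegative integer radius.
#' @return Dilated logical edge map.
#' @export
dilate_edge_map <- function(edges, selem_radius = 1L) {
  edges <- as_edge_map(edges)
  if (!is_scalar_num(selem_radius) || selem_radius < 0 ||
      selem_radius != round(selem_radius))
    stopf("`selem_radius` must be a nonnegative integer")
  r <- as.integer(selem_radius)
  if (r == 0L) return(edges)
  out <- edges
  for (dr in -r:r) {
    for (dc in -r:r) {
      if (dr == 0L && dc == 0L) next
      out <- out | shift_matrix(edges, dr, dc, fill = FALSE)
    }
  }
  out
}

#' Build the grayscale edge map
#'
#' Dilates the candidate edge map and multiplies it with the original image,
#' so mask pixels retain the original intensities and all other pixels are
#' zero. `ne` is the number of edge pixels after dilation, the count the
#' density penalty is based on.
#'
#' @param image A [gray_image].
#' @param edges Logical edge map of the same shape.
#' @param selem_radius Dilation radius (default 1).
#' @return A `grayscale_edge_map`: list with `dilated_mask`, `values`
#'   (intensities on the mask, 0 elsewhere), `ne` and `dynamic_range`.
#' @export
make_grayscale_edge_map <- function(image, edges, selem_radius = 1L) {
  image <- as_gray_image(image)
  edges <- as_edge_map(edges, expected_shape = dim(image))
  dm <- dilate_edge_map(edges, selem_radius)
  structure(list(dilated_mask = dm,
                 values = image$pixels * dm,
                 ne = sum(dm),
                 dynamic_range = image$dynamic_range),
            class = "grayscale_edge_map")
}

#' @export
print.grayscale_edge_map <- function(x, ...) {
  cat(sprintf("<grayscale_edge_map> %d x %d, Ne = %d (%.1f%% of pixels)\n",
              nrow(x$dilated_mask), ncol(x$dilated_mask), x$ne,
              100 * x$ne / length(x$dilated_mask)))
  invisible(x)
}
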