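# Synthetic phantoms: piecewise-constant scenes (axis-aligned rectangles and
# circles) with additive Gaussian noise and exact ground-truth edge masks,
# so every stage of the pipeline is testable without external image data.

#' Rectangle phantom object
#'
#' @param rows,cols Inclusive 1-based index ranges `c(from, to)`.
#' @param intensity Object intensity.
#' @return Object description for [phantom_spec()].
#' @export
phantom_rect <- function(rows, cols, intensity) {
  list(type = "rect", rows = as.integer(rows), cols = as.integer(cols),
       intensity = intensity)
}

#' Circle phantom object
#'
#' @param center `c(row, col)` of the center.
#' @param radius Radius in pixels; a pixel belongs to the disc when its
#'   squared center distance is `<= radius^2`.
#' @param intensity Object intensity.
#' @return Object description for [phantom_spec()].
#' @export
phantom_circle <- function(center, radius, intensity) {
  list(type = "circle", center = as.numeric(center), radius = radius,
       intensity = intensity)
}

#' Phantom specification
#'
#' @param shape `c(rows, cols)` canvas size.
#' @param objects List of [phantom_rect()] / [phantom_circle()] objects,
#'   rendered in order (later objects overwrite earlier ones).
#' @param background Background intensity.
#' @param noise_sigma Additive Gaussian noise standard deviation in intensity
#'   units, applied after ground-truth extraction.
#' @param seed Integer seed; the phantom is fully determined by it.
#' @param dynamic_range Dynamic range `L` (default 255).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(64L, 64L), objects = list(),
                         background = 100, noise_sigma = 0, seed = 1L,
                         dynamic_range = 255) {
  if (length(shape) != 2L || any(shape < 1))
    stopf("`shape` must be two positive integers")
  if (!is_scalar_num(noise_sigma) || noise_sigma < 0)
    stopf("`noise_sigma` must be >= 0")
  if (background < 0 || background > dynamic_range)
    stopf("`background` must lie in [0, L]")
  M <- as.integer(shape[1]); N <- as.integer(shape[2])
  for (ob in objects) {
    if (ob$intensity < 0 || ob$intensity > dynamic_range)
      stopf("object intensity outside [0, L]")
    if (ob$type == "rect") {
      if (ob$rows[1] < 1 || ob$rows[2] > M || ob$cols[1] < 1 || ob$cols[2] > N ||
          ob$rows[1] > ob$rows[2] || ob$cols[1] > ob$cols[2])
        stopf("rectangle outside the %d x %d canvas", M, N)
    } else if (ob$type == "circle") {
      if (ob$center[1] - ob$radius < 1 || ob$center[1] + ob$radius > M ||
          ob$center[2] - ob$radius < 1 || ob$center[2] + ob$radius > N)
        stopf("circle outside the %d x %d canvas", M, N)
    } else stopf("unknown phantom object type '%s'", ob$type)
  }
  structure(list(shape = c(M, N), objects = objects, background = background,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 dynamic_range = dynamic_range),
            class = "phantom_spec")
}

#' Canonical shapes phantom
#'
#' The package's reference scene on a 64 x 64 canvas over background 100: a
#' high-contrast rectangle (180), a high-contrast circle (220), and a
#' low-contrast rectangle (130) emulating soft tissue whose normalized
#' gradient response (~0.06) sits inside the usual threshold sweep range —
#' so low thresholds admit noise while high thresholds discard real
#' structure, the tradeoff the score is designed to resolve.
#'
#' @param noise_sigma Additive Gaussian noise sigma (default 0).
#' @param seed Integer seed.
#' @param shape Canvas size (default `c(64, 64)`).
#' @return A [phantom_spec()].
#' @export
shapes_phantom_spec <- function(noise_sigma = 0, seed = 1L, shape = c(64L, 64L)) {
  phantom_spec(
    shape = shape,
    objects = list(
      phantom_rect(rows = c(10L, 30L), cols = c(8L, 28L), intensity = 180),
      phantom_circle(center = c(44, 42), radius = 10, intensity = 220),
      phantom_rect(rows = c(40L, 56L), cols = c(6L, 22L), intensity = 130)
    ),
    background = 100,
    noise_sigma = noise_sigma,
    seed = seed
  )
}

#' Render a phantom
#'
#' Renders the noiseless geometry, extracts the exact ground-truth edge mask
#' (object pixels with a 4-neighbor of different rendered intensity — a
#' 1-pixel-thin closed contour on the object side of each boundary), then
#' adds Gaussian noise and clips to `[0, L]`. The truth mask is by
#' construction independent of `noise_sigma`, and the output is fully
#' determined by the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (noisy [gray_image]), `clean` (noiseless
#'   [gray_image]), `truth` (logical ground-truth edge mask) and `spec`.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("`spec` must be a phantom_spec")
  M <- spec$shape[1]; N <- spec$shape[2]
  z <- matrix(spec$background, M, N)
  owned <- matrix(FALSE, M, N)
  for (ob in spec$objects) {
    sel <- if (ob$type == "rect") {
      m <- matrix(FALSE, M, N)
      m[ob$rows[1]:ob$rows[2], ob$cols[1]:ob$cols[2]] <- TRUE
      m
    } else {
      rr <- matrix(seq_len(M), M, N)
      cc <- matrix(seq_len(N), M, N, byrow = TRUE)
      (rr - ob$center[1])^2 + (cc - ob$center[2])^2 <= ob$radius^2
    }
    z[sel] <- ob$intensity
    owned <- owned | sel
  }
  differs <- matrix(FALSE, M, N)
  for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- shift_matrix(z, o[1], o[2], fill = NA_real_)
    differs <- differs | (!is.na(nb) & nb != z)
  }
  truth <- owned & differs
  px <- z
  if (spec$noise_sigma > 0) {
    px <- with_seed(spec$seed,
                    z + matrix(stats::rnorm(M * N, 0, spec$noise_sigma), M, N))
    px <- pmin(pmax(px, 0), spec$dynamic_range)
  }
  list(image = gray_image(px, spec$dynamic_range),
       clean = gray_image(z, spec$dynamic_range),
       truth = truth,
       spec = spec)
}

#' Degrade an edge map
#'
#' Deletes `round(drop_frac * |truth|)` uniformly chosen true pixels and adds
#' `round(add_frac * |truth|)` false positives at uniformly chosen locations
#' that are non-edge in the input map. Deterministic for a given seed.
#'
#' @param truth Logical edge map.
#' @param drop_frac,add_frac Fractions in `[0, 1]` of the input's edge count.
#' @param seed Integer seed.
#' @return Degraded logical edge map.
#' @export
degrade_edge_map <- function(truth, drop_frac = 0, add_frac = 0, seed = 1L) {
  truth <- as_edge_map(truth)
  if (drop_frac < 0 || drop_frac > 1 || add_frac < 0 || add_frac > 1)
    stopf("`drop_frac` and `add_frac` must lie in [0, 1]")
  n_true <- sum(truth)
  n_drop <- round(drop_frac * n_true)
  n_add <- round(add_frac * n_true)
  out <- truth
  with_seed(seed, {
    if (n_drop > 0) {
      idx <- which(truth)
      out[sample_int(idx, n_drop)] <- FALSE
    }
    if (n_add > 0) {
      idx <- which(!truth)
      out[sample_int(idx, min(n_add, length(idx)))] <- TRUE
    }
  })
  out
}

# sample() without the length-1 surprise
sample_int <- function(x, n) {
  if (length(x) == 1L) return(rep(x, min(n, 1L)))
  sample(x, n)
}
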