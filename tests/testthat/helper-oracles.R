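# Independent brute-force oracles, written against the definitions rather
# than the production code paths: per-pixel ray scans, literal replication
# medians, literal sort-and-trim means.

oracle_scan_neighbors <- function(mask, values, i, j) {
  dirs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  t <- numeric(0); d <- numeric(0)
  for (dd in dirs) {
    s <- 1
    repeat {
      ii <- i + s * dd[1]; jj <- j + s * dd[2]
      if (ii < 1 || ii > nrow(mask) || jj < 1 || jj > ncol(mask)) break
      if (mask[ii, jj]) {
        t <- c(t, values[ii, jj])
        d <- c(d, s * sqrt(dd[1]^2 + dd[2]^2))
        break
      }
      s <- s + 1
    }
  }
  list(t = t, d = d)
}

# median by literally materializing the replicated sequence
oracle_replicated_median <- function(t, w) {
  seqv <- rep(t, times = w)
  if (length(seqv) == 0) return(NA_real_)
  seqv <- sort(seqv)
  n <- length(seqv)
  if (n %% 2 == 1) seqv[(n + 1) / 2] else (seqv[n / 2] + seqv[n / 2 + 1]) / 2
}

oracle_value <- function(t, d, method, alpha = 0.125) {
  if (method == "weighted_mean") return(sum(t / d) / sum(1 / d))
  if (method %in% c("weighted_median", "central_weighted_median"))
    return(oracle_replicated_median(t, round(100 / d)))
  # alpha_trimmed, renormalized over survivors of the x = t/d ranking
  K <- length(t)
  Ta <- ceiling(alpha * K)
  if (K - 2 * Ta < 1) return(sum(t / d) / sum(1 / d))
  ord <- order(t / d)
  keep <- ord[(Ta + 1):(K - Ta)]
  sum(t[keep] / d[keep]) / sum(1 / d[keep])
}

# full naive reconstruction: dilation by shifting done with plain loops too
oracle_dilate <- function(mask, r) {
  M <- nrow(mask); N <- ncol(mask)
  out <- matrix(FALSE, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    ri <- max(1, i - r):min(M, i + r)
    ci <- max(1, j - r):min(N, j + r)
    out[i, j] <- any(mask[ri, ci])
  }
  out
}

oracle_reconstruct <- function(image, edges, method, alpha = 0.125, radius = 1) {
  px <- if (inherits(image, "gray_image")) image$pixels else image
  L <- if (inherits(image, "gray_image")) image$dynamic_range else 255
  dm <- oracle_dilate(edges, radius)
  values <- px * dm
  out <- matrix(0, nrow(px), ncol(px))
  out[dm] <- px[dm]
  if (!any(dm)) return(matrix(mean(px), nrow(px), ncol(px)))
  fallback <- mean(values[dm])
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (dm[i, j]) next
    nb <- oracle_scan_neighbors(dm, values, i, j)
    v <- if (length(nb$t) == 0) fallback else oracle_value(nb$t, nb$d, method, alpha)
    if (is.na(v)) v <- fallback
    out[i, j] <- v
  }
  pmin(pmax(out, 0), L)
}

# random grayscale-edge-map test instance
random_instance <- function(seed, M = 16, N = 16, density = 0.12) {
  set.seed(seed)
  img <- gray_image(matrix(runif(M * N, 0, 255), M, N))
  edges <- matrix(runif(M * N) < density, M, N)
  list(image = img, edges = edges)
}

per_window_gssim_oracle <- function(x, y, cfg = similarity_config()) {
  gx <- gradient_magnitude(x)
  gy <- gradient_magnitude(y)
  ws <- cfg$window_size
  L <- x$dynamic_range
  nr <- floor(nrow(x$pixels) / ws)
  nc <- floor(ncol(x$pixels) / ws)
  vals <- c()
  for (a in seq_len(nr)) for (b in seq_len(nc)) {
    rows <- ((a - 1) * ws + 1):(a * ws)
    cols <- ((b - 1) * ws + 1):(b * ws)
    st <- window_stats(x$pixels[rows, cols], y$pixels[rows, cols],
                       gx[rows, cols], gy[rows, cols])
    vals <- c(vals, gssim_window(st, cfg, L))
  }
  vals
}
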