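gem_of <- function(px, mask, radius = 0) {
  make_grayscale_edge_map(gray_image(px), mask, radius)
}

test_that("directional neighbor search honors distances and direction limits", {
  px <- matrix(50, 11, 11)
  mask <- matrix(FALSE, 11, 11)
  mask[5, 6] <- TRUE # one axial neighbor east of (5, 5)
  gem <- gem_of(px, mask)
  nb <- find_directional_neighbors(gem, 5, 5)
  expect_identical(nrow(nb), 1L)
  expect_equal(nb$d, 1)
  expect_equal(nb$t, 50)

  mask2 <- matrix(FALSE, 11, 11)
  mask2[7, 7] <- TRUE # southeast of (5, 5), two diagonal steps
  nb2 <- find_directional_neighbors(gem_of(px, mask2), 5, 5)
  expect_equal(nb2$d, 2 * sqrt(2))

  expect_identical(nrow(find_directional_neighbors(gem_of(px, matrix(FALSE, 11, 11)), 5, 5)), 0L)
  expect_error(find_directional_neighbors(gem, 5, 6), "on the dilated edge mask")
})

test_that("interpolator values match direct evaluation of their definitions", {
  # weighted mean
  expect_equal(weighted_mean_value(c(10, 20), c(1, 1)), 15)
  expect_equal(weighted_mean_value(42, 3.7), 42)
  expect_equal(weighted_mean_value(c(12, 0), c(1, 3)), 9) # (12 + 0) / (1 + 1/3)

  # weighted / central weighted median with the x100 integerization
  expect_equal(weighted_median_value(c(5, 9, 100), c(1, 1, 1)), 9)
  expect_equal(weighted_median_value(3, 2), 3)
  expect_equal(weighted_median_value(c(0, 10), c(1, 2)), 0) # weights 100, 50
  expect_equal(central_weighted_median_value(rep(7, 8), rep(1, 8)), 7)
  expect_equal(central_weighted_median_value(c(4, 8), c(1, 1)), 6)
  expect_equal(central_weighted_median_value(c(0, 10, 20), c(1, 1, 2)), 10)
  # weight rounding to zero drops the neighbor entirely
  expect_equal(central_weighted_median_value(c(0, 99), c(1, 300)), 0)
  expect_true(is.na(central_weighted_median_value(99, 300)))

  # alpha-trimmed mean
  expect_equal(alpha_trimmed_value(rep(3, 8), rep(1, 8), alpha = 0.125), 3)
  expect_equal(alpha_trimmed_value(c(0, 10, 10, 100), rep(1, 4), alpha = 0.125), 10)
  # K = 2 with T = 1 trims everything: falls back to the weighted mean
  expect_equal(alpha_trimmed_value(c(0, 10), c(1, 1), alpha = 0.3),
               weighted_mean_value(c(0, 10), c(1, 1)))
  expect_error(weighted_mean_value(numeric(0), numeric(0)), "nonempty")
  expect_error(alpha_trimmed_value(1, 1, alpha = 0.7), "alpha")
})

test_that("replication medians agree with a literal rep()-based oracle", {
  set.seed(31)
  for (i in 1:50) {
    K <- sample(1:8, 1)
    t <- round(runif(K, 0, 255), 2)
    d <- sample(c(1, sqrt(2), 2, 3, 2 * sqrt(2), 5), K, replace = TRUE)
    expect_equal(weighted_median_value(t, d),
                 oracle_replicated_median(t, round(100 / d)))
  }
})

test_that("production reconstruction equals the naive per-pixel oracle for all methods", {
  methods <- c("weighted_mean", "weighted_median", "central_weighted_median",
               "alpha_trimmed")
  for (seed in 1:6) {
    inst <- random_instance(seed)
    for (m in methods) {
      got <- reconstruct_image(inst$image, inst$edges,
                               reconstruction_config(method = m), selem_radius = 1)
      want <- oracle_reconstruct(inst$image, inst$edges, m)
      expect_lt(max(abs(got$pixels - want)), 1e-9)
    }
  }
})

test_that("reconstruction preserves on-mask pixels and stays within the neighbor hull", {
  inst <- random_instance(99, density = 0.15)
  gem <- make_grayscale_edge_map(inst$image, inst$edges, 1)
  for (m in c("weighted_mean", "alpha_trimmed", "central_weighted_median")) {
    rec <- reconstruct_image(inst$image, inst$edges, reconstruction_config(m))
    expect_identical(rec$pixels[gem$dilated_mask],
                     inst$image$pixels[gem$dilated_mask])
    # off-mask values lie between the min and max on-mask intensity
    on <- inst$image$pixels[gem$dilated_mask]
    expect_true(all(rec$pixels >= min(on) - 1e-9))
    expect_true(all(rec$pixels <= max(on) + 1e-9))
  }
})

test_that("all-equal distances collapse to plain mean/median, alpha = 0 to the weighted mean", {
  set.seed(13)
  for (i in 1:20) {
    K <- sample(2:8, 1)
    t <- runif(K, 0, 255)
    expect_equal(weighted_mean_value(t, rep(2, K)), mean(t))
    expect_equal(central_weighted_median_value(t, rep(2, K)), median(t))
    d <- sample(c(1, 2, 3, sqrt(2)), K, replace = TRUE)
    expect_equal(alpha_trimmed_value(t, d, alpha = 0), weighted_mean_value(t, d))
  }
})

test_that("degenerate edge maps follow the documented fallback policies", {
  px <- matrix(rep(c(60, 200), each = 72), 12, 12)
  img <- gray_image(px)
  # all-true mask: reconstruction is the identity
  rec <- reconstruct_image(img, matrix(TRUE, 12, 12))
  expect_identical(rec$pixels, px)
  # constant image with any nonempty mask reconstructs the constant
  cimg <- gray_image(matrix(77, 12, 12))
  m <- matrix(FALSE, 12, 12); m[3, 3] <- TRUE
  expect_equal(reconstruct_image(cimg, m)$pixels, matrix(77, 12, 12),
               tolerance = 1e-12)
  # empty mask: constant fallback at the global mean, with a warning
  expect_warning(rec0 <- reconstruct_image(img, matrix(FALSE, 12, 12)), "empty edge map")
  expect_true(all(rec0$pixels == mean(px)))
})

test_that("adding true edge pixels does not worsen reconstruction of noiseless phantoms", {
  worse <- 0
  for (seed in 1:8) {
    ph <- make_phantom(shapes_phantom_spec(noise_sigma = 0, seed = seed))
    deg <- degrade_edge_map(ph$truth, drop_frac = 0.6, add_frac = 0, seed = seed)
    # adding back edge pixels = comparing the degraded map against the truth
    mae_full <- mse_mae(ph$image, reconstruct_image(ph$image, ph$truth))["mae"]
    mae_deg <- mse_mae(ph$image, reconstruct_image(ph$image, deg))["mae"]
    if (mae_full > mae_deg + 1e-9) worse <- worse + 1
  }
  expect_lte(worse, 1)
})
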