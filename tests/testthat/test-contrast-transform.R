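test_that("histogram-spread exponent peaks at the center and decays to alpha_min", {
  cfg <- alpha_config(alpha_min = 0.4, alpha_max = 0.9, s = 1,
                      hist_center = 2, hist_scale = pi)
  expect_equal(alpha_from_histogram(matrix(2), cfg)[1, 1], 0.9)
  expect_equal(alpha_from_histogram(matrix(1e6), cfg)[1, 1], 0.4)
  # half decay: (h - a)^2 = 2 scale^2 ln 2 puts alpha at the midpoint
  h_half <- 2 + sqrt(2 * pi^2 * log(2))
  expect_equal(alpha_from_histogram(matrix(h_half), cfg)[1, 1],
               0.9 - (0.9 - 0.4) / 2)
})

test_that("entropy exponent interpolates between the map extremes", {
  cfg <- alpha_config(alpha_min = 0.4, alpha_max = 0.9, s = 1)
  eps <- matrix(c(0.2, 0.5, 0.8), 1)
  a <- alpha_from_entropy(eps, cfg)
  expect_equal(as.numeric(a), c(0.4, 0.65, 0.9))
  # degenerate constant map collapses to alpha_min
  expect_true(all(alpha_from_entropy(matrix(3, 2, 2), cfg) == 0.4))
})

test_that("dispersion exponent decreases from alpha_max to alpha_min", {
  cfg <- alpha_config(alpha_min = 0.4, alpha_max = 0.9, s = 1)
  sigma <- matrix(c(0, 30, 60), 1) # normalized to 0, 0.5, 1
  a <- alpha_from_std(sigma, cfg)
  expect_equal(a[1, 1], 0.9)
  expect_equal(a[1, 2], (0.4 + 0.9) / 2)
  expect_equal(a[1, 3], 0.4)
  expect_true(all(alpha_from_std(matrix(0, 2, 2), cfg) == 0.9))
})

test_that("all exponent maps respect the configured band", {
  cfg <- alpha_config(alpha_min = 0.3, alpha_max = 0.8, s = 2.5,
                      hist_center = 10, hist_scale = 4)
  for (seed in 1:5) {
    set.seed(seed)
    feat <- matrix(runif(64, 0, 120), 8, 8)
    for (a in list(alpha_from_histogram(feat, cfg),
                   alpha_from_entropy(feat, cfg),
                   alpha_from_std(feat, cfg))) {
      expect_true(all(a >= 0.3 - 1e-12 & a <= 0.8 + 1e-12))
    }
  }
  expect_error(alpha_config(alpha_min = 0), "alpha_min")
  expect_error(alpha_config(alpha_min = 0.8, alpha_max = 0.5), "alpha_min")
  expect_error(alpha_config(alpha_max = 1.2), "alpha_max")
  expect_error(alpha_config(hist_scale = 0), "hist_scale")
})

test_that("the contrast transform fixes its three anchor points", {
  cfg <- contrast_transform_config(R = 1, A0 = 0, B0 = 0)
  set.seed(1)
  C <- matrix(runif(100), 10, 10)
  C[1] <- 0; C[2] <- 1 # pin the extremes
  alpha <- matrix(0.7, 10, 10)
  out <- enhance_local_contrast(C, alpha, cfg)
  c_hat <- mean(C)
  expect_equal(out[C == 0], 0)
  expect_equal(out[C == 1], 1)
  # at the pivot both branches give R/2: ramp map with mean exactly 0.5
  Cp <- matrix(seq(0, 1, length.out = 25), 5, 5)
  expect_equal(enhance_local_contrast(Cp, matrix(0.7, 5, 5), cfg)[Cp == 0.5],
               0.5)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("with unit exponent the transform reduces to two affine segments", {
  cfg <- contrast_transform_config()
  set.seed(2)
  C <- matrix(runif(144), 12, 12)
  out <- enhance_local_contrast(C, matrix(1, 12, 12), cfg)
  c_min <- min(C); c_max <- max(C); c_hat <- mean(C)
  closed <- ifelse(C <= c_hat,
                   0.5 * (C - c_min) / (c_hat - c_min),
                   1 - 0.5 * (c_max - C) / (c_max - c_hat))
  expect_equal(out, closed, tolerance = 1e-12)
})

test_that("the transform is monotone nondecreasing within each branch", {
  cfg <- contrast_transform_config()
  set.seed(3)
  for (alpha_val in c(0.3, 0.6, 1)) {
    C <- matrix(sort(runif(64)), 8, 8)
    out <- enhance_local_contrast(C, matrix(alpha_val, 8, 8), cfg)
    c_hat <- mean(C)
    lower <- sort(out[C <= c_hat]); upper <- sort(out[C > c_hat])
    expect_equal(out[C <= c_hat], lower)
    expect_equal(out[C > c_hat], upper)
  }
})

test_that("a degenerate contrast map passes through untouched", {
  cfg <- contrast_transform_config()
  C <- matrix(0.25, 4, 4)
  expect_identical(enhance_local_contrast(C, matrix(0.5, 4, 4), cfg), C)
})

test_that("transform configuration is validated", {
  expect_error(contrast_transform_config(A0 = 0.6), "A0")
  expect_error(contrast_transform_config(B0 = -1), "B0")
  expect_error(contrast_transform_config(R = 0), "R")
})

test_that("reconstruction applies the mean-anchored gain rule", {
  # constant window mean 100, pixel 150, gain 2 -> 200
  img <- matrix(100, 5, 5)
  img[3, 3] <- 150
  win <- window_spec(3, 3)
  st_mean <- 100 + 50 / 9 # window mean at the bright pixel
  C <- local_contrast_map(img, win)
  out <- reconstruct_image(img, C, 2 * C, win)
  expect_equal(out[3, 3], floor(st_mean + (150 - st_mean) * 2 + 0.5))
  # unit gain leaves the image unchanged (to rounding)
  out_id <- reconstruct_image(img, C, C, win)
  expect_true(max(abs(out_id - img)) <= 1)
  # constant image is untouched via the zero-contrast guard
  cimg <- matrix(42, 4, 4)
  Z <- matrix(0, 4, 4)
  expect_identical(reconstruct_image(cimg, Z, Z, win), cimg)
})

test_that("reconstruction preserves position relative to the window mean", {
  set.seed(9)
  img <- rand_gray(12, 12, 21)
  win <- window_spec(3, 3)
  C <- local_contrast_map(img, win)
  alpha <- alpha_from_entropy(fuzzy_entropy_map(img, win), alpha_config())
  Cs <- enhance_local_contrast(C, alpha, contrast_transform_config())
  st <- fuzzycontrast:::window_stack(img, win)
  m_w <- Reduce(`+`, st) / length(st)
  out <- reconstruct_image(img, C, Cs, win)
  # gains are nonnegative, so sides of the local mean are preserved
  # (up to the one-intensity rounding step)
  expect_true(all(out[img > m_w] >= m_w[img > m_w] - 1))
  expect_true(all(out[img < m_w] <= m_w[img < m_w] + 1))
})
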