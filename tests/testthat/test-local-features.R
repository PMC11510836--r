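# Frozen expected values below were computed by direct hand evaluation of
# the window formulas on tiny windows (see also the brute-force oracle
# helpers, which recompute every map independently).

test_that("local contrast is the normalized window range", {
  img <- matrix(100, 5, 5)
  expect_true(all(local_contrast_map(img) == 0))
  img[3, 3] <- 155 # window min 100, max 155
  C <- local_contrast_map(img)
  expect_equal(C[3, 3], 55 / 255)
  img[3, 3] <- 255; img[3, 2] <- 0
  expect_equal(local_contrast_map(img)[3, 3], 1)
})

test_that("window kernels reproduce hand-computed 2x2 values", {
  # the 2x2 window {0, 0, 255, 255} with unit memberships
  f <- list(matrix(0), matrix(0), matrix(255), matrix(255))
  counts <- fuzzycontrast:::window_counts(f)
  # fuzzy entropy: 4 terms of (0.5 ln 0.5 + 0.5 ln 0.5) / ln 4, a = 1
  expect_equal(fuzzycontrast:::entropy_from_counts(counts, 4, 1)[1, 1], 2)
  # histogram spread: range 255 / max bin count 2
  spread <- (Reduce(pmax, f) - Reduce(pmin, f)) / Reduce(pmax, counts)
  expect_equal(spread[1, 1], 127.5)
  # entropy is linear in the a coefficient
  expect_equal(fuzzycontrast:::entropy_from_counts(counts, 4, 2.5)[1, 1], 5)
})

test_that("weighted dispersion features match hand-summed 2x2 loops", {
  # embed {0,0,255,255} in a 1x4 image with a 1x1-high window: use direct
  # dispersion core on stacks instead
  f <- list(matrix(0), matrix(0), matrix(255), matrix(255))
  mu1 <- list(matrix(1), matrix(1), matrix(1), matrix(1))
  mloc <- Reduce(`+`, f) / 4
  wss <- Reduce(`+`, Map(function(a, m) (a - mloc)^2 * m, f, mu1))
  musum <- Reduce(`+`, mu1)
  expect_equal(2 * sqrt(wss / musum)[1, 1] / 255, 1)        # global contrast
  expect_equal(sqrt(wss / musum / 4)[1, 1], 63.75)          # fuzzy std
})

test_that("homogeneous windows yield zero spread, entropy and dispersion", {
  img <- matrix(77, 6, 6)
  mu <- matrix(0.5, 6, 6)
  expect_true(all(histogram_spread_map(img) == 0))
  expect_true(all(fuzzy_entropy_map(img) == 0))
  expect_true(all(fuzzy_std_map(img, mu) == 0))
  expect_true(all(global_contrast_map(img, mu) == 0))
})

test_that("zero memberships give zero weighted features by convention", {
  img <- rand_gray(6, 6, 11)
  mu <- matrix(0, 6, 6)
  expect_true(all(fuzzy_std_map(img, mu) == 0))
  expect_true(all(global_contrast_map(img, mu) == 0))
})

test_that("histogram spread separates homogeneous from binary windows", {
  img <- matrix(0, 9, 9)
  img[, 5:9] <- 255 # binary edge region
  h <- histogram_spread_map(img)
  expect_true(all(h[, 1:2] == 0))
  expect_true(max(h) > 40) # edge windows have split histograms
  # 3x3 window of 9 distinct values 10..90: spread 80 / hmax 1
  img2 <- matrix(seq(10, 90, by = 10), 3, 3)
  expect_equal(histogram_spread_map(img2)[2, 2], 80)
})

test_that("every sliding-window map agrees with the brute-force oracle", {
  for (seed in 1:5) {
    img <- rand_gray(16, 16, seed)
    mu <- refine_membership(fuzzify(normalize_image(img)))
    for (ws in c(3L, 5L)) {
      win <- window_spec(ws, ws)
      expect_equal(local_contrast_map(img, win),
                   oracle_feature_map(img, ws, ws, "local_contrast"),
                   tolerance = 1e-9)
      expect_equal(histogram_spread_map(img, win),
                   oracle_feature_map(img, ws, ws, "histogram_spread"),
                   tolerance = 1e-9)
      expect_equal(fuzzy_entropy_map(img, win, a_coeff = 1.3),
                   oracle_feature_map(img, ws, ws, "fuzzy_entropy",
                                      a_coeff = 1.3),
                   tolerance = 1e-9)
      expect_equal(global_contrast_map(img, mu, win),
                   oracle_feature_map(img, ws, ws, "global_contrast", mu = mu),
                   tolerance = 1e-9)
      expect_equal(fuzzy_std_map(img, mu, win),
                   oracle_feature_map(img, ws, ws, "fuzzy_std", mu = mu),
                   tolerance = 1e-9)
    }
  }
})

test_that("feature maps are translation-equivariant in the interior", {
  img <- rand_gray(14, 14, 42)
  shifted <- img[c(2:14, 14), ] # shift up one row (bottom row padded)
  C1 <- local_contrast_map(img)
  C2 <- local_contrast_map(shifted)
  expect_equal(C2[2:11, ], C1[3:12, ])
  e1 <- fuzzy_entropy_map(img)
  e2 <- fuzzy_entropy_map(shifted)
  expect_equal(e2[2:11, ], e1[3:12, ])
})

test_that("contrast maps are invariant to a constant intensity offset", {
  img <- rand_gray(10, 10, 7, levels = 200L) # headroom for +50
  mu <- matrix(1, 10, 10)
  expect_equal(local_contrast_map(img + 50), local_contrast_map(img))
  expect_equal(global_contrast_map(img + 50, mu), global_contrast_map(img, mu))
})

test_that("fuzzy entropy depends only on the multiset of window counts", {
  img <- rand_gray(10, 10, 13, levels = 8L)
  # permute intensity labels: x -> 7 - x is a bijection on {0..7}
  relabeled <- 7 - img
  expect_equal(fuzzy_entropy_map(relabeled), fuzzy_entropy_map(img))
})

test_that("window specifications are validated", {
  expect_error(window_spec(2, 3), "odd")
  expect_error(window_spec(3, 0), "odd")
  expect_error(fuzzy_entropy_map(rand_gray(4, 4, 1), window_spec(1, 1)),
               "at least 2")
  expect_error(local_contrast_map(rand_gray(4, 4, 1), win = list(3, 3)),
               "window_spec")
})
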