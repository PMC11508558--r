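test_that("gradient-family measures vanish on constant and linear frames", {
  const <- matrix(7, 8, 8)
  ramp <- matrix(rep(1:8, each = 8), 8, 8)   # ramp[i, j] = j
  for (fn in list(function(m) fm_tenengrad(m, 2), function(m) fm_tenengrad(m, 1),
                  function(m) fm_laplacian_energy(m, "EOL"),
                  function(m) fm_laplacian_energy(m, "SML"),
                  function(m) fm_laplacian_energy(m, "DLF"),
                  function(m) fm_derivative(m, 1, 1), function(m) fm_derivative(m, 1, 2),
                  function(m) fm_derivative(m, 2, 2), fm_energy_of_gradient, fm_boddeke))
    expect_equal(fn(const), 0)
  # second derivative of a linear ramp is zero
  expect_equal(fm_laplacian_energy(ramp, "EOL"), 0)
  expect_equal(fm_laplacian_energy(ramp, "SML"), 0)
  expect_equal(fm_boddeke(ramp), 0)   # no variation along the spatial axis
})

test_that("Tenengrad matches the hand-convolved ramp and its threshold rule", {
  ramp <- matrix(rep(1:5, times = 5), 5, 5, byrow = TRUE)  # I(i,j) = j
  expect_equal(fm_tenengrad(ramp, a = 2, threshold = 0), 9 * 64)
  expect_equal(fm_tenengrad(ramp, a = 2, threshold = 100), 0)
  # Prewitt response on the same ramp: gx = 6 at every interior pixel
  expect_equal(fm_tenengrad(ramp, a = 1, threshold = 0), 9 * 36)
})

test_that("SML on a single bright pixel accumulates 8v over the interior", {
  v <- 13
  img <- matrix(0, 7, 7); img[4, 4] <- v
  expect_equal(fm_laplacian_energy(img, "SML"), 8 * v)
})

test_that("difference measures reproduce enumeration examples", {
  col4 <- matrix(c(1, 2, 3, 4), 4, 1)
  expect_equal(fm_derivative(col4, k = 2, p = 2), 8)   # (1-3)^2 + (2-4)^2
  expect_equal(fm_derivative(col4, k = 1, p = 1), 3)
  expect_error(fm_derivative(col4, k = 4), "lag")

  expect_equal(fm_energy_of_gradient(rbind(c(0, 1), c(2, 3))), 10)
  expect_equal(fm_boddeke(matrix(1:5, 5, 1)), 12)
  expect_equal(fm_vollath_f4(matrix(1:3, 3, 1)), 5)
  expect_equal(fm_vollath_f5(matrix(1:3, 3, 1)), -4)
})

test_that("EIG checkerboard closed form matches enumeration", {
  v <- 3; n <- 6L
  cb <- v * outer(1:n, 1:n, function(i, j) (i + j) %% 2)
  expect_equal(fm_energy_of_gradient(cb), 2 * (n - 1) * n * v^2)
})

test_that("Vollath measures obey their constant-frame closed forms", {
  v <- 5; n <- 6L
  const <- matrix(v, n, n)
  expect_equal(fm_vollath_f4(const), v^2 * n)          # v^2 n(n-1) - v^2 n(n-2)
  expect_equal(fm_vollath_f5(const), -n * v^2)
  expect_equal(fm_vollath_f4(matrix(0, 4, 4)), 0)
  expect_equal(fm_vollath_f5(matrix(0, 4, 4)), 0)
})

test_that("normalized variance matches hand computation and scaling law", {
  m <- rbind(c(0, 2), c(0, 2))
  expect_equal(fm_normalized_variance(m), 1)
  expect_equal(fm_normalized_variance(matrix(9, 5, 5)), 0)
  expect_error(fm_normalized_variance(matrix(0, 4, 4)), "zero-mean")
  r <- random_int_frame(42) + 1
  expect_equal(fm_normalized_variance(3.7 * r), 3.7 * fm_normalized_variance(r))
})

test_that("entropy hits exact uniform-histogram values", {
  expect_equal(fm_entropy(matrix(100, 4, 4)), 0)
  four <- matrix(rep(c(10, 20, 30, 40), 4), 4, 4)
  expect_equal(fm_entropy(four), 2)
  eight <- matrix(rep(1:8, 8), 8, 8)
  expect_equal(fm_entropy(eight), 3)
})

test_that("log-histogram variance matches direct summation and degenerates to 0", {
  expect_equal(fm_log_histogram(matrix(50, 4, 4)), 0)
  # two occupied levels 0 and 1, half the pixels each
  m <- matrix(c(0, 1), 4, 4)
  e <- 0 * log(0.5) + 1 * log(0.5)
  expect_equal(fm_log_histogram(m),
               (0 - e)^2 * log(0.5) + (1 - e)^2 * log(0.5))
  expect_lte(fm_log_histogram(random_int_frame(1)), 0)
})

test_that("weighted histogram reproduces the single-bright-pixel value and monotonicity", {
  expect_equal(fm_weighted_histogram(matrix(0, 4, 4)), 0)
  m <- matrix(0, 8, 8); m[1, 1] <- 1000
  expect_equal(fm_weighted_histogram(image_frame(m)), 1e-15 * 1000^5)
  base <- random_int_frame(3, max_val = 200)
  brighter <- base; brighter[5, 5] <- 255
  expect_gte(fm_weighted_histogram(brighter), fm_weighted_histogram(base))
})

test_that("histogram measures are invariant to spatial permutation", {
  set.seed(8)
  m <- random_int_frame(8)
  p <- matrix(sample(as.numeric(m)), nrow(m), ncol(m))
  expect_equal(fm_entropy(p), fm_entropy(m))
  expect_equal(fm_log_histogram(p), fm_log_histogram(m))
  expect_equal(fm_weighted_histogram(p), fm_weighted_histogram(m))
})

test_that("Fourier measure kills DC and prefers higher spatial frequency", {
  expect_equal(fm_fourier(matrix(0, 8, 8)), 0)
  expect_equal(fm_fourier(matrix(5, 8, 8)), 0)
  x <- seq_len(32)
  lo <- outer(rep(1, 32), cos(2 * pi * 2 * x / 32))
  hi <- outer(rep(1, 32), cos(2 * pi * 8 * x / 32))
  expect_gt(fm_fourier(hi), fm_fourier(lo))
})

test_that("block DCT satisfies Parseval and offset invariance", {
  expect_equal(fm_dct(matrix(3, 8, 8)), 0)
  b <- random_int_frame(11)
  Tm <- hsfocus:::dct_matrix(8L)
  S <- Tm %*% b %*% t(Tm)
  expect_equal(sum(S^2), sum(b^2), tolerance = 1e-12)
  expect_equal(fm_dct(b), sum(S^2) - S[1, 1]^2, tolerance = 1e-9)
  expect_equal(fm_dct(b + 40), fm_dct(b), tolerance = 1e-6)
})

test_that("mid-frequency DCT reproduces its dot-product and ramp examples", {
  expect_equal(fm_midfreq_dct(matrix(2, 6, 6)), 0)
  op <- matrix(c(1, 1, -1, -1, 1, 1, -1, -1,
                 -1, -1, 1, 1, -1, -1, 1, 1), 4, 4, byrow = TRUE)
  expect_equal(fm_midfreq_dct(op), 256)
  ramp <- matrix(rep(1:10, each = 10), 10, 10)
  expect_equal(fm_midfreq_dct(ramp), 0)
})

test_that("wavelet transform annihilates constants and conserves energy", {
  const <- matrix(4, 16, 16)
  b <- dwt2_db6(const)
  expect_lt(sum(abs(b$lh)) + sum(abs(b$hl)) + sum(abs(b$hh)), 1e-9)
  x <- random_int_frame(21, 16, 16)
  b2 <- dwt2_db6(x)
  expect_equal(sum(b2$ll^2) + sum(b2$lh^2) + sum(b2$hl^2) + sum(b2$hh^2),
               sum(x^2), tolerance = 1e-9)
})

test_that("wavelet measures: WL1 sign-flip invariance, WL2/WL3 non-negative", {
  x <- random_int_frame(5, 16, 16)
  xc <- x - mean(x)
  expect_equal(fm_wavelet(xc, "WL1"), fm_wavelet(-xc, "WL1"), tolerance = 1e-9)
  for (v in c("WL1", "WL2", "WL3")) expect_gte(fm_wavelet(x, v), 0)
  expect_error(fm_wavelet(matrix(1, 8, 8), "WL1"), "too small")
})

test_that("every convolution/difference measure matches its naive oracle", {
  pairs <- oracle_fm_pairs()
  for (s in 1:6) {
    m <- random_int_frame(100 + s)
    for (id in names(pairs))
      expect_equal(pairs[[id]]$pkg(m), pairs[[id]]$ora(m),
                   info = paste(id, "seed", s))
  }
})

test_that("thresholds gate the thresholded measures consistently with the oracle", {
  for (s in 1:3) {
    m <- random_int_frame(200 + s)
    for (th in c(30, 120)) {
      expect_equal(fm_tenengrad(m, 2, th), naive_tenengrad(m, 2, th))
      expect_equal(fm_derivative(m, 1, 1, th), naive_derivative(m, 1, 1, th))
      expect_equal(fm_derivative(m, 2, 2, th), naive_derivative(m, 2, 2, th))
    }
  }
})

test_that("compute_all_fms returns all 22 measures in stable order", {
  m <- random_int_frame(9, 16, 16)
  r1 <- compute_all_fms(image_frame(m))
  expect_equal(nrow(r1), 22L)
  expect_identical(r1$fm_id, fm_registry()$fm_id)
  expect_identical(r1, compute_all_fms(image_frame(m)))
  expect_true(all(r1$value[r1$family == "gradient"] >= 0))
  # constant frame: gradient family identically zero, no fatal failures
  r2 <- compute_all_fms(image_frame(matrix(6, 16, 16)))
  expect_equal(nrow(r2), 22L)
  expect_true(all(r2$value[r2$family == "gradient"] == 0))
})

test_that("the VAR alias resolves to LOG and unknown ids fail", {
  r <- compute_all_fms(random_int_frame(2, 16, 16), fms = c("VAR", "TEN1"))
  expect_identical(r$fm_id, c("LOG", "TEN1"))
  expect_error(compute_all_fms(random_int_frame(2), fms = "XYZ"), "unknown")
})
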