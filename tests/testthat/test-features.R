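test_that("SDNN is the population standard deviation of the intervals", {
  expect_equal(hrv_sdnn(c(800, 800, 800)), 0)
  expect_equal(hrv_sdnn(c(790, 810)), 10)
  x <- c(812, 795, 803, 780, 820)
  m <- sum(x) / 5
  expect_equal(hrv_sdnn(x), sqrt(sum((x - m)^2) / 5))
  expect_error(hrv_sdnn(800), class = "cardiopipe_invalid_argument")
})

test_that("QRS duration recovers the generator's configured bump width", {
  bt <- gen_ecg_beats(3, 3, 187, noise_sd = 0, seed = 1)
  cp <- attr(bt, "class_params")
  fs <- bt$fs
  for (i in seq_len(nrow(bt$signals))) {
    truth <- cp$qrs_ms[bt$labels[i] + 1]
    got <- qrs_duration(bt$signals[i, ], fs)
    expect_lt(abs(got - truth), 2 * 1000 / fs + 1e-9)
  }
  pulse <- c(rep(0, 20), rep(1, 10), rep(0, 20))
  expect_equal(qrs_duration(pulse, 125), 80)
  expect_error(qrs_duration(numeric(50), 125),
               class = "cardiopipe_undefined_qrs")
})

test_that("periodogram concentrates a sinusoid and satisfies Parseval", {
  fs <- 125; n <- 250; f0 <- 10
  x <- sin(2 * pi * f0 * (0:(n - 1)) / fs)
  sp <- psd_periodogram(x, fs)
  peak_bin <- which.min(abs(sp$freq - f0))
  expect_gte(sp$power[peak_bin] / sum(sp$power), 0.9)
  expect_equal(psd_periodogram(numeric(64), fs)$power, rep(0, 33))
  set.seed(3)
  y <- rnorm(100)
  two <- psd_periodogram(y, fs, one_sided = FALSE)
  expect_equal(sum(two$power) * fs / 100, mean(y^2), tolerance = 1e-8)
  one <- psd_periodogram(y, fs)
  expect_equal(sum(one$power) * fs / 100, mean(y^2), tolerance = 1e-8)
  lit <- psd_periodogram(y, fs, squared = FALSE, one_sided = FALSE)
  expect_equal(lit$power, Mod(stats::fft(y)) / 100)
})

test_that("band powers partition the one-sided spectrum", {
  set.seed(4)
  x <- rnorm(128)
  sp <- psd_periodogram(x, 125)
  bp <- band_powers(sp, list(lo = c(0, 20), hi = c(20, 63)))
  expect_equal(sum(bp), sum(sp$power[sp$freq < 63]) * diff(sp$freq[1:2]))
})

test_that("shape descriptors: circle, ellipse, bounding box", {
  ax <- seq_len(101) - 51
  disk <- outer(ax, ax, function(r, c) r^2 + c^2 <= 900)
  sf <- shape_features(disk)
  expect_equal(sf$eccentricity, 0, tolerance = 0.02)
  expect_equal(sf$aspect_ratio, 1)
  expect_gt(sf$circularity, 0.85)
  expect_lt(sf$circularity, 1.1)
  # frozen against the Moore boundary-walk perimeter of this rasterization
  expect_equal(sf$circularity, 0.9058530, tolerance = 1e-6)
  b <- 30 * sqrt(1 - 0.6^2)
  ell <- outer(ax, ax, function(r, c) (c / 30)^2 + (r / b)^2 <= 1)
  expect_equal(shape_features(ell)$eccentricity, 0.6, tolerance = 0.02)
  square <- matrix(FALSE, 20, 20); square[5:14, 3:12] <- TRUE
  expect_equal(shape_features(square)$aspect_ratio, 1)
  expect_error(shape_features(matrix(FALSE, 4, 4)),
               class = "cardiopipe_invalid_argument")
})

test_that("GLCM: constant image, hand-enumerated checkerboard, banded image", {
  g <- glcm_features(matrix(7, 8, 8))
  expect_equal(g[["energy"]], 1)
  expect_equal(g[["contrast"]], 0)
  expect_equal(g[["homogeneity"]], 1)
  expect_equal(g[["entropy"]], 0)
  # 2x2 checkerboard, one horizontal offset: pairs (0,1) and (1,0);
  # symmetrized and normalized P = [[0,.5],[.5,0]]
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  g2 <- glcm_features(cb, glcm_spec(distance = 1, angles = 0, levels = 2))
  expect_equal(g2[["contrast"]], 1)
  expect_equal(g2[["correlation"]], -1)
  expect_equal(g2[["energy"]], 0.5)
  expect_equal(g2[["homogeneity"]], 0.5)
  expect_equal(g2[["entropy"]], log(2))
  # linear ramp: neighbor intensity is a linear function of the center
  ramp <- matrix(rep(0:7, each = 8), 8, 8, byrow = TRUE)
  g3 <- glcm_features(ramp, glcm_spec(distance = 1, angles = 0, levels = 8,
                                      symmetric = FALSE))
  expect_equal(g3[["correlation"]], 1, tolerance = 1e-9)
})

test_that("LBP codes match a per-pixel loop oracle exactly", {
  expect_equal(lbp_histogram(matrix(5, 6, 6))[256], 1)
  bright <- matrix(0, 3, 3); bright[2, 2] <- 9
  expect_equal(lbp_histogram(bright)[1], 1)   # code 0
  set.seed(6)
  for (rep in 1:5) {
    img <- matrix(sample(0:9, 25, TRUE), 5, 5)
    h <- lbp_histogram(img)
    expect_equal(sum(h), 1)
    oracle <- tabulate(oracle_lbp_codes(img) + 1, nbins = 256) / 9
    expect_identical(h, oracle)
  }
})

test_that("statistical moments use the population formulas", {
  m <- stat_moments(1:5)
  expect_equal(m$skewness, 0)
  expect_equal(m$mean, 3); expect_equal(m$median, 3)
  m2 <- stat_moments(c(2, 4))
  expect_equal(m2$mean, 3); expect_equal(m2$median, 3); expect_equal(m2$sd, 1)
  set.seed(7)
  x <- rnorm(1e5)
  expect_lt(abs(stat_moments(x)$kurtosis), 0.05)
  if (requireNamespace("e1071", quietly = TRUE)) {
    expect_equal(stat_moments(x)$skewness, e1071::skewness(x, type = 1))
    expect_equal(stat_moments(x)$kurtosis, e1071::kurtosis(x, type = 1))
  }
  expect_equal(stat_moments(rep(2, 5))$skewness, 0)
})

test_that("extract_all yields deterministic schemas with finite values", {
  bt <- gen_ecg_beats(5, 3, 187, noise_sd = 0.05, seed = 1)
  f1 <- extract_all("ecg", bt)
  expect_equal(f1$names, c("mean", "median", "sd", "skewness", "kurtosis",
                           "qrs_ms", "bp_low", "bp_mid", "bp_high",
                           "hrv_proxy"))
  expect_true(all(is.finite(f1$values)))
  expect_identical(f1$names, extract_all("ecg", bt)$names)
  im <- gen_cardiac_images(2, 3, 48, seed = 2)
  f2 <- extract_all("image", im)
  expect_equal(ncol(f2$values), 10L)
  expect_true(all(is.finite(f2$values)))
  rt <- gen_patient_records(40, 3, 3, seed = 3)
  f3 <- extract_all("tabular", rt)
  expect_equal(ncol(f3$values), 6L + 5L)
  expect_true(all(is.finite(f3$values)))
  md <- clean_metadata(gen_metadata(50, seed = 4))
  f4 <- extract_all("metadata", md)
  expect_true(all(is.finite(f4$values)))
})
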