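test_that("wavelet decomposition round-trips exactly", {
  set.seed(4)
  for (n in c(64, 100, 187)) {
    x <- rnorm(n)
    dec <- wavelet_decompose(x, "db4", 3)
    expect_equal(wavelet_reconstruct(dec), x, tolerance = 1e-10)
  }
  expect_error(wavelet_decompose(rnorm(4), "db4", 3),
               class = "cardiopipe_invalid_argument")
})

test_that("denoising: zero in, zero out; SNR gain on noisy beats", {
  expect_equal(wavelet_denoise(numeric(64)), numeric(64))
  clean <- gen_ecg_beats(1, 2, 187, noise_sd = 0, seed = 1)$signals[1, ]
  set.seed(10)
  gains <- replicate(50, {
    e <- rnorm(187)
    e <- e * sqrt(sum(clean^2) / 10^(5 / 10) / sum(e^2))  # exactly 5 dB in
    noisy <- clean + e
    c(snr_db(clean, noisy), snr_db(clean, wavelet_denoise(noisy)))
  })
  expect_equal(median(gains[1, ]), 5, tolerance = 1e-12)
  expect_gte(median(gains[2, ]), 10)
})

test_that("hard thresholding a pure-noise signal removes energy", {
  set.seed(11)
  x <- rnorm(256)
  y <- wavelet_denoise(x, denoise_spec(threshold_rule = "universal-hard"))
  expect_lt(sum(y^2), sum(x^2))
})

test_that("repeated denoising is stable (second pass changes less)", {
  clean <- gen_ecg_beats(1, 2, 187, noise_sd = 0, seed = 2)$signals[1, ]
  set.seed(12)
  noisy <- clean + rnorm(187, 0, 0.1)
  d1 <- wavelet_denoise(noisy)
  d2 <- wavelet_denoise(d1)
  expect_lt(sum((d2 - d1)^2), sum((d1 - noisy)^2))
})

test_that("min-max normalization endpoints, degenerate case, and properties", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-3, 1), 0, 10), c(0, 10))
  expect_warning(out <- minmax_normalize(c(7, 7, 7)), "degenerate")
  expect_equal(out, c(0, 0, 0))
  set.seed(1)
  for (i in 1:5) {
    v <- rnorm(50)
    s <- minmax_normalize(v, -1, 2)
    expect_true(all(s >= -1 & s <= 2))
    expect_equal(order(s), order(v))
  }
})

test_that("fitted normalization replays on held-out data", {
  spec <- fit_normalization(c(2, 4, 10))
  expect_equal(apply_normalization(c(6, 14), spec), c(0.5, 1.5))
})

test_that("histogram equalization matches the per-pixel CDF formula", {
  img <- matrix(c(0L, 2L, 1L, 3L), 2, 2)   # [[0,1],[2,3]]
  # cdf = (.25,.5,.75,1); round(cdf*3) half-up = (1,2,2,3)
  expect_equal(hist_equalize(img, 4), matrix(c(1L, 2L, 2L, 3L), 2, 2))
  expect_equal(hist_equalize(matrix(5L, 3, 3), 8), matrix(7L, 3, 3))
  expect_error(hist_equalize(matrix(9L, 2, 2), 8),
               class = "cardiopipe_invalid_argument")
})

test_that("equalization flattens the cumulative histogram and keeps order", {
  set.seed(2)
  img <- matrix(sample(0:63, 400, TRUE, prob = (64:1)^2), 20, 20)
  eq <- hist_equalize(img, 64)
  ks <- function(m) {
    cdf <- cumsum(tabulate(m + 1L, 64)) / length(m)
    max(abs(cdf - (1:64) / 64))
  }
  expect_lt(ks(eq), ks(img))
  expect_equal(length(eq), length(img))
  ord <- order(img)
  expect_true(all(diff(eq[ord]) >= 0))
})

test_that("bilinear resize: identity, constants, smooth round trip", {
  img <- matrix(rnorm(48), 6, 8)
  expect_equal(resize_bilinear(img, 8, 6), img)
  expect_equal(resize_bilinear(matrix(3.5, 8, 8), 16, 16), matrix(3.5, 16, 16))
  ramp <- outer(seq(0, 63, length.out = 16), seq(0, 63, length.out = 16), "+") / 2
  rt <- resize_bilinear(resize_bilinear(ramp, 32, 32), 16, 16)
  expect_lt(max(abs(rt - ramp)), 1)
})

test_that("mean imputation is exact, mean-preserving and idempotent", {
  rt <- record_table(data.frame(a = c(1, NA, 3), b = c(2, 2, 2)), c(0L, 1L, 0L))
  imp <- impute_mean(rt)
  expect_equal(imp$data$a, c(1, 2, 3))
  expect_identical(impute_mean(imp)$data, imp$data)
  gen <- gen_patient_records(300, 3, 3, missing_frac = 0.15, seed = 8)
  pre_means <- vapply(gen$data, function(v) mean(v, na.rm = TRUE), numeric(1))
  post <- impute_mean(gen)
  expect_false(anyNA(post$data))
  expect_equal(vapply(post$data, mean, numeric(1)), pre_means)
  allna <- record_table(data.frame(a = c(NA_real_, NA_real_)), c(0L, 1L))
  expect_error(impute_mean(allna), class = "cardiopipe_invalid_argument")
})

test_that("z-score outlier flags follow the formula", {
  expect_equal(zscore_outliers(c(0, 0, 0, 0, 100), 1.5),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(zscore_outliers(rep(4, 10)), rep(FALSE, 10))
  w <- winsorize_outliers(c(0, 0, 0, 0, 100), 1.5)
  expect_lt(max(w), 100)
  expect_equal(w[1:4], c(0, 0, 0, 0))
})

test_that("metadata cleaning dedupes, encodes and normalizes", {
  df <- data.frame(x = c(1, 2, 1, 3), lab = c("b", "a", "b", "a"),
                   stringsAsFactors = FALSE)
  rt <- record_table(df, c(0L, 1L, 0L, 1L))
  cl <- clean_metadata(rt)
  expect_equal(nrow(cl$data), 3L)          # one exact duplicate removed
  enc <- attr(cl, "encodings")$lab
  expect_equal(enc, c(b = 0L, a = 1L))     # first-appearance order
  for (j in seq_along(cl$data))
    expect_true(all(cl$data[[j]] >= 0 & cl$data[[j]] <= 1))
  md <- gen_metadata(200, dup_frac = 0.05, seed = 2)
  cleaned <- clean_metadata(md)
  expect_equal(attr(cleaned, "n_removed"), 10L)
})
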