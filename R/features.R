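# Multi-feature extraction: ECG time/frequency descriptors, image shape and
# texture statistics, and statistical moments, assembled per modality into a
# feature table.

#' Construct a feature table
#'
#' The common post-extraction currency: a numeric sample-by-feature matrix
#' with deterministic column names and a per-sample class label.
#'
#' @param values `n_samples x n_features` numeric matrix.
#' @param names feature identifiers (length `n_features`).
#' @param labels integer class per sample.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, names, labels) {
  values <- as.matrix(values)
  if (length(names) != ncol(values))
    stop_invalid("names length must equal n_features")
  if (length(labels) != nrow(values))
    stop_invalid("labels length must equal n_samples")
  colnames(values) <- names
  structure(list(values = values, names = as.character(names),
                 labels = as.integer(labels)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features, %d classes\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  invisible(x)
}

#' SDNN heart-rate-variability statistic
#'
#' Population standard deviation of normal-to-normal inter-beat intervals.
#'
#' @param nn_intervals interval sequence in milliseconds (length >= 2).
#' @return SDNN in ms.
#' @export
hrv_sdnn <- function(nn_intervals) {
  if (length(nn_intervals) < 2L)
    stop_invalid("need at least 2 NN intervals")
  mu <- mean(nn_intervals)
  sqrt(mean((nn_intervals - mu)^2))
}

#' QRS complex duration
#'
#' Locates the global absolute-amplitude peak and expands left and right
#' while the absolute amplitude stays at or above `theta` times the peak;
#' the duration is the width of that supra-threshold region in samples,
#' converted to milliseconds (a rectangular pulse of `k` samples yields
#' `k * 1000/fs` ms).
#'
#' @param beat amplitude sequence containing a dominant peak.
#' @param fs sampling frequency in Hz.
#' @param theta onset/offset threshold as a fraction of the peak amplitude.
#' @return Duration in ms.
#' @export
qrs_duration <- function(beat, fs = 125, theta = 0.2) {
  a <- abs(beat)
  peak <- max(a)
  if (peak == 0)
    stop(errorCondition("flat beat: QRS duration undefined",
                        class = c("cardiopipe_undefined_qrs", "error")))
  p <- which.max(a)
  cut <- theta * peak
  s <- p; while (s > 1L && a[s - 1L] >= cut) s <- s - 1L
  e <- p; while (e < length(a) && a[e + 1L] >= cut) e <- e + 1L
  (e - s + 1L) * 1000 / fs
}

#' Periodogram power spectral density
#'
#' Standard periodogram `|DFT|^2 / (N fs)` (power per Hz) on the DFT
#' frequency grid. One-sided output folds the negative frequencies into the
#' positive bins (doubling all bins except DC and, for even lengths,
#' Nyquist), so that summing `power * delta_f` recovers the mean signal
#' power either way. `squared = FALSE` gives the un-squared magnitude
#' variant `|DFT| / N` for comparison.
#'
#' @param signal amplitude sequence.
#' @param fs sampling frequency in Hz.
#' @param one_sided fold onto nonnegative frequencies (default TRUE).
#' @param squared use the squared modulus (default TRUE).
#' @return List with `freq` (Hz) and `power`.
#' @export
psd_periodogram <- function(signal, fs = 125, one_sided = TRUE, squared = TRUE) {
  n <- length(signal)
  if (n < 2L) stop_invalid("signal must have length >= 2")
  X <- stats::fft(signal)
  pw <- if (squared) Mod(X)^2 / (n * fs) else Mod(X) / n
  freq <- (seq_len(n) - 1L) * fs / n
  if (!one_sided) return(list(freq = freq, power = pw))
  half <- floor(n / 2)
  idx <- seq_len(half + 1L)
  ps <- pw[idx]
  dbl <- 2L:(if (n %% 2L == 0L) half else half + 1L)
  ps[dbl] <- 2 * ps[dbl]
  list(freq = freq[idx], power = ps)
}

#' Integrate spectral power over frequency bands
#'
#' @param spectrum a [psd_periodogram()] result.
#' @param bands named list of `c(lo, hi)` band edges in Hz; a bin at
#'   frequency `f` belongs to the band when `lo <= f < hi`.
#' @return Named vector of band powers (`sum(power) * delta_f`).
#' @export
band_powers <- function(spectrum, bands) {
  df <- diff(spectrum$freq[1:2])
  vapply(bands, function(b) {
    sel <- spectrum$freq >= b[1] & spectrum$freq < b[2]
    sum(spectrum$power[sel]) * df
  }, numeric(1))
}

# Moore-neighbor boundary trace of the foreground component containing the
# first foreground pixel in scan order. Chain length: axis steps count 1,
# diagonal steps sqrt(2). An isolated pixel gets its unit-square perimeter.
boundary_perimeter <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c]
  start <- NULL
  for (cc in seq_len(W)) {
    rs <- which(mask[, cc])
    if (length(rs)) { start <- c(rs[1], cc); break }
  }
  if (is.null(start)) return(0)
  # 8-neighborhood offsets in clockwise order (row, col), index 1 = west
  dirs <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                 ncol = 2, byrow = TRUE)
  # entered start moving east from its west background neighbor
  cur <- start
  back <- 1L  # direction (from cur) of the backtrack pixel
  per <- 0
  first_move <- NULL
  steps <- 0L
  limit <- 4L * H * W + 8L
  repeat {
    nxt <- NULL
    for (k in 1:8) {
      d <- (back - 1L + k) %% 8L + 1L  # clockwise scan from the backtrack
      nr <- cur[1] + dirs[d, 1]; nc <- cur[2] + dirs[d, 2]
      if (fg(nr, nc)) { nxt <- c(nr, nc); nd <- d; nk <- k; break }
    }
    if (is.null(nxt)) return(4)  # isolated pixel
    step_len <- if (nd %% 2L == 0L) sqrt(2) else 1
    per <- per + step_len
    if (is.null(first_move)) first_move <- c(cur, nxt)
    else if (all(c(cur, nxt) == first_move)) return(per - step_len)
    # new backtrack: the (background) ring neighbor examined just before
    # nxt; consecutive ring positions are 8-adjacent, so it neighbors nxt
    d_prev <- (back - 1L + nk - 1L) %% 8L + 1L
    b <- if (nk == 1L) cur + dirs[back, ] else cur + dirs[d_prev, ]
    delta <- b - nxt
    back <- which(dirs[, 1] == delta[1] & dirs[, 2] == delta[2])
    cur <- nxt
    steps <- steps + 1L
    if (steps > limit) return(per)
  }
}

#' Shape descriptors of a binary mask
#'
#' Circularity `4 pi A / p^2` (area = pixel count, perimeter = Moore
#' boundary-trace length with sqrt(2) diagonal steps), bounding-box aspect
#' ratio (width / height), and eccentricity `sqrt(1 - b^2/a^2)` of the
#' second-central-moment ellipse with semi-axes `a >= b`.
#'
#' @param mask logical (or 0/1) matrix with at least one foreground pixel.
#' @return Named list: `circularity`, `aspect_ratio`, `eccentricity`.
#' @export
shape_features <- function(mask) {
  mask <- mask > 0
  A <- sum(mask)
  if (A == 0L) stop_invalid("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  rows <- idx[, 1]; cols <- idx[, 2]
  p <- boundary_perimeter(mask)
  circ <- if (p > 0) 4 * pi * A / p^2 else 1
  ar <- (max(cols) - min(cols) + 1) / (max(rows) - min(rows) + 1)
  mu_r <- mean(rows); mu_c <- mean(cols)
  m20 <- mean((cols - mu_c)^2); m02 <- mean((rows - mu_r)^2)
  m11 <- mean((cols - mu_c) * (rows - mu_r))
  tr <- m20 + m02; det <- m20 * m02 - m11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  list(circularity = circ, aspect_ratio = ar, eccentricity = ecc)
}

#' Fill interior holes of a binary mask
#'
#' Background pixels not reachable from the image border (4-connectivity)
#' are converted to foreground. Useful for recovering a cavity region as
#' `fill_holes(mask) & !mask`.
#'
#' @param mask logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  outside <- matrix(FALSE, H, W)
  queue <- integer(0)
  push <- function(r, c) {
    if (r >= 1 && r <= H && c >= 1 && c <= W && !outside[r, c] && !mask[r, c]) {
      outside[r, c] <<- TRUE
      queue <<- c(queue, (c - 1L) * H + r)
    }
  }
  for (r in seq_len(H)) { push(r, 1L); push(r, W) }
  for (c in seq_len(W)) { push(1L, c); push(H, c) }
  while (length(queue)) {
    v <- queue[length(queue)]; queue <- queue[-length(queue)]
    r <- (v - 1L) %% H + 1L; c <- (v - 1L) %/% H + 1L
    push(r - 1L, c); push(r + 1L, c); push(r, c - 1L); push(r, c + 1L)
  }
  mask | !outside
}

#' GLCM specification
#'
#' @param distance pixel offset (>= 1).
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @param levels quantization bin count (>= 2).
#' @param symmetric add the transposed counts (default TRUE).
#' @param normalized normalize counts to probabilities (default TRUE).
#' @return An object of class `glcm_spec`.
#' @export
glcm_spec <- function(distance = 1L, angles = c(0, 45, 90, 135), levels = 16L,
                      symmetric = TRUE, normalized = TRUE) {
  if (!all(angles %in% c(0, 45, 90, 135)))
    stop_invalid("angles must be among 0, 45, 90, 135")
  structure(list(distance = check_count(distance, "distance"),
                 angles = angles, levels = check_count(levels, "levels", 2L),
                 symmetric = isTRUE(symmetric), normalized = isTRUE(normalized)),
            class = "glcm_spec")
}

# Uniform quantization of the image's intensity range into `levels` bins.
quantize_levels <- function(image, levels) {
  r <- range(image)
  if (r[1] == r[2]) return(matrix(0L, nrow(image), ncol(image)))
  q <- floor((image - r[1]) / (r[2] - r[1]) * levels)
  matrix(pmin(as.integer(q), levels - 1L), nrow(image), ncol(image))
}

glcm_offsets <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d))
}

# Co-occurrence matrix for one angle.
glcm_matrix <- function(q, levels, angle, distance, symmetric, normalized) {
  off <- glcm_offsets(angle, distance)
  H <- nrow(q); W <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(H, H - off[1])
  c1 <- max(1L, 1L - off[2]):min(W, W - off[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  P <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = 0:(levels - 1L)),
               factor(b, levels = 0:(levels - 1L)))
  P <- P + unclass(tab)
  if (symmetric) P <- P + t(P)
  if (normalized && sum(P) > 0) P <- P / sum(P)
  P
}

glcm_stats <- function(P) {
  levels <- nrow(P)
  i <- matrix(0:(levels - 1L), levels, levels)
  j <- t(i)
  contrast <- sum((i - j)^2 * P)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  pos <- P > 0
  entropy <- -sum(P[pos] * log(P[pos]))
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
  correlation <- if (s_i * s_j == 0) 1 else
    sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j)
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy)
}

#' Gray-level co-occurrence texture statistics
#'
#' Quantizes the image, accumulates a co-occurrence matrix per angle
#' (symmetrized and normalized as configured), computes contrast,
#' correlation, energy, homogeneity and natural-log entropy
#' (with `0 log 0 = 0`), and averages the statistics over angles.
#' The correlation of a degenerate (zero-variance) matrix is defined as 1.
#'
#' @param image numeric intensity matrix.
#' @param spec a [glcm_spec()].
#' @return Named vector of the five statistics averaged over angles.
#' @export
glcm_features <- function(image, spec = glcm_spec()) {
  q <- quantize_levels(image, spec$levels)
  stats <- vapply(spec$angles, function(ang) {
    glcm_stats(glcm_matrix(q, spec$levels, ang, spec$distance,
                           spec$symmetric, spec$normalized))
  }, numeric(5))
  rowMeans(stats)
}

#' Local binary pattern histogram
#'
#' For each interior pixel, compares the `points` circular neighbors
#' (radius `radius`, neighbor 0 east, proceeding counter-clockwise, offsets
#' rounded to the pixel grid) against the center with the step convention
#' `s(u) = 1` iff `u >= 0`, forming the code `sum s_i 2^i`. Returns the
#' normalized histogram over the `2^points` codes (border pixels within
#' `radius` of the edge are excluded).
#'
#' @param image numeric intensity matrix.
#' @param radius neighborhood radius in pixels.
#' @param points number of neighbors (<= 16).
#' @return Numeric vector of length `2^points` summing to 1.
#' @export
lbp_histogram <- function(image, radius = 1L, points = 8L) {
  radius <- check_count(radius, "radius")
  points <- check_count(points, "points", 2L)
  if (points > 16L) stop_invalid("points must be <= 16")
  H <- nrow(image); W <- ncol(image)
  ang <- 2 * pi * (seq_len(points) - 1L) / points
  dc <- round(radius * cos(ang)); dr <- -round(radius * sin(ang))
  m <- max(abs(c(dc, dr)))
  if (H <= 2 * m || W <= 2 * m)
    stop_invalid("image too small for radius ", radius)
  rows <- (m + 1L):(H - m); cols <- (m + 1L):(W - m)
  center <- image[rows, cols, drop = FALSE]
  code <- matrix(0, length(rows), length(cols))
  for (i in seq_len(points)) {
    nb <- image[rows + dr[i], cols + dc[i], drop = FALSE]
    code <- code + (nb >= center) * 2^(i - 1L)
  }
  counts <- tabulate(as.integer(code) + 1L, nbins = 2^points)
  counts / sum(counts)
}

#' Statistical moments of a numeric sequence
#'
#' Population formulas throughout (divisor `n`): mean, median, population
#' standard deviation, skewness `mean(((x - m)/sd)^3)`, and excess kurtosis
#' `mean(((x - m)/sd)^4 - 3)`. Skewness and kurtosis of a constant sequence
#' are defined as 0.
#'
#' @param values non-empty numeric vector.
#' @return Named list: `mean`, `median`, `sd`, `skewness`, `kurtosis`.
#' @export
stat_moments <- function(values) {
  if (!length(values)) stop_invalid("values must be non-empty")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  z3 <- if (s > 0) mean(((values - m) / s)^3) else 0
  z4 <- if (s > 0) mean(((values - m) / s)^4 - 3) else 0
  list(mean = m, median = stats::median(values), sd = s,
       skewness = z3, kurtosis = z4)
}

# Within-beat peak-interval SDNN proxy: population sd of the sample
# intervals between local maxima exceeding 30% of the beat's peak
# amplitude (in ms). Falls back to 0 when fewer than 3 peaks exist.
beat_hrv_proxy <- function(beat, fs) {
  a <- beat - min(beat)
  thr <- 0.3 * max(a)
  n <- length(a)
  if (n < 3 || max(a) == 0) return(0)
  core <- a[2:(n - 1)]
  peaks <- which(core > a[1:(n - 2)] & core >= a[3:n] & core > thr) + 1L
  if (length(peaks) < 3L) return(0)
  hrv_sdnn(diff(peaks) * 1000 / fs)
}

DEFAULT_ECG_BANDS <- list(bp_low = c(0, 5), bp_mid = c(5, 15), bp_high = c(15, 40))

#' Extract the per-modality feature schema
#'
#' Assembles the documented feature set for each modality into a
#' [feature_table] with deterministic feature names and order:
#' * `ecg` (a [beat_table]): beat statistical moments, QRS duration, band
#'   powers over `bands`, and a within-beat peak-interval SDNN proxy
#'   (true normal-to-normal intervals are unavailable on single-beat rows;
#'   the proxy is documented as such).
#' * `image` (an [image_set]): mask shape descriptors (foreground taken as
#'   intensities above the image mean when no mask is present), GLCM
#'   statistics, and the LBP histogram pooled to energy/entropy summaries.
#' * `tabular` / `metadata` (a [record_table]): pass-through of the
#'   min-max-scaled numeric predictors plus per-row statistical-moment
#'   augmentation computed across the scaled predictors.
#'
#' @param modality one of `"ecg"`, `"image"`, `"tabular"`, `"metadata"`.
#' @param data the modality's container.
#' @param bands ECG band definition (named list of Hz ranges).
#' @param glcm a [glcm_spec()] for images.
#' @return A [feature_table].
#' @export
extract_all <- function(modality = c("ecg", "image", "tabular", "metadata"),
                        data, bands = DEFAULT_ECG_BANDS, glcm = glcm_spec()) {
  modality <- match.arg(modality)
  if (modality == "ecg") {
    stopifnot(inherits(data, "beat_table"))
    feats <- t(apply(data$signals, 1, function(beat) {
      mom <- stat_moments(beat)
      qrs <- tryCatch(qrs_duration(beat, data$fs),
                      cardiopipe_undefined_qrs = function(e) 0)
      bp <- band_powers(psd_periodogram(beat, data$fs), bands)
      c(mean = mom$mean, median = mom$median, sd = mom$sd,
        skewness = mom$skewness, kurtosis = mom$kurtosis,
        qrs_ms = qrs, bp, hrv_proxy = beat_hrv_proxy(beat, data$fs))
    }))
    return(feature_table(feats, colnames(feats), data$labels))
  }
  if (modality == "image") {
    stopifnot(inherits(data, "image_set"))
    feats <- t(mapply(function(img, i) {
      mask <- if (!is.null(data$masks)) data$masks[[i]] else img > mean(img)
      sh <- shape_features(mask)
      g <- glcm_features(img, glcm)
      h <- lbp_histogram(img)
      pos <- h > 0
      c(circularity = sh$circularity, aspect_ratio = sh$aspect_ratio,
        eccentricity = sh$eccentricity,
        glcm_contrast = g[["contrast"]], glcm_correlation = g[["correlation"]],
        glcm_energy = g[["energy"]], glcm_homogeneity = g[["homogeneity"]],
        glcm_entropy = g[["entropy"]],
        lbp_energy = sum(h^2), lbp_entropy = -sum(h[pos] * log(h[pos])))
    }, data$images, seq_along(data$images)))
    return(feature_table(feats, colnames(feats), data$labels))
  }
  # tabular / metadata
  stopifnot(inherits(data, "record_table"))
  df <- data$data
  num <- vapply(df, is.numeric, TRUE)
  if (!all(num))
    stop_invalid("non-numeric columns present; run clean_metadata() first")
  X <- as.matrix(df)
  Xs <- apply(X, 2, function(v) suppressWarnings(minmax_normalize(v)))
  aug <- t(apply(Xs, 1, function(r) {
    mom <- stat_moments(r)
    c(row_mean = mom$mean, row_median = mom$median, row_sd = mom$sd,
      row_skewness = mom$skewness, row_kurtosis = mom$kurtosis)
  }))
  feats <- cbind(Xs, aug)
  feature_table(feats, colnames(feats), data$target)
}
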