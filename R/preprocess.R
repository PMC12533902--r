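# Per-modality cleaning: normalization, histogram equalization, bilinear
# resizing, mean imputation, z-score outlier handling, and metadata cleaning.
# Fitted statistics are carried in replayable spec objects so train-fitted
# transforms can be applied unchanged to held-out data.

#' Fit a min-max normalization spec
#'
#' @param values numeric vector the statistics are observed on.
#' @param lo,hi target range bounds (`lo < hi`).
#' @return An object of class `normalization_spec` with the observed min/max.
#' @export
fit_normalization <- function(values, lo = 0, hi = 1) {
  if (!length(values)) stop_invalid("values must be non-empty")
  if (lo >= hi) stop_invalid("lo must be < hi")
  r <- range(values, na.rm = TRUE)
  structure(list(lo = lo, hi = hi, observed_min = r[1], observed_max = r[2]),
            class = "normalization_spec")
}

#' Apply a fitted min-max normalization spec
#'
#' Values are mapped affinely so the observed min/max land on `lo`/`hi`.
#' A degenerate observed range maps everything to `lo` with a warning.
#'
#' @param values numeric vector.
#' @param spec a [fit_normalization()] result.
#' @return Rescaled numeric vector.
#' @export
apply_normalization <- function(values, spec) {
  if (spec$observed_min == spec$observed_max) {
    warning("degenerate min-max range; mapping all values to lo")
    out <- rep(spec$lo, length(values))
    out[is.na(values)] <- NA_real_
    return(out)
  }
  spec$lo + (values - spec$observed_min) * (spec$hi - spec$lo) /
    (spec$observed_max - spec$observed_min)
}

#' Min-max normalization
#'
#' Rescales so the minimum maps to `lo` and the maximum to `hi`:
#' `lo + (v - min)(hi - lo)/(max - min)`. A constant input maps to `lo`
#' with a degenerate-range warning rather than erroring, so constant
#' columns in small tables do not abort a pipeline.
#'
#' @param values non-empty numeric vector.
#' @param lo,hi target bounds, `lo < hi`.
#' @return Rescaled vector in `[lo, hi]`.
#' @export
minmax_normalize <- function(values, lo = 0, hi = 1) {
  apply_normalization(values, fit_normalization(values, lo, hi))
}

#' Histogram equalization
#'
#' Redistributes integer pixel intensities through the empirical cumulative
#' distribution: `e = round(cdf(i) * (levels - 1))`, with the CDF normalized
#' over all pixels and half-up rounding.
#'
#' @param image integer intensity matrix with values in `[0, levels)`.
#' @param levels number of gray levels.
#' @return Equalized intensity matrix, same shape.
#' @export
hist_equalize <- function(image, levels = 256L) {
  levels <- check_count(levels, "levels", min = 2L)
  if (any(image < 0) || any(image >= levels) || any(image != floor(image)))
    stop_invalid("image intensities must be integers in [0, levels)")
  counts <- tabulate(image + 1L, nbins = levels)
  cdf <- cumsum(counts) / length(image)
  eq <- floor(cdf * (levels - 1L) + 0.5)   # half-up rounding
  matrix(eq[image + 1L], nrow(image), ncol(image))
}

#' Bilinear image resizing
#'
#' Resamples on an align-corners grid: output pixel `(j, i)` samples source
#' coordinate `(j-1)(H-1)/(h-1)` x `(i-1)(W-1)/(w-1)` with bilinear weights,
#' so an identity resize returns the input exactly and a constant image stays
#' constant.
#'
#' @param image numeric matrix.
#' @param w,h output width (columns) and height (rows).
#' @return `h x w` numeric matrix.
#' @export
resize_bilinear <- function(image, w, h) {
  w <- check_count(w, "w"); h <- check_count(h, "h")
  H <- nrow(image); W <- ncol(image)
  src <- function(out_n, in_n) {
    if (out_n == 1L) rep((in_n - 1) / 2, 1L)
    else (seq_len(out_n) - 1) * (in_n - 1) / (out_n - 1)
  }
  ry <- src(h, H); rx <- src(w, W)
  y0 <- pmin(floor(ry), H - 1); x0 <- pmin(floor(rx), W - 1)
  fy <- ry - y0; fx <- rx - x0
  i0 <- y0 + 1L; i1 <- pmin(y0 + 2L, H); j0 <- x0 + 1L; j1 <- pmin(x0 + 2L, W)
  top <- image[i0, j0, drop = FALSE] * outer(1 - fy, 1 - fx) +
         image[i0, j1, drop = FALSE] * outer(1 - fy, fx)
  bot <- image[i1, j0, drop = FALSE] * outer(fy, 1 - fx) +
         image[i1, j1, drop = FALSE] * outer(fy, fx)
  top + bot
}

#' Mean imputation of missing cells
#'
#' Replaces each missing numeric cell by the mean of the column's non-missing
#' entries, which leaves every column mean unchanged. Non-numeric columns are
#' passed through. A fully missing column cannot be resolved and errors.
#'
#' @param table a [record_table].
#' @return The table with no missing numeric cells.
#' @export
impute_mean <- function(table) {
  stopifnot(inherits(table, "record_table"))
  df <- table$data
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) next
    nas <- is.na(df[[j]])
    if (!any(nas)) next
    if (all(nas))
      stop_invalid("column '", names(df)[j], "' is entirely missing; ",
                   "mean imputation is unresolvable")
    df[[j]][nas] <- mean(df[[j]][!nas])
  }
  out <- record_table(df, table$target, table$provenance)
  attributes(out) <- utils::modifyList(attributes(table), attributes(out))
  out
}

#' Z-score outlier flags
#'
#' Flags values whose standardized distance from the mean exceeds
#' `threshold`: `|(v - mu)/sigma| > threshold`, with `mu` and the population
#' standard deviation `sigma` computed over the input itself. A constant
#' input (`sigma = 0`) yields no flags. Missing values are never flagged.
#'
#' @param values numeric vector.
#' @param threshold z-units cutoff (default 3).
#' @return Logical vector of flags.
#' @export
zscore_outliers <- function(values, threshold = 3) {
  ok <- !is.na(values)
  mu <- mean(values[ok])
  sigma <- sqrt(mean((values[ok] - mu)^2))
  flags <- rep(FALSE, length(values))
  if (sigma == 0) return(flags)
  flags[ok] <- abs((values[ok] - mu) / sigma) > threshold
  flags
}

#' Winsorize flagged outliers
#'
#' Clamps values flagged by [zscore_outliers()] to `mu +/- threshold * sigma`
#' rather than dropping rows.
#'
#' @inheritParams zscore_outliers
#' @return Numeric vector with outliers clamped.
#' @export
winsorize_outliers <- function(values, threshold = 3) {
  flags <- zscore_outliers(values, threshold)
  if (!any(flags)) return(values)
  ok <- !is.na(values)
  mu <- mean(values[ok])
  sigma <- sqrt(mean((values[ok] - mu)^2))
  pmin(pmax(values, mu - threshold * sigma), mu + threshold * sigma)
}

#' Clean a metadata table
#'
#' Removes exact-duplicate rows (all feature columns plus the target,
#' keeping the first occurrence), maps categorical columns to integer codes
#' in first-appearance order, and min-max normalizes numeric columns to
#' `[0, 1]`. The categorical code maps and per-column normalization specs are
#' attached as attributes (`encodings`, `normalization`) so the transform can
#' be persisted and replayed on held-out data.
#'
#' @param table a [record_table].
#' @return Cleaned [record_table].
#' @export
clean_metadata <- function(table) {
  stopifnot(inherits(table, "record_table"))
  df <- table$data
  key <- do.call(paste, c(df, list(table$target, sep = "\r")))
  keep <- !duplicated(key)
  df <- df[keep, , drop = FALSE]
  target <- table$target[keep]
  rownames(df) <- NULL
  encodings <- list()
  norms <- list()
  for (j in seq_along(df)) {
    nm <- names(df)[j]
    if (is.character(df[[j]]) || is.factor(df[[j]])) {
      v <- as.character(df[[j]])
      lv <- unique(v)                               # first-appearance order
      encodings[[nm]] <- stats::setNames(seq_along(lv) - 1L, lv)
      df[[j]] <- encodings[[nm]][v]
      names(df[[j]]) <- NULL
    }
    spec <- fit_normalization(df[[j]], 0, 1)
    norms[[nm]] <- spec
    df[[j]] <- suppressWarnings(apply_normalization(df[[j]], spec))
  }
  out <- record_table(df, target, table$provenance)
  attr(out, "encodings") <- encodings
  attr(out, "normalization") <- norms
  attr(out, "n_removed") <- sum(!keep)
  out
}
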