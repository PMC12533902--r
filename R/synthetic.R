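# Synthetic-data generators. Every generator is a pure function of its
# arguments (including `seed`) and carries its ground truth (class templates,
# planted coefficients, injected-cell positions) in attributes so tests can
# check recovery against known structure.

NUTRIENTS <- c("sodium_mg", "satfat_g", "fiber_g", "calories_kcal", "cholesterol_mg")

#' Construct a beat table
#'
#' A beat table holds fixed-length ECG beats, one per row, with an integer
#' class label per beat and the sampling frequency in Hz.
#'
#' @param signals numeric matrix, `n_beats x beat_len`, amplitude values.
#' @param labels integer class per beat, in `[0, n_classes)`.
#' @param fs sampling frequency in Hz.
#' @return An object of class `beat_table`.
#' @export
beat_table <- function(signals, labels, fs = 125) {
  signals <- as.matrix(signals)
  labels <- as.integer(labels)
  if (nrow(signals) != length(labels))
    stop_invalid("signals and labels disagree: ", nrow(signals), " beats vs ",
                 length(labels), " labels")
  if (any(labels < 0)) stop_invalid("labels must be non-negative integers")
  if (!is.numeric(fs) || fs <= 0) stop_invalid("fs must be positive")
  structure(list(signals = signals, labels = labels, fs = fs),
            class = "beat_table")
}

#' @export
print.beat_table <- function(x, ...) {
  cat(sprintf("<beat_table> %d beats x %d samples @ %g Hz, %d classes\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              length(unique(x$labels))))
  invisible(x)
}

gaussian_bump <- function(t, center, sd, amp) amp * exp(-(t - center)^2 / (2 * sd^2))

# Per-class ECG template parameters. Class 0 is the base morphology; higher
# classes perturb R amplitude, QRS width, and T-wave amplitude/position by
# class_sep times a fixed per-class offset (zero at class 0).
ecg_class_params <- function(n_classes, class_sep, qrs_ms) {
  k <- seq_len(n_classes) - 1
  data.frame(
    class   = k,
    p_amp   = 0.15 * (1 + class_sep * 0.6 * sin(2.1 * k)),
    r_amp   = 1.00 + class_sep * 0.30 * sin(2.3 * k),
    qrs_ms  = qrs_ms * (1 + class_sep * 0.35 * sin(1.7 * k)),
    t_amp   = 0.30 + class_sep * 0.15 * sin(2.9 * k),
    t_pos   = 0.70 + class_sep * 0.05 * sin(1.9 * k)
  )
}

#' Generate class-structured synthetic ECG beats
#'
#' Each beat is a sum of three Gaussian bumps emulating the P wave, the QRS
#' complex and the T wave, whose amplitudes, widths and positions are
#' class-dependent templates, plus white noise of standard deviation
#' `noise_sd` and a low-frequency baseline-wander sinusoid whose amplitude
#' scales with `wander_amp`. Class 0 carries the base morphology; `class_sep`
#' dials how far the other class templates sit from it, which makes class
#' separability directly controllable in tests.
#'
#' The QRS "width" of a class is defined as the distance between the 20%%-of-
#' peak crossings of its QRS bump (the convention the duration detector uses);
#' per-class ground-truth widths are stored in `attr(, "class_params")`.
#'
#' @param n_per_class beats per class.
#' @param n_classes number of classes (>= 2).
#' @param beat_len samples per beat (>= 32); default 187 matches the common
#'   single-beat CSV dialect at `fs = 125` Hz.
#' @param noise_sd white-noise standard deviation (amplitude units).
#' @param class_sep class-template separation dial (0 = identical templates).
#' @param wander_amp baseline-wander amplitude; defaults to `noise_sd` so a
#'   noiseless call is fully deterministic per class.
#' @param fs sampling frequency in Hz.
#' @param seed RNG seed.
#' @return A [beat_table] with `n_per_class * n_classes` rows; ground truth in
#'   attributes `class_params` (template table) and `r_pos` (R-peak position).
#' @export
gen_ecg_beats <- function(n_per_class, n_classes, beat_len = 187L,
                          noise_sd = 0.05, class_sep = 1, wander_amp = noise_sd,
                          fs = 125, seed = 1L) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  beat_len <- check_count(beat_len, "beat_len", min = 32L)
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  params <- ecg_class_params(n_classes, class_sep, qrs_ms = 80)
  # 20%-crossing half-width of a Gaussian: sd * sqrt(2 log 5)
  crossing <- sqrt(2 * log(5))
  tt <- seq(0, 1, length.out = beat_len)
  with_seed(seed, {
    n <- n_per_class * n_classes
    labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    sig <- matrix(0, n, beat_len)
    for (k in seq_len(n_classes)) {
      p <- params[k, ]
      # width in seconds -> fraction of the beat -> Gaussian sd
      qrs_sd <- (p$qrs_ms / 1000) / (beat_len / fs) / (2 * crossing)
      template <- gaussian_bump(tt, 0.20, 0.025, p$p_amp) +
        gaussian_bump(tt, 0.45, qrs_sd, p$r_amp) +
        gaussian_bump(tt, p$t_pos, 0.045, p$t_amp)
      rows <- which(labels == k - 1L)
      for (i in rows) {
        wander <- if (wander_amp > 0)
          wander_amp * runif(1) * sin(2 * pi * runif(1, 0.3, 1) * tt + runif(1, 0, 2 * pi))
        else 0
        noise <- if (noise_sd > 0) rnorm(beat_len, 0, noise_sd) else 0
        sig[i, ] <- template + wander + noise
      }
    }
    out <- beat_table(sig, labels, fs = fs)
    attr(out, "class_params") <- params
    attr(out, "r_pos") <- 0.45
    out
  })
}

#' Construct an image set
#'
#' @param images list of numeric matrices with integer intensities in
#'   `[0, levels)`.
#' @param labels integer class per image.
#' @param masks optional list of logical foreground masks, same shapes.
#' @param levels number of gray levels.
#' @return An object of class `image_set`.
#' @export
image_set <- function(images, labels, masks = NULL, levels = 256L) {
  if (length(images) != length(labels))
    stop_invalid("images and labels lengths differ")
  if (length(images)) {
    rng <- range(vapply(images, range, numeric(2)))
    if (rng[1] < 0 || rng[2] >= levels)
      stop_invalid("intensities must lie in [0, levels)")
  }
  if (!is.null(masks)) {
    ok <- mapply(function(im, m) identical(dim(im), dim(m)), images, masks)
    if (!all(ok)) stop_invalid("masks must match image shapes")
  }
  structure(list(images = images, labels = as.integer(labels),
                 masks = masks, levels = as.integer(levels)),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- if (length(x$images)) paste(dim(x$images[[1]]), collapse = "x") else "0x0"
  cat(sprintf("<image_set> %d images (%s), %d gray levels, %d classes\n",
              length(x$images), d, x$levels, length(unique(x$labels))))
  invisible(x)
}

# class -> phantom geometry: wall thickness fraction, cavity eccentricity,
# outer radius fraction. 0 = healthy, 1 = hypertrophic (thick wall),
# 2 = dilated/failing (thin wall, large eccentric cavity); further classes
# interpolate.
image_class_params <- function(n_classes) {
  base <- data.frame(
    wall_frac  = c(0.22, 0.38, 0.10),
    cavity_ecc = c(0.35, 0.45, 0.62),
    outer_frac = c(0.32, 0.34, 0.42)
  )
  idx <- ((seq_len(n_classes) - 1) %% 3) + 1
  out <- base[idx, , drop = FALSE]
  out$class <- seq_len(n_classes) - 1
  rownames(out) <- NULL
  out
}

# Separable moving-average smoothing of a matrix (reflective edges).
smooth_matrix <- function(m, w = 5L) {
  k <- rep(1 / w, w)
  pad <- (w - 1L) %/% 2L
  sm_rows <- t(apply(m, 1, function(r) {
    r2 <- c(rev(r[seq_len(pad)]), r, rev(r[length(r) - seq_len(pad) + 1L]))
    stats::filter(r2, k, sides = 2)[(pad + 1L):(pad + length(r))]
  }))
  t(apply(t(sm_rows), 1, function(r) {
    r2 <- c(rev(r[seq_len(pad)]), r, rev(r[length(r) - seq_len(pad) + 1L]))
    stats::filter(r2, k, sides = 2)[(pad + 1L):(pad + length(r))]
  }))
}

#' Generate annular cardiac-phantom images
#'
#' Each image is a geometric short-axis phantom: a bright elliptical annulus
#' ("myocardium") around a darker cavity on a dark background, textured with
#' smoothed noise and quantized to `levels` gray levels. The class controls
#' wall thickness, cavity eccentricity and overall size (healthy /
#' thick-walled / dilated thin-walled geometries). The returned masks mark the
#' annulus.
#'
#' @param n_per_class images per class.
#' @param n_classes number of classes (default 3).
#' @param size image side length in pixels (>= 32).
#' @param texture_amp amplitude of the smoothed-noise texture, in intensity
#'   fraction units.
#' @param seed RNG seed.
#' @return An [image_set] with ground-truth geometry in
#'   `attr(, "class_params")`.
#' @export
gen_cardiac_images <- function(n_per_class, n_classes = 3L, size = 64L,
                               texture_amp = 0.08, seed = 1L) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  n_classes <- check_count(n_classes, "n_classes")
  size <- check_count(size, "size", min = 32L)
  params <- image_class_params(n_classes)
  levels <- 256L
  with_seed(seed, {
    images <- list(); masks <- list(); labels <- integer(0)
    ax <- seq_len(size) - (size + 1) / 2
    for (k in seq_len(n_classes)) {
      p <- params[k, ]
      for (i in seq_len(n_per_class)) {
        cx <- runif(1, -2, 2); cy <- runif(1, -2, 2)
        outer_a <- p$outer_frac * size * runif(1, 0.97, 1.03)
        outer_b <- outer_a                      # round epicardium
        cav_a <- outer_a * (1 - p$wall_frac)    # semi-major of cavity
        cav_b <- cav_a * sqrt(1 - p$cavity_ecc^2)
        X <- outer(ax - cx, rep(1, size)); Y <- outer(rep(1, size), ax - cy)
        r_out <- (X / outer_a)^2 + (Y / outer_b)^2
        r_cav <- (X / cav_a)^2 + (Y / cav_b)^2
        annulus <- r_out <= 1 & r_cav > 1
        cavity <- r_cav <= 1
        base <- matrix(0.06, size, size)
        base[annulus] <- 0.80
        base[cavity] <- 0.22
        tex <- smooth_matrix(matrix(rnorm(size * size), size, size), 5L)
        img <- pmin(pmax(base + texture_amp * tex, 0), 1 - 1e-9)
        images[[length(images) + 1L]] <- matrix(as.integer(floor(img * levels)),
                                                size, size)
        masks[[length(masks) + 1L]] <- annulus
        labels <- c(labels, k - 1L)
      }
    }
    out <- image_set(images, labels, masks, levels = levels)
    attr(out, "class_params") <- params
    out
  })
}

#' Construct a record table
#'
#' Tabular records: a data frame of feature columns, a per-row label vector,
#' and a provenance map tagging every feature column as `signal` (used by the
#' generative model for the target) or `noise`.
#'
#' @param data data frame of feature columns.
#' @param target integer label per row.
#' @param provenance named character vector, one entry per feature column,
#'   values in `c("signal", "noise")`.
#' @return An object of class `record_table`.
#' @export
record_table <- function(data, target, provenance = NULL) {
  if (nrow(data) != length(target))
    stop_invalid("data and target lengths differ")
  if (is.null(provenance))
    provenance <- stats::setNames(rep("noise", ncol(data)), names(data))
  if (!setequal(names(provenance), names(data)))
    stop_invalid("provenance must cover every feature column exactly")
  structure(list(data = data, target = as.integer(target),
                 provenance = provenance[names(data)]),
            class = "record_table")
}

#' @export
print.record_table <- function(x, ...) {
  cat(sprintf("<record_table> %d rows x %d features (%d signal, %d noise)\n",
              nrow(x$data), ncol(x$data),
              sum(x$provenance == "signal"), sum(x$provenance == "noise")))
  invisible(x)
}

UCI_NAMES <- c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
               "thalach", "exang", "oldpeak", "slope", "ca", "thal")

#' Generate tabular patient records with planted informative features
#'
#' Draws latent standard-normal feature scores, maps them onto clinically
#' scaled columns, and draws a binary target from a logistic model that uses
#' only the `n_signal` signal features (coefficients recorded in the
#' provenance attributes). Noise features are independent of the target.
#' Missing cells and mean +/- 6 sd outliers are then injected at the stated
#' fractions; injected positions are recorded so detection tests have ground
#' truth. When `n_signal + n_noise == 13` the columns carry the standard
#' 13-predictor clinical schema names so real files can be swapped in.
#'
#' @param n rows.
#' @param n_signal,n_noise counts of informative / uninformative features.
#' @param missing_frac,outlier_frac fractions in `[0, 0.5)` of feature cells
#'   set missing / replaced by mean +/- 6 sd.
#' @param seed RNG seed.
#' @return A [record_table]; attributes `coefficients`, `missing_cells`,
#'   `outlier_cells` carry the planted truth.
#' @export
gen_patient_records <- function(n, n_signal = 5L, n_noise = 8L,
                                missing_frac = 0, outlier_frac = 0,
                                seed = 1L) {
  n <- check_count(n, "n", min = 0L)
  n_signal <- check_count(n_signal, "n_signal")
  n_noise <- check_count(n_noise, "n_noise", min = 0L)
  missing_frac <- check_fraction(missing_frac, "missing_frac", 0, 0.5, hi_open = TRUE)
  outlier_frac <- check_fraction(outlier_frac, "outlier_frac", 0, 0.5, hi_open = TRUE)
  p <- n_signal + n_noise
  nm <- if (p == 13L) UCI_NAMES else
    c(sprintf("sig%02d", seq_len(n_signal)), sprintf("nse%02d", seq_len(n_noise)))
  with_seed(seed, {
    Z <- matrix(rnorm(n * p), n, p)
    beta <- (0.8 + 0.7 * runif(n_signal)) * sample(c(-1, 1), n_signal, TRUE)
    eta <- if (n > 0) Z[, seq_len(n_signal), drop = FALSE] %*% beta else numeric(0)
    target <- as.integer(stats::runif(n) < stats::plogis(eta))
    # clinically scaled columns: location/scale per column, cycled
    loc <- rep(c(54, 130, 246, 150, 1.0, 0.8, 3.0), length.out = p)
    scl <- rep(c(9, 17, 51, 23, 1.1, 0.4, 1.2), length.out = p)
    X <- sweep(sweep(Z, 2, scl, "*"), 2, loc, "+")
    df <- as.data.frame(X)
    names(df) <- nm
    prov <- stats::setNames(rep(c("signal", "noise"), c(n_signal, n_noise)), nm)
    miss <- out_cells <- matrix(FALSE, n, p)
    if (outlier_frac > 0 && n > 0) {
      idx <- which(matrix(runif(n * p) < outlier_frac, n, p))
      for (j in seq_len(p)) {
        rows <- ((idx - 1) %% n) + 1; cols <- ((idx - 1) %/% n) + 1
        sel <- rows[cols == j]
        if (length(sel)) {
          mu <- mean(df[[j]]); s <- stats::sd(df[[j]])
          df[[j]][sel] <- mu + sample(c(-6, 6), length(sel), TRUE) * s
          out_cells[sel, j] <- TRUE
        }
      }
    }
    if (missing_frac > 0 && n > 0) {
      mm <- matrix(runif(n * p) < missing_frac, n, p) & !out_cells
      for (j in seq_len(p)) df[[j]][mm[, j]] <- NA_real_
      miss <- mm
    }
    out <- record_table(df, target, prov)
    attr(out, "coefficients") <- stats::setNames(beta, nm[seq_len(n_signal)])
    attr(out, "missing_cells") <- miss
    attr(out, "outlier_cells") <- out_cells
    out
  })
}

#' Generate wearable-style metadata records
#'
#' Continuous wearable summaries (resting heart rate, an RMSSD-style HRV
#' proxy, daily step count, sleep hours, active minutes) plus a categorical
#' activity level, with a binary risk target driven by resting HR and HRV
#' (signal) while the remaining columns are noise. Exact duplicate rows are
#' injected at `dup_frac` for downstream cleaning tests.
#'
#' @param n rows in the returned table (including injected duplicates).
#' @param dup_frac fraction of rows that are exact copies of earlier rows.
#' @param seed RNG seed.
#' @return A [record_table]; `attr(, "n_duplicates")` counts injected copies.
#' @export
gen_metadata <- function(n, dup_frac = 0.05, seed = 1L) {
  n <- check_count(n, "n", min = 0L)
  dup_frac <- check_fraction(dup_frac, "dup_frac", 0, 0.5, hi_open = TRUE)
  n_dup <- floor(n * dup_frac)
  n_base <- n - n_dup
  with_seed(seed, {
    z_hr <- rnorm(n_base); z_hrv <- rnorm(n_base)
    df <- data.frame(
      resting_hr = round(68 + 10 * z_hr, 1),
      hrv_rmssd = round(pmax(5, 42 + 14 * z_hrv), 1),
      steps = round(pmax(0, 7500 + 3000 * rnorm(n_base))),
      sleep_hours = round(pmin(pmax(7 + 1.2 * rnorm(n_base), 3), 12), 2),
      active_minutes = round(pmax(0, 45 + 25 * rnorm(n_base))),
      activity_level = sample(c("low", "moderate", "high"), n_base, TRUE,
                              prob = c(0.3, 0.5, 0.2)),
      stringsAsFactors = FALSE
    )
    eta <- 1.1 * z_hr - 1.0 * z_hrv
    target <- as.integer(runif(n_base) < stats::plogis(eta))
    if (n_dup > 0) {
      src <- sample(n_base, n_dup, replace = TRUE)
      df <- rbind(df, df[src, , drop = FALSE])
      target <- c(target, target[src])
      rownames(df) <- NULL
    }
    prov <- stats::setNames(
      c("signal", "signal", "noise", "noise", "noise", "noise"), names(df))
    out <- record_table(df, target, prov)
    attr(out, "n_duplicates") <- n_dup
    out
  })
}

#' Construct a food item
#'
#' @param id item identifier.
#' @param nutrients named nonnegative vector over the five tracked nutrients
#'   (sodium mg, saturated fat g, fiber g, calories kcal, cholesterol mg).
#' @param cost nonnegative cost in currency units.
#' @param tags character set of dietary tags.
#' @return An object of class `food_item`.
#' @export
food_item <- function(id, nutrients, cost, tags = character(0)) {
  nutrients <- nutrients[NUTRIENTS]
  if (anyNA(nutrients) || any(nutrients < 0))
    stop_invalid("nutrients must be named over ", paste(NUTRIENTS, collapse = ", "),
                 " and nonnegative")
  if (cost < 0) stop_invalid("cost must be >= 0")
  structure(list(id = as.character(id),
                 nutrients = stats::setNames(as.numeric(nutrients), NUTRIENTS),
                 cost = as.numeric(cost), tags = as.character(tags)),
            class = "food_item")
}

#' Generate a toy food database
#'
#' Items are drawn from five serving archetypes (balanced meal, high-fiber
#' plate, snack, indulgent/fried dish, fish dish) with per-serving nutrient
#' means at realistic scales and ~15%% multiplicative jitter, so that a
#' day of about five balanced servings lands near standard daily guideline
#' targets.
#'
#' @param n_items number of items (default 20).
#' @param seed RNG seed.
#' @return A list of [food_item] with class `food_db`.
#' @export
gen_food_db <- function(n_items = 20L, seed = 1L) {
  n_items <- check_count(n_items, "n_items")
  arche <- list(
    balanced  = list(mu = c(400, 2.4, 6.0, 420, 55), cost = 4,
                     tags = character(0)),
    highfiber = list(mu = c(150, 1.0, 12.0, 250, 5), cost = 3,
                     tags = c("vegetarian", "vegan")),
    snack     = list(mu = c(250, 3.0, 2.0, 220, 20), cost = 2,
                     tags = "vegetarian"),
    indulgent = list(mu = c(900, 8.0, 1.0, 700, 160), cost = 6,
                     tags = "fried"),
    fish      = list(mu = c(300, 1.5, 0.5, 350, 80), cost = 7, tags = "fish")
  )
  # fixed archetype mix: half balanced so guideline-adherent days exist
  kinds <- rep(c("balanced", "highfiber", "snack", "indulgent", "fish"),
               times = ceiling(n_items * c(0.5, 0.15, 0.15, 0.1, 0.1)))[seq_len(n_items)]
  with_seed(seed, {
    db <- lapply(seq_len(n_items), function(i) {
      a <- arche[[kinds[i]]]
      jit <- exp(rnorm(5, 0, 0.14))
      food_item(sprintf("food%02d", i),
                stats::setNames(round(a$mu * jit, 1), NUTRIENTS),
                cost = round(a$cost * exp(rnorm(1, 0, 0.2)), 2),
                tags = a$tags)
    })
    structure(db, class = "food_db", kinds = kinds)
  })
}

#' @export
print.food_db <- function(x, ...) {
  cat(sprintf("<food_db> %d items (%s)\n", length(x),
              paste(names(table(attr(x, "kinds"))), table(attr(x, "kinds")),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Construct a patient profile
#'
#' Holds the guideline data that parameterize the nutrition environment:
#' per-nutrient lower/upper bounds, guideline targets with tolerances and
#' hard maxima, risk weights, preference tags and excluded foods, plus the
#' demographic scalars and the model-predicted disease risk.
#'
#' @param age years. @param bmi kg/m^2. @param risk predicted risk in `[0,1]`.
#' @param prefs list with character elements `required` and `forbidden` tags.
#' @param exclusions character vector of excluded food ids.
#' @param lower,upper per-nutrient bound vectors (`lower <= upper`).
#' @param targets per-nutrient guideline vector `g` within `[lower, upper]`.
#' @param tol per-nutrient nonnegative tolerance around `targets`.
#' @param gmax per-nutrient hard maximum for the risk term.
#' @param risk_weights nonnegative per-nutrient risk weights.
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(age, bmi, risk, prefs = list(required = character(0),
                                                         forbidden = character(0)),
                            exclusions = character(0),
                            lower, upper, targets, tol, gmax, risk_weights) {
  vecs <- list(lower = lower, upper = upper, targets = targets, tol = tol,
               gmax = gmax, risk_weights = risk_weights)
  vecs <- lapply(vecs, function(v) stats::setNames(as.numeric(v[NUTRIENTS]), NUTRIENTS))
  if (any(vapply(vecs, anyNA, TRUE)))
    stop_invalid("all nutrient vectors must be named over the five nutrients")
  if (any(vecs$lower > vecs$upper)) stop_invalid("lower must be <= upper")
  if (any(vecs$tol < 0)) stop_invalid("tol must be >= 0")
  if (any(vecs$targets < vecs$lower | vecs$targets > vecs$upper))
    stop_invalid("targets must lie within [lower, upper]")
  if (any(vecs$risk_weights < 0)) stop_invalid("risk_weights must be >= 0")
  structure(c(list(age = age, bmi = bmi, risk = check_fraction(risk, "risk"),
                   prefs = prefs, exclusions = as.character(exclusions)), vecs),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile> age %g, BMI %g, risk %.2f\n", x$age, x$bmi, x$risk))
  m <- rbind(lower = x$lower, target = x$targets, tol = x$tol,
             gmax = x$gmax, upper = x$upper, w_risk = x$risk_weights)
  print(round(m, 1))
  invisible(x)
}

#' Generate a guideline-based patient profile
#'
#' Ships three profile kinds. All use one-day guideline targets over the five
#' tracked nutrients (sodium, saturated fat, fiber, calories, cholesterol)
#' with a 15%% tolerance band; the hypertension profile tightens the sodium
#' budget and weights sodium heavily in the risk term, the dyslipidemia
#' profile weights cholesterol and saturated fat and forbids fried items.
#'
#' @param kind `"healthy"`, `"hypertension"` or `"dyslipidemia"`.
#' @param seed RNG seed (jitters age/BMI only; guideline data are fixed).
#' @return A [patient_profile].
#' @export
gen_patient_profile <- function(kind = c("healthy", "hypertension", "dyslipidemia"),
                                seed = 1L) {
  kind <- match.arg(kind)
  g <- c(2000, 12, 28, 2000, 270)          # daily targets per nutrient
  lower <- c(500, 0, 15, 1500, 0)
  upper <- c(2800, 18, 60, 2600, 450)
  gmax <- c(2400, 15, 60, 2400, 330)
  w <- c(1, 1, 1, 1, 1)
  prefs <- list(required = character(0), forbidden = character(0))
  risk <- 0.1
  if (kind == "hypertension") {
    g["sodium_mg"] <- 1500; upper["sodium_mg"] <- 2300; gmax["sodium_mg"] <- 1800
    w[] <- c(5, 1, 1, 1, 1); risk <- 0.7
  } else if (kind == "dyslipidemia") {
    g["cholesterol_mg"] <- 200; gmax["cholesterol_mg"] <- 300
    g["satfat_g"] <- 10; gmax["satfat_g"] <- 13
    w[] <- c(1, 4, 1, 1, 5); risk <- 0.6
    prefs$forbidden <- "fried"
  }
  names(g) <- names(lower) <- names(upper) <- names(gmax) <- names(w) <- NUTRIENTS
  with_seed(seed, {
    patient_profile(age = round(runif(1, 45, 75)), bmi = round(runif(1, 21, 33), 1),
                    risk = risk, prefs = prefs,
                    lower = lower, upper = upper, targets = g,
                    tol = 0.15 * g, gmax = gmax, risk_weights = w)
  })
}
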