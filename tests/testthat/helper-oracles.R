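# Independent brute-force oracles used to pin down the vectorized
# implementations. Each oracle re-derives its quantity from the defining
# formula with explicit loops, sharing no code with the package paths it
# checks.

# ReliefF: full distance matrix, explicit neighbor sort, per-feature loops.
oracle_relieff <- function(X, y, k) {
  S <- apply(X, 2, function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  })
  n <- nrow(S); p <- ncol(S)
  classes <- sort(unique(y))
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  names(priors) <- classes
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum(abs(S[i, ] - S[j, ]))
    upd <- numeric(p)
    for (cl in classes) {
      rows <- which(y == cl)
      if (cl == y[i]) rows <- setdiff(rows, i)
      nb <- rows[order(d[rows], rows)][seq_len(k)]
      for (f in seq_len(p)) {
        md <- mean(abs(S[i, f] - S[nb, f]))
        if (cl == y[i]) upd[f] <- upd[f] - md
        else upd[f] <- upd[f] +
            priors[as.character(cl)] / (1 - priors[as.character(y[i])]) * md
      }
    }
    w <- w + upd / n
  }
  w
}

# Confusion-matrix-first metric oracle with independent formulations
# (covariance form for MCC, marginal products for kappa).
oracle_report <- function(y_true, y_pred, averaging = "macro") {
  classes <- sort(unique(c(y_true, y_pred)))
  K <- length(classes); n <- length(y_true)
  C <- matrix(0, K, K)
  for (i in seq_len(n)) {
    r <- match(y_true[i], classes); c <- match(y_pred[i], classes)
    C[r, c] <- C[r, c] + 1
  }
  tp <- diag(C); row_s <- rowSums(C); col_s <- colSums(C)
  prec <- ifelse(col_s > 0, tp / col_s, 0)
  rec <- ifelse(row_s > 0, tp / row_s, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  jac <- ifelse(row_s + col_s - tp > 0, tp / (row_s + col_s - tp), 0)
  wavg <- function(v) sum(v * row_s) / n
  agg <- switch(averaging, macro = mean, weighted = wavg)
  acc <- sum(tp) / n
  if (averaging == "micro") {
    precision <- recall <- f1v <- acc
    jaccard <- sum(tp) / (2 * n - sum(tp))
  } else {
    precision <- agg(prec); recall <- agg(rec); f1v <- agg(f1); jaccard <- agg(jac)
  }
  # MCC, covariance formulation
  cov_xy <- n * sum(tp) - sum(row_s * col_s)
  cov_xx <- n^2 - sum(col_s^2); cov_yy <- n^2 - sum(row_s^2)
  mcc <- if (cov_xx * cov_yy == 0) 0 else cov_xy / sqrt(cov_xx) / sqrt(cov_yy)
  pe <- sum(row_s * col_s) / n^2
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) as.numeric(all(y_true == y_pred))
        else 1 - sum((y_true - y_pred)^2) / ss_tot
  list(accuracy = acc, recall = recall, f1 = f1v, precision = precision,
       r2 = r2, mcc = mcc, cohen_kappa = kappa,
       hamming_loss = mean(y_true != y_pred), jaccard = jaccard)
}

# GAE by direct double-loop summation of the defining series.
oracle_gae <- function(rewards, values, gamma, lam) {
  Tn <- length(rewards)
  adv <- numeric(Tn)
  for (t in seq_len(Tn)) {
    s <- 0
    for (l in 0:(Tn - t)) {
      delta <- rewards[t + l] + gamma * values[t + l + 1] - values[t + l]
      s <- s + (gamma * lam)^l * delta
    }
    adv[t] <- s
  }
  adv
}

# Per-pixel LBP loop with the same neighbor convention (east first,
# counter-clockwise, s(u >= 0) = 1).
oracle_lbp_codes <- function(image, radius = 1, points = 8) {
  H <- nrow(image); W <- ncol(image)
  ang <- 2 * pi * (0:(points - 1)) / points
  dc <- round(radius * cos(ang)); dr <- -round(radius * sin(ang))
  m <- max(abs(c(dc, dr)))
  codes <- c()
  for (r in (m + 1):(H - m)) for (cc in (m + 1):(W - m)) {
    code <- 0
    for (i in seq_len(points)) {
      if (image[r + dr[i], cc + dc[i]] >= image[r, cc])
        code <- code + 2^(i - 1)
    }
    codes <- c(codes, code)
  }
  codes
}

expect_report_equal <- function(rep, oracle, tol = 1e-12) {
  for (nm in names(oracle))
    expect_equal(rep[[nm]], oracle[[nm]], tolerance = tol,
                 info = paste("metric", nm))
}
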