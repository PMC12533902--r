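# A deliberately small configuration keeps the heavier checks fast.
tiny_cfg <- function(...) cilad_config(input_len = 32, n_classes = 2,
                                       filters1 = 4, filters2 = 5,
                                       filters_angle = 6, inception_width = 3,
                                       lstm_units = 4, fc = c(8, 6),
                                       dropout = 0, epochs = 3,
                                       early_stop_acc = NULL, seed = 2, ...)

test_that("forward pass lands on the probability simplex", {
  m <- build_cilad(tiny_cfg())
  set.seed(1)
  p <- predict(m, matrix(rnorm(5 * 32), 5, 32))
  expect_equal(rowSums(p$prob), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p$prob >= 0))
  expect_equal(p$labels, apply(p$prob, 1, which.max) - 1L)
})

test_that("infeasible input lengths error with the minimal admissible length", {
  err <- tryCatch(build_cilad(cilad_config(input_len = 4, n_classes = 2)),
                  error = function(e) e)
  expect_s3_class(err, "cardiopipe_invalid_argument")
  expect_match(conditionMessage(err), "minimal admissible length is")
  lmin <- as.integer(sub(".*minimal admissible length is (\\d+).*", "\\1",
                         conditionMessage(err)))
  expect_no_error(build_cilad(cilad_config(input_len = lmin, n_classes = 2)))
})

test_that("parameter count of the default configuration is stable", {
  m <- build_cilad(cilad_config(input_len = 187, n_classes = 5))
  expect_identical(n_params(m), 1574661)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_cfg()
  m <- build_cilad(cfg)
  set.seed(3)
  x <- array(rnorm(3 * 32), c(3, 32, 1))
  y <- c(0L, 1L, 0L)
  fw <- cilad_forward(m, x, training = TRUE)
  sc <- softmax_ce(fw$logits, y)
  grads <- cilad_backward(m, fw$caches, sc$grad)
  loss_at <- function(model) {
    f <- cilad_forward(model, x, training = TRUE)
    softmax_ce(f$logits, y)$loss
  }
  eps <- 1e-5
  for (chain in c("p1", "p2", "head")) {
    for (li in seq_along(m[[chain]])) {
      for (pn in names(m[[chain]][[li]]$params)) {
        pv <- m[[chain]][[li]]$params[[pn]]
        for (i in sample(length(pv), min(3, length(pv)))) {
          mp <- m; mp[[chain]][[li]]$params[[pn]][i] <- pv[i] + eps
          mm <- m; mm[[chain]][[li]]$params[[pn]][i] <- pv[i] - eps
          num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
          expect_equal(grads[[chain]][[li]][[pn]][i], num, tolerance = 1e-5)
        }
      }
    }
  }
  # one parameter inside each inception branch
  for (bi in 1:4) {
    br <- m$p1[[6]]$branches[[bi]]
    li <- length(br)
    pv <- br[[li]]$params$W
    i <- 1L
    mp <- m; mp$p1[[6]]$branches[[bi]][[li]]$params$W[i] <- pv[i] + eps
    mm <- m; mm$p1[[6]]$branches[[bi]][[li]]$params$W[i] <- pv[i] - eps
    num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    expect_equal(grads$p1[[6]]$branches[[bi]][[li]]$W[i], num, tolerance = 1e-5)
  }
})

test_that("training improves accuracy on separable data and is seeded", {
  bt <- gen_ecg_beats(30, 2, 32, noise_sd = 0.1, seed = 5)
  m0 <- build_cilad(tiny_cfg())
  m <- train_model(m0, bt, epochs = 5)
  expect_gt(tail(m$history$train_acc, 1), m$history$train_acc[1])
  m2 <- train_model(build_cilad(tiny_cfg()), bt, epochs = 5)
  expect_equal(m$history, m2$history, tolerance = 1e-12)
  zero <- train_model(m0, bt, epochs = 0)
  expect_equal(nrow(zero$history), 0L)
  expect_identical(zero$p1, m0$p1)
})

test_that("training rejects label sets missing a class", {
  bt <- gen_ecg_beats(10, 2, 32, noise_sd = 0.1, seed = 5)
  only0 <- subset_rows(bt, which(bt$labels == 0))
  expect_error(train_model(build_cilad(tiny_cfg()), only0),
               class = "cardiopipe_invalid_argument")
})

test_that("trained model beats the majority baseline by a wide margin", {
  bt <- gen_ecg_beats(40, 2, 32, noise_sd = 0.1, class_sep = 1.5, seed = 6)
  sp <- split_data(bt, split_spec(0.75, seed = 1))
  m <- train_model(build_cilad(tiny_cfg()), sp$train, epochs = 8)
  acc <- mean(predict(m, sp$test)$labels == sp$test$labels)
  baseline <- max(table(sp$train$labels)) / length(sp$train$labels)
  expect_gte(acc, baseline + 0.3)
})

test_that("predict handles empty input", {
  m <- build_cilad(tiny_cfg())
  p <- predict(m, array(numeric(0), c(0, 32, 1)))
  expect_equal(dim(p$prob), c(0L, 2L))
  expect_length(p$labels, 0L)
})

test_that("stratified splits are disjoint, exhaustive and proportional", {
  bt <- gen_ecg_beats(1000, 5, 32, noise_sd = 0.2, seed = 7)
  sp <- split_data(bt, split_spec(0.8, stratified = TRUE, seed = 3))
  expect_equal(nrow(sp$train$signals) + nrow(sp$test$signals), 5000L)
  joined <- rbind(sp$train$signals, sp$test$signals)
  expect_equal(nrow(unique(joined)), 5000L)   # disjoint, exhaustive
  for (k in 0:4) {
    frac_tr <- mean(sp$train$labels == k)
    expect_lt(abs(frac_tr - 0.2), 0.02)
    n_tr_k <- sum(sp$train$labels == k)
    expect_lte(abs(n_tr_k - 0.8 * 1000), 1)
  }
  sp2 <- split_data(bt, split_spec(0.8, stratified = TRUE, seed = 3))
  expect_identical(sp$train$labels, sp2$train$labels)
})

# fast stand-in classifier for harness checks: nearest class centroid
centroid_fit <- function(tr) {
  classes <- sort(unique(tr$labels))
  list(classes = classes,
       centroids = t(vapply(classes, function(k)
         colMeans(tr$signals[tr$labels == k, , drop = FALSE]),
         numeric(ncol(tr$signals)))))
}
centroid_predict <- function(fit, te) {
  d <- apply(te$signals, 1, function(row)
    which.min(colSums((t(fit$centroids) - row)^2)))
  fit$classes[d]
}

test_that("cross-validation folds partition the data exactly once each", {
  bt <- gen_ecg_beats(30, 3, 32, noise_sd = 0.2, seed = 8)
  cv <- crossvalidate(bt, k = 5, fit = centroid_fit,
                      predict_fn = centroid_predict, seed = 4)
  expect_setequal(cv$predictions$row, seq_len(90))
  expect_equal(nrow(cv$predictions), 90L)
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)
  # pooled accuracy equals the fold-size-weighted mean of fold accuracies
  fold_acc <- vapply(cv$folds, function(r) r$accuracy, numeric(1))
  fold_n <- as.numeric(table(cv$predictions$fold))
  pooled <- mean(cv$predictions$truth == cv$predictions$pred)
  expect_equal(pooled, sum(fold_acc * fold_n) / sum(fold_n), tolerance = 1e-12)
})

test_that("leave-one-out is the k = n edge case", {
  bt <- gen_ecg_beats(6, 2, 32, noise_sd = 0.2, seed = 9)
  # single-sample folds legitimately warn about single-class reports
  cv <- suppressWarnings(crossvalidate(bt, k = 12, fit = centroid_fit,
                                       predict_fn = centroid_predict, seed = 1))
  expect_equal(nrow(cv$predictions), 12L)
  expect_true(all(table(cv$predictions$fold) == 1L))
})

test_that("the full model runs end-to-end inside the cv harness", {
  bt <- gen_ecg_beats(10, 2, 32, noise_sd = 0.15, seed = 10)
  cfg <- tiny_cfg()
  cv <- crossvalidate(bt, k = 2, config = cfg, seed = 2)
  expect_length(cv$folds, 2L)
  expect_equal(nrow(cv$predictions), 20L)
  expect_true(all(c("accuracy", "mcc") %in% cv$summary$metric))
})
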