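# Two-pathway sequence classifier and its training/evaluation harness.
#
# Pathway 1: conv(32) -> maxpool -> dropout(0.5) -> conv(64) -> maxpool ->
#            inception block (1/3/5 kernels + pooled 1x1 branch,
#            channel-concatenated) -> LSTM(64), last hidden state.
# Pathway 2 (angular-feature branch): conv(128) -> ReLU -> maxpool ->
#            batchnorm -> flatten.
# Both pathway outputs are concatenated and fed through fully connected
# layers with dropout into a softmax over the classes.

#' Configuration for the two-pathway classifier
#'
#' Filter counts default to 32/64 (pathway 1), 128 (pathway 2), inception
#' branch width 16, LSTM width 64 and a 128 -> 64 fully connected head; all
#' remaining knobs (kernel size, pool size, dropout, optimizer step size,
#' epochs, batch size) are exposed here.
#'
#' @param input_len input sequence length.
#' @param n_classes number of classes.
#' @param filters1,filters2 pathway-1 convolution filter counts.
#' @param filters_angle pathway-2 convolution filter count.
#' @param kernel convolution kernel size.
#' @param pool max-pool width.
#' @param dropout dropout rate in `[0, 1)`.
#' @param inception_width per-branch channel count of the inception block.
#' @param lstm_units LSTM hidden size.
#' @param fc fully connected layer sizes.
#' @param lr Adam step size.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param early_stop_acc stop training once the epoch training accuracy
#'   reaches this level (`NULL` disables; default 0.98 — with 50%% dropout
#'   the per-epoch training accuracy saturates just below 0.99 even on
#'   cleanly separable data). Standard early stopping: the epoch budget is
#'   an upper limit, not a quota.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return An object of class `cilad_config`.
#' @export
cilad_config <- function(input_len, n_classes, filters1 = 32L, filters2 = 64L,
                         filters_angle = 128L, kernel = 3L, pool = 2L,
                         dropout = 0.5, inception_width = 16L,
                         lstm_units = 64L, fc = c(128L, 64L), lr = 1e-3,
                         epochs = 20L, batch_size = 32L,
                         early_stop_acc = 0.98, seed = 1L) {
  if (dropout < 0 || dropout >= 1) stop_invalid("dropout must be in [0, 1)")
  structure(list(input_len = check_count(input_len, "input_len"),
                 n_classes = check_count(n_classes, "n_classes", 2L),
                 filters1 = filters1, filters2 = filters2,
                 filters_angle = filters_angle, kernel = kernel, pool = pool,
                 dropout = dropout, inception_width = inception_width,
                 lstm_units = lstm_units, fc = fc, lr = lr,
                 epochs = check_count(epochs, "epochs", 0L),
                 batch_size = check_count(batch_size, "batch_size"),
                 early_stop_acc = early_stop_acc, seed = seed),
            class = "cilad_config")
}

# Shape arithmetic of the two pathways; returns NULL when the chain is
# infeasible for length L.
cilad_shapes <- function(L, cfg) {
  v <- function(x) if (is.na(x) || x < 1L) NA_integer_ else x
  l1 <- v(L - cfg$kernel + 1L)
  l1 <- v(l1 %/% cfg$pool)
  l1 <- v(l1 - cfg$kernel + 1L)
  l1 <- v(l1 %/% cfg$pool)
  l2 <- v(L - cfg$kernel + 1L)
  l2 <- v(l2 %/% cfg$pool)
  if (is.na(l1) || is.na(l2)) return(NULL)
  list(lstm_T = l1, p2_len = l2,
       concat = cfg$lstm_units + l2 * cfg$filters_angle)
}

#' Minimal input length admissible for a configuration's pooling chain
#' @param config a [cilad_config()] (its `input_len` is ignored).
#' @return The smallest sequence length the layer chain accepts.
#' @export
min_input_len <- function(config) {
  L <- 1L
  while (is.null(cilad_shapes(L, config))) {
    L <- L + 1L
    if (L > 10000L) stop_invalid("no admissible input length found")
  }
  L
}

#' Build the two-pathway classifier
#'
#' Instantiates all layers with seeded initialization. Errors when
#' `input_len` cannot pass the convolution/pooling chain, reporting the
#' minimal admissible length.
#'
#' @param config a [cilad_config()].
#' @return An object of class `cilad_model`.
#' @export
build_cilad <- function(config) {
  stopifnot(inherits(config, "cilad_config"))
  shp <- cilad_shapes(config$input_len, config)
  if (is.null(shp))
    stop_invalid("input_len ", config$input_len, " too short for the ",
                 "pooling chain; minimal admissible length is ",
                 min_input_len(config))
  with_seed(config$seed, {
    p1 <- list(nn_conv1d(1L, config$filters1, config$kernel),
               nn_maxpool(config$pool),
               nn_dropout(config$dropout),
               nn_conv1d(config$filters1, config$filters2, config$kernel),
               nn_maxpool(config$pool),
               nn_inception(config$filters2, config$inception_width),
               nn_lstm(4L * config$inception_width, config$lstm_units))
    p2 <- list(nn_conv1d(1L, config$filters_angle, config$kernel),
               nn_relu(),
               nn_maxpool(config$pool),
               nn_batchnorm(config$filters_angle),
               nn_flatten())
    head <- list(nn_dense(shp$concat, config$fc[1]), nn_relu(),
                 nn_dropout(config$dropout),
                 nn_dense(config$fc[1], config$fc[2]), nn_relu(),
                 nn_dense(config$fc[2], config$n_classes, init = "glorot"))
    structure(list(config = config, shapes = shp,
                   p1 = p1, p2 = p2, head = head, trained_epochs = 0L),
              class = "cilad_model")
  })
}

#' @export
print.cilad_model <- function(x, ...) {
  cat(sprintf(paste0("<cilad_model> input_len %d, %d classes, %s parameters",
                     " (%d epochs trained)\n"),
              x$config$input_len, x$config$n_classes,
              format(n_params(x), big.mark = ","), x$trained_epochs))
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model a `cilad_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(c(model$p1, model$p2, model$head), layer_n_params, numeric(1)))
}

# (N, L, 1) input array + labels from a beat or feature table.
as_model_input <- function(data) {
  if (inherits(data, "beat_table"))
    return(list(x = array(data$signals, c(nrow(data$signals), ncol(data$signals), 1L)),
                y = data$labels))
  if (inherits(data, "feature_table"))
    return(list(x = array(data$values, c(nrow(data$values), ncol(data$values), 1L)),
                y = data$labels))
  if (is.matrix(data))
    return(list(x = array(data, c(nrow(data), ncol(data), 1L)), y = NULL))
  stop_invalid("expected a beat_table, feature_table, or matrix")
}

cilad_forward <- function(model, x, training = FALSE) {
  r1 <- chain_forward(model$p1, x, training)
  r2 <- chain_forward(model$p2, x, training)
  model$p1 <- r1$layers; model$p2 <- r2$layers
  comb <- cbind(r1$out, r2$out)
  rh <- chain_forward(model$head, comb, training)
  model$head <- rh$layers
  list(logits = rh$out, model = model,
       caches = list(p1 = r1$caches, p2 = r2$caches, head = rh$caches,
                     d1 = ncol(r1$out)))
}

cilad_backward <- function(model, caches, glogits) {
  bh <- chain_backward(model$head, caches$head, glogits)
  d1 <- caches$d1
  g1 <- bh$gin[, seq_len(d1), drop = FALSE]
  g2 <- bh$gin[, (d1 + 1L):ncol(bh$gin), drop = FALSE]
  b1 <- chain_backward(model$p1, caches$p1, g1)
  b2 <- chain_backward(model$p2, caches$p2, g2)
  list(p1 = b1$grads, p2 = b2$grads, head = bh$grads)
}

#' Train the two-pathway classifier
#'
#' Minimizes softmax cross-entropy with Adam over shuffled minibatches.
#' Fully seeded (initialization, shuffling, dropout), so two runs with the
#' same seed produce identical histories. With `epochs = 0` the model is
#' returned unchanged with an empty history.
#'
#' @param model a [build_cilad()] model.
#' @param train training data: a [beat_table] or [feature_table].
#' @param val optional validation data of the same type.
#' @param epochs,batch_size,lr overrides of the model's config.
#' @return The trained model; per-epoch history (train/val loss and
#'   accuracy) in `model$history`.
#' @export
train_model <- function(model, train, val = NULL,
                        epochs = model$config$epochs,
                        batch_size = model$config$batch_size,
                        lr = model$config$lr) {
  stopifnot(inherits(model, "cilad_model"))
  tr <- as_model_input(train)
  need <- seq_len(model$config$n_classes) - 1L
  if (!all(need %in% tr$y))
    stop_invalid("training labels must contain every class 0..",
                 model$config$n_classes - 1L)
  epochs <- check_count(epochs, "epochs", min = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  if (epochs == 0L) { model$history <- hist; return(model) }
  vl <- if (!is.null(val)) as_model_input(val)
  n <- dim(tr$x)[1]
  step <- 0L
  with_seed(derive_seed(model$config$seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hits <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        xb <- tr$x[b, , , drop = FALSE]
        yb <- tr$y[b]
        fw <- cilad_forward(model, xb, training = TRUE)
        model <- fw$model
        sc <- softmax_ce(fw$logits, yb)
        grads <- cilad_backward(model, fw$caches, sc$grad)
        step <- step + 1L
        model$p1 <- chain_update(model$p1, grads$p1, lr, step)
        model$p2 <- chain_update(model$p2, grads$p2, lr, step)
        model$head <- chain_update(model$head, grads$head, lr, step)
        ep_loss <- ep_loss + sc$loss * length(b)
        ep_hits <- ep_hits + sum(max.col(sc$prob, ties.method = "first") - 1L == yb)
      }
      vloss <- vacc <- NA_real_
      if (!is.null(vl)) {
        pv <- predict(model, vl$x)
        vloss <- -mean(log(pmax(pv$prob[cbind(seq_along(vl$y), vl$y + 1L)], 1e-300)))
        vacc <- mean(pv$labels == vl$y)
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / n,
                                     train_acc = ep_hits / n,
                                     val_loss = vloss, val_acc = vacc))
      if (!is.null(model$config$early_stop_acc) &&
          ep_hits / n >= model$config$early_stop_acc) break
    }
  })
  model$history <- hist
  model$trained_epochs <- model$trained_epochs + epochs
  model
}

#' Predict class probabilities and labels
#'
#' Forward pass in evaluation mode (dropout off, batch norm running
#' statistics). Rows of the probability matrix sum to 1; labels are the row
#' argmax with ties resolved to the lowest class index.
#'
#' @param object a `cilad_model`.
#' @param newdata a [beat_table], [feature_table], or numeric matrix
#'   (rows = samples) / `(N, L, 1)` array.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return List with `prob` (N x n_classes) and integer `labels`.
#' @export
predict.cilad_model <- function(object, newdata, batch_size = 256L, ...) {
  x <- if (is.array(newdata) && length(dim(newdata)) == 3L) newdata
       else as_model_input(newdata)$x
  n <- dim(x)[1]
  K <- object$config$n_classes
  if (n == 0L)
    return(list(prob = matrix(numeric(0), 0, K), labels = integer(0)))
  prob <- matrix(0, n, K)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- cilad_forward(object, x[b, , , drop = FALSE], training = FALSE)
    prob[b, ] <- softmax_rows(fw$logits)
  }
  list(prob = prob, labels = max.col(prob, ties.method = "first") - 1L)
}

# ---- splitting and cross-validation --------------------------------------

#' Train/test split specification
#' @param train_fraction fraction in (0, 1) assigned to training.
#' @param stratified preserve per-class proportions (default TRUE).
#' @param seed RNG seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, stratified = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_invalid("train_fraction must be in (0, 1)")
  structure(list(train_fraction = train_fraction, stratified = isTRUE(stratified),
                 seed = seed), class = "split_spec")
}

#' Subset the rows of a data container
#' @param x a [beat_table], [feature_table] or [record_table].
#' @param idx integer row indices.
#' @return Container of the same class restricted to `idx`.
#' @export
subset_rows <- function(x, idx) UseMethod("subset_rows")

#' @export
subset_rows.beat_table <- function(x, idx)
  beat_table(x$signals[idx, , drop = FALSE], x$labels[idx], x$fs)

#' @export
subset_rows.feature_table <- function(x, idx)
  feature_table(x$values[idx, , drop = FALSE], x$names, x$labels[idx])

#' @export
subset_rows.record_table <- function(x, idx)
  record_table(x$data[idx, , drop = FALSE], x$target[idx], x$provenance)

data_labels <- function(x) {
  if (inherits(x, "record_table")) x$target else x$labels
}

#' Split a data container into train and test parts
#'
#' Disjoint and exhaustive; when stratified, per-class training fractions
#' are honored to within one sample per class. Deterministic per seed.
#'
#' @param table a [beat_table], [feature_table] or [record_table].
#' @param spec a [split_spec()].
#' @return List with `train` and `test` containers.
#' @export
split_data <- function(table, spec = split_spec()) {
  y <- data_labels(table)
  n <- length(y)
  with_seed(spec$seed, {
    if (spec$stratified) {
      tr <- unlist(lapply(unique(y), function(cl) {
        rows <- which(y == cl)
        sample(rows, round(length(rows) * spec$train_fraction))
      }))
    } else {
      tr <- sample.int(n, round(n * spec$train_fraction))
    }
    tr <- sort(tr)
    list(train = subset_rows(table, tr),
         test = subset_rows(table, setdiff(seq_len(n), tr)))
  })
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    start <- 0L   # rotate the fold counter across classes so no fold is
    for (cl in unique(y)) {   # left empty when k approaches n (e.g. LOO)
      rows <- sample(which(y == cl))
      fold[rows] <- (start + seq_along(rows) - 1L) %% k + 1L
      start <- start + length(rows)
    }
    fold
  })
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into `k` stratified folds, trains on the complement of
#' each fold and evaluates on the fold, so each sample is tested exactly
#' once. By default the classifier is a [build_cilad()] model trained with
#' [train_model()]; a custom `fit`/`predict_fn` pair can stand in (e.g. a
#' fast baseline for harness tests). Returns per-fold nine-metric reports,
#' their mean and standard deviation, and the pooled out-of-fold
#' predictions.
#'
#' @param table a [beat_table] or [feature_table].
#' @param k number of folds (`k = n` gives leave-one-out).
#' @param config a [cilad_config()] (ignored when `fit` is supplied).
#' @param fit optional `function(train_table)` returning a fitted object.
#' @param predict_fn optional `function(fitted, test_table)` returning
#'   integer labels.
#' @param averaging metric averaging mode.
#' @param seed fold-assignment seed.
#' @return An object of class `cv_result`: `folds` (list of reports),
#'   `summary` (mean/sd per metric), `predictions` (data frame with row
#'   index, fold, truth, prediction).
#' @export
crossvalidate <- function(table, k = 5L, config = NULL, fit = NULL,
                          predict_fn = NULL, averaging = "macro", seed = 1L) {
  y <- data_labels(table)
  k <- check_count(k, "k", 2L)
  if (k > length(y)) stop_invalid("k exceeds the number of samples")
  if (is.null(fit)) {
    if (is.null(config)) stop_invalid("provide config or fit/predict_fn")
    fit <- function(tr) train_model(build_cilad(config), tr)
    predict_fn <- function(m, te) predict(m, te)$labels
  }
  fold <- stratified_folds(y, k, seed)
  reports <- vector("list", k)
  preds <- data.frame(row = integer(0), fold = integer(0),
                      truth = integer(0), pred = integer(0))
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    fitted <- fit(subset_rows(table, tr))
    yhat <- predict_fn(fitted, subset_rows(table, te))
    reports[[f]] <- classification_report(y[te], yhat, averaging)
    preds <- rbind(preds, data.frame(row = te, fold = f, truth = y[te],
                                     pred = as.integer(yhat)))
  }
  metric_names <- c("accuracy", "recall", "f1", "precision", "r2", "mcc",
                    "cohen_kappa", "hamming_loss", "jaccard")
  M <- t(vapply(reports, function(r) unlist(r[metric_names]), numeric(9)))
  structure(list(folds = reports,
                 summary = data.frame(metric = metric_names,
                                      mean = colMeans(M),
                                      sd = apply(M, 2, stats::sd)),
                 predictions = preds, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", x$k))
  print(transform(x$summary, mean = round(mean, 4), sd = round(sd, 4)))
  invisible(x)
}
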