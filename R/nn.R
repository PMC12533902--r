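# Minimal vectorized neural-network core: 1-D convolution, max pooling,
# dropout, batch normalization, an inception block, LSTM, dense layers,
# softmax cross-entropy and Adam. Batched activations are (N, L, C) arrays
# for sequence layers and (N, D) matrices after flattening. Every layer is a
# plain list; forward returns (out, cache, layer) so layers with running
# state (batch norm) stay functional; backward returns the input gradient
# plus named parameter gradients. Gradients of every layer are checked
# against central finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# column-wise bias add / scale via vector recycling (faster than sweep)
add_bias <- function(M, b) M + rep(b, each = nrow(M))
col_scale <- function(M, s) M * rep(s, each = nrow(M))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

he_normal <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

nn_dense <- function(din, dout, init = "he") {
  W <- if (init == "he") he_normal(din, dout) else glorot(din, dout)
  list(kind = "dense", params = list(W = W, b = numeric(dout)))
}

nn_conv1d <- function(cin, cout, k = 3L, pad = 0L, init = "he") {
  W <- if (init == "he") he_normal(k * cin, cout) else glorot(k * cin, cout)
  list(kind = "conv1d", k = k, cin = cin, cout = cout, pad = pad,
       params = list(W = W, b = numeric(cout)))
}

nn_relu <- function() list(kind = "relu", params = list())
nn_tanh <- function() list(kind = "tanh", params = list())
nn_flatten <- function() list(kind = "flatten", params = list())
nn_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(kind = "dropout", rate = rate, params = list())
}
nn_maxpool <- function(p = 2L) list(kind = "maxpool", p = p, params = list())
nn_maxpool_same3 <- function() list(kind = "maxpool_same3", params = list())

nn_batchnorm <- function(c, momentum = 0.9, eps = 1e-5) {
  list(kind = "batchnorm", momentum = momentum, eps = eps,
       running_mean = numeric(c), running_var = rep(1, c),
       params = list(gamma = rep(1, c), beta = numeric(c)))
}

nn_lstm <- function(cin, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1   # forget-gate bias
  list(kind = "lstm", H = h, cin = cin,
       params = list(Wx = glorot(cin, 4 * h), Wh = glorot(h, 4 * h), b = b))
}

nn_inception <- function(cin, width = 16L) {
  list(kind = "inception", cout = 4L * width,
       branches = list(
         list(nn_conv1d(cin, width, k = 1L, pad = 0L)),
         list(nn_conv1d(cin, width, k = 3L, pad = 1L)),
         list(nn_conv1d(cin, width, k = 5L, pad = 2L)),
         list(nn_maxpool_same3(), nn_conv1d(cin, width, k = 1L, pad = 0L))),
       params = list())
}

conv_pad <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * pad, d[3]))
  xp[, (pad + 1L):(pad + d[2]), ] <- x
  xp
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$kind,
    dense = {
      out <- add_bias(x %*% layer$params$W, layer$params$b)
      list(out = out, cache = list(x = x), layer = layer)
    },
    relu = list(out = {m <- x > 0; x * m}, cache = list(m = x > 0), layer = layer),
    tanh = {out <- tanh(x); list(out = out, cache = list(out = out), layer = layer)},
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1], d[2] * d[3]), cache = list(d = d), layer = layer)
    },
    dropout = {
      if (!training || layer$rate == 0) return(list(out = x, cache = NULL, layer = layer))
      keep <- 1 - layer$rate
      m <- array((stats::runif(length(x)) < keep) / keep, dim(x))
      list(out = x * m, cache = list(m = m), layer = layer)
    },
    conv1d = {
      xp <- conv_pad(x, layer$pad)
      d <- dim(xp); N <- d[1]; L <- d[2]; Cin <- d[3]
      k <- layer$k; Lout <- L - k + 1L
      if (Lout < 1L) stop_invalid("conv1d: input length ", dim(x)[2],
                                  " too short for kernel ", k)
      M <- matrix(0, N * Lout, k * Cin)
      for (j in seq_len(k))
        M[, (seq_len(Cin) - 1L) * k + j] <-
          matrix(xp[, j:(j + Lout - 1L), , drop = FALSE], N * Lout, Cin)
      out <- add_bias(M %*% layer$params$W, layer$params$b)
      list(out = array(out, c(N, Lout, layer$cout)),
           cache = list(M = M, dpad = d, Lout = Lout), layer = layer)
    },
    maxpool = {
      p <- layer$p; d <- dim(x); Lout <- d[2] %/% p
      if (Lout < 1L) stop_invalid("maxpool: input length ", d[2],
                                  " shorter than pool ", p)
      out <- array(-Inf, c(d[1], Lout, d[3]))
      arg <- array(1L, c(d[1], Lout, d[3]))
      for (j in seq_len(p)) {
        sl <- x[, seq(j, by = p, length.out = Lout), , drop = FALSE]
        better <- sl > out
        out[better] <- sl[better]; arg[better] <- j
      }
      list(out = out, cache = list(arg = arg, d = d, Lout = Lout), layer = layer)
    },
    maxpool_same3 = {
      d <- dim(x); L <- d[2]
      xp <- array(-Inf, c(d[1], L + 2L, d[3]))
      xp[, 2L:(L + 1L), ] <- x
      out <- array(-Inf, c(d[1], L, d[3]))
      arg <- array(1L, c(d[1], L, d[3]))
      for (j in 1:3) {
        sl <- xp[, j:(j + L - 1L), , drop = FALSE]
        better <- sl > out
        out[better] <- sl[better]; arg[better] <- j
      }
      list(out = out, cache = list(arg = arg, d = d), layer = layer)
    },
    batchnorm = {
      d <- dim(x); C <- d[3]
      xm <- matrix(x, d[1] * d[2], C)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        layer$running_mean <- layer$momentum * layer$running_mean + (1 - layer$momentum) * mu
        layer$running_var <- layer$momentum * layer$running_var + (1 - layer$momentum) * v
      } else {
        mu <- layer$running_mean; v <- layer$running_var
      }
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- col_scale(add_bias(xm, -mu), inv)
      y <- add_bias(col_scale(xhat, layer$params$gamma), layer$params$beta)
      list(out = array(y, d),
           cache = list(xhat = xhat, inv = inv, d = d, training = training),
           layer = layer)
    },
    lstm = {
      d <- dim(x); N <- d[1]; Tn <- d[2]; Cin <- d[3]; H <- layer$H
      Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
      # project all time steps through Wx at once; rows (t-1)*N + n
      Xm <- matrix(x, N * Tn, Cin)
      xW <- add_bias(Xm %*% Wx, b)
      h <- matrix(0, N, H); cs <- matrix(0, N, H)
      steps <- vector("list", Tn)
      for (t in seq_len(Tn)) {
        z <- xW[((t - 1L) * N + 1L):(t * N), , drop = FALSE] + h %*% Wh
        i <- sigmoid(z[, 1:H, drop = FALSE])
        f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
        g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
        o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
        c_prev <- cs
        cs <- f * cs + i * g
        tc <- tanh(cs)
        steps[[t]] <- list(h_prev = h, c_prev = c_prev,
                           i = i, f = f, g = g, o = o, tc = tc)
        h <- o * tc
      }
      list(out = h, cache = list(steps = steps, d = d, Xm = Xm), layer = layer)
    },
    inception = {
      outs <- vector("list", length(layer$branches))
      caches <- vector("list", length(layer$branches))
      for (bi in seq_along(layer$branches)) {
        r <- chain_forward(layer$branches[[bi]], x, training)
        outs[[bi]] <- r$out; caches[[bi]] <- r$caches
        layer$branches[[bi]] <- r$layers
      }
      widths <- vapply(outs, function(o) dim(o)[3], integer(1))
      d <- dim(outs[[1]])
      out <- array(0, c(d[1], d[2], sum(widths)))
      at <- 0L
      for (bi in seq_along(outs)) {
        out[, , (at + 1L):(at + widths[bi])] <- outs[[bi]]
        at <- at + widths[bi]
      }
      list(out = out, cache = list(caches = caches, widths = widths),
           layer = layer)
    },
    stop("unknown layer kind ", layer$kind))
}

layer_backward <- function(layer, cache, gout) {
  switch(layer$kind,
    dense = list(gin = tcrossprod(gout, layer$params$W),
                 grads = list(W = crossprod(cache$x, gout), b = colSums(gout))),
    relu = list(gin = gout * cache$m, grads = list()),
    tanh = list(gin = gout * (1 - cache$out^2), grads = list()),
    flatten = list(gin = array(gout, cache$d), grads = list()),
    dropout = {
      if (is.null(cache)) list(gin = gout, grads = list())
      else list(gin = gout * cache$m, grads = list())
    },
    conv1d = {
      d <- cache$dpad; N <- d[1]; Cin <- d[3]
      k <- layer$k; Lout <- cache$Lout
      G <- matrix(gout, N * Lout, layer$cout)
      gW <- crossprod(cache$M, G)
      gb <- colSums(G)
      gM <- tcrossprod(G, layer$params$W)
      gx <- array(0, d)
      for (j in seq_len(k)) {
        sl <- array(gM[, (seq_len(Cin) - 1L) * k + j], c(N, Lout, Cin))
        gx[, j:(j + Lout - 1L), ] <- gx[, j:(j + Lout - 1L), , drop = FALSE] + sl
      }
      if (layer$pad > 0L)
        gx <- gx[, (layer$pad + 1L):(d[2] - layer$pad), , drop = FALSE]
      list(gin = gx, grads = list(W = gW, b = gb))
    },
    maxpool = {
      p <- layer$p; d <- cache$d; Lout <- cache$Lout
      gx <- array(0, d)
      for (j in seq_len(p)) {
        sel <- (cache$arg == j) * gout
        gx[, seq(j, by = p, length.out = Lout), ] <-
          gx[, seq(j, by = p, length.out = Lout), , drop = FALSE] + sel
      }
      list(gin = gx, grads = list())
    },
    maxpool_same3 = {
      d <- cache$d; L <- d[2]
      gp <- array(0, c(d[1], L + 2L, d[3]))
      for (j in 1:3) {
        sel <- (cache$arg == j) * gout
        gp[, j:(j + L - 1L), ] <- gp[, j:(j + L - 1L), , drop = FALSE] + sel
      }
      list(gin = gp[, 2L:(L + 1L), , drop = FALSE], grads = list())
    },
    batchnorm = {
      d <- cache$d
      gy <- matrix(gout, d[1] * d[2], d[3])
      xhat <- cache$xhat
      dgamma <- colSums(gy * xhat)
      dbeta <- colSums(gy)
      dxhat <- col_scale(gy, layer$params$gamma)
      if (cache$training) {
        gx <- col_scale(add_bias(dxhat, -colMeans(dxhat)) -
                          col_scale(xhat, colMeans(dxhat * xhat)),
                        cache$inv)
      } else {
        gx <- col_scale(dxhat, cache$inv)
      }
      list(gin = array(gx, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    lstm = {
      d <- cache$d; N <- d[1]; Tn <- d[2]; H <- layer$H
      Wx <- layer$params$Wx; Wh <- layer$params$Wh
      gWh <- array(0, dim(Wh))
      dz_all <- matrix(0, N * Tn, 4L * H)
      dh <- gout; dc <- matrix(0, N, H)
      for (t in rev(seq_len(Tn))) {
        s <- cache$steps[[t]]
        do <- dh * s$tc
        dc <- dc + dh * s$o * (1 - s$tc^2)
        di <- dc * s$g; df <- dc * s$c_prev; dg <- dc * s$i
        dz <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                    dg * (1 - s$g^2), do * s$o * (1 - s$o))
        dz_all[((t - 1L) * N + 1L):(t * N), ] <- dz
        gWh <- gWh + crossprod(s$h_prev, dz)
        dh <- tcrossprod(dz, Wh)
        dc <- dc * s$f
      }
      gWx <- crossprod(cache$Xm, dz_all)
      gx <- array(tcrossprod(dz_all, Wx), d)
      list(gin = gx, grads = list(Wx = gWx, Wh = gWh, b = colSums(dz_all)))
    },
    inception = {
      widths <- cache$widths
      gin <- NULL
      grads <- vector("list", length(layer$branches))
      at <- 0L
      for (bi in seq_along(layer$branches)) {
        gb <- gout[, , (at + 1L):(at + widths[bi]), drop = FALSE]
        at <- at + widths[bi]
        r <- chain_backward(layer$branches[[bi]], cache$caches[[bi]], gb)
        grads[[bi]] <- r$grads
        gin <- if (is.null(gin)) r$gin else gin + r$gin
      }
      list(gin = gin, grads = list(branches = grads))
    },
    stop("unknown layer kind ", layer$kind))
}

chain_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$out; caches[[i]] <- r$cache; layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

chain_backward <- function(layers, caches, gout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], gout)
    grads[[i]] <- r$grads
    gout <- r$gin
  }
  list(gin = gout, grads = grads)
}

# Softmax cross-entropy; returns loss, probabilities, and the logit gradient
# (already divided by batch size).
softmax_ce <- function(logits, y) {
  N <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(N), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, prob = p, grad = g / N)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam ----------------------------------------------------------------

adam_layer <- function(layer, grads, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (layer$kind == "inception") {
    for (bi in seq_along(layer$branches))
      for (li in seq_along(layer$branches[[bi]]))
        layer$branches[[bi]][[li]] <-
          adam_layer(layer$branches[[bi]][[li]], grads$branches[[bi]][[li]],
                     lr, t, b1, b2, eps)
    return(layer)
  }
  if (!length(layer$params)) return(layer)
  if (is.null(layer$opt))
    layer$opt <- list(m = lapply(layer$params, function(p) p * 0),
                      v = lapply(layer$params, function(p) p * 0))
  # bias corrections folded into scalars to keep large temporaries few
  c1 <- lr / (1 - b1^t)
  c2 <- 1 / sqrt(1 - b2^t)
  for (nm in names(layer$params)) {
    g <- grads[[nm]]
    m <- layer$opt$m[[nm]]; v <- layer$opt$v[[nm]]
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    layer$opt$m[[nm]] <- m
    layer$opt$v[[nm]] <- v
    layer$params[[nm]] <- layer$params[[nm]] - c1 * m / (c2 * sqrt(v) + eps)
  }
  layer
}

chain_update <- function(layers, grads, lr, t) {
  for (i in seq_along(layers)) layers[[i]] <- adam_layer(layers[[i]], grads[[i]], lr, t)
  layers
}

layer_n_params <- function(layer) {
  if (layer$kind == "inception")
    return(sum(vapply(layer$branches,
                      function(b) sum(vapply(b, layer_n_params, numeric(1))),
                      numeric(1))))
  sum(vapply(layer$params, length, numeric(1)))
}
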