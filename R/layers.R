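# Layer engine for the sequence regressors.
#
# A "layer" is a plain list: list(kind, params = list(...), buffers, <attrs>).
# A model is an ordered, named list of layers; `net_forward()` threads a batch
# through them and collects per-layer caches, `net_backward()` replays them in
# reverse and returns gradients with the same nesting as the parameters.
#
# Batch layout: cube-shaped arrays dim (L, C, B) -- sequence position, channel,
# batch -- matching the compiled kernels; readout layers collapse to (B, C)
# matrices. The LSTM path uses (B, C, T) so each step is one contiguous matrix.

## ---- activations ------------------------------------------------------------

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
elu_grad <- function(y, dy) {        # from the *output* y: dy/dx = y + 1 for x<0
  neg <- y < 0
  dy[neg] <- dy[neg] * (y[neg] + 1)
  dy
}
gelu <- function(x) .gelu_fwd(x)$y
relu <- function(x) (x > 0) * x
relu_grad <- function(y, dy) dy * (y > 0)

## ---- normalization ----------------------------------------------------------

# Batch norm over (position, batch) per channel; compiled kernels.
bn_forward <- function(x, gamma, beta, rmean, rvar, training, momentum = 0.1) {
  r <- .bn_fwd(x, gamma, beta, rmean, rvar, training, momentum, 1e-5)
  list(y = r$y, cache = list(xhat = r$xhat, invsd = as.numeric(r$invsd)),
       rmean = as.numeric(r$rmean), rvar = as.numeric(r$rvar))
}

bn_backward <- function(cache, gamma, dy) {
  r <- .bn_bwd(cache$xhat, cache$invsd, gamma, dy)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

# Layer norm over channels per (position, batch); compiled kernels.
ln_forward <- function(x, gamma, beta, eps = 1e-5) {
  r <- .ln_fwd(x, gamma, beta, eps)
  list(y = r$y, cache = list(xhat = r$xhat, invsd = r$invsd))
}

ln_backward <- function(cache, gamma, dy) {
  .ln_bwd(cache$xhat, cache$invsd, gamma, dy)
}

## ---- parameter initialization ----------------------------------------------

init_conv_w <- function(k, cin, cout) {
  matrix(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))), k * cin, cout)
}
init_linear_w <- function(cin, cout) {
  lim <- sqrt(6 / (cin + cout))
  matrix(stats::runif(cin * cout, -lim, lim), cin, cout)
}

## ---- layer constructors -----------------------------------------------------

layer_conv <- function(cin, cout, k, stride = 1, dil = 1,
                       pad = c("valid", "same", "causal")) {
  pad <- match.arg(pad)
  span <- (k - 1) * dil
  pads <- switch(pad,
    valid = c(0L, 0L),
    same = c(span %/% 2L, span - span %/% 2L),
    causal = c(span, 0L))
  list(kind = "conv", k = k, stride = stride, dil = dil,
       padL = pads[1], padR = pads[2],
       params = list(W = init_conv_w(k, cin, cout), b = numeric(cout)))
}

layer_bn <- function(C) {
  list(kind = "bn", params = list(gamma = rep(1, C), beta = numeric(C)),
       buffers = list(rmean = numeric(C), rvar = rep(1, C)))
}

layer_act <- function(fun) list(kind = "act", fun = fun, params = list())

# Efficient downsampling: stride-2 kernel-2 convolution (C -> C) in parallel
# with kernel-2 average pooling, concatenated on channels: (L, C) -> (L/2, 2C).
layer_hed <- function(C) {
  list(kind = "hed", C = C,
       params = list(W = init_conv_w(2, C, C), b = numeric(C)))
}

# Multi-scale convolution: 4-way channel split, same-length convolutions with
# kernels `kernels` on groups 1..3, identity on group 4.
layer_msc <- function(C, kernels = c(3L, 5L, 7L)) {
  if (C %% 4L != 0L)
    stopf("MSC needs a channel width divisible by 4, got %d", C)
  g <- C %/% 4L
  p <- list()
  for (i in 1:3) {
    p[[paste0("W", i)]] <- init_conv_w(kernels[i], g, g)
    p[[paste0("b", i)]] <- numeric(g)
  }
  list(kind = "msc", C = C, g = g, kernels = as.integer(kernels), params = p)
}

# Pre-LN residual attention sublayer: x + MHA(LN(x)).
layer_attn_res <- function(C, heads, scale_d = C) {
  w <- C %/% heads
  P <- w * heads
  list(kind = "attn_res", heads = heads, scale_d = scale_d, P = P,
       params = list(
         ln_g = rep(1, C), ln_b = numeric(C),
         Wq = init_linear_w(C, P), bq = numeric(P),
         Wk = init_linear_w(C, P), bk = numeric(P),
         Wv = init_linear_w(C, P), bv = numeric(P),
         Wm = init_linear_w(P, C), bm = numeric(C)))
}

# Pre-LN residual feed-forward sublayer: x + W2 %*% GELU(W1 %*% LN(x)).
layer_ffn_res <- function(C, expansion = 4L) {
  H <- C * expansion
  list(kind = "ffn_res",
       params = list(ln_g = rep(1, C), ln_b = numeric(C),
                     W1 = init_linear_w(C, H), b1 = numeric(H),
                     W2 = init_linear_w(H, C), b2 = numeric(C)))
}

# TCN residual level: two dilated causal convolutions with ReLU, plus a
# kernel-1 shortcut when channel counts differ; ReLU after the sum.
layer_tcn_level <- function(cin, cout, k, dil) {
  p <- list(W1 = init_conv_w(k, cin, cout), b1 = numeric(cout),
            W2 = init_conv_w(k, cout, cout), b2 = numeric(cout))
  if (cin != cout) {
    p$Wd <- init_conv_w(1, cin, cout)
    p$bd <- numeric(cout)
  }
  list(kind = "tcn_level", k = as.integer(k), dil = as.integer(dil),
       cin = cin, cout = cout, params = p)
}

# Embedding for the BERT-style baseline: per-frame linear map, a learned class
# token prepended at position 1, learned positional embeddings.
layer_bert_embed <- function(cin, C, L) {
  list(kind = "bert_embed", L = L, C = C,
       params = list(W = init_linear_w(cin, C), b = numeric(C),
                     cls = stats::rnorm(C, sd = 0.02),
                     pos = matrix(stats::rnorm((L + 1) * C, sd = 0.02), L + 1, C)))
}

layer_lstm <- function(cin, hidden) {
  lim <- 1 / sqrt(hidden)
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1          # forget-gate bias
  list(kind = "lstm", hidden = hidden,
       params = list(
         Wx = matrix(stats::runif(cin * 4 * hidden, -lim, lim), cin, 4 * hidden),
         Wh = matrix(stats::runif(hidden * 4 * hidden, -lim, lim), hidden, 4 * hidden),
         b = b))
}

layer_to_bct <- function() list(kind = "to_bct", params = list())
layer_gap <- function() list(kind = "gap", params = list())
layer_last_step <- function() list(kind = "last_step", params = list())
layer_last_step_bct <- function() list(kind = "last_step_bct", params = list())
layer_cls_pick <- function() list(kind = "cls_pick", params = list())
layer_linear <- function(cin, cout) {
  list(kind = "linear",
       params = list(W = init_linear_w(cin, cout), b = numeric(cout)))
}

## ---- forward / backward dispatch -------------------------------------------

layer_forward <- function(ly, x, training) {
  p <- ly$params
  switch(ly$kind,
    conv = {
      y <- .conv1d_fwd(x, p$W, p$b, ly$k, ly$stride, ly$dil, ly$padL, ly$padR)
      list(y = y, cache = list(x = x), layer = ly)
    },
    bn = {
      r <- bn_forward(x, p$gamma, p$beta, ly$buffers$rmean, ly$buffers$rvar,
                      training)
      if (training) ly$buffers <- list(rmean = r$rmean, rvar = r$rvar)
      list(y = r$y, cache = r$cache, layer = ly)
    },
    act = {
      if (ly$fun == "gelu") {
        r <- .gelu_fwd(x)
        return(list(y = r$y, cache = list(x = x, th = r$th), layer = ly))
      }
      y <- switch(ly$fun, elu = elu(x), relu = relu(x))
      list(y = y, cache = list(y = y), layer = ly)
    },
    hed = {
      d <- dim(x)
      if (d[1] %% 2L != 0L)
        stopf("HED requires an even sequence length, got %d", d[1])
      conv <- .conv1d_fwd(x, p$W, p$b, 2L, 2L, 1L, 0L, 0L)
      odd <- seq(1, d[1], by = 2)
      pool <- (x[odd, , , drop = FALSE] + x[odd + 1, , , drop = FALSE]) / 2
      d2 <- dim(conv)
      y <- array(0, c(d2[1], 2 * d2[2], d2[3]))
      y[, 1:d2[2], ] <- conv
      y[, (d2[2] + 1):(2 * d2[2]), ] <- pool
      list(y = y, cache = list(x = x), layer = ly)
    },
    msc = {
      g <- ly$g
      y <- x
      cache <- list(xg = vector("list", 3))
      for (i in 1:3) {
        sp <- ((i - 1) * g + 1):(i * g)
        xg <- x[, sp, , drop = FALSE]
        cache$xg[[i]] <- xg
        k <- ly$kernels[i]
        span <- k - 1L
        y[, sp, ] <- .conv1d_fwd(xg, p[[paste0("W", i)]], p[[paste0("b", i)]],
                                 k, 1L, 1L, span %/% 2L, span - span %/% 2L)
      }
      list(y = y, cache = cache, layer = ly)
    },
    attn_res = {
      lr <- ln_forward(x, p$ln_g, p$ln_b)
      at <- .mha_fwd(lr$y, p$Wq, p$bq, p$Wk, p$bk, p$Wv, p$bv, p$Wm, p$bm,
                     ly$heads, ly$scale_d)
      list(y = x + at$out,
           cache = list(ln = lr$cache, xn = lr$y, Q = at$Q, K = at$K, V = at$V),
           layer = ly)
    },
    ffn_res = {
      lr <- ln_forward(x, p$ln_g, p$ln_b)
      d <- dim(x)
      Xn <- .stack3(lr$y)                                   # (B*L) x C
      A <- .linbias(Xn, p$W1, p$b1)
      g <- .gelu_fwd(A)
      Y <- .linbias(g$y, p$W2, p$b2)
      yr <- .unstack3(Y, d[1], d[3])
      list(y = x + yr,
           cache = list(ln = lr$cache, Xn = Xn, A = A, th = g$th,
                        H = g$y, dim = d),
           layer = ly)
    },
    tcn_level = {
      span <- (ly$k - 1L) * ly$dil
      a1 <- .conv1d_fwd(x, p$W1, p$b1, ly$k, 1L, ly$dil, span, 0L)
      h1 <- relu(a1)
      a2 <- .conv1d_fwd(h1, p$W2, p$b2, ly$k, 1L, ly$dil, span, 0L)
      h2 <- relu(a2)
      sc <- if (is.null(p$Wd)) x else .conv1d_fwd(x, p$Wd, p$bd, 1L, 1L, 1L, 0L, 0L)
      y <- relu(h2 + sc)
      list(y = y, cache = list(x = x, h1 = h1, a1 = a1, a2 = a2, h2 = h2, y = y),
           layer = ly)
    },
    bert_embed = {
      d <- dim(x)
      Xm <- .stack3(x)                                      # (B*L) x cin
      E <- .linbias(Xm, p$W, p$b)
      C <- ly$C
      y <- array(0, c(d[1] + 1, C, d[3]))
      Ec <- .unstack3(E, d[1], d[3])
      y[2:(d[1] + 1), , ] <- Ec
      y[1, , ] <- matrix(p$cls, C, d[3])
      y <- y + as.vector(p$pos)            # (L+1) x C recycled over the batch
      list(y = y, cache = list(Xm = Xm, dim = d), layer = ly)
    },
    to_bct = list(y = aperm(x, c(3, 2, 1)), cache = list(), layer = ly),
    lstm = {
      r <- .lstm_fwd(x, p$Wx, p$Wh, p$b)
      list(y = r$H, cache = c(list(x = x), r), layer = ly)
    },
    gap = {
      d <- dim(x)
      y <- t(matrix(.colMeans(matrix(x, nrow = d[1]), d[1], d[2] * d[3]), d[2]))
      list(y = y, cache = list(dim = d), layer = ly)  # y: B x C
    },
    last_step = {
      d <- dim(x)
      list(y = t(matrix(x[d[1], , ], d[2], d[3])), cache = list(dim = d),
           layer = ly)
    },
    last_step_bct = {
      d <- dim(x)
      list(y = matrix(x[, , d[3]], d[1], d[2]), cache = list(dim = d), layer = ly)
    },
    cls_pick = {
      d <- dim(x)
      list(y = t(matrix(x[1, , ], d[2], d[3])), cache = list(dim = d),
           layer = ly)
    },
    linear = {
      y <- .linbias(x, p$W, p$b)
      list(y = y, cache = list(x = x), layer = ly)
    },
    stopf("unknown layer kind '%s'", ly$kind))
}

layer_backward <- function(ly, cache, dy) {
  p <- ly$params
  switch(ly$kind,
    conv = {
      r <- .conv1d_bwd(cache$x, p$W, dy, ly$k, ly$stride, ly$dil, ly$padL, ly$padR)
      list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    bn = {
      r <- bn_backward(cache, p$gamma, dy)
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    act = {
      dx <- switch(ly$fun,
        elu = elu_grad(cache$y, dy),
        gelu = .gelu_bwd(cache$x, cache$th, dy),
        relu = relu_grad(cache$y, dy))
      list(dx = dx, grads = list())
    },
    hed = {
      d2 <- dim(dy); C <- d2[2] %/% 2L
      dconv <- dy[, 1:C, , drop = FALSE]
      dpool <- dy[, (C + 1):(2 * C), , drop = FALSE]
      r <- .conv1d_bwd(cache$x, p$W, dconv, 2L, 2L, 1L, 0L, 0L)
      dx <- r$dx
      d <- dim(cache$x)
      odd <- seq(1, d[1], by = 2)
      dx[odd, , ] <- dx[odd, , , drop = FALSE] + dpool / 2
      dx[odd + 1, , ] <- dx[odd + 1, , , drop = FALSE] + dpool / 2
      list(dx = dx, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    msc = {
      g <- ly$g
      dx <- dy
      grads <- list()
      for (i in 1:3) {
        sp <- ((i - 1) * g + 1):(i * g)
        k <- ly$kernels[i]
        span <- k - 1L
        r <- .conv1d_bwd(cache$xg[[i]], p[[paste0("W", i)]],
                         dy[, sp, , drop = FALSE], k, 1L, 1L,
                         span %/% 2L, span - span %/% 2L)
        dx[, sp, ] <- r$dx
        grads[[paste0("W", i)]] <- r$dW
        grads[[paste0("b", i)]] <- as.numeric(r$db)
      }
      list(dx = dx, grads = grads)
    },
    attn_res = {
      r <- .mha_bwd(cache$xn, p$Wq, p$Wk, p$Wv, p$Wm, cache$Q, cache$K, cache$V,
                    dy, ly$heads, ly$scale_d)
      lr <- ln_backward(cache$ln, p$ln_g, r$dx)
      list(dx = dy + lr$dx,
           grads = list(ln_g = as.numeric(lr$dgamma),
                        ln_b = as.numeric(lr$dbeta),
                        Wq = r$dWq, bq = as.numeric(r$dbq),
                        Wk = r$dWk, bk = as.numeric(r$dbk),
                        Wv = r$dWv, bv = as.numeric(r$dbv),
                        Wm = r$dWm, bm = as.numeric(r$dbm)))
    },
    ffn_res = {
      d <- cache$dim
      dYm <- .stack3(dy)
      dW2 <- crossprod(cache$H, dYm)
      db2 <- colSums(dYm)
      dH <- tcrossprod(dYm, p$W2)
      dA <- .gelu_bwd(cache$A, cache$th, dH)
      dW1 <- t(cache$Xn) %*% dA
      db1 <- colSums(dA)
      dXn <- dA %*% t(p$W1)
      dXc <- .unstack3(dXn, d[1], d[3])
      lr <- ln_backward(cache$ln, p$ln_g, dXc)
      list(dx = dy + lr$dx,
           grads = list(ln_g = as.numeric(lr$dgamma),
                        ln_b = as.numeric(lr$dbeta),
                        W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
    },
    tcn_level = {
      span <- (ly$k - 1L) * ly$dil
      dsum <- relu_grad(cache$y, dy)
      dh2 <- relu_grad(cache$h2, dsum)
      r2 <- .conv1d_bwd(cache$h1, p$W2, dh2, ly$k, 1L, ly$dil, span, 0L)
      dh1 <- relu_grad(cache$h1, r2$dx)
      r1 <- .conv1d_bwd(cache$x, p$W1, dh1, ly$k, 1L, ly$dil, span, 0L)
      grads <- list(W1 = r1$dW, b1 = as.numeric(r1$db),
                    W2 = r2$dW, b2 = as.numeric(r2$db))
      if (is.null(p$Wd)) {
        dx <- r1$dx + dsum
      } else {
        rd <- .conv1d_bwd(cache$x, p$Wd, dsum, 1L, 1L, 1L, 0L, 0L)
        dx <- r1$dx + rd$dx
        grads$Wd <- rd$dW
        grads$bd <- as.numeric(rd$db)
      }
      list(dx = dx, grads = grads)
    },
    bert_embed = {
      d <- cache$dim; C <- ly$C
      dpos <- matrix(rowSums(matrix(dy, nrow = (d[1] + 1) * C)), d[1] + 1, C)
      dcls <- rowSums(matrix(dy[1, , ], C, d[3]))
      dE <- dy[2:(d[1] + 1), , , drop = FALSE]
      dEm <- .stack3(dE)
      dW <- t(cache$Xm) %*% dEm
      db <- colSums(dEm)
      dXm <- dEm %*% t(p$W)
      dx <- .unstack3(dXm, d[1], d[3])
      list(dx = dx, grads = list(W = dW, b = db, cls = dcls, pos = dpos))
    },
    to_bct = list(dx = aperm(dy, c(3, 2, 1)), grads = list()),
    lstm = {
      r <- .lstm_bwd(cache$x, p$Wx, p$Wh, cache$H, cache$C, cache$I, cache$F,
                     cache$G, cache$O, dy)
      list(dx = r$dx, grads = list(Wx = r$dWx, Wh = r$dWh, b = as.numeric(r$db)))
    },
    gap = {
      d <- cache$dim
      dx <- array(0, d)
      dx[] <- rep(as.vector(t(dy)) / d[1], each = d[1])
      list(dx = dx, grads = list())
    },
    last_step = {
      d <- cache$dim
      dx <- array(0, d)
      dx[d[1], , ] <- t(dy)
      list(dx = dx, grads = list())
    },
    last_step_bct = {
      d <- cache$dim
      dx <- array(0, d)
      dx[, , d[3]] <- dy
      list(dx = dx, grads = list())
    },
    cls_pick = {
      d <- cache$dim
      dx <- array(0, d)
      dx[1, , ] <- t(dy)
      list(dx = dx, grads = list())
    },
    linear = {
      list(dx = dy %*% t(p$W),
           grads = list(W = t(cache$x) %*% dy, b = colSums(dy)))
    },
    stopf("unknown layer kind '%s'", ly$kind))
}

net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(y = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  names(grads) <- names(layers)
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}
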