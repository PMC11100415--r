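ns <- asNamespace("fitnet")

test_that("FIT shape chain halves length and doubles channels per block", {
  cfg <- fit_config(seed = 2)
  m <- build_model(cfg)
  set.seed(1)
  x <- array(rnorm(200 * 12 * 2), c(200, 12, 2))
  # stem: 200 x 12 -> 200 x 32
  r <- ns$layer_forward(m$layers$stem, x, FALSE)
  expect_equal(dim(r$y), c(200, 32, 2))
  # block 1 inception: -> 100 x 64; block 2: -> 50 x 128
  h <- ns$net_forward(m$layers[1:8], x, FALSE)$y
  expect_equal(dim(h), c(100, 64, 2))
  h2 <- ns$net_forward(m$layers[1:15], x, FALSE)$y
  expect_equal(dim(h2), c(50, 128, 2))
  y <- model_forward(m, x)
  expect_equal(dim(y), c(2, 10))
  expect_true(all(is.finite(y)))
  # shifted inputs still give a well-defined finite forward pass
  expect_true(all(is.finite(model_forward(m, x + 5))))
  expect_error(fit_config(L = 150), "divisible")
})

test_that("HED: conv + average-pooling branches concatenated on channels", {
  set.seed(3)
  ly <- ns$layer_hed(2L)
  x <- array(rnorm(6 * 2 * 1), c(6, 2, 1))
  # zero the conv branch: channels 3..4 must be exact 2-sample means
  ly$params$W[] <- 0
  ly$params$b[] <- 0
  y <- ns$layer_forward(ly, x, FALSE)$y
  expect_equal(dim(y), c(3, 4, 1))
  expect_equal(y[, 1:2, 1], matrix(0, 3, 2))
  hand <- (x[c(1, 3, 5), , 1] + x[c(2, 4, 6), , 1]) / 2
  expect_equal(y[, 3:4, 1], hand)
  # constant input, sum kernel: both branches constant; shape 2 x 8
  ly2 <- ns$layer_hed(4L)
  ly2$params$W[] <- 0
  for (c in 1:4) ly2$params$W[c(c, 4 + c), c] <- 0.5   # average the 2 taps
  ly2$params$b[] <- 0
  ones <- array(1, c(4, 4, 1))
  y2 <- ns$layer_forward(ly2, ones, FALSE)$y
  expect_equal(dim(y2), c(2, 8, 1))
  expect_true(all(abs(y2 - 1) < 1e-12))
  expect_error(ns$layer_forward(ns$layer_hed(2L), array(0, c(5, 2, 1)), FALSE),
               "even")
})

test_that("MSC: identity path exact, zero-weight paths reduce to bias", {
  set.seed(4)
  ly <- ns$layer_msc(8L, c(3L, 5L, 7L))
  x <- array(rnorm(10 * 8 * 3), c(10, 8, 3))
  y <- ns$layer_forward(ly, x, FALSE)$y
  expect_equal(dim(y), dim(x))
  expect_identical(y[, 7:8, ], x[, 7:8, ])             # group 4 untouched
  for (i in 1:3) ly$params[[paste0("W", i)]][] <- 0
  ly$params$b1[] <- 0.5
  y0 <- ns$layer_forward(ly, x, FALSE)$y
  expect_true(all(abs(y0[, 1:2, ] - 0.5) < 1e-12))     # bias broadcast
  expect_true(all(abs(y0[, 3:6, ]) < 1e-12))
  expect_error(ns$layer_msc(6L), "divisible by 4")
})

test_that("multi-head attention equals an explicit-loop oracle", {
  set.seed(5)
  C <- 8L; N <- 2L; L <- 5L
  ly <- ns$layer_attn_res(C, N, scale_d = C)
  x <- array(rnorm(L * C * 2), c(L, C, 2))
  y <- ns$layer_forward(ly, x, FALSE)$y
  p <- ly$params
  w <- C %/% N
  for (s in 1:2) {
    X <- x[, , s]
    mu <- rowMeans(X); sdv <- sqrt(pmax(apply(X, 1, function(r)
      mean(r^2) - mean(r)^2), 0) + 1e-5)
    Xn <- sweep(sweep(X, 1, mu, "-"), 1, sdv, "/")
    Xn <- sweep(sweep(Xn, 2, p$ln_g, "*"), 2, p$ln_b, "+")
    Q <- sweep(Xn %*% p$Wq, 2, p$bq, "+")
    K <- sweep(Xn %*% p$Wk, 2, p$bk, "+")
    V <- sweep(Xn %*% p$Wv, 2, p$bv, "+")
    H <- matrix(0, L, N * w)
    for (h in 1:N) {
      cs <- ((h - 1) * w + 1):(h * w)
      S <- Q[, cs] %*% t(K[, cs]) / sqrt(C)
      S <- exp(S - apply(S, 1, max))
      S <- S / rowSums(S)
      H[, cs] <- S %*% V[, cs]
    }
    out <- X + sweep(H %*% p$Wm, 2, p$bm, "+")
    expect_lt(max(abs(out - y[, , s])), 1e-6)
  }
})

test_that("attention is permutation-equivariant and single-token attention
           collapses to the value row", {
  set.seed(6)
  ly <- ns$layer_attn_res(8L, 2L)
  x <- array(rnorm(6 * 8), c(6, 8, 1))
  y <- ns$layer_forward(ly, x, FALSE)$y
  perm <- c(3, 1, 6, 2, 5, 4)
  yp <- ns$layer_forward(ly, x[perm, , , drop = FALSE], FALSE)$y
  expect_equal(yp[, , 1], y[perm, , 1], tolerance = 1e-12)
  # L = 1: softmax over one key gives weight 1 regardless of Q, K
  x1 <- array(rnorm(8), c(1, 8, 1))
  ly$params$Wq[] <- rnorm(64); ly$params$Wk[] <- rnorm(64)
  y1 <- ns$layer_forward(ly, x1, FALSE)$y
  ly$params$Wq[] <- 0; ly$params$Wk[] <- 0
  y1b <- ns$layer_forward(ly, x1, FALSE)$y
  expect_equal(y1, y1b, tolerance = 1e-12)
})

test_that("FFN sublayer matches a two-matrix-multiply oracle", {
  set.seed(8)
  ly <- ns$layer_ffn_res(4L)
  x <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  y <- ns$layer_forward(ly, x, FALSE)$y
  p <- ly$params
  gelu <- function(v) 0.5 * v * (1 + tanh(sqrt(2 / pi) * (v + 0.044715 * v^3)))
  for (s in 1:2) {
    X <- x[, , s]
    mu <- rowMeans(X); sdv <- sqrt(pmax(apply(X, 1, function(r)
      mean(r^2) - mean(r)^2), 0) + 1e-5)
    Xn <- sweep(sweep(X, 1, mu, "-"), 1, sdv, "/")
    Xn <- sweep(sweep(Xn, 2, p$ln_g, "*"), 2, p$ln_b, "+")
    H <- gelu(sweep(Xn %*% p$W1, 2, p$b1, "+"))
    out <- X + sweep(H %*% p$W2, 2, p$b2, "+")
    expect_lt(max(abs(out - y[, , s])), 1e-10)
  }
  # hidden width is 4x the channel width
  expect_equal(dim(ly$params$W1), c(4, 16))
  # zero input, zero biases, zero output delta
  ly$params$b1[] <- 0; ly$params$b2[] <- 0; ly$params$ln_b[] <- 0
  z <- array(0, c(3, 4, 1))
  expect_true(all(abs(ns$layer_forward(ly, z, FALSE)$y) < 1e-12))
})

test_that("transformer block with zeroed sublayer outputs is the identity", {
  set.seed(9)
  attn <- ns$layer_attn_res(8L, 2L)
  ffn <- ns$layer_ffn_res(8L)
  attn$params$Wm[] <- 0; attn$params$bm[] <- 0
  ffn$params$W2[] <- 0; ffn$params$b2[] <- 0
  x <- array(rnorm(5 * 8 * 3), c(5, 8, 3))
  y <- ns$net_forward(list(attn, ffn), x, FALSE)$y
  expect_equal(y, x, tolerance = 1e-14)
  # composing one block twice equals a 2-block stack applied once
  set.seed(10)
  a1 <- ns$layer_attn_res(8L, 2L); f1 <- ns$layer_ffn_res(8L)
  a2 <- ns$layer_attn_res(8L, 2L); f2 <- ns$layer_ffn_res(8L)
  once <- ns$net_forward(list(a1, f1), x, FALSE)$y
  twice <- ns$net_forward(list(a2, f2), once, FALSE)$y
  stacked <- ns$net_forward(list(a1, f1, a2, f2), x, FALSE)$y
  expect_equal(twice, stacked, tolerance = 1e-12)
})

test_that("baseline families map a window to the joint vector", {
  set.seed(11)
  x <- array(rnorm(200 * 12 * 2), c(200, 12, 2))
  for (fam in c("lstm", "tcn", "bert")) {
    m <- build_model(baseline_config(fam, seed = 4))
    y <- model_forward(m, x)
    expect_equal(dim(y), c(2, 10))
    expect_true(all(is.finite(y)))
  }
  expect_error(baseline_config("mlp"), "arg")
})

test_that("TCN is causal with a 125-frame receptive field", {
  set.seed(12)
  m <- build_model(baseline_config("tcn", seed = 6))
  levels <- m$layers[1:5]
  x <- array(rnorm(200 * 12), c(200, 12, 1))
  base <- ns$net_forward(levels, x, FALSE)$y
  # causality: perturbing frames after t never changes features at <= t
  t0 <- 120L
  xa <- x; xa[(t0 + 1):200, , 1] <- rnorm(80 * 12)
  pert <- ns$net_forward(levels, xa, FALSE)$y
  expect_equal(pert[1:t0, , 1], base[1:t0, , 1], tolerance = 1e-12)
  # receptive field 1 + 2*(k-1)*sum(dilations) = 125: features at t = 200
  # ignore anything earlier than frame 76
  xb <- x; xb[1:75, , 1] <- rnorm(75 * 12)
  pert2 <- ns$net_forward(levels, xb, FALSE)$y
  expect_equal(pert2[200, , 1], base[200, , 1], tolerance = 1e-12)
  xc <- x; xc[76, , 1] <- x[76, , 1] + 10
  pert3 <- ns$net_forward(levels, xc, FALSE)$y
  expect_gt(max(abs(pert3[200, , 1] - base[200, , 1])), 1e-6)
})

test_that("parameter counts match closed forms and are seed-stable", {
  # lone 128 -> 10 linear readout: 1290 parameters
  lin <- ns$layer_linear(128L, 10L)
  expect_equal(sum(lengths(lin$params)), 1290)
  m <- build_model(baseline_config("lstm", seed = 1))
  p <- ns$model_params(m)
  lstm_count <- function(i, h) 4 * (h * (i + h) + h)
  expect_equal(sum(lengths(p$lstm1)), lstm_count(12, 128))
  expect_equal(sum(lengths(p$lstm2)), lstm_count(128, 128))
  # architecture-only quantity: identical across seeds
  n1 <- count_parameters(build_model(fit_config(seed = 1)))$n_params
  n2 <- count_parameters(build_model(fit_config(seed = 999)))$n_params
  expect_equal(n1, n2)
  expect_gt(n1, 1e5)
})

test_that("weight initialization is reproducible and eval mode deterministic", {
  for (make in list(function(s) fit_config(seed = s),
                    function(s) baseline_config("bert", seed = s))) {
    m1 <- build_model(make(42))
    m2 <- build_model(make(42))
    expect_identical(ns$model_params(m1), ns$model_params(m2))
    m3 <- build_model(make(43))
    expect_false(identical(ns$model_params(m1), ns$model_params(m3)))
  }
  m <- build_model(fit_config(seed = 2))
  x1 <- array(rnorm(200 * 12), c(200, 12, 1))
  xrep <- array(rep(x1, 3), c(200, 12, 3))     # batch of identical windows
  y <- model_forward(m, xrep)
  expect_equal(y[1, ], y[2, ], tolerance = 1e-12)
  expect_equal(y[1, ], y[3, ], tolerance = 1e-12)
})

test_that("checkpoints rebuild the exact model", {
  m <- build_model(fit_config(L = 8L, in_channels = 3L, stem_channels = 4L,
                              heads = c(2L, 2L), n_joints = 2L, seed = 5))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  x <- array(rnorm(8 * 3 * 2), c(8, 3, 2))
  expect_identical(model_forward(m, x), model_forward(m2, x))
})

test_that("analytic gradients agree with finite differences (spot check)", {
  set.seed(20)
  cfg <- fit_config(in_channels = 3L, stem_channels = 4L, L = 8L,
                    heads = c(2L, 2L), n_joints = 2L, seed = 3)
  m <- build_model(cfg)
  for (ln in names(m$layers))
    m$layers[[ln]]$params <- lapply(m$layers[[ln]]$params, function(p)
      p + stats::rnorm(length(p)) * 0.05)
  x <- array(rnorm(8 * 3 * 2), c(8, 3, 2))
  fw <- model_forward(m, x, training = TRUE)
  wt <- matrix(rnorm(length(fw$y)), nrow(fw$y))
  bw <- ns$model_backward(fw$model, fw$caches, wt)
  for (ln in c("stem", "b1_attn", "b2_ffn", "head")) {
    pn <- names(m$layers[[ln]]$params)[1]
    p0 <- m$layers[[ln]]$params[[pn]]
    i <- sample(seq_along(p0), 1)
    f <- function(v) {
      m2 <- m; m2$layers[[ln]]$params[[pn]][i] <- v
      sum(model_forward(m2, x, training = TRUE)$y * wt)
    }
    g_num <- (f(p0[i] + 1e-5) - f(p0[i] - 1e-5)) / 2e-5
    expect_equal(bw$grads[[ln]][[pn]][i], g_num, tolerance = 1e-4)
  }
})
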