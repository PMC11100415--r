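#' Training configuration
#'
#' Defaults follow the training protocol used for all four model families:
#' batch size 64, 100 epochs (200 for the LSTM family, which converges more
#' slowly), Adam with learning rate 1e-3 dropped to 1e-4 once half of the
#' epochs are completed, and mean-squared-error loss on z-scored targets.
#'
#' @param batch_size windows per optimizer step.
#' @param epochs training epochs.
#' @param epochs_lstm training epochs for the LSTM family.
#' @param epochs_tcn optional override for the TCN family (defaults to
#'   `epochs`); the un-normalized TCN converges more slowly than the
#'   batch- or layer-normalized models at small epoch budgets.
#' @param lr_initial,lr_after_half Adam step sizes before and after the
#'   half-way point of training.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param seed seed for weight init (combined with the model seed) and for
#'   the shuffling of training windows.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, epochs = 100L, epochs_lstm = 200L,
                         epochs_tcn = NULL, lr_initial = 1e-3,
                         lr_after_half = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, seed = 1L) {
  stopifnot(epochs >= 1, lr_initial > 0, lr_after_half > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 epochs_lstm = as.integer(epochs_lstm),
                 epochs_tcn = if (!is.null(epochs_tcn)) as.integer(epochs_tcn),
                 lr_initial = lr_initial, lr_after_half = lr_after_half,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Gather a batch of windows into an (L, C, B) cube from the frame matrix.
gather_windows <- function(features, starts, L) {
  B <- length(starts)
  idx <- as.vector(outer(0:(L - 1L), starts, "+"))
  aperm(array(features[idx, , drop = FALSE], c(L, B, ncol(features))),
        c(1, 3, 2))
}

adam_init <- function(params) {
  zero <- function(p) lapply(p, function(x) array(0, dim(x) %||% length(x)))
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1, b2, eps) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (ln in names(params)) {
    for (pn in names(params[[ln]])) {
      g <- grads[[ln]][[pn]]
      m <- b1 * state$m[[ln]][[pn]] + (1 - b1) * g
      v <- b2 * state$v[[ln]][[pn]] + (1 - b2) * g * g
      state$m[[ln]][[pn]] <- m
      state$v[[ln]][[pn]] <- v
      params[[ln]][[pn]] <- params[[ln]][[pn]] -
        lr * (m / c1) / (sqrt(v / c2) + eps)
    }
  }
  list(params = params, state = state)
}

#' Train a model on a windowed dataset
#'
#' Minimizes mean-squared error between the model output and `ds$y` (expected
#' to be scaler-transformed targets) with Adam, dropping the learning rate to
#' `lr_after_half` once half of the epochs are completed. Fully deterministic
#' given `(model config seed, cfg$seed)`: the data order is shuffled by a
#' seeded RNG each epoch.
#'
#' @param model a [build_model()] result.
#' @param ds a windowed dataset from [make_windows()] whose `y` has been
#'   scaled (see [fit_target_scaler()]).
#' @param cfg a [train_config()].
#' @param epochs optional override of the epoch count (otherwise taken from
#'   `cfg`, using `epochs_lstm` for the LSTM family).
#' @param verbose print per-epoch loss.
#' @return list with the trained `model` and `history` (per-epoch mean
#'   training loss).
#' @export
train_model <- function(model, ds, cfg = train_config(), epochs = NULL,
                        verbose = FALSE) {
  n <- length(ds$starts)
  if (n == 0) stopf("training dataset is empty")
  if (model$family == "oracle") return(list(model = model, history = numeric()))
  epochs <- epochs %||% switch(model$family,
    lstm = cfg$epochs_lstm,
    tcn = cfg$epochs_tcn %||% cfg$epochs,
    cfg$epochs)
  B <- cfg$batch_size
  params <- model_params(model)
  state <- adam_init(params)
  history <- numeric(epochs)
  half <- floor(epochs / 2)
  with_seed(derive_seed(cfg$seed, 17L), {
    for (ep in seq_len(epochs)) {
      lr <- if (ep > half) cfg$lr_after_half else cfg$lr_initial
      ord <- sample.int(n)
      losses <- numeric(0)
      for (i0 in seq(1, n, by = B)) {
        ix <- ord[i0:min(i0 + B - 1L, n)]
        x <- gather_windows(ds$features, ds$starts[ix], ds$L)
        y <- ds$y[ix, , drop = FALSE]
        model <- set_model_params(model, params)
        fw <- model_forward(model, x, training = TRUE)
        model <- fw$model
        err <- fw$y - y
        loss <- mean(err^2)
        if (!is.finite(loss))
          stopf("training diverged (non-finite loss) at epoch %d", ep)
        losses <- c(losses, loss)
        dy <- 2 * err / length(err)
        bw <- model_backward(model, fw$caches, dy)
        up <- adam_step(params, bw$grads, state, lr, cfg$beta1, cfg$beta2,
                        cfg$adam_eps)
        params <- up$params
        state <- up$state
      }
      history[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %3d/%d  lr %.0e  loss %.5f", ep, epochs, lr,
                        history[ep]))
    }
  })
  model <- set_model_params(model, params)
  list(model = model, history = history)
}

#' Predict on a windowed dataset
#'
#' Runs the model in evaluation mode (running batch-norm statistics, no
#' updates) over all windows.
#'
#' @inheritParams train_model
#' @param batch_size forward-pass batch size (memory knob only).
#' @return `(n_windows, n_joints)` prediction matrix on the scale of `ds$y`.
#' @export
predict_model <- function(model, ds, batch_size = 256L) {
  n <- length(ds$starts)
  if (model$family == "oracle") return(ds$y)
  out <- matrix(0, n, model$config$n_joints)
  for (i0 in seq(1, n, by = batch_size)) {
    ix <- i0:min(i0 + batch_size - 1L, n)
    x <- gather_windows(ds$features, ds$starts[ix], ds$L)
    out[ix, ] <- model_forward(model, x, training = FALSE)
  }
  out
}
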