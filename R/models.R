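#' Configuration for the FIT regressor
#'
#' FIT stacks a kernel-1 "stem" convolution with `n_blocks` repetitions of an
#' inception block (efficient downsampling + multi-scale convolution) followed
#' by a pre-layer-norm transformer encoder block, then global average pooling
#' over time and a linear readout. Each inception block halves the sequence
#' length and doubles the channel width, so with the defaults the internal
#' shape chain is 200 x 32 -> 100 x 64 -> 50 x 128 -> 10 outputs.
#'
#' @param in_channels number of input channels (EMG electrodes).
#' @param stem_channels channel width C after the stem convolution.
#' @param L input window length in feature frames; must be divisible by
#'   `2^n_blocks`.
#' @param n_blocks number of inception + transformer block pairs.
#' @param msc_kernels kernel sizes of the three convolutional paths of the
#'   multi-scale convolution (the fourth path is the identity).
#' @param heads head counts of the multi-head attention, one per block.
#' @param scale_mode softmax logit scaling: `"channels"` divides by
#'   `sqrt(C_b)` (the block channel width), `"per_head"` by the conventional
#'   `sqrt(C_b / N)`.
#' @param ffn_expansion hidden-width multiplier of the feed-forward sublayer.
#' @param n_joints number of regression targets.
#' @param readout `"gap"` (average over remaining frames) or `"last"`.
#' @param seed integer seed controlling weight initialization.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(in_channels = 12L, stem_channels = 32L, L = 200L,
                       n_blocks = 2L, msc_kernels = c(3L, 5L, 7L),
                       heads = c(4L, 6L), scale_mode = c("channels", "per_head"),
                       ffn_expansion = 4L, n_joints = 10L,
                       readout = c("gap", "last"), seed = 1L) {
  scale_mode <- match.arg(scale_mode)
  readout <- match.arg(readout)
  if (L %% (2L^n_blocks) != 0L)
    stopf("window length L = %d must be divisible by 2^%d", L, n_blocks)
  if (length(heads) != n_blocks)
    stopf("`heads` must supply one head count per block")
  structure(list(family = "fit", in_channels = as.integer(in_channels),
                 stem_channels = as.integer(stem_channels), L = as.integer(L),
                 n_blocks = as.integer(n_blocks),
                 msc_kernels = as.integer(msc_kernels),
                 heads = as.integer(heads), scale_mode = scale_mode,
                 ffn_expansion = as.integer(ffn_expansion),
                 n_joints = as.integer(n_joints), readout = readout,
                 seed = as.integer(seed)),
            class = c("fit_config", "model_config"))
}

#' Configuration for a baseline regressor
#'
#' Three sequence-regression baselines sharing the FIT training protocol:
#' * `lstm`: two stacked LSTM layers of 128 hidden units, last hidden state
#'   to a linear readout.
#' * `tcn`: five dilated causal residual levels (kernel 3, dilations
#'   1,2,4,8,16, channels 32/64/64/64/128), last time step to a linear
#'   readout; the receptive field is 1 + 2(k-1)(1+2+4+8+16) = 125 frames.
#' * `bert`: linear embedding to 128 dims, learned class token and positional
#'   embeddings, two pre-layer-norm encoder blocks with 8 heads, class-token
#'   readout.
#' * `oracle`: a stub that outputs the true targets; used to validate the
#'   evaluation pipeline end to end.
#'
#' @param family one of `"lstm"`, `"tcn"`, `"bert"`, `"oracle"`.
#' @param in_channels,n_joints,L input/output dimensions as in [fit_config()].
#' @param seed integer seed controlling weight initialization.
#' @param hidden LSTM hidden width per layer.
#' @param n_layers LSTM layer count.
#' @param tcn_channels,tcn_kernel,tcn_dilations TCN level configuration.
#' @param bert_dim,bert_heads,bert_blocks BERT encoder configuration.
#' @return an object of class `baseline_config`.
#' @export
baseline_config <- function(family = c("lstm", "tcn", "bert", "oracle"),
                            in_channels = 12L, n_joints = 10L, L = 200L,
                            seed = 1L, hidden = 128L, n_layers = 2L,
                            tcn_channels = c(32L, 64L, 64L, 64L, 128L),
                            tcn_kernel = 3L,
                            tcn_dilations = c(1L, 2L, 4L, 8L, 16L),
                            bert_dim = 128L, bert_heads = 8L,
                            bert_blocks = 2L) {
  family <- match.arg(family)
  structure(list(family = family, in_channels = as.integer(in_channels),
                 n_joints = as.integer(n_joints), L = as.integer(L),
                 seed = as.integer(seed), hidden = as.integer(hidden),
                 n_layers = as.integer(n_layers),
                 tcn_channels = as.integer(tcn_channels),
                 tcn_kernel = as.integer(tcn_kernel),
                 tcn_dilations = as.integer(tcn_dilations),
                 bert_dim = as.integer(bert_dim),
                 bert_heads = as.integer(bert_heads),
                 bert_blocks = as.integer(bert_blocks)),
            class = c("baseline_config", "model_config"))
}

#' Build a model from its configuration
#'
#' Weight initialization is a pure function of `(config, config$seed)`: two
#' builds from the same configuration have identical parameters.
#'
#' @param config a [fit_config()] or [baseline_config()].
#' @return an object of class `fitnet_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  layers <- with_seed(config$seed, {
    if (config$family == "fit") build_fit_layers(config)
    else switch(config$family,
      lstm = build_lstm_layers(config),
      tcn = build_tcn_layers(config),
      bert = build_bert_layers(config),
      oracle = list(),
      stopf("unknown model family '%s'", config$family))
  })
  structure(list(family = config$family, config = config, layers = layers),
            class = "fitnet_model")
}

build_fit_layers <- function(cfg) {
  C <- cfg$stem_channels
  layers <- list(stem = layer_conv(cfg$in_channels, C, k = 1L))
  Cb <- C
  for (b in seq_len(cfg$n_blocks)) {
    nm <- function(s) paste0("b", b, "_", s)
    blk <- list(
      layer_hed(Cb), layer_bn(2L * Cb),
      layer_msc(2L * Cb, cfg$msc_kernels), layer_act("elu"), layer_bn(2L * Cb),
      layer_attn_res(2L * Cb, cfg$heads[b],
                     scale_d = if (cfg$scale_mode == "channels") 2L * Cb
                               else (2L * Cb) / cfg$heads[b]),
      layer_ffn_res(2L * Cb, cfg$ffn_expansion))
    names(blk) <- c(nm("hed"), nm("bn1"), nm("msc"), nm("elu"), nm("bn2"),
                    nm("attn"), nm("ffn"))
    layers <- c(layers, blk)
    Cb <- 2L * Cb
  }
  pool <- if (cfg$readout == "gap") layer_gap() else layer_last_step()
  c(layers, list(pool = pool, head = layer_linear(Cb, cfg$n_joints)))
}

build_lstm_layers <- function(cfg) {
  layers <- list(perm = layer_to_bct())
  cin <- cfg$in_channels
  for (i in seq_len(cfg$n_layers)) {
    layers[[paste0("lstm", i)]] <- layer_lstm(cin, cfg$hidden)
    cin <- cfg$hidden
  }
  c(layers, list(pick = layer_last_step_bct(),
                 head = layer_linear(cfg$hidden, cfg$n_joints)))
}

build_tcn_layers <- function(cfg) {
  layers <- list()
  cin <- cfg$in_channels
  for (i in seq_along(cfg$tcn_channels)) {
    layers[[paste0("level", i)]] <-
      layer_tcn_level(cin, cfg$tcn_channels[i], cfg$tcn_kernel,
                      cfg$tcn_dilations[i])
    cin <- cfg$tcn_channels[i]
  }
  c(layers, list(pick = layer_last_step(),
                 head = layer_linear(cin, cfg$n_joints)))
}

build_bert_layers <- function(cfg) {
  C <- cfg$bert_dim
  layers <- list(embed = layer_bert_embed(cfg$in_channels, C, cfg$L))
  for (b in seq_len(cfg$bert_blocks)) {
    layers[[paste0("attn", b)]] <-
      layer_attn_res(C, cfg$bert_heads, scale_d = C / cfg$bert_heads)
    layers[[paste0("ffn", b)]] <- layer_ffn_res(C)
  }
  c(layers, list(pick = layer_cls_pick(),
                 head = layer_linear(C, cfg$n_joints)))
}

#' Forward pass of a model on a batch of windows
#'
#' @param model a [build_model()] result.
#' @param x array of dim `(L, in_channels, batch)`.
#' @param training logical; `TRUE` uses batch statistics in batch-norm layers
#'   and updates their running estimates.
#' @return with `training = FALSE`, the `(batch, n_joints)` prediction matrix;
#'   with `training = TRUE`, a list with `y`, per-layer `caches`, and the
#'   updated `model` (running statistics).
#' @export
model_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "fitnet_model"))
  r <- net_forward(model$layers, x, training)
  if (!training) return(r$y)
  model$layers <- r$layers
  list(y = r$y, caches = r$caches, model = model)
}

model_backward <- function(model, caches, dy) {
  net_backward(model$layers, caches, dy)
}

#' Count trainable parameters
#'
#' @param model a [build_model()] result.
#' @return a list with `n_params` (number of trainable scalars) and `mb`
#'   (float32 footprint in megabytes).
#' @export
count_parameters <- function(model) {
  n <- sum(vapply(model$layers,
                  function(ly) sum(vapply(ly$params, length, 0L)), 0))
  list(n_params = n, mb = n * 4 / 2^20)
}

model_params <- function(model) lapply(model$layers, `[[`, "params")

set_model_params <- function(model, params) {
  for (nm in names(params)) model$layers[[nm]]$params <- params[[nm]]
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, all weights and normalization
#' buffers, so a run can be rebuilt exactly.
#'
#' @param model a `fitnet_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, layers = model$layers,
               family = model$family), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(family = obj$family, config = obj$config,
                 layers = obj$layers), class = "fitnet_model")
}

#' @export
print.fitnet_model <- function(x, ...) {
  cp <- count_parameters(x)
  cat(sprintf("<fitnet_model %s: %d layers, %s parameters (%.2f MB fp32)>\n",
              x$family, length(x$layers), format(cp$n_params, big.mark = ","),
              cp$mb))
  invisible(x)
}
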