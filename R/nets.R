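#' Declarative model configuration
#'
#' Describes one of the three classifier families operating on 256-sample,
#' 6-channel windows:
#'
#' * `cnn` - three convolutional blocks (1-D convolution kernel 3, 64
#'   channels, batch normalization, ReLU, max pooling kernel 3 stride 2),
#'   flatten, then fully connected 1920 -> 512 -> 3 with a softmax output.
#'   Per-block convolution paddings default to (1, 0, 1): that is the unique
#'   choice under which the block output lengths follow the printed design
#'   (256 -> 127 -> 62 -> 30, flatten width 1920).
#' * `lstm` - stacked LSTM layers over the raw sequence, ReLU and dropout on
#'   the final time step's state, then a fully connected softmax head.
#' * `convlstm` - the hybrid: four convolutional blocks (padding 1 each)
#'   whose feature map is fed as a sequence into two stacked LSTM layers
#'   (hidden width = `width`) with dropout between and after them, then a
#'   fully connected softmax head on the final time step. The defaults are
#'   the hyperparameter-tuning winner: width 64, 4 conv blocks, 2 LSTM
#'   layers, dropout 0.5.
#'
#' @param family `"cnn"`, `"lstm"` or `"convlstm"`.
#' @param width Channels per conv layer / LSTM hidden width.
#' @param n_conv_blocks Number of convolutional blocks.
#' @param n_lstm_layers Number of stacked LSTM layers.
#' @param kernel_len Convolution kernel length.
#' @param pool_len,pool_stride Max-pooling kernel and stride.
#' @param conv_padding Per-block convolution padding; defaults depend on the
#'   family (see above).
#' @param dropout Dropout probability in `[0, 1)`.
#' @param fc_hidden Hidden width of the CNN's first fully connected layer.
#' @param n_classes Number of output classes (3 stages).
#' @param input_len,input_channels Window shape consumed by the model.
#' @return An object of class `model_config`.
#' @export
model_config <- function(family = c("convlstm", "cnn", "lstm"),
                         width = 64L,
                         n_conv_blocks = NULL,
                         n_lstm_layers = NULL,
                         kernel_len = 3L,
                         pool_len = 3L,
                         pool_stride = 2L,
                         conv_padding = NULL,
                         dropout = NULL,
                         fc_hidden = 512L,
                         n_classes = 3L,
                         input_len = 256L,
                         input_channels = 6L) {
  family <- match.arg(family)
  n_conv_blocks <- as.integer(n_conv_blocks %||% switch(family, cnn = 3L, lstm = 0L, convlstm = 4L))
  n_lstm_layers <- as.integer(n_lstm_layers %||% switch(family, cnn = 0L, 2L))
  dropout <- dropout %||% switch(family, cnn = 0, 0.5)
  if (dropout < 0 || dropout >= 1) stop("model_config: dropout must be in [0, 1)", call. = FALSE)
  if (is.null(conv_padding)) {
    conv_padding <- if (family == "cnn" && n_conv_blocks == 3L) c(1L, 0L, 1L)
                    else rep(1L, n_conv_blocks)
  }
  if (length(conv_padding) != n_conv_blocks) {
    stop("model_config: conv_padding must have one entry per conv block", call. = FALSE)
  }
  structure(
    list(family = family, width = as.integer(width),
         n_conv_blocks = n_conv_blocks, n_lstm_layers = n_lstm_layers,
         kernel_len = as.integer(kernel_len), pool_len = as.integer(pool_len),
         pool_stride = as.integer(pool_stride),
         conv_padding = as.integer(conv_padding), dropout = dropout,
         fc_hidden = as.integer(fc_hidden), n_classes = as.integer(n_classes),
         input_len = as.integer(input_len), input_channels = as.integer(input_channels)),
    class = "model_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s: width %d, %d conv blocks, %d LSTM layers, dropout %g\n",
              x$family, x$width, x$n_conv_blocks, x$n_lstm_layers, x$dropout))
  cat(sprintf("  input %d x %d -> %d classes\n", x$input_len, x$input_channels, x$n_classes))
  invisible(x)
}

#' Symbolic per-layer shape trace
#'
#' Computes the (temporal length, channel) shape after every layer of a
#' configuration without instantiating any parameters, using the layer
#' arithmetic: convolution `L -> L + 2*pad - kernel + 1`, pooling
#' `L -> floor((L - pool) / stride) + 1` (floor division), flatten
#' `L x C -> 1 x (L*C)`. For the default CNN this reproduces the printed
#' design exactly: lengths 256, 127, 62, 30 and flatten width 1920.
#'
#' @param config A [model_config()].
#' @return Data frame of class `shape_trace` with columns `layer`, `out_len`,
#'   `out_ch`.
#' @export
shape_trace <- function(config) {
  rows <- list(list(layer = "input", out_len = config$input_len, out_ch = config$input_channels))
  L <- config$input_len; C <- config$input_channels
  for (bk in seq_len(config$n_conv_blocks)) {
    Lc <- L + 2L * config$conv_padding[bk] - config$kernel_len + 1L
    if (Lc < 1L) {
      stop(sprintf("architecture error in conv block %d: input length %d too short for kernel %d (pad %d)",
                   bk, L, config$kernel_len, config$conv_padding[bk]), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- list(layer = sprintf("conv%d", bk), out_len = Lc, out_ch = config$width)
    Lp <- (Lc - config$pool_len) %/% config$pool_stride + 1L
    if (Lp < 1L) {
      stop(sprintf("architecture error in conv block %d: length %d too short for pooling kernel %d",
                   bk, Lc, config$pool_len), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- list(layer = sprintf("pool%d", bk), out_len = Lp, out_ch = config$width)
    L <- Lp; C <- config$width
  }
  if (config$family == "cnn") {
    rows[[length(rows) + 1L]] <- list(layer = "flatten", out_len = 1L, out_ch = L * C)
    rows[[length(rows) + 1L]] <- list(layer = "fc1", out_len = 1L, out_ch = config$fc_hidden)
    rows[[length(rows) + 1L]] <- list(layer = "fc2", out_len = 1L, out_ch = config$n_classes)
  } else {
    for (lk in seq_len(config$n_lstm_layers)) {
      rows[[length(rows) + 1L]] <- list(layer = sprintf("lstm%d", lk), out_len = L, out_ch = config$width)
    }
    rows[[length(rows) + 1L]] <- list(layer = "last_step", out_len = 1L, out_ch = config$width)
    rows[[length(rows) + 1L]] <- list(layer = "fc", out_len = 1L, out_ch = config$n_classes)
  }
  rows[[length(rows) + 1L]] <- list(layer = "softmax", out_len = 1L,
                                    out_ch = config$n_classes)
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  class(out) <- c("shape_trace", "data.frame")
  out
}

#' Flatten width of a CNN configuration
#'
#' Convenience accessor: the input width of the first fully connected layer,
#' read off the shape trace.
#'
#' @param config A `cnn` [model_config()].
#' @return Integer feature count (1920 for the default CNN).
#' @export
cnn_flatten_width <- function(config = model_config("cnn")) {
  tr <- shape_trace(config)
  as.integer(tr$out_ch[tr$layer == "flatten"])
}

#' Build a model from a configuration
#'
#' Instantiates the layer stack with freshly initialized parameters. Models
#' are pure functions of `(config, seed)`: identical arguments give
#' bit-identical initial parameters.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `fall_model`.
#' @export
build_model <- function(config, seed = 1L) {
  tr <- shape_trace(config)   # validates the architecture arithmetic
  set.seed(seed)
  layers <- list()
  in_ch <- config$input_channels
  for (bk in seq_len(config$n_conv_blocks)) {
    layers <- c(layers, list(
      nn_conv1d(in_ch, config$width, config$kernel_len, config$conv_padding[bk]),
      nn_batchnorm(config$width),
      nn_relu(),
      nn_maxpool(config$pool_len, config$pool_stride)
    ))
    in_ch <- config$width
  }
  if (config$family == "cnn") {
    flat <- tr$out_ch[tr$layer == "flatten"]
    layers <- c(layers, list(
      nn_flatten(),
      nn_dense(flat, config$fc_hidden),
      nn_dense(config$fc_hidden, config$n_classes)
    ))
  } else {
    for (lk in seq_len(config$n_lstm_layers)) {
      layers <- c(layers, list(nn_lstm(in_ch, config$width)))
      in_ch <- config$width
      if (lk < config$n_lstm_layers && config$dropout > 0) {
        layers <- c(layers, list(nn_dropout(config$dropout)))
      }
    }
    layers <- c(layers, list(nn_last_step()))
    if (config$family == "lstm") layers <- c(layers, list(nn_relu()))
    if (config$dropout > 0) layers <- c(layers, list(nn_dropout(config$dropout)))
    layers <- c(layers, list(nn_dense(config$width, config$n_classes)))
  }
  structure(list(family = config$family, config = config, seed = as.integer(seed),
                 layers = layers),
            class = "fall_model")
}

#' @export
print.fall_model <- function(x, ...) {
  cat(sprintf("<fall_model> %s (%s parameters, seed %d)\n", x$family,
              format(n_params(x), big.mark = ","), x$seed))
  invisible(x)
}

#' Convenience builders for the three families
#'
#' `build_cnn()`, `build_lstm()` and `build_convlstm()` build the family
#' defaults (or a custom config of the matching family).
#'
#' @param config A [model_config()] of the matching family.
#' @param seed Initialization seed.
#' @return A `fall_model`.
#' @export
build_cnn <- function(config = model_config("cnn"), seed = 1L) {
  stopifnot(config$family == "cnn")
  build_model(config, seed)
}

#' @rdname build_cnn
#' @export
build_lstm <- function(config = model_config("lstm"), seed = 1L) {
  stopifnot(config$family == "lstm")
  build_model(config, seed)
}

#' @rdname build_cnn
#' @export
build_convlstm <- function(config = model_config("convlstm"), seed = 1L) {
  stopifnot(config$family == "convlstm")
  build_model(config, seed)
}

#' Observed per-layer shapes on a real forward pass
#'
#' Instruments a forward pass and records the actual (length, channels) after
#' every configured stage; used to check the symbolic [shape_trace()] against
#' reality.
#'
#' @param model A built `fall_model`.
#' @param batch Number of probe windows.
#' @return Data frame `layer`, `out_len`, `out_ch` (trainable stages only).
#' @export
observed_shapes <- function(model, batch = 2L) {
  cfg <- model$config
  x <- array(stats::rnorm(batch * cfg$input_len * cfg$input_channels),
             c(batch, cfg$input_len, cfg$input_channels))
  a <- act(matrix(x, batch * cfg$input_len, cfg$input_channels), batch, cfg$input_len)
  rows <- list(list(layer = "input", out_len = cfg$input_len, out_ch = cfg$input_channels))
  conv_i <- 0L; pool_i <- 0L; lstm_i <- 0L; fc_i <- 0L
  for (l in model$layers) {
    a <- layer_forward(l, a, training = FALSE)$out
    nm <- switch(l$type,
      conv1d = sprintf("conv%d", conv_i <- conv_i + 1L),
      maxpool = sprintf("pool%d", pool_i <- pool_i + 1L),
      lstm = sprintf("lstm%d", lstm_i <- lstm_i + 1L),
      flatten = "flatten",
      last_step = "last_step",
      dense = if (model$family == "cnn") sprintf("fc%d", fc_i <- fc_i + 1L) else "fc",
      NA_character_)
    if (!is.na(nm)) {
      rows[[length(rows) + 1L]] <- list(layer = nm, out_len = a$L, out_ch = ncol(a$x))
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Save / load a model checkpoint
#'
#' One file holding the trained parameters plus a config echo and the seed,
#' so any checkpoint is reproducible and reloadable.
#'
#' @param model A `fall_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, seed = model$seed,
               snapshot = model_snapshot(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, ck$seed)
  model_restore(model, ck$snapshot)
}
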