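#' Encoder architecture configuration
#'
#' The shared feature extractor maps a `(channels, window_len)` sensor
#' window to an H-dimensional embedding through a stack of 1-D convolution
#' blocks (valid convolution over time + ReLU) followed by two LSTM layers;
#' the last LSTM hidden state is projected linearly to the embedding z. Two
#' affine heads on z produce the known-class and novel-class logits. The
#' default preset follows the DeepConvLSTM shape used in sensor-based HAR
#' (four convolution blocks of 64 filters with kernel length 5, LSTM hidden
#' size 128, H = 128); the `"tiny"` preset (two strided blocks of 32
#' filters, hidden 32, H = 32) is sized for CPU-scale experiments.
#'
#' @param n_channels input sensor channels.
#' @param window_len window length in samples.
#' @param n_known number of known classes C_l (labeled head width).
#' @param n_novel number of novel classes C_u (unlabeled head width).
#' @param preset `"deepconvlstm"` (4 conv blocks, hidden 128, H = 128) or
#'   `"tiny"` (2 strided conv blocks, hidden 32, H = 32).
#' @param conv_filters,conv_kernels,conv_strides per-block overrides.
#' @param lstm_hidden hidden size of the two LSTM layers.
#' @param feature_dim embedding dimensionality H.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(n_channels, window_len, n_known, n_novel,
                           preset = c("tiny", "deepconvlstm"),
                           conv_filters = NULL, conv_kernels = NULL,
                           conv_strides = NULL, lstm_hidden = NULL,
                           feature_dim = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    deepconvlstm = list(filters = rep(64L, 4), kernels = rep(5L, 4),
                        strides = rep(1L, 4), hidden = 128L, H = 128L),
    tiny = list(filters = rep(32L, 2), kernels = rep(5L, 2),
                strides = rep(2L, 2), hidden = 32L, H = 32L))
  filters <- if (is.null(conv_filters)) defaults$filters else as.integer(conv_filters)
  kernels <- if (is.null(conv_kernels)) defaults$kernels else as.integer(conv_kernels)
  strides <- if (is.null(conv_strides)) defaults$strides else as.integer(conv_strides)
  hidden <- if (is.null(lstm_hidden)) defaults$hidden else as.integer(lstm_hidden)
  H <- if (is.null(feature_dim)) defaults$H else as.integer(feature_dim)
  stopifnot(length(filters) == length(kernels),
            length(filters) == length(strides),
            H >= 2, hidden >= 1, n_known >= 1, n_novel >= 1)
  # minimal input length admitted by the conv stack (every block needs
  # at least one valid output position)
  lmin <- 1L
  for (b in rev(seq_along(filters)))
    lmin <- kernels[b] + (lmin - 1L) * strides[b]
  if (window_len < lmin)
    stop(sprintf("window_len %d below the conv stack's receptive field; minimum admissible length is %d",
                 window_len, lmin))
  lt <- window_len
  for (b in seq_along(filters)) lt <- (lt - kernels[b]) %/% strides[b] + 1L
  structure(list(n_channels = as.integer(n_channels),
                 window_len = as.integer(window_len),
                 n_known = as.integer(n_known), n_novel = as.integer(n_novel),
                 conv_filters = filters, conv_kernels = kernels,
                 conv_strides = strides, lstm_hidden = hidden,
                 feature_dim = H, preset = preset, conv_out_len = lt,
                 min_window_len = lmin),
            class = "encoder_config")
}

#' Build an encoder model with deterministic initialization
#'
#' Parameters are drawn from uniform distributions scaled by fan-in/fan-out
#' (Glorot-style) using R's RNG, so the same seed always yields identical
#' initial weights. All biases start at zero so the initial embeddings are
#' driven by the input rather than by shared bias dynamics.
#'
#' @param config an [encoder_config()].
#' @param seed integer RNG seed.
#' @return object of class `model_state`: list with `config` and `params`
#'   (named list of numeric arrays).
#' @export
build_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "encoder_config"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(as.integer(seed))
  glorot <- function(dims, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    array(stats::runif(prod(dims), -lim, lim), dim = dims)
  }
  p <- list()
  cin <- config$n_channels
  for (b in seq_along(config$conv_filters)) {
    f <- config$conv_filters[b]; k <- config$conv_kernels[b]
    p[[sprintf("conv%d_W", b)]] <- glorot(c(f, cin, k), cin * k, f)
    p[[sprintf("conv%d_b", b)]] <- numeric(f)
    cin <- f
  }
  h <- config$lstm_hidden
  inp <- cin
  for (l in 1:2) {
    p[[sprintf("lstm%d_W", l)]] <- glorot(c(4 * h, inp), inp, h)
    p[[sprintf("lstm%d_U", l)]] <- glorot(c(4 * h, h), h, h)
    bias <- numeric(4 * h)
    # forget-gate bias left at 0: a positive bias makes the initial last-state
    # features nearly input-independent, which poisons the cosine pseudo-labels
    # in the first epoch
    p[[sprintf("lstm%d_b", l)]] <- bias
    inp <- h
  }
  H <- config$feature_dim
  p$proj_W <- glorot(c(H, h), h, H)
  p$proj_b <- numeric(H)
  p$headl_W <- glorot(c(config$n_known, H), H, config$n_known)
  p$headl_b <- numeric(config$n_known)
  p$headu_W <- glorot(c(config$n_novel, H), H, config$n_novel)
  p$headu_b <- numeric(config$n_novel)
  structure(list(config = config, params = p), class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<model_state: %s preset, %d parameters, H = %d, heads %d/%d>\n",
              x$config$preset, np, x$config$feature_dim,
              x$config$n_known, x$config$n_novel))
  invisible(x)
}

#' Forward pass through the encoder and both heads
#'
#' @param model a [build_model()] result.
#' @param x window batch: array `(channels, window_len, n)` or a single
#'   `(channels, window_len)` matrix.
#' @param keep_cache retain the activations needed for a subsequent
#'   [model_backward()] call (training); `FALSE` for pure inference.
#' @return list with `z` (n x H), `logits_l` (n x C_l), `logits_u`
#'   (n x C_u).
#' @export
model_forward <- function(model, x, keep_cache = FALSE) {
  stopifnot(inherits(model, "model_state"))
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  cfg <- model$config
  if (dim(x)[1] != cfg$n_channels || dim(x)[2] != cfg$window_len)
    stop(sprintf("shape mismatch: expected (%d, %d, n), got (%d, %d, %d)",
                 cfg$n_channels, cfg$window_len, dim(x)[1], dim(x)[2], dim(x)[3]))
  enc_forward(model$params, x, cfg$conv_strides, keep_cache)
}

#' Backward pass: parameter gradients from upstream output gradients
#'
#' Must follow a `model_forward(..., keep_cache = TRUE)` call on the same
#' batch. The upstream gradients are with respect to the forward outputs
#' (`z`, `logits_l`, `logits_u`), each in batch-rows orientation.
#'
#' @param model a [build_model()] result.
#' @param dz gradient on z (n x H).
#' @param dlogits_l gradient on the labeled head output (n x C_l).
#' @param dlogits_u gradient on the unlabeled head output (n x C_u).
#' @return named list of gradients matching `model$params`.
#' @export
model_backward <- function(model, dz, dlogits_l, dlogits_u) {
  enc_backward(model$params, model$config$conv_strides,
               dz, dlogits_l, dlogits_u)
}

#' Save and restore model checkpoints
#'
#' The checkpoint is a flat named-parameter container with the
#' architecture configuration embedded, written as a single RDS file.
#'
#' @param model a `model_state`.
#' @param file checkpoint path.
#' @return `file` (save) / the restored `model_state` (load).
#' @export
save_checkpoint <- function(model, file) {
  stopifnot(inherits(model, "model_state"))
  saveRDS(list(config = unclass(model$config), params = model$params), file)
  invisible(file)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(file) {
  obj <- readRDS(file)
  structure(list(config = structure(obj$config, class = "encoder_config"),
                 params = obj$params),
            class = "model_state")
}
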