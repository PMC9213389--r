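#' Configuration of one member CNN
#'
#' The member network is a small 3D residual CNN: three blocks whose main
#' branch is a strided 3x3x3 convolution (16, 32, then 64 filters) followed
#' by a stride-1 3x3x3 convolution, and whose shortcut branch is a single
#' 1-filter strided 3x3x3 convolution added (broadcast across channels) to
#' the main branch. Spatial sizes follow 50 -> 25 -> 13 -> 7 with ceil-mode
#' same padding. Block 3 is followed by global average pooling to a
#' 64-vector, dropout, and a single logistic output unit scoring 0 = benign,
#' 1 = premalignant.
#'
#' @param in_channels 1 (image only, noSEG) or 2 (image + mask, SEG).
#' @param block_filters Filters per block; only the reference `(16, 32, 64)`
#'   configuration is implemented.
#' @param dropout_rate Dropout probability on the pooled 64-vector during
#'   training (default 0.5).
#' @param activation Elementwise nonlinearity; only `"relu"` is implemented.
#' @return A `network_config` object.
#' @export
network_config <- function(in_channels = 1, block_filters = c(16, 32, 64),
                           dropout_rate = 0.5, activation = "relu") {
  if (!in_channels %in% c(1, 2)) abort("`in_channels` must be 1 or 2")
  if (!identical(as.numeric(block_filters), c(16, 32, 64)))
    abort("only the reference block filter configuration (16, 32, 64) is implemented")
  if (any(diff(block_filters) <= 0))
    abort("`block_filters` must be strictly increasing")
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort("`dropout_rate` must lie in [0, 1)")
  if (!identical(activation, "relu"))
    abort("only the rectifier activation is implemented")
  structure(list(in_channels = as.integer(in_channels),
                 block_filters = as.integer(block_filters),
                 dropout_rate = dropout_rate, activation = activation),
            class = "network_config")
}

# Spatial side lengths through the three strided blocks (ceil mode).
network_shapes <- function(input_side = 50) {
  s <- input_side
  sides <- c(s, ceiling(s / 2), ceiling(s / 4), ceiling(s / 8))
  list(sides = sides, pooled = 64L)
}

#' Build an (untrained) member network
#'
#' Initialises weights (He-normal for the rectifier convolutions) from
#' `seed` and asserts the reference spatial-size sequence
#' 50 -> 25 -> 13 -> 7 with a pooled width of 64.
#'
#' @param config A [network_config()].
#' @param seed Integer weight-initialisation seed.
#' @return A `member_network` object.
#' @export
build_member <- function(config = network_config(), seed = 1) {
  stopifnot(inherits(config, "network_config"))
  shp <- network_shapes(50)
  stopifnot(identical(shp$sides, c(50, 25, 13, 7)), shp$pooled == 64L)
  weights <- cpp_init_weights(config$in_channels, as.integer(seed))
  structure(list(config = config, weights = weights, trained = FALSE,
                 history = NULL, seeds = list(init = as.integer(seed))),
            class = "member_network")
}

#' Forward pass of a member network
#'
#' Maps model inputs to scores in `[0, 1]`. In evaluation mode (the default)
#' dropout is disabled and the pass is deterministic; in training mode
#' dropout draws come from `seed`.
#'
#' @param net A `member_network`.
#' @param input A `model_input`, a `(50, 50, 50, C)` array, a
#'   `(50, 50, 50, C, N)` batch, or a `model_dataset`.
#' @param training Enable dropout (training mode).
#' @param seed Dropout seed for training mode.
#' @return Numeric vector of scores in `[0, 1]`, one per input.
#' @export
forward <- function(net, input, training = FALSE, seed = 0) {
  stopifnot(inherits(net, "member_network"))
  x <- as_input_batch(input)
  if (dim(x)[4] != net$config$in_channels)
    abort(sprintf("input has %d channel(s) but this %s network expects %d",
                  dim(x)[4],
                  if (net$config$in_channels == 2) "SEG" else "noSEG",
                  net$config$in_channels))
  out <- cpp_forward(net$weights, x, training = training,
                     dropout = net$config$dropout_rate,
                     seed = as.integer(seed))
  out$scores
}

#' @export
predict.member_network <- function(object, newdata, ...) {
  forward(object, newdata, ...)
}

# Coerce a single input / batch / dataset to a (D, D, D, C, N) array.
as_input_batch <- function(input) {
  if (inherits(input, "model_dataset")) return(input$x)
  x <- unclass(input)
  nd <- length(dim(x))
  if (nd == 3) dim(x) <- c(dim(x), 1L, 1L)
  else if (nd == 4) dim(x) <- c(dim(x), 1L)
  else if (nd != 5) abort("expected a 3D/4D input or a 5D batch array")
  x
}

#' Number of trainable parameters of a member network
#'
#' @param net A `member_network`.
#' @return Integer parameter count.
#' @export
member_parameter_count <- function(net) {
  sum(vapply(net$weights, length, numeric(1)))
}

#' @export
print.member_network <- function(x, ...) {
  cat(sprintf(
    "<member_network> %d-channel input (%s), %s, %d parameters\n",
    x$config$in_channels,
    if (x$config$in_channels == 2) "SEG" else "noSEG",
    if (x$trained) sprintf("trained (%d epochs, best val AUC %.3f)",
                           nrow(x$history), max(x$history$val_auc))
    else "untrained",
    member_parameter_count(x)))
  invisible(x)
}
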