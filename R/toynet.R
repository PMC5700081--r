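#' Specify a deterministic toy convolutional network
#'
#' A small, seeded stand-in for a large pretrained classification network:
#' it exposes named layer activations and exact input gradients, which is
#' all the dream engine requires of a model. The default architecture is
#' three convolution + rectifier blocks (3 -> 8 -> 16 -> 16 channels, 3x3
#' kernels, stride 1, same padding) with weights drawn uniformly on
#' \eqn{[-0.5, 0.5] \cdot \mathrm{fan}_{in}^{-1/2}} and zero biases --
#' small enough that 64x64 frames dream in seconds, yet deep enough that
#' shallow and deep layers produce visibly different dream textures.
#'
#' @param layer_defs Ordered list of layer definitions. Each element is a
#'   list with `id` (unique string) and `type` (`"conv"`, `"relu"` or
#'   `"pool"`); conv layers also take `kernel` (odd size, default 3) and
#'   `out_channels`. `"pool"` is 2x2 max pooling (stride 2).
#' @param in_channels Channels of the input image (default 3).
#' @param seed Integer seed; identical seeds give bit-identical weights.
#' @param padding `"circular"` (periodic; shift-equivariant, pairs with
#'   equirectangular wrap) or `"zero"`.
#' @param weight_scale Half-width multiplier for the uniform weight
#'   initializer; a conv layer draws from
#'   `[-weight_scale, weight_scale] / sqrt(kernel^2 * in_channels)`.
#' @return A `toy_net_spec` list.
#' @export
toy_net_spec <- function(layer_defs = NULL, in_channels = 3L, seed = 1L,
                         padding = c("circular", "zero"),
                         weight_scale = 0.5) {
  padding <- match.arg(padding)
  if (is.null(layer_defs)) {
    layer_defs <- list(
      list(id = "conv1", type = "conv", kernel = 3L, out_channels = 8L),
      list(id = "relu1", type = "relu"),
      list(id = "conv2", type = "conv", kernel = 3L, out_channels = 16L),
      list(id = "relu2", type = "relu"),
      list(id = "conv3", type = "conv", kernel = 3L, out_channels = 16L),
      list(id = "relu3", type = "relu")
    )
  }
  ids <- vapply(layer_defs, function(l) l$id, character(1))
  if (anyDuplicated(ids)) stop("layer ids must be unique", call. = FALSE)
  for (l in layer_defs) {
    if (!l$type %in% c("conv", "relu", "pool")) {
      stop("unknown layer operation: ", l$type, call. = FALSE)
    }
  }
  structure(
    list(layer_defs = layer_defs, in_channels = as.integer(in_channels),
         seed = as.integer(seed), padding = padding,
         weight_scale = weight_scale),
    class = "toy_net_spec"
  )
}

#' Build the toy network from its specification
#'
#' Materializes weights deterministically from `spec$seed` (the caller's
#' RNG stream is untouched). The returned object satisfies the layer-
#' activation-model contract used by [dream_image()]: forward activations
#' at any named layer via [toy_net_forward()] and input gradients via
#' [input_gradient()].
#'
#' @param spec A [toy_net_spec()].
#' @return A `toy_net` object.
#' @export
build_toy_net <- function(spec) {
  stopifnot(inherits(spec, "toy_net_spec"))
  layers <- with_seed(spec$seed, {
    cin <- spec$in_channels
    lapply(spec$layer_defs, function(l) {
      if (l$type == "conv") {
        k <- as.integer(l$kernel %||% 3L)
        if (k %% 2L == 0L) stop("conv kernel size must be odd", call. = FALSE)
        cout <- as.integer(l$out_channels)
        a <- spec$weight_scale / sqrt(k * k * cin)
        w <- array(runif(k * k * cin * cout, -a, a), dim = c(k, k, cin, cout))
        lay <- list(id = l$id, type = "conv", w = w, bias = numeric(cout),
                    in_channels = cin, out_channels = cout)
        cin <<- cout
        lay
      } else {
        list(id = l$id, type = l$type, channels = cin)
      }
    })
  })
  structure(
    list(spec = spec, layers = layers,
         layer_ids = vapply(layers, `[[`, character(1), "id"),
         pad_mode = if (spec$padding == "circular") 1L else 0L),
    class = "toy_net"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.toy_net <- function(x, ...) {
  cat("<toy_net>", length(x$layers), "layers, padding:", x$spec$padding,
      ", seed:", x$spec$seed, "\n")
  for (l in x$layers) {
    if (l$type == "conv") {
      cat(sprintf("  %-8s conv %dx%d  %d -> %d\n", l$id, dim(l$w)[1],
                  dim(l$w)[2], l$in_channels, l$out_channels))
    } else {
      cat(sprintf("  %-8s %s\n", l$id, l$type))
    }
  }
  invisible(x)
}

layer_index <- function(model, layer_id) {
  i <- match(layer_id, model$layer_ids)
  if (is.na(i)) {
    stop("unknown layer id '", layer_id, "'; available: ",
         paste(model$layer_ids, collapse = ", "), call. = FALSE)
  }
  i
}

#' Forward pass of the toy network
#'
#' @param model A `toy_net` from [build_toy_net()].
#' @param image Input image (`H x W x in_channels` numeric array).
#' @param layer_id Stop after this layer (default: run all layers).
#' @return Named list of activation arrays, one per executed layer, in
#'   order.
#' @export
toy_net_forward <- function(model, image, layer_id = NULL) {
  stopifnot(inherits(model, "toy_net"))
  as_image(image, channels = model$spec$in_channels)
  upto <- if (is.null(layer_id)) length(model$layers) else layer_index(model, layer_id)
  acts <- vector("list", upto)
  cur <- image
  for (i in seq_len(upto)) {
    l <- model$layers[[i]]
    cur <- switch(l$type,
      conv = conv2d_forward_cpp(cur, dim(cur), l$w, dim(l$w), l$bias, model$pad_mode),
      relu = pmax(cur, 0),
      pool = maxpool_forward(cur)
    )
    acts[[i]] <- cur
  }
  names(acts) <- model$layer_ids[seq_len(upto)]
  if (!all(is.finite(acts[[upto]]))) {
    stop("non-finite activations at layer '", model$layer_ids[upto], "'",
         call. = FALSE)
  }
  acts
}

maxpool_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L
  w2 <- d[2] %/% 2L
  if (h2 < 1L || w2 < 1L) stop("input too small for 2x2 max pooling", call. = FALSE)
  a <- x[seq_len(2L * h2), seq_len(2L * w2), , drop = FALSE]
  pmax(a[c(TRUE, FALSE), c(TRUE, FALSE), , drop = FALSE],
       a[c(FALSE, TRUE), c(TRUE, FALSE), , drop = FALSE],
       a[c(TRUE, FALSE), c(FALSE, TRUE), , drop = FALSE],
       a[c(FALSE, TRUE), c(FALSE, TRUE), , drop = FALSE])
}

# Route pooled gradient back to the first position attaining each max
# (ties are measure-zero under random weights).
maxpool_backward <- function(grad_out, x) {
  d <- dim(x)
  h2 <- dim(grad_out)[1]
  w2 <- dim(grad_out)[2]
  gin <- array(0, dim = d)
  pooled <- maxpool_forward(x)
  for (oy in 0:1) {
    for (ox in 0:1) {
      ys <- seq(1L + oy, 2L * h2, by = 2L)
      xs <- seq(1L + ox, 2L * w2, by = 2L)
      hit <- (x[ys, xs, , drop = FALSE] == pooled)
      hit[is.na(hit)] <- FALSE
      gin[ys, xs, ] <- gin[ys, xs, , drop = FALSE] + grad_out * hit
      pooled[hit] <- NA  # first match wins
    }
  }
  gin
}

#' Layer activations of a model
#'
#' Generic entry point of the layer-activation-model contract used by the
#' dream engine; the bundled implementation is the toy network
#' ([toy_net_forward()]), and adapters for external pretrained networks
#' can register their own methods.
#'
#' @inheritParams toy_net_forward
#' @return Named list of activation arrays up to `layer_id`.
#' @export
model_activations <- function(model, image, layer_id = NULL) {
  UseMethod("model_activations")
}

#' @export
model_activations.toy_net <- function(model, image, layer_id = NULL) {
  toy_net_forward(model, image, layer_id)
}

#' Gradient of the dream objective with respect to the input image
#'
#' Backpropagates through the (weight-frozen) network from `layer_id`,
#' seeding with the derivative of the dream objective -- half the sum of
#' squared activations, optionally restricted to one channel for guided
#' dreams -- so the returned array is the exact pixel-wise gradient of
#' [dream_objective()]. Generic, with a method for the toy network.
#'
#' @inheritParams toy_net_forward
#' @param layer_id Layer whose activation is clamped (required).
#' @param channel Optional single channel index for a guided objective;
#'   `NULL` (default) uses the full layer.
#' @return Gradient array with the shape of `image`.
#' @export
input_gradient <- function(model, image, layer_id, channel = NULL) {
  UseMethod("input_gradient")
}

#' @export
input_gradient.toy_net <- function(model, image, layer_id, channel = NULL) {
  acts <- toy_net_forward(model, image, layer_id)
  upto <- length(acts)
  grad <- acts[[upto]]
  if (!is.null(channel)) {
    mask <- array(0, dim = dim(grad))
    mask[, , channel] <- grad[, , channel]
    grad <- mask
  }
  inputs <- c(list(image), acts[-upto])
  for (i in rev(seq_len(upto))) {
    l <- model$layers[[i]]
    grad <- switch(l$type,
      conv = conv2d_backward_cpp(grad, dim(grad), l$w, dim(l$w), model$pad_mode),
      relu = grad * (inputs[[i]] > 0),
      pool = maxpool_backward(grad, inputs[[i]])
    )
  }
  if (!all(is.finite(grad))) stop("non-finite input gradient", call. = FALSE)
  grad
}
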