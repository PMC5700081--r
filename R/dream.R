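#' Dream engine configuration
#'
#' Bundles every parameter of the multi-octave gradient-ascent loop. The
#' defaults are the parameter set used to generate the high-level
#' hallucination videos in the source experiments: octaves = 3, octave
#' scale = 1.8, iterations = 32, jitter = 32, zoom = 1, step size = 1.5.
#'
#' @param layer_id Network layer whose activation is clamped (maximized).
#' @param octaves Number of pyramid levels (>= 1).
#' @param octave_scale Downscaling ratio between levels (> 1).
#' @param iterations Ascent steps per octave (>= 0).
#' @param jitter Maximum cyclic pixel shift drawn before each step (>= 0).
#' @param zoom Per-frame centre zoom factor (1 disables).
#' @param step_size Ascent magnitude after gradient normalization (>= 0).
#' @param seed Integer seed controlling the jitter stream.
#' @param channel Optional channel index for a guided (single-channel)
#'   objective; `NULL` clamps the full layer.
#' @return A `dream_config` list.
#' @export
dream_config <- function(layer_id, octaves = 3L, octave_scale = 1.8,
                         iterations = 32L, jitter = 32L, zoom = 1,
                         step_size = 1.5, seed = 0L, channel = NULL) {
  stopifnot(octaves >= 1, octave_scale > 1, iterations >= 0, jitter >= 0,
            zoom >= 1, step_size >= 0)
  structure(
    list(layer_id = layer_id, octaves = as.integer(octaves),
         octave_scale = octave_scale, iterations = as.integer(iterations),
         jitter = as.integer(jitter), zoom = zoom, step_size = step_size,
         seed = as.integer(seed), channel = channel),
    class = "dream_config"
  )
}

#' Map a named preset to a toy-network layer
#'
#' The source pipeline selected one of three layers of its pretrained
#' network to control the style of hallucination: a deep layer for
#' complex, object-like content, a middle layer for object parts, and a
#' shallow layer for geometric textures. For the bundled toy network the
#' presets map to the deepest, middle and shallowest rectifier layers.
#'
#' @param preset One of `"higher"`, `"middle"`, `"lower"`.
#' @param model A `toy_net`.
#' @return A layer id string.
#' @export
dream_preset_layer <- function(preset = c("higher", "middle", "lower"), model) {
  preset <- match.arg(preset)
  relus <- model$layer_ids[vapply(model$layers, function(l) l$type == "relu",
                                  logical(1))]
  if (length(relus) < 3L) relus <- model$layer_ids
  switch(preset,
         higher = relus[length(relus)],
         middle = relus[ceiling(length(relus) / 2)],
         lower = relus[1L])
}

#' Dream objective: half the sum of squared layer activations
#'
#' Maximizing this "amplifies what the layer already detects"; its
#' gradient with respect to the activations is the activation tensor
#' itself, which seeds the backward pass in [input_gradient()].
#'
#' @param activations Activation array of the clamped layer.
#' @param channel Optional single channel to restrict the objective to.
#' @return Non-negative scalar.
#' @export
dream_objective <- function(activations, channel = NULL) {
  if (length(activations) == 0) stop("empty activation tensor", call. = FALSE)
  if (!is.null(channel)) activations <- activations[, , channel]
  0.5 * sum(activations^2)
}

#' Octave pyramid sizes
#'
#' Sizes ascend from coarsest to the base resolution:
#' `size_k = round(base / octave_scale^k)` with round-half-away-from-zero,
#' and the last entry equals the base size exactly.
#'
#' @param base_hw Integer vector `c(height, width)`.
#' @param octaves Number of levels.
#' @param octave_scale Ratio between successive levels.
#' @return List of `c(height, width)` pairs, smallest first.
#' @export
octave_sizes <- function(base_hw, octaves, octave_scale) {
  stopifnot(length(base_hw) == 2, octaves >= 1, octave_scale > 1)
  rhaz <- function(x) floor(x + 0.5)  # positive inputs only
  sizes <- lapply(rev(seq_len(octaves) - 1L), function(k) {
    as.integer(rhaz(base_hw / octave_scale^k))
  })
  sizes[[octaves]] <- as.integer(base_hw)
  for (s in sizes) {
    if (any(s < 8L)) {
      stop("octave size ", paste(s, collapse = "x"),
           " below the 8 px minimum; reduce octaves or octave_scale",
           call. = FALSE)
    }
  }
  sizes
}

#' One gradient-ascent step on the image
#'
#' Draws a cyclic jitter shift uniform on `[-jitter, jitter]^2` from the
#' current RNG stream, shifts the image, adds
#' `step_size * g / mean(|g|)` where `g` is the input gradient of the
#' dream objective, undoes the shift and clamps to \[0, 255\]. A
#' gradient that is zero everywhere returns the input unchanged.
#'
#' @param image Input image.
#' @param model Layer-activation model (e.g. a `toy_net`).
#' @param layer_id Clamped layer.
#' @param step_size Ascent magnitude (>= 0).
#' @param jitter Maximum shift in pixels (>= 0).
#' @param channel Optional guided-objective channel.
#' @return Updated image, same shape, clamped to the working range.
#' @export
ascent_step <- function(image, model, layer_id, step_size = 1.5, jitter = 32L,
                        channel = NULL) {
  stopifnot(step_size >= 0, jitter >= 0)
  jitter <- min(as.integer(jitter), dim(image)[1] - 1L, dim(image)[2] - 1L)
  shift <- if (jitter > 0) sample(seq.int(-jitter, jitter), 2, replace = TRUE) else c(0L, 0L)
  x <- roll_image(image, shift[1], shift[2])
  g <- input_gradient(model, x, layer_id, channel = channel)
  gm <- mean(abs(g))
  if (gm > 0 && step_size > 0) x <- x + step_size * g / gm
  x <- roll_image(x, -shift[1], -shift[2])
  clamp_image(x)
}

#' Deep-dream a single image
#'
#' The classic octave loop: a detail buffer (initially zero) carries
#' dreamed structure up the pyramid. For each octave size, ascending, the
#' base image is resized to that size, the upsampled detail is added, and
#' `iterations` ascent steps are run; the octave's detail is the result
#' minus the resized base. Deterministic given `config$seed` (the
#' caller's RNG stream is untouched).
#'
#' @param image Input image (`H x W x 3`, working range \[0, 255\]).
#' @param model Layer-activation model.
#' @param config A [dream_config()].
#' @return Dreamed image, same size as the input.
#' @export
dream_image <- function(image, model, config) {
  stopifnot(inherits(config, "dream_config"))
  as_image(image)
  sizes <- octave_sizes(dim(image)[1:2], config$octaves, config$octave_scale)
  with_seed(config$seed, {
    detail <- array(0, dim = c(sizes[[1]], dim(image)[3]))
    out <- image
    for (s in sizes) {
      base <- resize_image(image, s[1], s[2])
      detail <- resize_image(detail, s[1], s[2])
      out <- clamp_image(base + detail)
      for (i in seq_len(config$iterations)) {
        out <- ascent_step(out, model, config$layer_id,
                           step_size = config$step_size,
                           jitter = config$jitter, channel = config$channel)
      }
      detail <- out - base
    }
    out
  })
}

#' Centre zoom
#'
#' Crops the central `1/zoom` extent and resizes back to the original
#' size (the dream-zoom effect of video dreaming; `zoom = 1` is the exact
#' identity).
#'
#' @param image Input image.
#' @param zoom Zoom factor (>= 1).
#' @return Image of the original size.
#' @export
apply_zoom <- function(image, zoom) {
  stopifnot(zoom >= 1)
  if (zoom == 1) return(image)
  d <- dim(image)
  ch <- floor(d[1] / zoom)
  cw <- floor(d[2] / zoom)
  if (ch < 2 || cw < 2) stop("zoom crop smaller than 2 px", call. = FALSE)
  y0 <- floor((d[1] - ch) / 2) + 1L
  x0 <- floor((d[2] - cw) / 2) + 1L
  crop <- image[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), , drop = FALSE]
  resize_image(crop, d[1], d[2])
}
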