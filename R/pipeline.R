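#' Video pipeline configuration
#'
#' Combines the dream and coherence configurations with panoramic
#' (equirectangular) handling and frame metadata. The source footage was
#' panoramic video at 16 fps, 4096 x 2048; frame rate and resolution are
#' carried as metadata only (processing is resolution-agnostic).
#'
#' @param dream A [dream_config()].
#' @param coherence A [coherence_config()].
#' @param equirect Treat frames as equirectangular: wrap-pad the vertical
#'   seam before dreaming and wrap flow/warp horizontally. Vertical edges
#'   are never wrapped (top/bottom are poles).
#' @param wrap_pad Columns of cyclic padding at each side when
#'   `equirect = TRUE` (default 16).
#' @param frame_rate Frames per second, metadata (default 16).
#' @param seed Master seed; each frame dreams under
#'   `frame_seed(seed, index)` so frames may be processed concurrently
#'   without reordering randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dream, coherence = coherence_config(),
                            equirect = FALSE, wrap_pad = 16L,
                            frame_rate = 16, seed = 0L) {
  stopifnot(inherits(dream, "dream_config"),
            inherits(coherence, "coherence_config"),
            wrap_pad >= 0, frame_rate > 0)
  structure(
    list(dream = dream, coherence = coherence, equirect = isTRUE(equirect),
         wrap_pad = as.integer(wrap_pad), frame_rate = frame_rate,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Deterministic per-frame seed
#'
#' Mixes the master seed with the frame index into a 31-bit seed, so the
#' randomness of frame `t` does not depend on how many frames were
#' processed before it.
#'
#' @param seed Master integer seed.
#' @param index Frame index (1-based).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
frame_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  for (k in c(as.double(index), 2654435769)) {
    s <- (s * 48271 + k) %% m
  }
  as.integer(s %% (m - 1)) + 1L
}

#' Equirectangular seam padding
#'
#' Copies `pad` columns cyclically onto the left and right edges so the
#' dream operates across the panoramic seam; [equirect_unpad()] crops
#' them back (`equirect_unpad(equirect_pad(x, p), p)` is the exact
#' identity). Vertical edges are untouched.
#'
#' @param image Image or matrix.
#' @param pad Columns to copy (0 <= pad < width / 2).
#' @return Padded (width + 2 pad) or cropped image.
#' @export
equirect_pad <- function(image, pad) {
  w <- dim(image)[2]
  if (pad >= w / 2) stop("pad must be smaller than half the width", call. = FALSE)
  if (pad == 0) return(image)
  idx <- c((w - pad + 1L):w, 1:w, 1:pad)
  if (length(dim(image)) == 2L) image[, idx, drop = FALSE] else image[, idx, , drop = FALSE]
}

#' @rdname equirect_pad
#' @export
equirect_unpad <- function(image, pad) {
  if (pad == 0) return(image)
  w <- dim(image)[2]
  if (2 * pad >= w) stop("pad larger than padded width", call. = FALSE)
  idx <- (pad + 1L):(w - pad)
  if (length(dim(image)) == 2L) image[, idx, drop = FALSE] else image[, idx, , drop = FALSE]
}

#' Process a video frame-by-frame with temporal coherence
#'
#' Frame 1 is dreamed directly. For every later frame `t`: estimate the
#' optical flow from raw frame `t - 1` to raw frame `t`, warp the
#' previous dreamed frame along it, build the flow-dependent blend-ratio
#' map, convexly blend the warped hallucinatory content into the raw
#' frame, apply the centre zoom (when `zoom > 1`), and dream the result
#' under the frame's own seed. In `"residual"` mode the warped quantity
#' is the previous dreamed-minus-raw residual added onto the raw frame
#' before dreaming.
#'
#' @param frames List of equally sized `H x W x 3` frames on \[0, 255\],
#'   or a directory path accepted by [read_frames()].
#' @param model Layer-activation model (e.g. [build_toy_net()]).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory: dreamed frames are written as a
#'   PNG sequence plus a `manifest.json` sufficient to re-run the job
#'   bit-identically.
#' @param verbose Print per-frame progress.
#' @return Invisible list with `frames` (dreamed frames) and `manifest`
#'   (config echo, per-frame seeds, objective values and timings).
#' @export
process_video <- function(frames, model, config, output_dir = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(frames)) frames <- read_frames(frames)
  n <- length(frames)
  if (n < 1) stop("no frames to process", call. = FALSE)
  d0 <- dim(frames[[1]])
  for (t in seq_len(n)) {
    if (!identical(dim(frames[[t]]), d0)) {
      stop("frame size changed at frame ", t, call. = FALSE)
    }
  }
  pad <- if (config$equirect) config$wrap_pad else 0L
  dreamed <- vector("list", n)
  seeds <- integer(n)
  objective <- numeric(n)
  elapsed <- numeric(n)
  dream_one <- function(img, seed) {
    cfg <- config$dream
    cfg$seed <- seed
    if (cfg$zoom > 1) img <- apply_zoom(img, cfg$zoom)
    if (pad > 0) img <- equirect_pad(img, pad)
    out <- dream_image(img, model, cfg)
    if (pad > 0) out <- equirect_unpad(out, pad)
    out
  }
  for (t in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    seeds[t] <- frame_seed(config$seed, t)
    if (t == 1L) {
      input <- frames[[1]]
    } else {
      flow <- estimate_flow(frames[[t - 1L]], frames[[t]], config$coherence)
      rmap <- flow_ratio_map(flow, config$coherence)
      if (config$coherence$mode == "frame") {
        warped <- warp_by_flow(dreamed[[t - 1L]], flow, wrap_x = config$equirect)
        input <- blend_frames(frames[[t]], warped, rmap)
      } else {
        resid <- dreamed[[t - 1L]] - frames[[t - 1L]]
        warped <- warp_by_flow(resid, flow, wrap_x = config$equirect)
        input <- frames[[t]]
        for (c in seq_len(d0[3])) {
          input[, , c] <- input[, , c] + rmap * warped[, , c]
        }
        input <- clamp_image(input)
      }
    }
    dreamed[[t]] <- dream_one(input, seeds[t])
    acts <- model_activations(model, dreamed[[t]], config$dream$layer_id)
    objective[t] <- dream_objective(acts[[length(acts)]], config$dream$channel)
    elapsed[t] <- proc.time()[["elapsed"]] - t0
    if (verbose) {
      message(sprintf("frame %d/%d  seed=%d  objective=%.4g  %.2fs",
                      t, n, seeds[t], objective[t], elapsed[t]))
    }
  }
  manifest <- list(
    package = "deepdreamr",
    n_frames = n,
    frame_height = d0[1], frame_width = d0[2],
    frame_rate = config$frame_rate,
    equirect = config$equirect, wrap_pad = config$wrap_pad,
    seed = config$seed,
    dream = unclass(config$dream),
    coherence = unclass(config$coherence),
    frame_seeds = seeds,
    frame_objective = objective,
    frame_seconds = round(elapsed, 4)
  )
  if (!is.null(output_dir)) {
    write_frames(output_dir, dreamed)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(frames = dreamed, manifest = manifest))
}

#' Read a PNG frame sequence
#'
#' Frames are read in lexicographic filename order, converted from 8-bit
#' to the \[0, 255\] working range, and must share one size.
#'
#' @param path Directory containing `.png` frames.
#' @return List of `H x W x 3` arrays.
#' @export
read_frames <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no frames found in ", path, call. = FALSE)
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- tryCatch(png::readPNG(files[i]),
                    error = function(e) stop("unreadable frame ", i, " (",
                                             basename(files[i]), "): ",
                                             conditionMessage(e), call. = FALSE))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    frames[[i]] <- img * 255
    if (i > 1L && !identical(dim(frames[[i]]), dim(frames[[1]]))) {
      stop("frame ", i, " (", basename(files[i]), ") has mismatched size",
           call. = FALSE)
    }
  }
  frames
}

#' Write a PNG frame sequence
#'
#' Frames are quantized to 8 bits and written as `frame_000001.png`,
#' `frame_000002.png`, ... so a later [read_frames()] returns them in
#' order.
#'
#' @param path Output directory (created if missing).
#' @param frames List of images on the \[0, 255\] working range.
#' @export
write_frames <- function(path, frames) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(clamp_image(frames[[i]]) / 255,
                  file.path(path, sprintf("frame_%06d.png", i)))
  }
  invisible(path)
}
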