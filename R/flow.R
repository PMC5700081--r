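#' Temporal-coherence configuration
#'
#' Parameters of the frame-to-frame inheritance stage: hallucinatory
#' content from the previous dreamed frame is warped along the estimated
#' optical flow and convexly blended into the current raw frame, with a
#' high blend weight where the scene moves (foreground) and a low weight
#' where it is static (background) to avoid saturating static areas.
#' Defaults follow the source pipeline: 0.9 foreground, 0.1 background.
#'
#' @param fg_ratio Blend weight where flow magnitude exceeds
#'   `flow_threshold` (default 0.9).
#' @param bg_ratio Blend weight elsewhere (default 0.1).
#' @param flow_threshold Flow magnitude (pixels) separating the two
#'   regimes (default 1.0).
#' @param pyramid_levels,window_sigma,iters_per_level Settings of the
#'   coarse-to-fine Lucas-Kanade flow estimator: pyramid depth, Gaussian
#'   window scale (pixels) of the local least-squares fit, and warp/solve
#'   refinements per level.
#' @param mode `"frame"` carries the full previous dreamed frame
#'   (default); `"residual"` carries only the dreamed-minus-raw residual.
#' @return A `coherence_config` list.
#' @export
coherence_config <- function(fg_ratio = 0.9, bg_ratio = 0.1,
                             flow_threshold = 1.0, pyramid_levels = 3L,
                             window_sigma = 3, iters_per_level = 3L,
                             mode = c("frame", "residual")) {
  stopifnot(fg_ratio >= 0, fg_ratio <= 1, bg_ratio >= 0, bg_ratio <= 1,
            flow_threshold >= 0, pyramid_levels >= 1, window_sigma > 0,
            iters_per_level >= 1)
  structure(
    list(fg_ratio = fg_ratio, bg_ratio = bg_ratio,
         flow_threshold = flow_threshold,
         pyramid_levels = as.integer(pyramid_levels),
         window_sigma = window_sigma,
         iters_per_level = as.integer(iters_per_level),
         mode = match.arg(mode)),
    class = "coherence_config"
  )
}

#' Dense optical flow between two frames
#'
#' Coarse-to-fine (pyramidal) Lucas-Kanade estimation on the greyscale
#' images: at each pyramid level the current estimate warps the second
#' frame back onto the first, and per-pixel displacement increments are
#' solved from the Gaussian-windowed structure tensor. Deterministic for
#' fixed inputs and settings.
#'
#' The returned field is the displacement previous -> current: content at
#' pixel `p` of `prev` appears at `p + flow(p)` in `cur`.
#'
#' @param prev,cur Frames of identical size (`H x W x C` or matrices).
#' @param config A [coherence_config()].
#' @return `H x W x 2` array; `[, , 1]` is the x (column) displacement
#'   `u`, `[, , 2]` the y (row) displacement `v`, in pixels.
#' @export
estimate_flow <- function(prev, cur, config = coherence_config()) {
  if (!identical(dim(prev)[1:2], dim(cur)[1:2])) {
    stop("frames must have identical dimensions", call. = FALSE)
  }
  g1 <- to_gray(prev)
  g2 <- to_gray(cur)
  # pyramid: level 1 = full resolution
  pyr1 <- list(g1)
  pyr2 <- list(g2)
  lv <- 1L
  while (lv < config$pyramid_levels && all(dim(pyr1[[lv]]) >= 16L)) {
    h2 <- ceiling(dim(pyr1[[lv]])[1] / 2)
    w2 <- ceiling(dim(pyr1[[lv]])[2] / 2)
    pyr1[[lv + 1L]] <- resize_image(gaussian_blur_cpp(pyr1[[lv]], 1), h2, w2)
    pyr2[[lv + 1L]] <- resize_image(gaussian_blur_cpp(pyr2[[lv]], 1), h2, w2)
    lv <- lv + 1L
  }
  u <- matrix(0, nrow(pyr1[[lv]]), ncol(pyr1[[lv]]))
  v <- matrix(0, nrow(pyr1[[lv]]), ncol(pyr1[[lv]]))
  eps <- 1e-4
  for (l in rev(seq_len(lv))) {
    h <- nrow(pyr1[[l]])
    w <- ncol(pyr1[[l]])
    if (!identical(dim(u), c(h, w))) {
      scale_y <- h / nrow(u)
      scale_x <- w / ncol(u)
      u <- resize_image(u, h, w) * scale_x
      v <- resize_image(v, h, w) * scale_y
    }
    f1 <- pyr1[[l]]
    f2 <- pyr2[[l]]
    for (it in seq_len(config$iters_per_level)) {
      warped <- warp_by_flow(f2, flow_stack(-u, -v))  # sample f2 at p + flow
      ix <- central_diff_x((f1 + warped) / 2)
      iy <- central_diff_y((f1 + warped) / 2)
      it_ <- warped - f1
      s <- config$window_sigma
      axx <- gaussian_blur_cpp(ix * ix, s)
      axy <- gaussian_blur_cpp(ix * iy, s)
      ayy <- gaussian_blur_cpp(iy * iy, s)
      bx <- gaussian_blur_cpp(ix * it_, s)
      by <- gaussian_blur_cpp(iy * it_, s)
      det <- axx * ayy - axy * axy + eps
      du <- (axy * by - ayy * bx) / det
      dv <- (axy * bx - axx * by) / det
      # limit per-iteration updates to keep the linearization honest
      du <- pmin(pmax(du, -2), 2)
      dv <- pmin(pmax(dv, -2), 2)
      u <- u + du
      v <- v + dv
    }
  }
  flow_stack(u, v)
}

flow_stack <- function(u, v) {
  f <- array(0, dim = c(dim(u), 2L))
  f[, , 1] <- u
  f[, , 2] <- v
  f
}

central_diff_x <- function(m) {
  w <- ncol(m)
  (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
}

central_diff_y <- function(m) {
  h <- nrow(m)
  (m[c(2:h, h), ] - m[c(1, 1:(h - 1)), ]) / 2
}

#' Per-pixel flow magnitude
#' @param flow `H x W x 2` displacement field.
#' @return `H x W` matrix of Euclidean magnitudes.
#' @export
flow_magnitude <- function(flow) {
  sqrt(flow[, , 1]^2 + flow[, , 2]^2)
}

#' Warp an image backwards along a flow field
#'
#' `out(p) = image(p - flow(p))` with bilinear sampling, so that warping
#' the previous frame by the previous -> current flow transports its
#' content into the current frame's geometry. Out-of-bounds samples
#' clamp to the nearest edge, or wrap horizontally in equirectangular
#' mode.
#'
#' @param image Image (`H x W x C` or matrix).
#' @param flow `H x W x 2` field (u = x, v = y displacement).
#' @param wrap_x Wrap the x axis (equirectangular seams).
#' @return Warped image, same shape as the input.
#' @export
warp_by_flow <- function(image, flow, wrap_x = FALSE) {
  if (!all(is.finite(flow))) stop("non-finite flow field", call. = FALSE)
  d <- dim(image)
  if (!identical(d[1:2], dim(flow)[1:2])) {
    stop("flow dimensions must match the image", call. = FALSE)
  }
  was_matrix <- length(d) == 2L
  if (was_matrix) dim(image) <- c(d, 1L)
  out <- bilinear_warp_cpp(image, dim(image), flow[, , 1], flow[, , 2],
                           as.integer(wrap_x))
  if (was_matrix) dim(out) <- dim(out)[1:2]
  out
}

#' Two-level blend-ratio map from a flow field
#'
#' `fg_ratio` where the flow magnitude exceeds `flow_threshold`
#' (foreground, moving areas), `bg_ratio` elsewhere (static background).
#'
#' @param flow `H x W x 2` field.
#' @param config A [coherence_config()].
#' @return `H x W` matrix of blend weights in \[0, 1\].
#' @export
flow_ratio_map <- function(flow, config = coherence_config()) {
  mag <- flow_magnitude(flow)
  ifelse(mag > config$flow_threshold, config$fg_ratio, config$bg_ratio) *
    array(1, dim = dim(mag))
}

#' Convex per-pixel blend of two frames
#'
#' `out = ratio * warped_prev_dreamed + (1 - ratio) * cur_raw`, applied
#' per pixel and channel; the ratio map is broadcast across channels.
#'
#' @param cur_raw Current raw frame.
#' @param warped_prev_dreamed Previous dreamed frame, already warped into
#'   the current geometry.
#' @param ratio_map `H x W` matrix of weights in \[0, 1\].
#' @return Blended frame.
#' @export
blend_frames <- function(cur_raw, warped_prev_dreamed, ratio_map) {
  if (!identical(dim(cur_raw), dim(warped_prev_dreamed))) {
    stop("frames must have identical dimensions", call. = FALSE)
  }
  if (any(ratio_map < 0) || any(ratio_map > 1)) {
    stop("blend ratios must lie in [0, 1]", call. = FALSE)
  }
  out <- cur_raw
  for (c in seq_len(dim(cur_raw)[3])) {
    out[, , c] <- ratio_map * warped_prev_dreamed[, , c] +
      (1 - ratio_map) * cur_raw[, , c]
  }
  out
}
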