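#' The 17 questionnaire dimensions
#'
#' Labels of the altered-states-of-consciousness questionnaire (ASCQ)
#' dimensions rated after each video: overall intensity, perceptual
#' pattern and imagery dimensions, self/ego and emotional dimensions, and
#' temporal/spatial distortion dimensions.
#'
#' @format Character vector of length 17.
#' @export
ascq_dimensions <- c(
  "intensity", "patterns", "imagery", "mood", "ego", "arousal", "strange",
  "vivid", "time", "space", "muddle", "merge", "control", "spirit",
  "peace", "float", "past"
)

#' Specify a synthetic moving-texture video
#'
#' A static textured background with a textured foreground patch that
#' translates by an integer `(dx, dy)` each frame -- a test double for
#' panoramic campus footage, with exactly known ground-truth optical
#' flow: `(dx, dy)` inside the moved patch, `(0, 0)` in the background.
#'
#' @param n_frames Number of frames (>= 1).
#' @param width,height Frame size in pixels.
#' @param patch_size Side of the square foreground patch.
#' @param patch_origin `c(x, y)` top-left corner of the patch in frame 1
#'   (1-based).
#' @param dx,dy Integer per-frame translation of the patch.
#' @param seed Integer seed; frames are deterministic given the spec.
#' @return A `synthetic_video_spec` list.
#' @export
synthetic_video_spec <- function(n_frames = 8L, width = 64L, height = 64L,
                                 patch_size = 16L, patch_origin = c(8L, 24L),
                                 dx = 3L, dy = 0L, seed = 1L) {
  stopifnot(n_frames >= 1, width >= 8, height >= 8, patch_size >= 2)
  structure(
    list(n_frames = as.integer(n_frames), width = as.integer(width),
         height = as.integer(height), patch_size = as.integer(patch_size),
         patch_origin = as.integer(patch_origin), dx = as.integer(dx),
         dy = as.integer(dy), seed = as.integer(seed)),
    class = "synthetic_video_spec"
  )
}

#' Generate a synthetic video with ground-truth flow
#'
#' @param spec A [synthetic_video_spec()].
#' @return List with `frames` (list of `H x W x 3` images on \[0, 255\])
#'   and `truth_flow` (list of `n_frames - 1` exact `H x W x 2` flow
#'   fields, previous -> current, evaluated on the current frame's patch
#'   footprint).
#' @export
generate_synthetic_video <- function(spec) {
  stopifnot(inherits(spec, "synthetic_video_spec"))
  h <- spec$height
  w <- spec$width
  ps <- spec$patch_size
  with_seed(spec$seed, {
    smooth3 <- function(m, sigma) gaussian_blur_cpp(m, sigma)
    bg <- lapply(1:3, function(c) 60 + 120 * pnorm(smooth3(matrix(rnorm(h * w), h, w), 1.5) * 3))
    patch <- lapply(1:3, function(c) 60 + 120 * pnorm(smooth3(matrix(rnorm(ps * ps), ps, ps), 1) * 3))
    frames <- vector("list", spec$n_frames)
    truth <- vector("list", max(spec$n_frames - 1L, 0L))
    for (t in seq_len(spec$n_frames)) {
      ox <- spec$patch_origin[1] + (t - 1L) * spec$dx
      oy <- spec$patch_origin[2] + (t - 1L) * spec$dy
      if (ox < 1 || oy < 1 || ox + ps - 1L > w || oy + ps - 1L > h) {
        stop("patch translated outside the frame at frame ", t, call. = FALSE)
      }
      fr <- array(0, dim = c(h, w, 3))
      for (c in 1:3) {
        m <- bg[[c]]
        m[oy:(oy + ps - 1L), ox:(ox + ps - 1L)] <- patch[[c]]
        fr[, , c] <- m
      }
      frames[[t]] <- fr
      if (t > 1L) {
        f <- array(0, dim = c(h, w, 2))
        f[oy:(oy + ps - 1L), ox:(ox + ps - 1L), 1] <- spec$dx
        f[oy:(oy + ps - 1L), ox:(ox + ps - 1L), 2] <- spec$dy
        truth[[t - 1L]] <- f
      }
    }
    list(frames = frames, truth_flow = truth)
  })
}

#' Specify synthetic two-condition questionnaire ratings
#'
#' Emulates a within- or between-subject questionnaire experiment: each
#' subject rates all 17 dimensions on a \[0, 100\] visual-analogue scale
#' under two conditions. `delta` is the standardized paired effect per
#' dimension -- the generator scales the condition shift so that the
#' population Cohen's d of the within-subject differences equals `delta`.
#'
#' @param n_subjects Subjects per condition (>= 2).
#' @param dimensions Dimension labels (default [ascq_dimensions]).
#' @param delta Standardized effect, scalar or one value per dimension.
#' @param mu Baseline mean rating.
#' @param sigma Within-subject noise SD (rating units).
#' @param subject_sd Between-subject intercept SD.
#' @param scale Rating bounds (default `c(0, 100)`); ratings are clipped.
#' @param seed Integer seed.
#' @return A `synthetic_ratings_spec` list.
#' @export
synthetic_ratings_spec <- function(n_subjects = 12L,
                                   dimensions = ascq_dimensions,
                                   delta = 0, mu = 45, sigma = 10,
                                   subject_sd = 8, scale = c(0, 100),
                                   seed = 1L) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  delta <- rep_len(delta, length(dimensions))
  if (!all(is.finite(delta))) stop("delta must be finite", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), dimensions = dimensions,
         delta = setNames(delta, dimensions), mu = mu, sigma = sigma,
         subject_sd = subject_sd, scale = scale, seed = as.integer(seed)),
    class = "synthetic_ratings_spec"
  )
}

#' Generate a synthetic ratings table
#'
#' @param spec A [synthetic_ratings_spec()].
#' @return Long-format tibble `(subject, condition, dimension, rating)`,
#'   complete over subjects x conditions ("A", "B") x dimensions, ratings
#'   clipped to the scale bounds. The condition shift is
#'   `delta * sqrt(2) * sigma` so that the standardized within-subject
#'   difference equals `delta`.
#' @export
generate_synthetic_ratings <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ratings_spec"))
  nd <- length(spec$dimensions)
  ns <- spec$n_subjects
  with_seed(spec$seed, {
    subj_int <- rnorm(ns, 0, spec$subject_sd)
    grid <- expand.grid(subject = seq_len(ns), condition = c("A", "B"),
                        dimension = spec$dimensions, stringsAsFactors = FALSE)
    shift <- ifelse(grid$condition == "B",
                    spec$delta[grid$dimension] * sqrt(2) * spec$sigma, 0)
    rating <- spec$mu + subj_int[grid$subject] + shift +
      rnorm(nrow(grid), 0, spec$sigma)
    rating <- pmin(pmax(rating, spec$scale[1]), spec$scale[2])
    tibble::tibble(subject = grid$subject, condition = grid$condition,
                   dimension = grid$dimension, rating = rating)
  })
}

#' Specify synthetic temporal-production data
#'
#' Emulates a tone-cued temporal production task under scalar timing:
#' target intervals of 1, 2 and 4 s (cued by 220, 440 and 1760 Hz tones
#' of 250 ms; metadata only, no audio is rendered), produced with a
#' multiplicative bias and Gaussian noise whose SD is a Weber fraction
#' of the target.
#'
#' @param n_subjects Number of subjects.
#' @param n_blocks Blocks per subject, alternating the two video types
#'   (default 12: six per type).
#' @param trials_per_target Productions of each target per block.
#' @param targets Named target intervals in seconds.
#' @param tone_hz Named cue frequencies (informational).
#' @param tone_ms Cue duration in milliseconds (informational).
#' @param weber Weber fraction `w` (>= 0): per-trial SD = `w * target`.
#' @param bias Multiplicative bias `b`: mean produced = `target * (1 + b)`.
#' @param video_effect Additional multiplicative bias applied in the
#'   `"dream"` video type only (default 0: no effect of video type).
#' @param seed Integer seed.
#' @return A `synthetic_timing_spec` list.
#' @export
synthetic_timing_spec <- function(n_subjects = 21L, n_blocks = 12L,
                                  trials_per_target = 2L,
                                  targets = c(low = 1, mid = 2, high = 4),
                                  tone_hz = c(low = 220, mid = 440, high = 1760),
                                  tone_ms = 250,
                                  weber = 0.15, bias = 0.1,
                                  video_effect = 0, seed = 1L) {
  if (weber < 0) stop("weber fraction must be >= 0", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), n_blocks = as.integer(n_blocks),
         trials_per_target = as.integer(trials_per_target),
         targets = targets, tone_hz = tone_hz, tone_ms = tone_ms,
         weber = weber, bias = bias, video_effect = video_effect,
         seed = as.integer(seed)),
    class = "synthetic_timing_spec"
  )
}

#' Generate a synthetic temporal-production table
#'
#' @param spec A [synthetic_timing_spec()].
#' @return Tibble `(subject, block, video_type, target_s, produced_s)`;
#'   produced intervals are strictly positive (truncated at 1 ms).
#' @export
generate_synthetic_timing <- function(spec) {
  stopifnot(inherits(spec, "synthetic_timing_spec"))
  with_seed(spec$seed, {
    grid <- expand.grid(trial = seq_len(spec$trials_per_target),
                        target_s = unname(spec$targets),
                        block = seq_len(spec$n_blocks),
                        subject = seq_len(spec$n_subjects))
    video <- ifelse(grid$block %% 2L == 1L, "control", "dream")
    mult <- (1 + spec$bias) * ifelse(video == "dream", 1 + spec$video_effect, 1)
    produced <- grid$target_s * mult +
      rnorm(nrow(grid), 0, spec$weber * grid$target_s)
    produced <- pmax(produced, 1e-3)
    tibble::tibble(subject = grid$subject, block = grid$block,
                   video_type = video, target_s = grid$target_s,
                   produced_s = produced)
  })
}
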