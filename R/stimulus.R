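#' Stimulus sequences
#'
#' A `stimulus_sequence` holds a stack of luminance frames together with the
#' presentation rate and a per-frame label record. Frames are stored as a
#' 3-D array indexed `[frame, row, col]` with luminance in `[0, 1]`; labels
#' carry the grating orientation, spatial frequency, discretized temporal
#' phase and a free-form condition tag. Spatial frequency is expressed in
#' cycles per degree of visual angle; the mapping between pixels and degrees
#' is fixed by `visual_field_deg`, the visual angle subtended by the frame
#' width (default 45 degrees across the full frame).
#'
#' @param frames numeric array `[time, height, width]` with values in `[0,1]`.
#' @param frame_rate_hz presentation rate in Hz.
#' @param labels data frame with one row per frame (columns
#'   `orientation_deg`, `spatial_freq_cpd`, `phase_bin`, `condition_tag`).
#' @param visual_field_deg visual angle covered by the frame width.
#' @return object of class `stimulus_sequence`.
#' @export
stimulus_sequence <- function(frames, frame_rate_hz, labels,
                              visual_field_deg = 45) {
  stopifnot(length(dim(frames)) == 3L)
  assert_scalar_positive(frame_rate_hz, "frame_rate_hz")
  if (nrow(labels) != dim(frames)[1L]) {
    stop("every frame needs exactly one label record", call. = FALSE)
  }
  if (length(frames) &&
      (min(frames) < -1e-9 || max(frames) > 1 + 1e-9)) {
    stop("frame luminance must lie within [0, 1]", call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz, labels = labels,
         visual_field_deg = visual_field_deg),
    class = "stimulus_sequence"
  )
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<stimulus_sequence> %d frames of %dx%d px at %g Hz (%.2f s)\n",
    d[1], d[2], d[3], x$frame_rate_hz, d[1] / x$frame_rate_hz))
  invisible(x)
}

#' Number of frames in a stimulus sequence
#' @param stimulus a `stimulus_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(stimulus) dim(stimulus$frames)[1L]

#' Drifting square-wave grating
#'
#' Generates a moving square grating: bars at `orientation_deg`, drifting
#' perpendicular to their own orientation at `temporal_freq_hz` cycles per
#' second. Michelson contrast of the emitted sequence equals `contrast`
#' exactly (`(max - min) / (max + min)` with luminance
#' `mean_luminance * (1 +/- contrast)`). The per-frame temporal phase in
#' `[0, 1)` is discretized into `phase_bins` equal bins and stored in the
#' label record.
#'
#' @param orientation_deg bar orientation in degrees, in `[0, 360)`.
#' @param spatial_freq_cpd spatial frequency in cycles/degree (> 0).
#' @param temporal_freq_hz drift rate in cycles/second.
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param mean_luminance mean luminance; `mean_luminance * (1 + contrast)`
#'   must stay within `[0, 1]`.
#' @param duration_s stimulus duration in seconds.
#' @param frame_rate_hz presentation rate (default 30 Hz).
#' @param frame_size frame side length in pixels (square frames).
#' @param visual_field_deg visual angle across the frame width.
#' @param phase_bins number of phase bins per temporal cycle (default 8).
#' @param condition_tag label tag copied to every frame.
#' @return a [stimulus_sequence()].
#' @export
make_grating_sequence <- function(orientation_deg, spatial_freq_cpd,
                                  temporal_freq_hz = 1, contrast = 0.5,
                                  mean_luminance = 0.5, duration_s = 1,
                                  frame_rate_hz = 30, frame_size = 64,
                                  visual_field_deg = 45, phase_bins = 8,
                                  condition_tag = "grating") {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  if (!is.numeric(frame_size) || frame_size <= 0) {
    stop("`frame_size` must be positive", call. = FALSE)
  }
  if (contrast < 0 || contrast > 1) {
    stop("`contrast` must lie in [0, 1]", call. = FALSE)
  }
  assert_scalar_positive(spatial_freq_cpd, "spatial_freq_cpd")
  if (orientation_deg < 0 || orientation_deg >= 360) {
    stop("`orientation_deg` must lie in [0, 360)", call. = FALSE)
  }
  if (mean_luminance * (1 + contrast) > 1 + 1e-9 || mean_luminance < 0) {
    stop("mean_luminance * (1 + contrast) must stay within [0, 1]",
         call. = FALSE)
  }

  nt <- as.integer(round(duration_s * frame_rate_hz))
  h <- w <- as.integer(frame_size)
  deg_per_px <- visual_field_deg / w

  # spatial phase axis: displacement along the drift direction (perpendicular
  # to the bars), in degrees of visual angle
  theta <- orientation_deg * pi / 180
  col_deg <- (seq_len(w) - 1) * deg_per_px
  row_deg <- (seq_len(h) - 1) * deg_per_px
  u <- outer(row_deg, col_deg, function(y, x) x * cos(theta) + y * sin(theta))

  frames <- array(0, dim = c(nt, h, w))
  t_s <- (seq_len(nt) - 1) / frame_rate_hz
  phase <- (temporal_freq_hz * t_s) %% 1
  for (i in seq_len(nt)) {
    # square wave from the fractional phase (half-open: [0, .5) is bright);
    # the half-cycle offset is exact in floating point, so a frame and its
    # counterphase partner are exactly symmetric about the mean luminance
    frac <- (spatial_freq_cpd * u - phase[i]) %% 1
    frames[i, , ] <- mean_luminance * (1 + contrast * ifelse(frac < 0.5, 1, -1))
  }

  labels <- data.frame(
    frame = seq_len(nt),
    orientation_deg = orientation_deg,
    spatial_freq_cpd = spatial_freq_cpd,
    phase_bin = as.integer(floor(phase * phase_bins)),
    condition_tag = condition_tag,
    stringsAsFactors = FALSE
  )
  stimulus_sequence(frames, frame_rate_hz, labels, visual_field_deg)
}

#' Sliding-window scan over a natural image
#'
#' Emulates a natural-scene protocol: each frame is a fixed-size crop of a
#' larger image, taken at successive positions of a trajectory. The label
#' record carries the trajectory index as the condition tag, which serves as
#' the discrete stimulus identity for mutual-information scoring.
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param window_hw integer vector `c(height, width)` of the sliding window.
#' @param trajectory two-column matrix/data frame of 1-based top-left window
#'   positions `(row, col)`, one per frame.
#' @param frame_rate_hz presentation rate.
#' @param visual_field_deg visual angle across the window width.
#' @return a [stimulus_sequence()].
#' @export
make_natural_scan <- function(image, window_hw, trajectory,
                              frame_rate_hz = 30, visual_field_deg = 45) {
  image <- as.matrix(image)
  trajectory <- as.matrix(trajectory)
  stopifnot(ncol(trajectory) == 2L, length(window_hw) == 2L)
  wh <- as.integer(window_hw[1L]); ww <- as.integer(window_hw[2L])
  if (any(trajectory[, 1] < 1) || any(trajectory[, 2] < 1) ||
      any(trajectory[, 1] + wh - 1 > nrow(image)) ||
      any(trajectory[, 2] + ww - 1 > ncol(image))) {
    stop("sliding window leaves the image bounds", call. = FALSE)
  }
  nt <- nrow(trajectory)
  frames <- array(0, dim = c(nt, wh, ww))
  for (i in seq_len(nt)) {
    r <- trajectory[i, 1]; c <- trajectory[i, 2]
    frames[i, , ] <- image[r:(r + wh - 1), c:(c + ww - 1)]
  }
  labels <- data.frame(
    frame = seq_len(nt),
    orientation_deg = NA_real_,
    spatial_freq_cpd = NA_real_,
    phase_bin = NA_integer_,
    condition_tag = sprintf("traj_%03d", seq_len(nt)),
    stringsAsFactors = FALSE
  )
  stimulus_sequence(frames, frame_rate_hz, labels, visual_field_deg)
}

#' Procedural brick-wall texture
#'
#' Deterministic high-contrast texture with the oriented edges and repeated
#' structure of a brick wall, for natural-scan protocols.
#'
#' @param height,width texture size in pixels.
#' @param brick_h,brick_w brick size in pixels (mortar lines 1 px wide).
#' @return matrix with values in `[0, 1]`.
#' @export
brick_texture <- function(height = 128, width = 128, brick_h = 12,
                          brick_w = 24) {
  img <- matrix(0.55, height, width)
  for (r in seq_len(height)) {
    row_band <- (r - 1) %/% brick_h
    offset <- if (row_band %% 2 == 0) 0 else brick_w %/% 2
    if ((r - 1) %% brick_h == 0) {
      img[r, ] <- 0.15  # horizontal mortar line
    } else {
      cols <- seq_len(width)
      mortar <- ((cols - 1 + offset) %% brick_w) == 0
      shade <- 0.45 + 0.25 * ((row_band + (cols - 1 + offset) %/% brick_w) %% 3) / 2
      img[r, ] <- ifelse(mortar, 0.15, shade)
    }
  }
  img
}

#' Concatenate stimulus sequences in time
#'
#' @param sequences list of `stimulus_sequence` objects with identical frame
#'   geometry and frame rate.
#' @return a single `stimulus_sequence`; label frame indices are renumbered
#'   consecutively.
#' @export
concat_stimuli <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  d1 <- dim(sequences[[1L]]$frames)
  fr <- sequences[[1L]]$frame_rate_hz
  for (s in sequences) {
    stopifnot(identical(dim(s$frames)[2:3], d1[2:3]), s$frame_rate_hz == fr)
  }
  frames <- do.call(abind_time, list(lapply(sequences, function(s) s$frames)))
  labels <- do.call(rbind, lapply(sequences, function(s) s$labels))
  labels$frame <- seq_len(nrow(labels))
  stimulus_sequence(frames, fr, labels, sequences[[1L]]$visual_field_deg)
}

# rbind for [time, h, w] arrays
abind_time <- function(arrays) {
  nt <- sum(vapply(arrays, function(a) dim(a)[1L], integer(1)))
  d <- dim(arrays[[1L]])
  out <- array(0, dim = c(nt, d[2L], d[3L]))
  at <- 0L
  for (a in arrays) {
    n <- dim(a)[1L]
    out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}

#' Michelson contrast of a stimulus sequence
#' @param stimulus a `stimulus_sequence`.
#' @return `(max - min) / (max + min)` over all pixels of all frames.
#' @export
michelson_contrast <- function(stimulus) {
  mx <- max(stimulus$frames); mn <- min(stimulus$frames)
  if (mx + mn == 0) return(0)
  (mx - mn) / (mx + mn)
}
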