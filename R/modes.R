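#' Binary latent states of a trained model
#'
#' Computes per-sample latent activation probabilities under a trained model
#' and binarizes them into a `binary_state_table`: a samples x units 0/1
#' matrix, a numeric `state_id` encoding each row's bit pattern, and a
#' per-column tag naming the latent set each unit belongs to. For the
#' mean-covariance model the state is, by default, the concatenation of the
#' binarized mean-unit and precision-unit activations (`mean_only = TRUE`
#' restricts it to the mean units). For the conditional model only samples
#' with a complete history are represented; `sample_index` records the
#' alignment with the input samples.
#'
#' @param model a trained `rbm`, `mcrbm` or `crbm`.
#' @param x samples x neurons matrix, standardized consistently with
#'   training.
#' @param binarize_rule `"threshold"` (deterministic; probability >= 0.5
#'   maps to 1, so exact ties round up) or `"sample"` (Bernoulli draws under
#'   `seed`, for sensitivity checks).
#' @param mean_only mcRBM only: use mean units alone.
#' @param seed RNG seed for `binarize_rule = "sample"`.
#' @return object of class `binary_state_table` with fields `states`,
#'   `state_id`, `unit_kind`, `sample_index`.
#' @export
infer_states <- function(model, x, binarize_rule = c("threshold", "sample"),
                         mean_only = FALSE, seed = NULL) {
  binarize_rule <- match.arg(binarize_rule)
  x <- as.matrix(x)
  if (inherits(model, "mcrbm")) {
    if (ncol(x) != nrow(model$W)) stop("dimension mismatch", call. = FALSE)
    probs <- mcrbm_hidden_probs(model, x)
    if (mean_only) {
      p <- probs$mean
      kind <- rep("mean", ncol(p))
    } else {
      p <- cbind(probs$mean, probs$precision)
      kind <- c(rep("mean", ncol(probs$mean)),
                rep("precision", ncol(probs$precision)))
    }
    idx <- seq_len(nrow(x))
  } else if (inherits(model, "crbm")) {
    if (ncol(x) != nrow(model$W)) stop("dimension mismatch", call. = FALSE)
    win <- crbm_history(x, model$order, model$frame_spacing)
    dyn <- crbm_dynamic_biases(model, win$history)
    p <- sigmoid(dyn$b_eff + win$present %*% model$W)
    kind <- rep("hidden", ncol(p))
    idx <- win$index
  } else if (inherits(model, "rbm")) {
    if (ncol(x) != nrow(model$W)) stop("dimension mismatch", call. = FALSE)
    p <- hidden_given_visible(model, x)
    kind <- rep("hidden", ncol(p))
    idx <- seq_len(nrow(x))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  bits <- if (binarize_rule == "threshold") {
    (p >= 0.5) * 1L
  } else {
    with_seed(seed, (matrix(stats::runif(length(p)), nrow(p)) < p) * 1L)
  }
  structure(list(
    states = bits,
    state_id = encode_state_id(bits),
    unit_kind = kind,
    sample_index = idx
  ), class = "binary_state_table")
}

#' @export
print.binary_state_table <- function(x, ...) {
  cat(sprintf("<binary_state_table> %d samples x %d units (%d distinct states)\n",
              nrow(x$states), ncol(x$states), length(unique(x$state_id))))
  invisible(x)
}

# Resolve triggering sample indices for a state id or a unit column.
triggering_samples <- function(states, state_id = NULL, unit_index = NULL) {
  stopifnot(inherits(states, "binary_state_table"))
  if (!is.null(state_id)) {
    rows <- which(states$state_id == state_id)
  } else {
    stopifnot(unit_index >= 1, unit_index <= ncol(states$states))
    rows <- which(states$states[, unit_index] == 1)
  }
  states$sample_index[rows]
}

sta_core <- function(sample_idx, stimulus, lag_frames, what) {
  frame_idx <- sample_idx - lag_frames
  skipped <- sum(frame_idx < 1)
  frame_idx <- frame_idx[frame_idx >= 1]
  if (!length(frame_idx)) {
    stop(sprintf("empty mode: %s never triggers (or all triggers precede time 0)",
                 what), call. = FALSE)
  }
  fr <- stimulus$frames[frame_idx, , , drop = FALSE]
  mean_frame <- apply(fr, c(2, 3), mean)
  structure(list(
    mean_frame = mean_frame,
    n_samples_averaged = length(frame_idx),
    n_skipped_before_origin = skipped,
    id = what,
    lag_frames = lag_frames
  ), class = "mode_image")
}

#' @export
print.mode_image <- function(x, ...) {
  cat(sprintf("<mode_image> %s: mean of %d frames (lag %d)\n",
              x$id, x$n_samples_averaged, x$lag_frames))
  invisible(x)
}

#' State-triggered stimulus average
#'
#' The spike-triggered-average idea lifted to latent states: select one
#' binary state, collect the samples whose latent vector equals it, and
#' average the stimulus frames presented `lag_frames` before those samples.
#'
#' @param states a [infer_states()] table whose rows align with stimulus
#'   frames.
#' @param stimulus the presented `stimulus_sequence`.
#' @param state_id the state to trigger on (must occur at least once).
#' @param lag_frames stimulus-to-sample lag; triggers whose lagged frame
#'   precedes the recording are skipped and counted.
#' @return object of class `mode_image` (`mean_frame`,
#'   `n_samples_averaged`, `id`, `lag_frames`).
#' @export
state_triggered_average <- function(states, stimulus, state_id,
                                    lag_frames = 0) {
  idx <- triggering_samples(states, state_id = state_id)
  if (!length(idx)) {
    stop(sprintf("empty mode: state %s never occurs", format(state_id)),
         call. = FALSE)
  }
  sta_core(idx, stimulus, lag_frames, sprintf("state %s", format(state_id)))
}

#' Unit-triggered stimulus average
#'
#' As [state_triggered_average()] but triggered on one latent unit being
#' active. A unit's triggering set is exactly the union of the triggering
#' sets of all states with that bit set, so unit averages aggregate (and
#' blur) the corresponding state averages.
#'
#' @param states a `binary_state_table`.
#' @param stimulus the presented `stimulus_sequence`.
#' @param unit_index latent unit column (1-based).
#' @param lag_frames stimulus-to-sample lag.
#' @return a `mode_image`.
#' @export
unit_triggered_average <- function(states, stimulus, unit_index,
                                   lag_frames = 0) {
  idx <- triggering_samples(states, unit_index = unit_index)
  if (!length(idx)) {
    stop(sprintf("empty mode: unit %d never activates", unit_index),
         call. = FALSE)
  }
  sta_core(idx, stimulus, lag_frames, sprintf("unit %d", unit_index))
}

#' Temporal state/unit-triggered average for conditional models
#'
#' Averages the stimulus *histories* of the triggering samples, slot by
#' slot, preserving temporal order: slot 1 is the most delayed frame
#' (`t - order*spacing`) and the last slot the least delayed
#' (`t - spacing`), one average per delayed visible layer.
#'
#' @param states a `binary_state_table` from a conditional model.
#' @param stimulus the presented `stimulus_sequence`.
#' @param target list with `kind` (`"state"` or `"unit"`) and `id` (state id
#'   or unit column).
#' @param order,spacing history layout (defaults: taken from `attr(states)`
#'   if absent, must be supplied).
#' @param lag_frames stimulus-to-sample lag applied before the history
#'   offsets.
#' @return object of class `mode_sequence`: list `slots` of `mode_image`s
#'   ordered most-delayed first, each tagged with its delay in frames.
#' @export
temporal_sta <- function(states, stimulus, target, order, spacing,
                         lag_frames = 0) {
  stopifnot(is.list(target), target$kind %in% c("state", "unit"))
  idx <- if (target$kind == "state") {
    triggering_samples(states, state_id = target$id)
  } else {
    triggering_samples(states, unit_index = target$id)
  }
  if (!length(idx)) stop("empty mode: target never triggers", call. = FALSE)
  # only samples with a complete in-range history
  max_delay <- order * spacing + lag_frames
  idx <- idx[idx - max_delay >= 1]
  if (!length(idx)) {
    stop("empty mode: no triggering sample has a complete history",
         call. = FALSE)
  }
  delays <- seq(order, 1) * spacing  # most delayed first
  slots <- lapply(seq_along(delays), function(s) {
    img <- sta_core(idx, stimulus, lag_frames + delays[s],
                    sprintf("%s %s / slot %d", target$kind,
                            format(target$id), s))
    img$delay_frames <- delays[s]
    img
  })
  structure(list(slots = slots, order = order, spacing = spacing,
                 target = target, n_triggers = length(idx)),
            class = "mode_sequence")
}

#' @export
print.mode_sequence <- function(x, ...) {
  cat(sprintf("<mode_sequence> %s %s: %d slots (spacing %d), %d triggers\n",
              x$target$kind, format(x$target$id), length(x$slots),
              x$spacing, x$n_triggers))
  invisible(x)
}

#' State occupancy census
#'
#' @param states a `binary_state_table`.
#' @return data frame (`state_id`, `count`, `fraction`) sorted by descending
#'   occupancy; fractions sum to 1.
#' @export
mode_census <- function(states) {
  stopifnot(inherits(states, "binary_state_table"),
            nrow(states$states) > 0)
  tab <- table(states$state_id)
  df <- data.frame(
    state_id = as.numeric(names(tab)),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  df$fraction <- df$count / sum(df$count)
  df[order(-df$count, df$state_id), , drop = FALSE]
}

#' Distribution of stimuli within one latent state
#'
#' Counts each stimulus label among the samples that trigger `state_id`.
#' Under an intact encoder a state concentrates on one (or few) labels;
#' under impairment the histogram spreads, e.g. over counterphase label
#' pairs.
#'
#' @param states a `binary_state_table`.
#' @param stimulus_labels per-sample label vector aligned with the rate
#'   samples (the table's `sample_index` selects into it).
#' @param state_id the state to profile.
#' @return data frame (`label`, `count`); counts sum to the state
#'   occupancy.
#' @export
state_stimulus_histogram <- function(states, stimulus_labels, state_id) {
  idx <- triggering_samples(states, state_id = state_id)
  if (!length(idx)) {
    stop(sprintf("empty mode: state %s never occurs", format(state_id)),
         call. = FALSE)
  }
  tab <- table(stimulus_labels[idx])
  data.frame(label = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}
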