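#' Conditional RBM parameters
#'
#' Gaussian-visible RBM augmented with a window of `order` delayed visible
#' frames spaced `frame_spacing` bins apart. Autoregressive weights `A_k`
#' (visible x visible) feed delayed frames into the visible bias and
#' history-to-hidden weights `B_k` (visible x hidden) feed them into the
#' hidden bias, so the history acts purely as a *dynamic bias*: with the
#' effective biases of [crbm_dynamic_biases()] every static-RBM operation
#' (conditionals, contrastive divergence) applies unchanged.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param order number of delayed visible layers (>= 1; default 12).
#' @param frame_spacing spacing between delayed layers, in bins.
#' @param seed,init_sd static weight initialization (`A_k`, `B_k` start at
#'   zero).
#' @return object of class `crbm`.
#' @export
crbm_params <- function(n_visible, n_hidden, order = 12, frame_spacing = 1,
                        seed = 1, init_sd = 0.01) {
  stopifnot(order >= 1, frame_spacing >= 1)
  W <- with_seed(seed, matrix(stats::rnorm(n_visible * n_hidden, 0, init_sd),
                              n_visible, n_hidden))
  structure(list(
    W = W, a = numeric(n_visible), b = numeric(n_hidden),
    A = replicate(order, matrix(0, n_visible, n_visible), simplify = FALSE),
    B = replicate(order, matrix(0, n_visible, n_hidden), simplify = FALSE),
    order = as.integer(order), frame_spacing = as.integer(frame_spacing)
  ), class = "crbm")
}

#' @export
print.crbm <- function(x, ...) {
  cat(sprintf("<crbm> %d visibles x %d hidden, order %d, spacing %d bins\n",
              nrow(x$W), ncol(x$W), x$order, x$frame_spacing))
  invisible(x)
}

#' History spacing from the counterphase rule
#'
#' For drifting gratings the history window is anchored so that the most
#' delayed visible layer sees activity in counterphase with the present one:
#' `order * spacing * bin_width = period / 2`. The spacing must be a whole
#' number of bins; when the rule is unsatisfiable at the given bin width the
#' call fails and names the nearest feasible spacing.
#'
#' @param order number of delayed layers.
#' @param temporal_period_s stimulus temporal period in seconds.
#' @param bin_width_s rate bin width in seconds.
#' @return integer spacing in bins.
#' @export
crbm_spacing <- function(order, temporal_period_s, bin_width_s) {
  half_bins <- temporal_period_s / (2 * bin_width_s)
  spacing <- half_bins / order
  if (abs(spacing - round(spacing)) > 1e-9 || round(spacing) < 1) {
    stop(sprintf(paste0(
      "counterphase rule unsatisfiable: half period = %.4g bins over %d ",
      "layers gives spacing %.4g; nearest feasible spacing is %d bins ",
      "(history span %.4g s)"),
      half_bins, order, spacing, max(1L, as.integer(round(spacing))),
      max(1L, as.integer(round(spacing))) * order * bin_width_s),
      call. = FALSE)
  }
  as.integer(round(spacing))
}

#' Effective (dynamic) biases given an input history
#'
#' `a_eff = a + sum_k A_k v_{t-k*spacing}` and
#' `b_eff = b + sum_k B_k' v_{t-k*spacing}`.
#'
#' @param params a `crbm`.
#' @param history list of `order` matrices (samples x visible); element `k`
#'   holds the frames delayed by `k * frame_spacing` bins.
#' @return list with matrices `a_eff` (samples x visible) and `b_eff`
#'   (samples x hidden).
#' @export
crbm_dynamic_biases <- function(params, history) {
  if (length(history) != params$order) {
    stop(sprintf("history must have %d delayed layers", params$order),
         call. = FALSE)
  }
  m <- nrow(history[[1L]])
  a_eff <- matrix(params$a, m, length(params$a), byrow = TRUE)
  b_eff <- matrix(params$b, m, length(params$b), byrow = TRUE)
  for (k in seq_len(params$order)) {
    a_eff <- a_eff + history[[k]] %*% t(params$A[[k]])
    b_eff <- b_eff + history[[k]] %*% params$B[[k]]
  }
  list(a_eff = a_eff, b_eff = b_eff)
}

#' Build history windows from a sample matrix
#'
#' @param x samples x visible matrix in temporal order.
#' @param order,spacing history layout in bins.
#' @return list with `present` (valid samples x visible), `history` (list of
#'   `order` matrices aligned to `present`; element `k` delayed by
#'   `k * spacing`), and `index` (row indices of `present` within `x`).
#' @export
crbm_history <- function(x, order, spacing) {
  x <- as.matrix(x)
  first <- order * spacing + 1L
  if (first > nrow(x)) {
    stop("not enough time bins to form any history window", call. = FALSE)
  }
  idx <- first:nrow(x)
  history <- lapply(seq_len(order), function(k) {
    x[idx - k * spacing, , drop = FALSE]
  })
  list(present = x[idx, , drop = FALSE], history = history, index = idx)
}

# CD-1 update extended to the autoregressive and history-to-hidden weights.
crbm_cd_update <- function(params, present, history, config) {
  m <- nrow(present)
  dyn <- crbm_dynamic_biases(params, history)
  ph_pos <- sigmoid(dyn$b_eff + present %*% params$W)
  h <- (matrix(stats::runif(length(ph_pos)), m) < ph_pos) * 1
  Vn <- present
  for (k in seq_len(config$cd_k)) {
    mu <- dyn$a_eff + h %*% t(params$W)
    Vn <- mu + matrix(stats::rnorm(length(mu)), m)
    ph_neg <- sigmoid(dyn$b_eff + Vn %*% params$W)
    if (k < config$cd_k) {
      h <- (matrix(stats::runif(length(ph_neg)), m) < ph_neg) * 1
    }
  }
  grad <- list(
    W = (crossprod(present, ph_pos) - crossprod(Vn, ph_neg)) / m -
      config$weight_decay * params$W,
    a = colMeans(present) - colMeans(Vn),
    b = colMeans(ph_pos) - colMeans(ph_neg)
  )
  dV <- present - Vn
  dH <- ph_pos - ph_neg
  gA <- lapply(seq_len(params$order), function(k) {
    crossprod(dV, history[[k]]) / m - config$weight_decay * params$A[[k]]
  })
  gB <- lapply(seq_len(params$order), function(k) {
    crossprod(history[[k]], dH) / m - config$weight_decay * params$B[[k]]
  })
  ok <- all(is.finite(unlist(grad))) &&
    all(vapply(c(gA, gB), function(g) all(is.finite(g)), logical(1)))
  if (!ok) stop("non-finite gradient in cRBM update (diverged)", call. = FALSE)
  vel <- params$velocity %||% list(
    W = 0 * params$W, a = 0 * params$a, b = 0 * params$b,
    A = lapply(params$A, function(x) 0 * x),
    B = lapply(params$B, function(x) 0 * x))
  lr <- config$learning_rate; mom <- config$momentum
  vel$W <- mom * vel$W + lr * grad$W; params$W <- params$W + vel$W
  vel$a <- mom * vel$a + lr * grad$a; params$a <- params$a + vel$a
  vel$b <- mom * vel$b + lr * grad$b; params$b <- params$b + vel$b
  for (k in seq_len(params$order)) {
    vel$A[[k]] <- mom * vel$A[[k]] + lr * gA[[k]]
    params$A[[k]] <- params$A[[k]] + vel$A[[k]]
    vel$B[[k]] <- mom * vel$B[[k]] + lr * gB[[k]]
    params$B[[k]] <- params$B[[k]] + vel$B[[k]]
  }
  params$velocity <- vel
  params
}

#' Train a conditional RBM
#'
#' Contrastive divergence with gradients extended to the autoregressive
#' (`A_k`) and history-to-hidden (`B_k`) weights. The history spacing is
#' either given directly or derived from the counterphase rule when a
#' stimulus temporal period is supplied (see [crbm_spacing()]).
#'
#' @param x samples x neurons matrix (standardized) in temporal order.
#' @param order number of delayed visible layers (default 12).
#' @param config a [train_config()].
#' @param spacing history spacing in bins; ignored when
#'   `temporal_period_s` is given.
#' @param temporal_period_s stimulus period for the counterphase rule.
#' @param bin_width_s rate bin width (required with `temporal_period_s`).
#' @return trained `crbm` with a `loss_trace` attribute.
#' @export
train_crbm <- function(x, order = 12, config = train_config(),
                       spacing = NULL, temporal_period_s = NULL,
                       bin_width_s = NULL) {
  x <- as.matrix(x)
  if (!is.null(temporal_period_s)) {
    if (is.null(bin_width_s)) {
      stop("`bin_width_s` is required to apply the counterphase rule",
           call. = FALSE)
    }
    spacing <- crbm_spacing(order, temporal_period_s, bin_width_s)
  }
  if (is.null(spacing)) stop("supply `spacing` or `temporal_period_s`",
                             call. = FALSE)
  params <- crbm_params(ncol(x), config$n_hidden, order = order,
                        frame_spacing = spacing, seed = config$seed)
  params$a <- colMeans(x)
  win <- crbm_history(x, order, spacing)
  n <- nrow(win$present)
  loss <- numeric(config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (idx in batches) {
        params <- crbm_cd_update(
          params, win$present[idx, , drop = FALSE],
          lapply(win$history, function(hmat) hmat[idx, , drop = FALSE]),
          config)
      }
      dyn <- crbm_dynamic_biases(params, win$history)
      ph <- sigmoid(dyn$b_eff + win$present %*% params$W)
      mu <- dyn$a_eff + ph %*% t(params$W)
      loss[ep] <- mean((win$present - mu)^2)
      if (!is.finite(loss[ep]) || (ep > 1 && loss[ep] > 1e3 * loss[1])) {
        stop("cRBM training diverged (reconstruction error exploded)",
             call. = FALSE)
      }
    }
  })
  params$velocity <- NULL
  attr(params, "loss_trace") <- loss
  params
}
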