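#' Training configuration for energy-based models
#'
#' @param n_hidden hidden units (mean units for the mean-covariance model).
#' @param n_factors,n_precision covariance factor and precision-unit counts
#'   (mean-covariance model only).
#' @param cd_k Gibbs sweeps in the contrastive-divergence negative phase.
#' @param learning_rate,momentum,weight_decay,batch_size,epochs optimizer
#'   settings.
#' @param seed RNG seed controlling shuffling and all sampling.
#' @return list of class `train_config`.
#' @export
train_config <- function(n_hidden = 16, n_factors = 64, n_precision = 16,
                         cd_k = 1, learning_rate = 1e-3, momentum = 0.9,
                         weight_decay = 1e-4, batch_size = 64, epochs = 50,
                         seed = 1) {
  cfg <- list(n_hidden = n_hidden, n_factors = n_factors,
              n_precision = n_precision, cd_k = cd_k,
              learning_rate = learning_rate, momentum = momentum,
              weight_decay = weight_decay, batch_size = batch_size,
              epochs = epochs, seed = seed)
  for (nm in c("n_hidden", "n_factors", "n_precision", "cd_k",
               "learning_rate", "batch_size", "epochs")) {
    if (cfg[[nm]] <= 0) stop(sprintf("`%s` must be positive", nm),
                             call. = FALSE)
  }
  if (cfg$cd_k < 1) stop("`cd_k` must be >= 1", call. = FALSE)
  structure(cfg, class = "train_config")
}

#' Restricted Boltzmann machine parameters
#'
#' Bipartite energy model over visible units `v` and binary hidden units
#' `h`. For binary visibles the energy is
#' `E(v, h) = -a'v - b'h - v'Wh`; for Gaussian (linear) visibles with unit
#' noise variance it is `E(v, h) = (1/2)||v - a||^2 - b'h - v'Wh`. The joint
#' density is proportional to `exp(-E)`.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param visible_kind `"gaussian"` or `"binary"`.
#' @param seed seed for the random weight initialization.
#' @param init_sd s.d. of the initial weights.
#' @return object of class `rbm` with fields `W` (visible x hidden), `a`,
#'   `b`, `visible_kind`.
#' @export
rbm_params <- function(n_visible, n_hidden,
                       visible_kind = c("gaussian", "binary"),
                       seed = 1, init_sd = 0.01) {
  visible_kind <- match.arg(visible_kind)
  W <- with_seed(seed, matrix(stats::rnorm(n_visible * n_hidden, 0, init_sd),
                              n_visible, n_hidden))
  structure(list(
    W = W, a = numeric(n_visible), b = numeric(n_hidden),
    visible_kind = visible_kind
  ), class = "rbm")
}

#' @export
print.rbm <- function(x, ...) {
  cat(sprintf("<rbm> %d %s visible x %d hidden units\n",
              nrow(x$W), x$visible_kind, ncol(x$W)))
  invisible(x)
}

#' RBM energy of a joint configuration
#'
#' @param params an `rbm`.
#' @param v,h visible and hidden vectors.
#' @return scalar energy.
#' @export
rbm_energy <- function(params, v, h) {
  if (length(v) != nrow(params$W) || length(h) != ncol(params$W)) {
    stop("dimension mismatch", call. = FALSE)
  }
  inter <- -sum(v * (params$W %*% h)) - sum(params$b * h)
  if (params$visible_kind == "binary") {
    -sum(params$a * v) + inter
  } else {
    0.5 * sum((v - params$a)^2) + inter
  }
}

#' Hidden activation probabilities given visibles
#'
#' `p(h_j = 1 | v) = logistic(b_j + v' W_.j)`, independently across hidden
#' units for both visible kinds.
#'
#' @param params an `rbm` (or any model with `W`, `b`).
#' @param v visible vector or samples x visible matrix.
#' @return samples x hidden matrix of probabilities.
#' @export
hidden_given_visible <- function(params, v) {
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  if (ncol(V) != nrow(params$W)) stop("dimension mismatch", call. = FALSE)
  sigmoid(sweep(V %*% params$W, 2, params$b, "+"))
}

#' Visible conditional given hiddens
#'
#' Gaussian visibles: independent unit-variance Gaussians with mean
#' `a + W h`. Binary visibles: independent Bernoullis with
#' `p = logistic(a + W h)`.
#'
#' @param params an `rbm`.
#' @param h hidden vector or samples x hidden matrix.
#' @return list with `kind` and either `mean` (gaussian) or `prob` (binary),
#'   samples x visible.
#' @export
visible_given_hidden <- function(params, h) {
  H <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  if (ncol(H) != ncol(params$W)) stop("dimension mismatch", call. = FALSE)
  act <- sweep(H %*% t(params$W), 2, params$a, "+")
  if (params$visible_kind == "gaussian") {
    list(kind = "gaussian", mean = act)
  } else {
    list(kind = "binary", prob = sigmoid(act))
  }
}

# Draw visible samples from the conditional given hiddens.
sample_visible <- function(params, H) {
  cond <- visible_given_hidden(params, H)
  if (cond$kind == "gaussian") {
    cond$mean + matrix(stats::rnorm(length(cond$mean)), nrow(cond$mean))
  } else {
    (matrix(stats::runif(length(cond$prob)), nrow(cond$prob)) < cond$prob) * 1
  }
}

#' One contrastive-divergence update
#'
#' CD-k: positive statistics from the data minibatch (using hidden
#' probabilities), negative statistics after `k` alternating Gibbs sweeps
#' (hidden samples drive the reconstructions; the final hidden layer uses
#' probabilities). Parameters move by gradient ascent with momentum and
#' weight decay on `W`. Deterministic under a fixed RNG state.
#'
#' @param params an `rbm` (velocities are kept in `params$velocity`).
#' @param minibatch samples x visible matrix.
#' @param config a [train_config()].
#' @return updated `rbm`.
#' @export
cd_update <- function(params, minibatch, config) {
  V <- as.matrix(minibatch)
  if (ncol(V) != nrow(params$W)) stop("dimension mismatch", call. = FALSE)
  m <- nrow(V)
  ph_pos <- hidden_given_visible(params, V)
  h <- (matrix(stats::runif(length(ph_pos)), m) < ph_pos) * 1
  Vn <- V
  for (k in seq_len(config$cd_k)) {
    Vn <- sample_visible(params, h)
    ph_neg <- hidden_given_visible(params, Vn)
    if (k < config$cd_k) {
      h <- (matrix(stats::runif(length(ph_neg)), m) < ph_neg) * 1
    }
  }
  gW <- (crossprod(V, ph_pos) - crossprod(Vn, ph_neg)) / m -
    config$weight_decay * params$W
  ga <- colMeans(V) - colMeans(Vn)
  gb <- colMeans(ph_pos) - colMeans(ph_neg)
  if (!all(is.finite(gW), is.finite(ga), is.finite(gb))) {
    stop("non-finite gradient in CD update (diverged); lower the learning rate",
         call. = FALSE)
  }
  vel <- params$velocity %||% list(W = 0 * params$W, a = 0 * params$a,
                                   b = 0 * params$b)
  vel$W <- config$momentum * vel$W + config$learning_rate * gW
  vel$a <- config$momentum * vel$a + config$learning_rate * ga
  vel$b <- config$momentum * vel$b + config$learning_rate * gb
  params$W <- params$W + vel$W
  params$a <- params$a + vel$a
  params$b <- params$b + vel$b
  params$velocity <- vel
  params
}

#' Train an RBM by contrastive divergence
#'
#' @param x samples x visible matrix (standardized when
#'   `visible_kind = "gaussian"`).
#' @param config a [train_config()].
#' @param visible_kind visible unit type.
#' @return trained `rbm` with a `loss_trace` attribute (per-epoch mean
#'   squared reconstruction error).
#' @export
train_rbm <- function(x, config = train_config(),
                      visible_kind = c("gaussian", "binary")) {
  visible_kind <- match.arg(visible_kind)
  x <- as.matrix(x)
  params <- rbm_params(ncol(x), config$n_hidden, visible_kind,
                       seed = config$seed)
  if (visible_kind == "gaussian") params$a <- colMeans(x)
  n <- nrow(x)
  loss <- numeric(config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      err <- 0
      for (idx in batches) {
        params <- cd_update(params, x[idx, , drop = FALSE], config)
      }
      ph <- hidden_given_visible(params, x)
      recon <- visible_given_hidden(params, ph)
      rec <- if (visible_kind == "gaussian") recon$mean else recon$prob
      loss[ep] <- mean((x - rec)^2)
      if (!is.finite(loss[ep]) || (ep > 1 && loss[ep] > 1e3 * loss[1])) {
        stop("training diverged (reconstruction error exploded)",
             call. = FALSE)
      }
    }
  })
  params$velocity <- NULL
  attr(params, "loss_trace") <- loss
  params
}

# --- exact small-model oracles ------------------------------------------

# all binary vectors of length n as a 2^n x n matrix
enumerate_bits <- function(n) {
  if (n == 0) return(matrix(numeric(0), 1, 0))
  as.matrix(expand.grid(rep(list(c(0, 1)), n)))[, n:1, drop = FALSE]
}

#' Exact average log-likelihood of an RBM (enumeration oracle)
#'
#' Brute-force normalization: binary models enumerate all visible and hidden
#' configurations; Gaussian-visible models enumerate hiddens and integrate
#' the visibles analytically. Feasible only for small models (the joint
#' enumeration is capped at 2^20 configurations).
#'
#' @param params an `rbm`.
#' @param data samples x visible matrix.
#' @return mean log-likelihood of the rows of `data`.
#' @export
exact_loglik <- function(params, data) {
  data <- as.matrix(data)
  nv <- nrow(params$W); nh <- ncol(params$W)
  if (params$visible_kind == "binary" && nv + nh > 20) {
    stop("enumeration limited to nv + nh <= 20 for binary models",
         call. = FALSE)
  }
  if (params$visible_kind == "gaussian" && nh > 20) {
    stop("enumeration limited to n_hidden <= 20 for gaussian models",
         call. = FALSE)
  }
  H <- enumerate_bits(nh)
  if (params$visible_kind == "binary") {
    V <- enumerate_bits(nv)
    # log sum over h of exp(-E(v,h)) for every v in rows of M
    log_unnorm <- function(M) {
      base <- as.numeric(M %*% params$a)
      act <- sweep(M %*% params$W, 2, params$b, "+")
      base + rowSums(softplus(act))
    }
    logZ <- logsumexp(log_unnorm(V))
    log_unnorm(data) - logZ
  } else {
    # integrate v analytically per h:
    # int exp(-E) dv = (2pi)^(nv/2) exp(b'h + ||a + Wh||^2/2 - ||a||^2/2)
    act_h <- function(Hm) {
      mu <- sweep(Hm %*% t(params$W), 2, params$a, "+")
      as.numeric(Hm %*% params$b) + 0.5 * rowSums(mu^2) -
        0.5 * sum(params$a^2)
    }
    logZ <- 0.5 * nv * log(2 * pi) + logsumexp(act_h(H))
    # log sum_h exp(-E(v, h)) per data row
    quad <- -0.5 * rowSums(sweep(data, 2, params$a, "-")^2)
    act <- sweep(data %*% params$W, 2, params$b, "+")
    quad + rowSums(softplus(act)) - logZ
  }
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Exact log-likelihood gradient of a binary RBM (enumeration oracle)
#'
#' Data expectations use `p(h|v)`; model expectations come from the fully
#' enumerated joint. Used to validate the direction of stochastic CD
#' updates on tiny models.
#'
#' @param params a binary-visible `rbm` (small).
#' @param data samples x visible 0/1 matrix.
#' @return list with gradients `W`, `a`, `b`.
#' @export
exact_grad <- function(params, data) {
  stopifnot(params$visible_kind == "binary")
  data <- as.matrix(data)
  nv <- nrow(params$W); nh <- ncol(params$W)
  if (nv + nh > 20) stop("model too large for enumeration", call. = FALSE)
  V <- enumerate_bits(nv)
  log_unnorm <- as.numeric(V %*% params$a) +
    rowSums(softplus(sweep(V %*% params$W, 2, params$b, "+")))
  pv <- exp(log_unnorm - logsumexp(log_unnorm))
  ph_V <- hidden_given_visible(params, V)
  ph_d <- hidden_given_visible(params, data)
  list(
    W = crossprod(data, ph_d) / nrow(data) - crossprod(V * pv, ph_V),
    a = colMeans(data) - as.numeric(pv %*% V),
    b = colMeans(ph_d) - as.numeric(pv %*% ph_V)
  )
}
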