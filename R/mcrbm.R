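#' Mean-covariance RBM parameters
#'
#' Third-order factored energy model with Gaussian visibles and two sets of
#' binary latent units: *mean* units shaping the conditional mean and
#' *precision* units gating the conditional covariance through factor
#' loadings. With visible vector `v`, mean units `h_m` and precision units
#' `h_c`, the energy is
#'
#' ```
#' E(v, h_m, h_c) = (1/2)||v - a||^2 - b_m' h_m - v' W h_m
#'                  - (1/2) sum_k h_ck sum_f P_fk (C_.f' v)^2 - b_c' h_c
#' ```
#'
#' with all pooling entries `P_fk <= 0`, so every active precision unit
#' *adds* positive-definite curvature `C diag(-P h_c) C'` to the visible
#' precision and the density stays proper. Conditioned on `(h_m, h_c)` the
#' visibles are exactly jointly Gaussian (see
#' [mcrbm_conditional_gaussian()]), so each binary latent vector indexes one
#' Gaussian mode of the modeled distribution. The visible vector enters the
#' covariance term unnormalized, which is what keeps that conditional exact;
#' see the methods vignette for the relation to length-normalized variants.
#'
#' @param n_visible visible units (neurons).
#' @param n_mean mean units.
#' @param n_factors covariance factors.
#' @param n_precision precision units; when `n_factors` is a multiple, `P`
#'   is initialized as block pooling (each precision unit pools a contiguous
#'   block of factors at weight -1), otherwise as uniform negative values.
#' @param seed,init_sd weight initialization.
#' @return object of class `mcrbm` with fields `W`, `a`, `b_m`, `C`, `P`,
#'   `b_c`.
#' @export
mcrbm_params <- function(n_visible, n_mean = 16, n_factors = 64,
                         n_precision = 16, seed = 1, init_sd = 0.02) {
  with_seed(seed, {
    W <- matrix(stats::rnorm(n_visible * n_mean, 0, init_sd),
                n_visible, n_mean)
    C <- matrix(stats::rnorm(n_visible * n_factors, 0, init_sd),
                n_visible, n_factors)
    if (n_factors %% n_precision == 0) {
      P <- matrix(0, n_factors, n_precision)
      per <- n_factors %/% n_precision
      for (k in seq_len(n_precision)) {
        P[((k - 1) * per + 1):(k * per), k] <- -1
      }
    } else {
      P <- -matrix(stats::runif(n_factors * n_precision, 0, 1 / n_precision),
                   n_factors, n_precision)
    }
    structure(list(
      W = W, a = numeric(n_visible), b_m = numeric(n_mean),
      C = C, P = P, b_c = rep(1, n_precision)
    ), class = "mcrbm")
  })
}

#' @export
print.mcrbm <- function(x, ...) {
  cat(sprintf("<mcrbm> %d visibles, %d mean units, %d factors, %d precision units\n",
              nrow(x$W), ncol(x$W), ncol(x$C), ncol(x$P)))
  invisible(x)
}

#' Latent activation probabilities of a mean-covariance RBM
#'
#' Mean units: `p(h_mj = 1 | v) = logistic(b_mj + v'W_.j)`. Precision units:
#' `p(h_ck = 1 | v) = logistic(b_ck + (1/2) sum_f P_fk (C_.f' v)^2)`.
#'
#' @param params an `mcrbm`.
#' @param v visible vector or samples x visible matrix.
#' @return list with matrices `mean` and `precision` (samples x units).
#' @export
mcrbm_hidden_probs <- function(params, v) {
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  if (ncol(V) != nrow(params$W)) stop("dimension mismatch", call. = FALSE)
  pm <- sigmoid(sweep(V %*% params$W, 2, params$b_m, "+"))
  eta <- sweep(0.5 * (V %*% params$C)^2 %*% params$P, 2, params$b_c, "+")
  list(mean = pm, precision = sigmoid(eta))
}

#' Free energy of visibles under a mean-covariance RBM
#'
#' `F(v) = (1/2)||v - a||^2 - sum_j softplus(b_mj + v'W_.j)
#'         - sum_k softplus(b_ck + (1/2) sum_f P_fk (C_.f'v)^2)`,
#' i.e. `p(v) propto exp(-F(v))` with both latent sets marginalized.
#'
#' @param params an `mcrbm`.
#' @param v visible vector or samples x visible matrix.
#' @return numeric vector of free energies (one per row).
#' @export
mcrbm_free_energy <- function(params, v) {
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  quad <- 0.5 * rowSums(sweep(V, 2, params$a, "-")^2)
  mterm <- rowSums(softplus(sweep(V %*% params$W, 2, params$b_m, "+")))
  cterm <- rowSums(softplus(
    sweep(0.5 * (V %*% params$C)^2 %*% params$P, 2, params$b_c, "+")))
  quad - mterm - cterm
}

#' Gradient of the mean-covariance free energy w.r.t. the visibles
#'
#' Used by the hybrid Monte Carlo negative phase.
#'
#' @param params an `mcrbm`.
#' @param V samples x visible matrix.
#' @return samples x visible matrix of gradients.
#' @export
mcrbm_free_energy_grad <- function(params, V) {
  probs <- mcrbm_hidden_probs(params, V)
  VC <- V %*% params$C
  sweep(V, 2, params$a, "-") -
    probs$mean %*% t(params$W) -
    (VC * (probs$precision %*% t(params$P))) %*% t(params$C)
}

#' Conditional Gaussian of visibles given the binary latents
#'
#' Given mean units `h_m` and precision units `h_c`, the visibles are
#' Gaussian with precision `M = I + C diag(s) C'` where
#' `s_f = -sum_k P_fk h_ck >= 0`, and mean `M^{-1} (a + W h_m)`. The
#' identity term is the unit-variance Gaussian-visible base case; with all
#' precision units off the covariance is exactly the identity.
#'
#' @param params an `mcrbm`.
#' @param h_mean binary mean-unit vector.
#' @param h_precision binary precision-unit vector.
#' @return list with `mean` (vector) and `cov` (symmetric positive-definite
#'   matrix).
#' @export
mcrbm_conditional_gaussian <- function(params, h_mean, h_precision) {
  stopifnot(length(h_mean) == ncol(params$W),
            length(h_precision) == ncol(params$P))
  s <- as.numeric(-params$P %*% h_precision)
  if (any(s < 0)) stop("pooling matrix P must be nonpositive", call. = FALSE)
  nv <- nrow(params$W)
  M <- diag(nv) + params$C %*% (s * t(params$C))
  L <- chol(M)
  cov <- chol2inv(L)
  mu <- as.numeric(cov %*% (params$a + params$W %*% h_mean))
  list(mean = mu, cov = (cov + t(cov)) / 2)
}

# One Gibbs sweep on the negative particles: sample both latent sets, then
# the exact conditional Gaussian per sample. O(n_visible^3) per sample.
mcrbm_gibbs_sweep <- function(params, V) {
  probs <- mcrbm_hidden_probs(params, V)
  Hm <- (matrix(stats::runif(length(probs$mean)), nrow(V)) < probs$mean) * 1
  Hc <- (matrix(stats::runif(length(probs$precision)), nrow(V)) <
           probs$precision) * 1
  out <- V
  for (i in seq_len(nrow(V))) {
    g <- mcrbm_conditional_gaussian(params, Hm[i, ], Hc[i, ])
    # chol() is upper triangular R with cov = R'R, so R'z has covariance cov
    out[i, ] <- g$mean +
      as.numeric(t(chol(g$cov)) %*% stats::rnorm(ncol(V)))
  }
  out
}

# Hybrid Monte Carlo on the marginal free energy: one trajectory of
# `n_leapfrog` steps per particle, per-particle Metropolis correction.
# Returns the particles and the acceptance rate (for step-size adaptation).
mcrbm_hmc <- function(params, V, eps, n_leapfrog = 20) {
  m <- nrow(V); nv <- ncol(V)
  P0 <- matrix(stats::rnorm(m * nv), m, nv)
  Vc <- V; Pc <- P0
  Pc <- Pc - 0.5 * eps * mcrbm_free_energy_grad(params, Vc)
  for (l in seq_len(n_leapfrog)) {
    Vc <- Vc + eps * Pc
    g <- mcrbm_free_energy_grad(params, Vc)
    if (l < n_leapfrog) Pc <- Pc - eps * g else Pc <- Pc - 0.5 * eps * g
  }
  H0 <- mcrbm_free_energy(params, V) + 0.5 * rowSums(P0^2)
  H1 <- mcrbm_free_energy(params, Vc) + 0.5 * rowSums(Pc^2)
  acc <- stats::runif(m) < exp(pmin(0, H0 - H1))
  acc[!is.finite(H1)] <- FALSE
  V[acc, ] <- Vc[acc, ]
  list(V = V, accept_rate = mean(acc))
}

# Free-energy derivatives w.r.t. parameters, averaged over rows of V.
# Log-likelihood gradient = stats(data) - stats(model particles).
mcrbm_suff_stats <- function(params, V) {
  m <- nrow(V)
  probs <- mcrbm_hidden_probs(params, V)
  VC <- V %*% params$C
  Q <- VC * (probs$precision %*% t(params$P))
  list(
    W = crossprod(V, probs$mean) / m,
    a = colMeans(V),
    b_m = colMeans(probs$mean),
    C = crossprod(V, Q) / m,
    P = 0.5 * crossprod(VC^2, probs$precision) / m,
    b_c = colMeans(probs$precision)
  )
}

#' One contrastive-divergence update of a mean-covariance RBM
#'
#' Positive statistics from the data minibatch; negative statistics from
#' particles initialized at the data and advanced either by one hybrid
#' Monte Carlo trajectory on the marginal free energy (default; latents
#' integrated out) or by `cd_k` blocked Gibbs sweeps through the exact
#' conditionals. After the update the pooling matrix is projected back onto
#' `P <= 0`.
#'
#' @param params an `mcrbm` (velocities and the adaptive HMC step size ride
#'   along in `params$velocity` / `params$hmc_eps`).
#' @param minibatch samples x visible matrix (standardized).
#' @param config a [train_config()].
#' @param negative_phase `"hmc"` or `"gibbs"`.
#' @return updated `mcrbm`.
#' @export
mcrbm_cd_update <- function(params, minibatch, config,
                            negative_phase = c("hmc", "gibbs")) {
  negative_phase <- match.arg(negative_phase)
  V <- as.matrix(minibatch)
  if (negative_phase == "hmc") {
    eps <- params$hmc_eps %||% 0.05
    hmc <- mcrbm_hmc(params, V, eps)
    Vn <- hmc$V
    params$hmc_eps <- max(1e-4, min(0.5,
      if (hmc$accept_rate > 0.9) eps * 1.05 else eps * 0.95))
  } else {
    Vn <- V
    for (k in seq_len(config$cd_k)) Vn <- mcrbm_gibbs_sweep(params, Vn)
  }
  pos <- mcrbm_suff_stats(params, V)
  neg <- mcrbm_suff_stats(params, Vn)
  grad <- list(
    W = pos$W - neg$W - config$weight_decay * params$W,
    a = pos$a - neg$a,
    b_m = pos$b_m - neg$b_m,
    C = pos$C - neg$C - config$weight_decay * params$C,
    P = pos$P - neg$P,
    b_c = pos$b_c - neg$b_c
  )
  if (!all(vapply(grad, function(g) all(is.finite(g)), logical(1)))) {
    stop("non-finite gradient in mcRBM update (diverged)", call. = FALSE)
  }
  vel <- params$velocity %||% lapply(grad, function(g) 0 * g)
  for (nm in names(grad)) {
    vel[[nm]] <- config$momentum * vel[[nm]] +
      config$learning_rate * grad[[nm]]
    params[[nm]] <- params[[nm]] + vel[[nm]]
  }
  params$P <- pmin(params$P, 0)
  params$velocity <- vel
  params
}

#' Train a mean-covariance RBM
#'
#' Contrastive divergence with an HMC (default) or Gibbs negative phase.
#' Input rows must be standardized (mean 0, s.d. 1 per visible), matching
#' the unit-variance Gaussian base term of the energy. Training aborts with
#' the last stable parameters if the reconstruction error explodes.
#'
#' @param x samples x neurons matrix (standardized), e.g. from
#'   [as_training_matrix()].
#' @param config a [train_config()] (`n_hidden` is the mean-unit count).
#' @param negative_phase `"hmc"` or `"gibbs"`.
#' @return trained `mcrbm` with a `loss_trace` attribute (per-epoch mean
#'   squared error of the conditional-mean reconstruction).
#' @export
train_mcrbm <- function(x, config = train_config(),
                        negative_phase = c("hmc", "gibbs")) {
  negative_phase <- match.arg(negative_phase)
  x <- as.matrix(x)
  params <- mcrbm_params(ncol(x), n_mean = config$n_hidden,
                         n_factors = config$n_factors,
                         n_precision = config$n_precision,
                         seed = config$seed)
  n <- nrow(x)
  loss <- numeric(config$epochs)
  recon_err <- function(p) {
    probs <- mcrbm_hidden_probs(p, x)
    mu <- t(vapply(seq_len(nrow(x)), function(i) {
      mcrbm_conditional_gaussian(p, round(probs$mean[i, ]),
                                 round(probs$precision[i, ]))$mean
    }, numeric(ncol(x))))
    mean((x - mu)^2)
  }
  with_seed(config$seed, {
    last_stable <- params
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (idx in batches) {
        params <- tryCatch(
          mcrbm_cd_update(params, x[idx, , drop = FALSE], config,
                          negative_phase),
          error = function(e) {
            stop(sprintf(
              "mcRBM training diverged at epoch %d; last stable checkpoint kept (%s)",
              ep, conditionMessage(e)), call. = FALSE)
          })
      }
      # cheap divergence proxy: mean free energy must stay finite
      fe <- mean(mcrbm_free_energy(params, x))
      loss[ep] <- fe
      if (!is.finite(fe)) {
        params <- last_stable
        stop(sprintf("mcRBM training diverged at epoch %d", ep),
             call. = FALSE)
      }
      last_stable <- params
    }
  })
  params$velocity <- NULL
  attr(params, "loss_trace") <- loss
  attr(params, "final_recon_mse") <- recon_err(params)
  params
}
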