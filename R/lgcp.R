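#' Bin spike trains into counts
#'
#' Half-open convention: a spike at time `t` falls in bin
#' `floor(t / bin_width)`, so a spike exactly on a boundary belongs to the
#' later bin. A spike at exactly the recording duration is placed in the
#' last bin.
#'
#' @param spike_train_set a `spike_train_set`.
#' @param bin_width_s bin width in seconds (> 0).
#' @return integer matrix, neurons x bins; total count equals the number of
#'   input spikes. An empty spike set yields an all-zero matrix with a
#'   warning.
#' @export
bin_spikes <- function(spike_train_set, bin_width_s) {
  stopifnot(inherits(spike_train_set, "spike_train_set"))
  assert_scalar_positive(bin_width_s, "bin_width_s")
  sts <- spike_train_set
  n_bins <- max(1L, as.integer(ceiling(sts$duration_s / bin_width_s - 1e-9)))
  counts <- matrix(0L, length(sts$spikes), n_bins,
                   dimnames = list(sts$neuron_ids, NULL))
  if (sum(lengths(sts$spikes)) == 0L) {
    warning("no spikes in input; returning all-zero count matrix")
    return(counts)
  }
  for (i in seq_along(sts$spikes)) {
    tt <- sts$spikes[[i]]
    if (!length(tt)) next
    b <- pmin(floor(tt / bin_width_s) + 1L, n_bins)
    tab <- tabulate(b, nbins = n_bins)
    counts[i, ] <- tab
  }
  counts
}

# Squared-exponential kernel matrix on bin centers (plus jitter).
se_kernel <- function(n_bins, bin_width_s, lengthscale_s, variance) {
  t <- (seq_len(n_bins) - 0.5) * bin_width_s
  d2 <- outer(t, t, function(a, b) (a - b)^2)
  variance * exp(-d2 / (2 * lengthscale_s^2)) + diag(1e-6, n_bins)
}

# Laplace/Newton MAP for one neuron on one chunk of bins.
# Model: y_b ~ Poisson(exp(g_b) * dt), g ~ GP(m, K); returns ghat = m + fhat.
lgcp_map_chunk <- function(y, dt, K, m, max_iter = 50, tol = 1e-8) {
  n <- length(y)
  f <- numeric(n)
  sW_solve <- function(L, sW, Kb) {
    backsolve(L, forwardsolve(t(L), sW * Kb))
  }
  obj <- function(f, a) {
    sum(y * (m + f)) - dt * sum(exp(m + f)) - 0.5 * sum(f * a)
  }
  a <- numeric(n)
  psi_old <- obj(f, a)
  for (it in seq_len(max_iter)) {
    mu <- dt * exp(m + f)
    W <- mu
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * K
    L <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(L)) {
      return(list(converged = FALSE, reason = "Cholesky failure", iter = it))
    }
    b <- W * f + (y - mu)
    Kb <- as.numeric(K %*% b)
    a_new <- b - sW * sW_solve(L, sW, Kb)
    f_new <- as.numeric(K %*% a_new)
    # backtracking toward the old iterate if the objective worsens
    step <- 1
    psi_new <- obj(f_new, a_new)
    while (!is.finite(psi_new) || psi_new < psi_old - 1e-12) {
      step <- step / 2
      if (step < 1e-4) break
      f_try <- f + step * (f_new - f)
      a_try <- a + step * (a_new - a)
      psi_new <- obj(f_try, a_try)
      f_new <- f_try; a_new <- a_try
    }
    delta <- max(abs(f_new - f))
    f <- f_new; a <- a_new
    conv <- is.finite(psi_new) && (abs(psi_new - psi_old) < tol || delta < 1e-7)
    psi_old <- psi_new
    if (conv) {
      return(list(converged = TRUE, g = m + f, iter = it))
    }
  }
  list(converged = FALSE, reason = "max iterations reached", iter = max_iter)
}

#' Log-Gaussian Cox process firing-rate inference (MAP)
#'
#' Infers a smooth positive firing rate per neuron from binned spike counts
#' under a log-Gaussian Cox process: counts are Poisson given the intensity,
#' and the log-intensity has a Gaussian-process prior with a
#' squared-exponential kernel. The posterior mode is found by a damped
#' Newton (Laplace) iteration. Long recordings are fit in overlapping
#' chunks and stitched on chunk interiors; the overlap (several kernel
#' lengthscales) makes the seams numerically invisible.
#'
#' @param counts nonnegative integer matrix (neurons x bins), e.g. from
#'   [bin_spikes()].
#' @param bin_width_s bin width in seconds.
#' @param kernel_lengthscale_s prior correlation length (default 0.25 s).
#' @param kernel_variance prior variance of the log-rate (default 1).
#' @param mean_log_rate prior mean of the log-rate (log Hz); scalar, vector
#'   (per neuron) or `NULL` for the per-neuron empirical value
#'   `log((total + 0.5) / duration)`.
#' @param chunk_bins,overlap_bins chunking of long recordings.
#' @param max_iter Newton iteration cap; non-convergence of any neuron is an
#'   error (no partial output).
#' @return a [rate_matrix()] of strictly positive rates in Hz.
#' @export
lgcp_fit <- function(counts, bin_width_s, kernel_lengthscale_s = 0.25,
                     kernel_variance = 1, mean_log_rate = NULL,
                     chunk_bins = 400L, overlap_bins = 60L, max_iter = 50L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be nonnegative integers", call. = FALSE)
  }
  assert_scalar_positive(bin_width_s, "bin_width_s")
  n <- nrow(counts); nb <- ncol(counts)
  duration <- nb * bin_width_s
  if (is.null(mean_log_rate)) {
    mean_log_rate <- log((rowSums(counts) + 0.5) / duration)
  }
  mean_log_rate <- rep_len(mean_log_rate, n)

  # chunk layout: cores tile the bins; each fit extends `overlap` both sides
  chunk_bins <- max(64L, as.integer(chunk_bins))
  n_chunks <- max(1L, as.integer(ceiling(nb / chunk_bins)))
  core_edges <- round(seq(0L, nb, length.out = n_chunks + 1L))
  kernels <- new.env()
  K_for <- function(len) {
    key <- as.character(len)
    if (is.null(kernels[[key]])) {
      kernels[[key]] <- se_kernel(len, bin_width_s, kernel_lengthscale_s,
                                  kernel_variance)
    }
    kernels[[key]]
  }

  G <- matrix(0, n, nb)
  for (ci in seq_len(n_chunks)) {
    core <- (core_edges[ci] + 1L):core_edges[ci + 1L]
    lo <- max(1L, core[1L] - overlap_bins)
    hi <- min(nb, core[length(core)] + overlap_bins)
    idx <- lo:hi
    K <- K_for(length(idx))
    for (i in seq_len(n)) {
      fit <- lgcp_map_chunk(counts[i, idx], bin_width_s, K,
                            mean_log_rate[i], max_iter = max_iter)
      if (!isTRUE(fit$converged)) {
        stop(sprintf(
          "LGCP MAP did not converge for neuron %d (chunk %d/%d, %s after %d iterations)",
          i, ci, n_chunks, fit$reason, fit$iter), call. = FALSE)
      }
      G[i, core] <- fit$g[core - lo + 1L]
    }
  }
  rate_matrix(exp(G), bin_width_s = bin_width_s,
              neuron_ids = rownames(counts))
}

#' Range of the firing-rate derivative
#'
#' Finite-difference derivative of a rate trace; returns
#' `max(d) - min(d)` in Hz/s. Note a linear ramp has constant derivative and
#' hence range 0, so ramping neurons count as "tonic" under this statistic.
#'
#' @param rate_trace numeric vector (length >= 2), Hz.
#' @param bin_width_s bin width in seconds.
#' @return scalar, Hz/s.
#' @export
derivative_range <- function(rate_trace, bin_width_s) {
  if (length(rate_trace) < 2L) {
    stop("rate trace must have at least 2 bins", call. = FALSE)
  }
  assert_scalar_positive(bin_width_s, "bin_width_s")
  d <- diff(rate_trace) / bin_width_s
  max(d) - min(d)
}

#' Drop silent and tonic neurons
#'
#' Removes neurons whose firing-rate derivative range falls below a fixed
#' threshold, i.e. neurons whose rate is (near-)constant and therefore
#' carries no stimulus information: silent neurons and tonically firing
#' neurons alike.
#'
#' @param rate_matrix a [rate_matrix()].
#' @param threshold minimum derivative range (Hz/s) to keep a neuron
#'   (>= 0). At 0 every neuron is kept.
#' @return list with `rates` (filtered [rate_matrix()]) and `report`
#'   (class `selection_report`: `kept_ids`, `dropped_ids`,
#'   `derivative_range`, `threshold`).
#' @export
select_active_neurons <- function(rate_matrix, threshold) {
  stopifnot(inherits(rate_matrix, "rate_matrix"))
  if (!is.numeric(threshold) || threshold < 0) {
    stop("`threshold` must be >= 0", call. = FALSE)
  }
  dr <- apply(rate_matrix$rates, 1, derivative_range,
              bin_width_s = rate_matrix$bin_width_s)
  keep <- dr >= threshold
  if (!any(keep)) {
    stop("all neurons removed; reduce the selection threshold", call. = FALSE)
  }
  kept_ids <- rate_matrix$neuron_ids[keep]
  report <- structure(list(
    kept_ids = kept_ids,
    dropped_ids = rate_matrix$neuron_ids[!keep],
    derivative_range = stats::setNames(dr, rate_matrix$neuron_ids),
    threshold = threshold
  ), class = "selection_report")
  filtered <- rate_matrix(
    rate_matrix$rates[keep, , drop = FALSE],
    bin_width_s = rate_matrix$bin_width_s,
    neuron_ids = kept_ids,
    time_origin_s = rate_matrix$time_origin_s,
    electrode_xy = if (!is.null(rate_matrix$electrode_xy)) {
      rate_matrix$electrode_xy[keep, , drop = FALSE]
    }
  )
  list(rates = filtered, report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> kept %d / %d neurons (threshold %g Hz/s)\n",
              length(x$kept_ids),
              length(x$kept_ids) + length(x$dropped_ids), x$threshold))
  invisible(x)
}
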