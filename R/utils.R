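# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow for large x
softplus <- function(x) {
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  out
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded operations do not perturb surrounding
#' stochastic code. With `seed = NULL` the code runs on the ambient RNG.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Smooth stationary Gaussian noise on a regular grid: white noise filtered
# with a Gaussian kernel, rescaled to unit marginal variance. Used for the
# doubly-stochastic rate perturbation and for latency jitter.
smooth_gaussian_noise <- function(n, lengthscale_bins) {
  stopifnot(n >= 1, lengthscale_bins > 0)
  half <- max(1L, as.integer(ceiling(4 * lengthscale_bins)))
  k <- stats::dnorm(seq(-half, half), sd = lengthscale_bins)
  k <- k / sqrt(sum(k^2))
  e <- stats::rnorm(n + 2L * half)
  sm <- stats::filter(e, k, method = "convolution", sides = 2)
  as.numeric(sm[(half + 1L):(half + n)])
}

assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

# Translate a matrix by (dr, dc) with zero fill (content moves down/right
# for positive shifts).
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Encode 0/1 rows as a numeric id (exact for <= 52 bits; bit j has weight 2^j)
encode_state_id <- function(bits) {
  n_units <- ncol(bits)
  if (n_units > 52L) {
    stop("state ids are exact only up to 52 latent units", call. = FALSE)
  }
  as.numeric(bits %*% (2^(seq_len(n_units) - 1)))
}
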