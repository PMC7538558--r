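#' Firing-rate matrix
#'
#' Container for neurons x time-bins firing rates (Hz) on a regular grid.
#'
#' @param rates numeric matrix, neurons in rows, time bins in columns; all
#'   entries nonnegative.
#' @param bin_width_s bin width in seconds.
#' @param neuron_ids row identifiers (default `n0001`, ...).
#' @param time_origin_s time of the left edge of the first bin.
#' @param electrode_xy optional two-column matrix of lattice coordinates.
#' @return object of class `rate_matrix`.
#' @export
rate_matrix <- function(rates, bin_width_s, neuron_ids = NULL,
                        time_origin_s = 0, electrode_xy = NULL) {
  rates <- as.matrix(rates)
  assert_scalar_positive(bin_width_s, "bin_width_s")
  if (any(rates < 0)) stop("rates must be nonnegative", call. = FALSE)
  if (is.null(neuron_ids)) neuron_ids <- sprintf("n%04d", seq_len(nrow(rates)))
  stopifnot(length(neuron_ids) == nrow(rates))
  rownames(rates) <- neuron_ids
  structure(list(
    rates = rates,
    bin_width_s = bin_width_s,
    neuron_ids = neuron_ids,
    time_origin_s = time_origin_s,
    electrode_xy = electrode_xy
  ), class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix> %d neurons x %d bins (bin %.4g s, %.1f s total)\n",
              nrow(x$rates), ncol(x$rates), x$bin_width_s,
              ncol(x$rates) * x$bin_width_s))
  invisible(x)
}

#' Row-standardize a firing-rate matrix
#'
#' Centers and scales each neuron's rate trace to mean 0 and s.d. 1, the
#' scale assumed by the Gaussian-visible energy models (which fix unit noise
#' variance). The per-neuron statistics are returned for the inverse
#' transform.
#'
#' @param rate_matrix a [rate_matrix()] (rows must have nonzero variance) or
#'   a plain numeric matrix.
#' @return list with `x` (standardized neurons x bins matrix), `center`,
#'   `scale` (per-neuron), class `standardized_rates`.
#' @export
standardize_rates <- function(rate_matrix) {
  R <- if (inherits(rate_matrix, "rate_matrix")) rate_matrix$rates
       else as.matrix(rate_matrix)
  center <- rowMeans(R)
  scale <- apply(R, 1, stats::sd)
  if (any(scale == 0 | !is.finite(scale))) {
    bad <- which(scale == 0 | !is.finite(scale))
    stop(sprintf(
      "zero-variance rows (should have been filtered): %s",
      paste(utils::head(rownames(R)[bad], 5), collapse = ", ")), call. = FALSE)
  }
  x <- (R - center) / scale
  structure(list(x = x, center = center, scale = scale),
            class = "standardized_rates")
}

#' Invert [standardize_rates()]
#' @param std a `standardized_rates` object.
#' @return the original neurons x bins rate matrix.
#' @export
unstandardize_rates <- function(std) {
  stopifnot(inherits(std, "standardized_rates"))
  std$x * std$scale + std$center
}

#' Training matrix from standardized rates
#'
#' Energy models take one time sample (the population rate vector) per row.
#' @param std a `standardized_rates` object or neurons x bins matrix.
#' @return samples x neurons matrix.
#' @export
as_training_matrix <- function(std) {
  x <- if (inherits(std, "standardized_rates")) std$x else as.matrix(std)
  t(x)
}
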