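#' Synthetic RGC population
#'
#' A `population_model` is the ground-truth encoder used by the synthetic
#' retina: a linear--nonlinear (LN) cascade per neuron. Each neuron has a
#' difference-of-Gaussians (DoG) receptive field centered on a 64x64
#' electrode/pixel lattice, an ON or OFF polarity, an output gain, a baseline
#' rate and an integer response latency in frames. The model is deliberately
#' simple: it is the minimal encoder that produces stimulus-locked modes in
#' the population rate vector and receptive-field-like unit averages, which
#' is what the downstream latent-variable analysis assumes.
#'
#' @name population_model
NULL

#' Build a synthetic RGC population
#'
#' @param n_neurons number of neurons (>= 1).
#' @param seed RNG seed; the same seed reproduces the model exactly.
#' @param rf_config optional list overriding defaults:
#'   * `lattice` - lattice side (default 64);
#'   * `layout` - `"uniform"` (random lattice sites) or `"jittered_grid"`;
#'   * `region` - `c(row_min, row_max, col_min, col_max)` (0-based, inclusive)
#'     restricting where centers are placed, e.g. one 16x16 electrode patch;
#'   * `center_sigma_px` - DoG center s.d. in pixels (default 6);
#'   * `surround_ratio` - surround/center sigma ratio (default 2);
#'   * `surround_weight` - surround weight relative to center (default 0.9,
#'     i.e. a nearly balanced DoG whose small positive DC lets ON cells
#'     respond to full-field luminance steps while OFF cells modulate on
#'     dark bars);
#'   * `gain_range`, `baseline_range_hz`, `latency_range_frames`,
#'     `on_fraction`.
#' @return object of class `population_model`.
#' @export
build_population <- function(n_neurons, seed = 1, rf_config = list()) {
  if (!is.numeric(n_neurons) || n_neurons < 1) {
    stop("`n_neurons` must be >= 1", call. = FALSE)
  }
  n <- as.integer(n_neurons)
  cfg <- utils::modifyList(list(
    lattice = 64L,
    layout = "uniform",
    region = NULL,
    center_sigma_px = 6,
    surround_ratio = 2,
    surround_weight = 0.9,
    gain_range = c(80, 160),
    baseline_range_hz = c(1, 3),
    latency_range_frames = c(1L, 3L),
    on_fraction = 0.5
  ), rf_config)
  L <- as.integer(cfg$lattice)
  region <- cfg$region %||% c(0L, L - 1L, 0L, L - 1L)

  with_seed(seed, {
    if (identical(cfg$layout, "jittered_grid")) {
      side <- ceiling(sqrt(n))
      rs <- seq(region[1], region[2], length.out = side)
      cs <- seq(region[3], region[4], length.out = side)
      grid <- expand.grid(row = rs, col = cs)[seq_len(n), ]
      jit <- diff(range(rs)) / max(1, side) / 2
      rows <- round(grid$row + stats::runif(n, -jit, jit))
      cols <- round(grid$col + stats::runif(n, -jit, jit))
    } else {
      rows <- sample(seq(region[1], region[2]), n, replace = TRUE)
      cols <- sample(seq(region[3], region[4]), n, replace = TRUE)
    }
    rows <- pmin(pmax(rows, 0L), L - 1L)
    cols <- pmin(pmax(cols, 0L), L - 1L)
    pol <- ifelse(stats::runif(n) < cfg$on_fraction, 1, -1)
    gain <- stats::runif(n, cfg$gain_range[1], cfg$gain_range[2])
    baseline <- stats::runif(n, cfg$baseline_range_hz[1],
                             cfg$baseline_range_hz[2])
    latency <- sample(seq(cfg$latency_range_frames[1],
                          cfg$latency_range_frames[2]), n, replace = TRUE)

    structure(list(
      n_neurons = n,
      lattice = L,
      rf_center = cbind(row = as.integer(rows), col = as.integer(cols)),
      polarity = pol,
      center_sigma_px = rep(cfg$center_sigma_px, n),
      surround_ratio = cfg$surround_ratio,
      surround_weight = cfg$surround_weight,
      gain = gain,
      baseline_rate_hz = baseline,
      latency_frames = as.integer(latency),
      latency_jitter_sd = 0,
      position_jitter_sd_px = 0,
      rectification_mix = 0,
      impairment_level = 0L,
      neuron_ids = sprintf("n%04d", seq_len(n)),
      seed = seed
    ), class = "population_model")
  })
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "<population_model> %d neurons on %dx%d lattice (impairment level %d)\n",
    x$n_neurons, x$lattice, x$lattice, x$impairment_level))
  invisible(x)
}

#' Graded encoding impairment
#'
#' Emulates progressive pharmacological impairment of the retina's inhibitory
#' circuitry as a graded loss of spatio-temporal encoding precision through
#' four mechanisms, all monotone in level:
#'
#' * receptive fields widen (level 1: 1.5x, level 2: 2x the baseline center
#'   sigma), coarsening spatial integration;
#' * the receptive-field center acquires slow positional scatter (s.d. 4
#'   and 8 px). This scrambles the spatial phase seen by each neuron in
#'   proportion to the stimulus spatial frequency (8 px is ~90 degrees of
#'   phase at 0.045 cycles/degree but only ~22 degrees at 0.011), so
#'   encoding degrades most where the stimulus is finest;
#' * the response latency acquires slow temporal jitter (s.d. 5 and 8
#'   frames, i.e. at or above the scale of one phase bin of a 1 Hz grating
#'   at 30 Hz), smearing temporal phase at every spatial frequency;
#' * the output nonlinearity loses ON/OFF selectivity (rectification mix
#'   0.5 and 1.0 toward full-wave rectification), the classic
#'   frequency-doubling signature of disinhibition. A fully rectified
#'   response is identical for a grating and its counterphase partner, so
#'   this is the mechanism that makes impaired latent states pool
#'   counterphase stimuli.
#'
#' Level 0 returns the model unchanged.
#'
#' @param population a `population_model`.
#' @param level 0 (none), 1 (partial) or 2 (full blockade analog).
#' @return an impaired copy of the model.
#' @export
apply_impairment <- function(population, level) {
  stopifnot(inherits(population, "population_model"))
  if (!length(level) == 1L || !level %in% c(0, 1, 2)) {
    stop("`level` must be one of 0, 1, 2", call. = FALSE)
  }
  level <- as.integer(level)
  if (level == 0L) return(population)
  widen <- c(1.5, 2)[level]
  pos_sd <- c(4, 8)[level]
  jitter_sd <- c(5, 8)[level]
  mix <- c(0.5, 1)[level]
  out <- population
  out$center_sigma_px <- population$center_sigma_px * widen
  out$position_jitter_sd_px <- pos_sd
  out$latency_jitter_sd <- jitter_sd
  out$rectification_mix <- mix
  out$impairment_level <- level
  out
}

# Dense receptive-field weight matrix, n_neurons x (H*W), for frames of the
# lattice size. Center and surround Gaussians are renormalized to their
# in-frame mass so DC response does not depend on boundary clipping.
rf_weight_matrix <- function(population) {
  L <- population$lattice
  px_r <- seq_len(L) - 1
  px_c <- seq_len(L) - 1
  n <- population$n_neurons
  K <- matrix(0, n, L * L)
  for (i in seq_len(n)) {
    s_c <- population$center_sigma_px[i]
    s_s <- s_c * population$surround_ratio
    dr2 <- (px_r - population$rf_center[i, "row"])^2
    dc2 <- (px_c - population$rf_center[i, "col"])^2
    gc <- exp(-outer(dr2, dc2, "+") / (2 * s_c^2))
    gs <- exp(-outer(dr2, dc2, "+") / (2 * s_s^2))
    k <- gc / sum(gc) - population$surround_weight * gs / sum(gs)
    K[i, ] <- population$polarity[i] * as.vector(k)
  }
  K
}

#' Simulate firing rates of a population for a stimulus
#'
#' LN-cascade ground truth: with drive
#' `d = <rf_kernel_n, frame_{t - latency_n(t)}>`, the rate is
#' `baseline_n + gain_n * ((1 - mix) * max(0, d) + mix * |d|)`, one rate bin
#' per stimulus frame; `mix` is the impairment's rectification mix (0 when
#' intact, giving a pure half-wave ON/OFF cascade). Under impairment the
#' latency also acquires smooth random jitter over time (seeded), the only
#' stochastic element; an unimpaired model is deterministic.
#'
#' @param population a `population_model`.
#' @param stimulus a `stimulus_sequence` whose frames are
#'   `lattice x lattice` pixels.
#' @param seed seed for latency jitter (ignored when jitter s.d. is 0).
#' @return a [rate_matrix()] with `electrode_xy` attached.
#' @export
simulate_rates <- function(population, stimulus, seed = 1) {
  stopifnot(inherits(population, "population_model"),
            inherits(stimulus, "stimulus_sequence"))
  d <- dim(stimulus$frames)
  if (d[1L] == 0) stop("empty stimulus", call. = FALSE)
  if (d[2L] != population$lattice || d[3L] != population$lattice) {
    stop("stimulus frames must cover the full electrode lattice", call. = FALSE)
  }
  nt <- d[1L]
  L <- population$lattice
  frames_flat <- matrix(stimulus$frames, nrow = nt)  # column-major [t, r, c]
  K <- rf_weight_matrix(population)
  n <- population$n_neurons

  pos_sd <- population$position_jitter_sd_px %||% 0
  lat_sd <- population$latency_jitter_sd %||% 0
  jit <- pos_path <- NULL
  if (lat_sd > 0 || pos_sd > 0) {
    noise <- with_seed(seed, {
      list(
        lat = if (lat_sd > 0) {
          vapply(seq_len(n), function(i)
            smooth_gaussian_noise(nt, 6) * lat_sd, numeric(nt))
        },
        pr = if (pos_sd > 0) {
          vapply(seq_len(n), function(i)
            round(smooth_gaussian_noise(nt, 6) * pos_sd), numeric(nt))
        },
        pc = if (pos_sd > 0) {
          vapply(seq_len(n), function(i)
            round(smooth_gaussian_noise(nt, 6) * pos_sd), numeric(nt))
        }
      )
    })
    jit <- noise$lat
  }

  # drive(t, i) = <kernel_i shifted by the neuron's positional offset at t,
  # frame_t>; offsets are grouped so each distinct shift costs one
  # matrix-vector product over its time bins
  if (pos_sd > 0) {
    drive <- matrix(0, nt, n)
    for (i in seq_len(n)) {
      ki <- matrix(K[i, ], L, L)
      offs <- paste(noise$pr[, i], noise$pc[, i])
      for (o in unique(offs)) {
        sel <- which(offs == o)
        dd <- as.integer(strsplit(o, " ")[[1L]])
        ks <- shift_matrix(ki, dd[1L], dd[2L])
        drive[sel, i] <- frames_flat[sel, , drop = FALSE] %*% as.vector(ks)
      }
    }
  } else {
    drive <- frames_flat %*% t(K)                    # nt x n_neurons
  }

  rates <- matrix(0, n, nt)
  mix <- population$rectification_mix %||% 0
  for (i in seq_len(n)) {
    lat <- rep(population$latency_frames[i], nt)
    if (!is.null(jit)) lat <- lat + round(jit[, i])
    src <- pmin(pmax(seq_len(nt) - lat, 1L), nt)
    d <- drive[src, i]
    rates[i, ] <- population$baseline_rate_hz[i] +
      population$gain[i] * ((1 - mix) * pmax(0, d) + mix * abs(d))
  }
  rate_matrix(rates, bin_width_s = 1 / stimulus$frame_rate_hz,
              neuron_ids = population$neuron_ids,
              electrode_xy = population$rf_center)
}

#' Sample spike trains from firing rates (log-Gaussian Cox process)
#'
#' Spikes are drawn from an inhomogeneous Poisson process whose intensity is
#' piecewise constant over rate bins. With `doubly_stochastic_sd > 0` the
#' log-intensity additionally receives a smooth Gaussian perturbation per
#' neuron (mean-corrected so the expected intensity stays at the input
#' rate), making the generator a log-Gaussian Cox process -- the same model
#' family the rate-inference stage assumes.
#'
#' @param rates a [rate_matrix()] with nonnegative entries.
#' @param seed RNG seed; identical seeds give identical spike trains.
#' @param doubly_stochastic_sd s.d. of the log-intensity perturbation
#'   (0 disables it; lengthscale ~10 bins).
#' @return object of class `spike_train_set`: per-neuron sorted spike times
#'   in seconds, total duration, electrode coordinates and neuron ids.
#' @export
sample_spikes <- function(rates, seed = 1, doubly_stochastic_sd = 0) {
  stopifnot(inherits(rates, "rate_matrix"))
  R <- rates$rates
  if (any(R < 0)) stop("negative rate entries", call. = FALSE)
  n <- nrow(R); nt <- ncol(R); dt <- rates$bin_width_s
  duration <- nt * dt
  spikes <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      lam <- R[i, ]
      if (doubly_stochastic_sd > 0) {
        g <- smooth_gaussian_noise(nt, lengthscale_bins = 10) *
          doubly_stochastic_sd
        lam <- lam * exp(g - doubly_stochastic_sd^2 / 2)
      }
      counts <- stats::rpois(nt, lam * dt)
      if (sum(counts) == 0) return(numeric(0))
      bins <- rep.int(seq_len(nt), counts)
      sort((bins - 1) * dt + stats::runif(length(bins)) * dt)
    })
  })
  names(spikes) <- rates$neuron_ids
  structure(list(
    spikes = spikes,
    duration_s = duration,
    electrode_xy = rates$electrode_xy,
    neuron_ids = rates$neuron_ids
  ), class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d neurons, %.1f s, %d spikes\n",
              length(x$spikes), x$duration_s,
              sum(lengths(x$spikes))))
  invisible(x)
}
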