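# Shared fixtures, all built in code.

# small binary RBM with non-trivial parameters
tiny_binary_rbm <- function(nv = 4, nh = 3, seed = 42) {
  p <- rbm_params(nv, nh, "binary", seed = seed, init_sd = 0.5)
  with_seed_local(seed + 1, {
    p$a <- stats::rnorm(nv, 0, 0.5)
    p$b <- stats::rnorm(nh, 0, 0.5)
  })
  p
}

tiny_mcrbm <- function(nv = 5, nm = 3, nf = 4, np = 2, seed = 42) {
  m <- mcrbm_params(nv, n_mean = nm, n_factors = nf, n_precision = np,
                    seed = seed, init_sd = 0.3)
  with_seed_local(seed + 1, {
    m$a <- stats::rnorm(nv, 0, 0.3)
    m$b_m <- stats::rnorm(nm, 0, 0.3)
    m$b_c <- stats::rnorm(np, 0, 0.5)
  })
  m
}

# evaluate code under a seed without disturbing the test RNG stream
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# all binary vectors of length n (rows), oldest bit first, as in the package
all_bits <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dimnames(m) <- NULL
  m[, n:1, drop = FALSE]
}

# independent hand-coded binary RBM energy (scalar loops, no linear algebra)
binary_energy_loops <- function(p, v, h) {
  e <- 0
  for (i in seq_along(v)) e <- e - p$a[i] * v[i]
  for (j in seq_along(h)) e <- e - p$b[j] * h[j]
  for (i in seq_along(v)) for (j in seq_along(h)) {
    e <- e - v[i] * p$W[i, j] * h[j]
  }
  e
}

# independent mcRBM joint energy (loops over both latent sets)
mcrbm_energy_loops <- function(m, v, hm, hc) {
  e <- 0.5 * sum((v - m$a)^2) - sum(m$b_m * hm) -
    sum(v * (m$W %*% hm)) - sum(m$b_c * hc)
  for (k in seq_along(hc)) {
    if (hc[k] == 0) next
    for (f in seq_len(ncol(m$C))) {
      e <- e - 0.5 * hc[k] * m$P[f, k] * sum(m$C[, f] * v)^2
    }
  }
  e
}

# spike set built directly from a list of spike-time vectors
spike_set <- function(times, duration) {
  structure(list(
    spikes = stats::setNames(times, sprintf("n%04d", seq_along(times))),
    duration_s = duration,
    electrode_xy = NULL,
    neuron_ids = sprintf("n%04d", seq_along(times))
  ), class = "spike_train_set")
}
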