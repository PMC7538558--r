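test_that("mcRBM latent conditionals match brute-force enumeration", {
  m <- tiny_mcrbm()
  v <- c(0.4, -0.2, 1.1, 0.3, -0.8)
  Hm <- all_bits(3); Hc <- all_bits(2)
  w <- matrix(0, nrow(Hm), nrow(Hc))
  for (i in seq_len(nrow(Hm))) for (j in seq_len(nrow(Hc))) {
    w[i, j] <- exp(-mcrbm_energy_loops(m, v, Hm[i, ], Hc[j, ]))
  }
  p_mean <- colSums(Hm * rowSums(w)) / sum(w)
  p_prec <- colSums(Hc * colSums(w)) / sum(w)
  probs <- mcrbm_hidden_probs(m, v)
  expect_equal(as.numeric(probs$mean), p_mean, tolerance = 1e-10)
  expect_equal(as.numeric(probs$precision), p_prec, tolerance = 1e-10)
})

test_that("mcRBM free energy is the exact latent marginalization", {
  m <- tiny_mcrbm()
  v <- c(-0.5, 0.2, 0.9, -1.2, 0.1)
  Hm <- all_bits(3); Hc <- all_bits(2)
  tot <- 0
  for (i in seq_len(nrow(Hm))) for (j in seq_len(nrow(Hc))) {
    tot <- tot + exp(-mcrbm_energy_loops(m, v, Hm[i, ], Hc[j, ]))
  }
  expect_equal(mcrbm_free_energy(m, v), -log(tot), tolerance = 1e-10)
  # and its visible gradient matches central differences
  V <- matrix(c(v, 0.3, -0.1, 0.4, 0.8, -0.6), 2, 5, byrow = TRUE)
  g <- mcrbm_free_energy_grad(m, V)
  eps <- 1e-6
  for (i in 1:2) for (j in 1:5) {
    Vp <- V; Vp[i, j] <- Vp[i, j] + eps
    Vm <- V; Vm[i, j] <- Vm[i, j] - eps
    num <- (mcrbm_free_energy(m, Vp)[i] - mcrbm_free_energy(m, Vm)[i]) /
      (2 * eps)
    expect_equal(g[i, j], num, tolerance = 1e-5)
  }
})

test_that("conditional Gaussian is exact, symmetric and positive definite", {
  m <- tiny_mcrbm(nv = 6, nm = 3, nf = 8, np = 4, seed = 17)
  # all precision units off: identity covariance base case
  off <- mcrbm_conditional_gaussian(m, c(1, 0, 1), rep(0, 4))
  expect_equal(off$cov, diag(6), tolerance = 1e-10)
  expect_equal(off$mean, as.numeric(m$a + m$W %*% c(1, 0, 1)),
               tolerance = 1e-10)
  # exhaustive PD check over every reachable precision configuration
  Hc <- all_bits(4)
  for (j in seq_len(nrow(Hc))) {
    g <- mcrbm_conditional_gaussian(m, c(0, 1, 1), Hc[j, ])
    expect_equal(g$cov, t(g$cov))
    expect_gt(min(eigen(g$cov, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  expect_error({
    bad <- m; bad$P[1, 1] <- 0.5
    mcrbm_conditional_gaussian(bad, c(0, 0, 0), c(1, 0, 0, 0))
  }, "nonpositive")
})

test_that("held-latent Gibbs samples match the analytic Gaussian", {
  m <- tiny_mcrbm(nv = 4, nm = 2, nf = 4, np = 2, seed = 23)
  hm <- c(1, 0); hc <- c(1, 1)
  g <- mcrbm_conditional_gaussian(m, hm, hc)
  draws <- with_seed_local(31, {
    R <- chol(g$cov)
    t(vapply(1:10000, function(i) {
      g$mean + as.numeric(t(R) %*% rnorm(4))
    }, numeric(4)))
  })
  expect_true(all(abs(colMeans(draws) - g$mean) <
                    4 * sqrt(diag(g$cov) / 10000)))
  expect_equal(stats::cov(draws), g$cov, tolerance = 0.08)
})

test_that("mcRBM training recovers well-separated modes and is reproducible", {
  # two Gaussian clusters in 8 dimensions
  x <- with_seed_local(41, {
    mu1 <- rep(c(1.2, -1.2), each = 4)
    rbind(
      matrix(rnorm(150 * 8, 0, 0.3), ncol = 8) + rep(mu1, each = 150),
      matrix(rnorm(150 * 8, 0, 0.3), ncol = 8) - rep(mu1, each = 150)
    )
  })
  x <- scale(x)
  cfg <- train_config(n_hidden = 4, n_factors = 8, n_precision = 4,
                      learning_rate = 0.02, epochs = 40, seed = 6)
  fit <- train_mcrbm(x, cfg)
  fit2 <- train_mcrbm(x, cfg)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$C, fit2$C)
  st <- infer_states(fit, x)
  cen <- mode_census(st)
  expect_gte(nrow(cen), 2L)
  # the top states jointly explain >90% of the samples, split by cluster
  expect_gt(sum(head(cen$fraction, 4)), 0.9)
  cl <- rep(1:2, each = 150)
  expect_gt(normalized_mi(cl, st$state_id)$nmi, 0.8)
})

test_that("Gibbs and HMC negative phases both drive learning", {
  x <- with_seed_local(51, {
    s <- matrix(rnorm(200 * 6), ncol = 6)
    s[, 2] <- s[, 1] * 0.9 + rnorm(200, 0, 0.4)  # correlated pair
    scale(s)
  })
  for (neg in c("hmc", "gibbs")) {
    cfg <- train_config(n_hidden = 4, n_factors = 6, n_precision = 3,
                        learning_rate = 0.02, epochs = 10, seed = 7)
    fit <- train_mcrbm(x, cfg, negative_phase = neg)
    expect_true(all(is.finite(fit$W)))
    expect_true(all(fit$P <= 0))
    expect_lt(attr(fit, "final_recon_mse"), 1.5)
  }
})
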