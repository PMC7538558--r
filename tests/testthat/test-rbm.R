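test_that("RBM energy matches hand evaluation", {
  p <- tiny_binary_rbm()
  expect_equal(rbm_energy(p, rep(0, 4), rep(0, 3)), 0)
  v <- c(1, 0, 1, 1); h <- c(0, 1, 1)
  expect_equal(rbm_energy(p, v, h), binary_energy_loops(p, v, h),
               tolerance = 1e-12)
  pg <- rbm_params(3, 2, "gaussian", seed = 1)
  pg$a <- c(0.5, -1, 2)
  expect_equal(rbm_energy(pg, pg$a, c(0, 0)), 0)
  expect_error(rbm_energy(p, c(1, 0), c(0, 1, 0)), "mismatch")
})

test_that("hidden conditionals match brute-force enumeration", {
  p <- tiny_binary_rbm()
  # degenerate limits
  p0 <- p; p0$W[] <- 0
  expect_equal(as.numeric(hidden_given_visible(p0, c(1, 1, 0, 0))),
               1 / (1 + exp(-p0$b)))
  p00 <- p0; p00$b[] <- 0
  expect_equal(as.numeric(hidden_given_visible(p00, c(1, 0, 1, 0))),
               rep(0.5, 3))
  # oracle: marginal activation from exp(-E) over all hidden configurations
  v <- c(1, 1, 0, 1)
  H <- all_bits(3)
  w <- vapply(seq_len(nrow(H)), function(i) {
    exp(-binary_energy_loops(p, v, H[i, ]))
  }, numeric(1))
  oracle <- colSums(H * w) / sum(w)
  expect_equal(as.numeric(hidden_given_visible(p, v)), oracle,
               tolerance = 1e-12)
})

test_that("visible conditional has the stated mean and unit variance", {
  pg <- rbm_params(4, 2, "gaussian", seed = 3, init_sd = 0.4)
  pg$a <- c(1, -2, 0, 0.5)
  cond <- visible_given_hidden(pg, c(0, 0))
  expect_equal(as.numeric(cond$mean), pg$a)
  h <- c(1, 0)
  mu <- pg$a + pg$W %*% h
  draws <- with_seed_local(8, {
    t(vapply(1:10000, function(i) {
      rgcmodes:::sample_visible(pg, matrix(h, 1))[1, ]
    }, numeric(4)))
  })
  se <- 1 / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - as.numeric(mu)) < 3 * se))
  expect_true(all(abs(apply(draws, 2, sd) - 1) < 0.05))
})

test_that("contrastive divergence follows the exact likelihood gradient", {
  p <- tiny_binary_rbm(nv = 6, nh = 3, seed = 5)
  data <- all_bits(6)[c(1, 8, 23, 41, 64, 13, 50, 29), ]
  cfg <- train_config(n_hidden = 3, learning_rate = 0.05, momentum = 0,
                      weight_decay = 0, epochs = 1)
  # learning rate 0 leaves parameters unchanged
  cfg0 <- cfg; cfg0$learning_rate <- 0
  upd0 <- with_seed_local(1, cd_update(p, data, cfg0))
  expect_equal(upd0$W, p$W)
  expect_equal(upd0$a, p$a)
  # averaged CD-1 direction has positive inner product with the exact gradient
  ex <- exact_grad(p, data)
  acc <- list(W = 0 * p$W, a = 0 * p$a, b = 0 * p$b)
  with_seed_local(99, {
    for (r in 1:500) {
      u <- cd_update(p, data, cfg)
      acc$W <- acc$W + (u$W - p$W)
      acc$a <- acc$a + (u$a - p$a)
      acc$b <- acc$b + (u$b - p$b)
    }
  })
  ip <- sum(acc$W * ex$W) + sum(acc$a * ex$a) + sum(acc$b * ex$b)
  norm <- sqrt(sum(unlist(acc)^2)) * sqrt(sum(unlist(ex)^2))
  expect_gt(ip / norm, 0.5)
})

test_that("exact log-likelihood oracle agrees with naive enumeration", {
  # 1 visible, 1 hidden, all parameters zero: uniform over two states
  p1 <- rbm_params(1, 1, "binary", seed = 1); p1$W[] <- 0
  expect_equal(exact_loglik(p1, matrix(c(0, 1), 2)), c(-log(2), -log(2)))
  # gaussian with W = 0 factorizes into unit gaussians around a
  pg <- rbm_params(3, 2, "gaussian", seed = 2); pg$W[] <- 0
  pg$a <- c(1, 0, -1)
  v <- c(0.2, -0.3, 0.7)
  expect_equal(exact_loglik(pg, matrix(v, 1)),
               sum(dnorm(v, pg$a, 1, log = TRUE)), tolerance = 1e-10)
  # random tiny model vs naive double sum over all (v, h)
  p <- tiny_binary_rbm(nv = 3, nh = 2, seed = 9)
  V <- all_bits(3); H <- all_bits(2)
  Z <- 0
  for (i in seq_len(nrow(V))) for (j in seq_len(nrow(H))) {
    Z <- Z + exp(-binary_energy_loops(p, V[i, ], H[j, ]))
  }
  naive <- vapply(seq_len(nrow(V)), function(i) {
    log(sum(vapply(seq_len(nrow(H)), function(j) {
      exp(-binary_energy_loops(p, V[i, ], H[j, ]))
    }, numeric(1)))) - log(Z)
  }, numeric(1))
  expect_equal(exact_loglik(p, V), naive, tolerance = 1e-12)
  expect_error(exact_loglik(rbm_params(15, 10, "binary"), all_bits(4)),
               "<= 20")
})

test_that("exact log-likelihood increases over CD training on a tiny dataset", {
  data <- all_bits(5)[c(2, 2, 9, 9, 17, 17, 28, 28, 32, 32), ]
  cfg <- train_config(n_hidden = 3, learning_rate = 0.05, momentum = 0.5,
                      weight_decay = 1e-4, batch_size = 5, epochs = 200,
                      seed = 4)
  init <- rbm_params(5, 3, "binary", seed = cfg$seed)
  ll0 <- mean(exact_loglik(init, data))
  fit <- train_rbm(data, cfg, visible_kind = "binary")
  ll1 <- mean(exact_loglik(fit, data))
  expect_gt(ll1, ll0 + 0.2)
})

test_that("Gibbs chain frequencies converge to the Boltzmann distribution", {
  p <- tiny_binary_rbm(nv = 2, nh = 2, seed = 21)
  V <- all_bits(2); H <- all_bits(2)
  joint <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j) {
    exp(-binary_energy_loops(p, V[i, ], H[j, ]))
  }))
  pv <- rowSums(joint) / sum(joint)
  # long alternating Gibbs chain
  counts <- with_seed_local(77, {
    v <- matrix(c(0, 0), 1); tab <- numeric(4)
    for (s in 1:20000) {
      ph <- hidden_given_visible(p, v)
      h <- (matrix(runif(2), 1) < ph) * 1
      v <- rgcmodes:::sample_visible(p, h)
      idx <- 1 + 2 * v[1] + v[2]  # all_bits rows: first element is the MSB
      tab[idx] <- tab[idx] + 1
    }
    tab
  })
  chi2 <- sum((counts - 20000 * pv)^2 / (20000 * pv))
  # 3 df; generous bound accounting for autocorrelation of the chain
  expect_lt(chi2, 30)
})
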