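test_that("counterphase rule fixes the history spacing", {
  # 1 Hz grating sampled at 24 Hz with 12 layers: half period = 12 bins
  expect_equal(crbm_spacing(12, 1, 1 / 24), 1L)
  expect_equal(crbm_spacing(6, 1, 1 / 24), 2L)
  # 30 Hz bins give a fractional spacing: explicit error names the nearest
  err <- tryCatch(crbm_spacing(12, 1, 1 / 30), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "nearest feasible spacing")
})

test_that("dynamic biases reduce to static biases without history input", {
  p <- crbm_params(3, 2, order = 2, frame_spacing = 1, seed = 3)
  p$a <- c(0.5, -1, 2); p$b <- c(0.3, -0.2)
  hist0 <- list(matrix(0, 2, 3), matrix(0, 2, 3))
  dyn <- crbm_dynamic_biases(p, hist0)
  expect_equal(dyn$a_eff, matrix(p$a, 2, 3, byrow = TRUE))
  expect_equal(dyn$b_eff, matrix(p$b, 2, 2, byrow = TRUE))
  # zero A, B with nonzero history: still static
  hist1 <- list(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3))
  dyn1 <- crbm_dynamic_biases(p, hist1)
  expect_equal(dyn1$a_eff, dyn$a_eff)
  expect_error(crbm_dynamic_biases(p, hist1[1]), "2 delayed layers")
})

test_that("dynamic biases match a hand-computed two-frame example", {
  p <- crbm_params(2, 2, order = 2, frame_spacing = 1, seed = 5)
  p$a <- c(1, -1); p$b <- c(0.5, 0)
  p$A[[1]] <- matrix(c(0.1, 0.2, 0.3, 0.4), 2)   # column-major
  p$A[[2]] <- matrix(c(-0.1, 0, 0.05, 0.2), 2)
  p$B[[1]] <- matrix(c(1, 0, 0, 1), 2)
  p$B[[2]] <- matrix(c(0, 0.5, 0.5, 0), 2)
  u1 <- c(2, 3); u2 <- c(-1, 1)
  dyn <- crbm_dynamic_biases(p, list(matrix(u1, 1), matrix(u2, 1)))
  a_hand <- p$a + p$A[[1]] %*% u1 + p$A[[2]] %*% u2
  b_hand <- p$b + t(p$B[[1]]) %*% u1 + t(p$B[[2]]) %*% u2
  # scalar-loop cross-check of the first component
  a1 <- p$a[1] + p$A[[1]][1, 1] * u1[1] + p$A[[1]][1, 2] * u1[2] +
    p$A[[2]][1, 1] * u2[1] + p$A[[2]][1, 2] * u2[2]
  expect_equal(as.numeric(dyn$a_eff), as.numeric(a_hand))
  expect_equal(as.numeric(dyn$b_eff), as.numeric(b_hand))
  expect_equal(dyn$a_eff[1, 1], a1)
})

test_that("history windows align delays correctly", {
  x <- matrix(seq_len(20), ncol = 1)  # sample t holds the value t
  win <- crbm_history(x, order = 3, spacing = 2)
  expect_equal(win$index, 7:20)
  expect_equal(win$present[, 1], 7:20)
  expect_equal(win$history[[1]][, 1], 5:18)   # delay 2
  expect_equal(win$history[[3]][, 1], 1:14)   # delay 6 (most delayed)
  expect_error(crbm_history(x, order = 10, spacing = 2), "not enough")
})

test_that("cRBM conditional likelihood improves with training", {
  # order-2 autoregressive data with a flip dynamic
  x <- with_seed_local(61, {
    n <- 240
    z <- matrix(0, n, 3)
    for (t in 3:n) {
      z[t, ] <- 0.8 * z[t - 1, ] - 0.4 * z[t - 2, ] + rnorm(3, 0, 0.5)
    }
    scale(z)
  })
  cfg <- train_config(n_hidden = 2, learning_rate = 0.02, momentum = 0.5,
                      batch_size = 32, epochs = 60, seed = 8)
  init <- crbm_params(3, 2, order = 2, frame_spacing = 1, seed = cfg$seed)
  init$a <- colMeans(x)
  fit <- train_crbm(x, order = 2, config = cfg, spacing = 1)

  # exact conditional log-likelihood via hidden enumeration per sample
  cond_ll <- function(p, x) {
    win <- crbm_history(x, p$order, p$frame_spacing)
    dyn <- crbm_dynamic_biases(p, win$history)
    H <- all_bits(ncol(p$W))
    ll <- 0
    for (i in seq_len(nrow(win$present))) {
      v <- win$present[i, ]; ae <- dyn$a_eff[i, ]; be <- dyn$b_eff[i, ]
      lse <- function(u) { mm <- max(u); mm + log(sum(exp(u - mm))) }
      num <- -0.5 * sum((v - ae)^2) +
        lse(as.numeric(H %*% (be + as.numeric(t(p$W) %*% v))))
      # the (2*pi)^(nv/2) factor cancels in the before/after comparison
      logZ <- lse(vapply(seq_len(nrow(H)), function(j) {
          mu <- ae + as.numeric(p$W %*% H[j, ])
          sum(H[j, ] * be) + 0.5 * sum(mu^2) - 0.5 * sum(ae^2)
        }, numeric(1)))
      ll <- ll + num - logZ
    }
    ll / nrow(win$present)
  }
  expect_gt(cond_ll(fit, x), cond_ll(init, x) + 0.1)
})
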