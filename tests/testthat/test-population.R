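test_that("population construction is reproducible and respects the lattice", {
  p1 <- build_population(1344, seed = 7)
  p2 <- build_population(1344, seed = 7)
  expect_equal(p1$n_neurons, 1344L)
  expect_identical(p1, p2)
  expect_true(all(p1$rf_center >= 0 & p1$rf_center <= 63))
  pg <- build_population(16, seed = 3,
                         rf_config = list(layout = "jittered_grid"))
  expect_true(all(pg$rf_center >= 0 & pg$rf_center <= 63))
  expect_error(build_population(0), ">= 1")
})

test_that("impairment is graded, monotone in RF width, and level 0 is identity", {
  p <- build_population(20, seed = 1)
  expect_identical(apply_impairment(p, 0), p)
  p1 <- apply_impairment(p, 1)
  p2 <- apply_impairment(p, 2)
  expect_true(all(p1$center_sigma_px > p$center_sigma_px))
  expect_true(all(p2$center_sigma_px > p1$center_sigma_px))
  expect_true(p2$latency_jitter_sd > p1$latency_jitter_sd)
  expect_true(p2$position_jitter_sd_px > p1$position_jitter_sd_px)
  expect_error(apply_impairment(p, 3), "level")
})

test_that("simulated rates follow the LN cascade", {
  st <- make_grating_sequence(0, 0.023, duration_s = 1)
  p <- build_population(8, seed = 5)
  # zero gain: constant baseline
  p0 <- p; p0$gain[] <- 0
  r0 <- simulate_rates(p0, st)
  expect_equal(r0$rates, matrix(p0$baseline_rate_hz, 8, 30),
               ignore_attr = TRUE)
  # single ON neuron, full-field bright frame: above baseline
  pon <- build_population(1, seed = 2)
  pon$polarity <- 1; pon$latency_frames <- 0L
  bright <- stimulus_sequence(array(1, dim = c(3, 64, 64)), 30,
                              data.frame(frame = 1:3,
                                         orientation_deg = NA,
                                         spatial_freq_cpd = NA,
                                         phase_bin = NA,
                                         condition_tag = "flat"))
  ron <- simulate_rates(pon, bright)
  expect_true(all(ron$rates > pon$baseline_rate_hz))
  # empty stimulus rejected
  empty <- stimulus_sequence(array(0, dim = c(0, 64, 64)), 30,
                             data.frame())
  expect_error(simulate_rates(p, empty), "empty")
})

test_that("a drifting grating makes single-neuron rates periodic at the drift rate", {
  st <- make_grating_sequence(0, 0.045, temporal_freq_hz = 1,
                              duration_s = 8)
  p <- build_population(1, seed = 11)
  r <- simulate_rates(p, st)
  x <- r$rates[1, ]
  ac <- stats::acf(x, lag.max = 40, plot = FALSE)$acf[-1]
  # autocorrelation peaks at the 1 s period (30 frames)
  expect_equal(which.max(ac[20:40]) + 19L, 30L)
  expect_gt(ac[30], 0.8)
})

test_that("spike sampling is a seeded inhomogeneous Poisson process", {
  dt <- 1 / 30
  rm0 <- rate_matrix(matrix(0, 2, 60), dt)
  expect_equal(sum(lengths(sample_spikes(rm0, seed = 1)$spikes)), 0L)
  # constant rate: count concentrates around r * T
  rT <- 10 * 10
  rmc <- rate_matrix(matrix(10, 1, 100), 0.1)  # 10 s at 10 Hz
  for (s in 1:5) {
    n <- length(sample_spikes(rmc, seed = s)$spikes[[1]])
    expect_lt(abs(n - rT), 4 * sqrt(rT))
  }
  s1 <- sample_spikes(rmc, seed = 9, doubly_stochastic_sd = 0.3)
  s2 <- sample_spikes(rmc, seed = 9, doubly_stochastic_sd = 0.3)
  expect_identical(s1, s2)
  bad <- rmc; bad$rates[1, 5] <- -1
  expect_error(sample_spikes(bad), "negative")
})

test_that("mean spike count converges to the intensity integral", {
  # 10 Hz for 10 s: relative error of the mean over 200 seeds < 5%
  rmc <- rate_matrix(matrix(10, 1, 100), 0.1)
  counts <- vapply(1:200, function(s) {
    length(sample_spikes(rmc, seed = s)$spikes[[1]])
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100) / 100, 0.05)
})

test_that("impairment degrades stimulus-rate dependence monotonically", {
  st <- make_grating_sequence(0, 0.045, duration_s = 8)
  p <- build_population(24, seed = 13)
  # square-wave temporal regressor at the grating's drift rate
  tt <- (seq_len(n_frames(st)) - 1) / st$frame_rate_hz
  reg <- sign(sin(2 * pi * tt))
  dep <- vapply(0:2, function(lv) {
    r <- simulate_rates(apply_impairment(p, lv), st, seed = 3)
    mean(abs(apply(r$rates, 1, function(x) suppressWarnings(cor(x, reg)))),
         na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(dep) < 0))
})
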