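# A small deterministic setup shared by the mode-analysis tests: a grating
# stimulus and a hand-built RBM whose states track the sign of the first
# visible unit, so triggering sets are known exactly.
mode_fixture <- function() {
  st <- make_grating_sequence(0, 0.045, duration_s = 2, frame_rate_hz = 10,
                              phase_bins = 4)
  x <- with_seed_local(71, matrix(rnorm(20 * 3), 20, 3))
  x[, 1] <- rep(c(2, -2), 10)  # unit 1 follows a deterministic pattern
  m <- rbm_params(3, 2, "gaussian", seed = 1)
  m$W[] <- 0; m$W[1, 1] <- 5
  list(st = st, x = x, model = m)
}

test_that("state inference binarizes probabilities with the documented tie rule", {
  m <- rbm_params(2, 3, "gaussian", seed = 2)
  m$W[] <- 0; m$b[] <- 0  # every probability is exactly 0.5
  st <- infer_states(m, matrix(rnorm(8), 4, 2))
  expect_true(all(st$states == 1L))  # ties round up
  expect_equal(st$state_id, rep(7, 4))
  # duplicate inputs give identical rows
  fx <- mode_fixture()
  x2 <- rbind(fx$x[1, ], fx$x[1, ])
  s2 <- infer_states(fx$model, x2)
  expect_identical(s2$states[1, ], s2$states[2, ])
  expect_error(infer_states(fx$model, matrix(0, 2, 5)), "mismatch")
})

test_that("thresholded states equal the per-sample MAP of the latent posterior", {
  p <- tiny_binary_rbm(nv = 3, nh = 3, seed = 33)
  V <- all_bits(3)
  st <- infer_states(p, V)
  H <- all_bits(3)
  for (i in seq_len(nrow(V))) {
    w <- vapply(seq_len(nrow(H)), function(j) {
      exp(-binary_energy_loops(p, V[i, ], H[j, ]))
    }, numeric(1))
    expect_equal(as.numeric(st$states[i, ]), H[which.max(w), ],
                 ignore_attr = TRUE)
  }
})

test_that("state-triggered averages reduce to frames in degenerate cases", {
  fx <- mode_fixture()
  st <- infer_states(fx$model, fx$x)
  # unit 1 active exactly on odd samples
  expect_equal(which(st$states[, 1] == 1), seq(1, 19, by = 2))
  cen <- mode_census(st)
  top <- cen$state_id[1]
  sta <- state_triggered_average(st, fx$st, top)
  trig <- which(st$state_id == top)
  expect_equal(sta$n_samples_averaged, length(trig))
  expect_equal(sta$mean_frame,
               apply(fx$st$frames[trig, , , drop = FALSE], c(2, 3), mean))
  # single triggering sample: the average IS that frame
  x1 <- fx$x; x1[, 1] <- -2; x1[7, 1] <- 2
  s1 <- infer_states(fx$model, x1)
  sta1 <- state_triggered_average(s1, fx$st, s1$state_id[7])
  expect_equal(sta1$mean_frame, fx$st$frames[7, , ])
  # absent state id errors; lag skips pre-origin triggers with a count
  expect_error(state_triggered_average(st, fx$st, 123456), "empty mode")
  odd_state <- st$state_id[1]  # triggers at t = 1, 3, ..., 19
  lagged <- state_triggered_average(st, fx$st, odd_state, lag_frames = 10)
  expect_equal(lagged$n_skipped_before_origin, 5L)
  expect_equal(lagged$n_samples_averaged, 5L)
  # a lag that empties the triggering set is an error
  x7 <- fx$x; x7[, 1] <- -2; x7[7, 1] <- 2
  s7 <- infer_states(fx$model, x7)
  expect_error(state_triggered_average(s7, fx$st, s7$state_id[7],
                                       lag_frames = 10), "empty mode")
})

test_that("unit averages aggregate their states' triggering sets exactly", {
  fx <- mode_fixture()
  st <- infer_states(fx$model, fx$x)
  for (u in 1:2) {
    unit_set <- which(st$states[, u] == 1)
    ids <- unique(st$state_id[st$states[, u] == 1])
    union_set <- sort(unlist(lapply(ids, function(id) {
      which(st$state_id == id)
    })))
    expect_equal(sort(unit_set), union_set)
  }
  # unit always on: average of all frames
  m1 <- fx$model; m1$b[] <- 100
  s_on <- infer_states(m1, fx$x)
  uta <- unit_triggered_average(s_on, fx$st, 2)
  expect_equal(uta$mean_frame, apply(fx$st$frames, c(2, 3), mean))
  # unit never on: empty-mode error
  m0 <- fx$model; m0$b[] <- -100; m0$W[] <- 0
  s_off <- infer_states(m0, fx$x)
  expect_error(unit_triggered_average(s_off, fx$st, 1), "empty mode")
})

test_that("mode images respect averaging linearity and the pixel hull", {
  fx <- mode_fixture()
  st <- infer_states(fx$model, fx$x)
  labels <- as.character(fx$st$labels$phase_bin)
  top <- mode_census(st)$state_id[1]
  sta <- state_triggered_average(st, fx$st, top)
  hist <- state_stimulus_histogram(st, labels, top)
  # exact identity: STA = histogram-weighted mean of per-label mean frames
  per_label <- lapply(hist$label, function(l) {
    idx <- intersect(which(labels == l), which(st$state_id == top))
    apply(fx$st$frames[idx, , , drop = FALSE], c(2, 3), mean)
  })
  weighted <- Reduce(`+`, Map(function(f, w) f * w, per_label,
                              hist$count)) / sum(hist$count)
  expect_equal(sta$mean_frame, weighted, tolerance = 1e-12)
  expect_gte(min(sta$mean_frame), min(fx$st$frames))
  expect_lte(max(sta$mean_frame), max(fx$st$frames))
})

test_that("temporal averages preserve history order", {
  fx <- mode_fixture()
  st <- infer_states(fx$model, fx$x)
  sid <- st$state_id[15]
  x1 <- fx$x; x1[, 1] <- -2; x1[15, 1] <- 2
  s1 <- infer_states(fx$model, x1)
  ts <- temporal_sta(s1, fx$st, list(kind = "state", id = s1$state_id[15]),
                     order = 3, spacing = 2)
  expect_length(ts$slots, 3L)
  # single trigger at t = 15: slots are the actual delayed frames,
  # most delayed (t - 6) first
  expect_equal(ts$slots[[1]]$mean_frame, fx$st$frames[9, , ])
  expect_equal(ts$slots[[2]]$mean_frame, fx$st$frames[11, , ])
  expect_equal(ts$slots[[3]]$mean_frame, fx$st$frames[13, , ])
  # static stimulus: all slots identical
  flat <- stimulus_sequence(array(0.5, dim = c(20, 8, 8)), 10,
                            data.frame(frame = 1:20,
                                       orientation_deg = NA,
                                       spatial_freq_cpd = NA,
                                       phase_bin = NA,
                                       condition_tag = "flat"))
  ts2 <- temporal_sta(st, flat, list(kind = "unit", id = 1),
                      order = 3, spacing = 2)
  expect_equal(ts2$slots[[1]]$mean_frame, ts2$slots[[3]]$mean_frame)
})

test_that("the census is a proper occupancy distribution", {
  fx <- mode_fixture()
  st <- infer_states(fx$model, fx$x)
  cen <- mode_census(st)
  expect_equal(sum(cen$fraction), 1)
  expect_true(all(diff(cen$count) <= 0))
  expect_lte(nrow(cen), 2^ncol(st$states))
  # one state only
  uni <- st; uni$state_id[] <- 3
  cen1 <- mode_census(uni)
  expect_equal(cen1$fraction, 1)
  # histogram counts sum to the state occupancy
  labels <- as.character(fx$st$labels$phase_bin)
  top <- cen$state_id[1]
  hist <- state_stimulus_histogram(st, labels, top)
  expect_equal(sum(hist$count), cen$count[cen$state_id == top])
})
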