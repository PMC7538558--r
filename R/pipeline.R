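#' Partition electrodes into the 4x4 patch grid
#'
#' The 64x64 electrode lattice is divided into 16 non-overlapping patches of
#' 16x16 electrodes, labeled `t0` to `t15` in row-major order; modeling is
#' typically run per patch to keep the visible layer small.
#'
#' @param x a `spike_train_set`, `population_model`, `rate_matrix` (with
#'   electrode coordinates) or a two-column matrix of 0-based `(row, col)`
#'   lattice coordinates.
#' @return object of class `patch_assignment`: `patch_index` (0-15 per
#'   neuron), `patch_label` (`t0`..`t15`), and a count table.
#' @export
partition_patches <- function(x) {
  xy <- if (inherits(x, "population_model")) x$rf_center
        else if (inherits(x, c("spike_train_set", "rate_matrix"))) x$electrode_xy
        else as.matrix(x)
  if (is.null(xy)) stop("no electrode coordinates available", call. = FALSE)
  if (any(xy < 0) || any(xy > 63)) {
    stop("electrode coordinates must lie on the 64x64 lattice (0-63)",
         call. = FALSE)
  }
  idx <- (xy[, 1] %/% 16L) * 4L + (xy[, 2] %/% 16L)
  lab <- factor(paste0("t", idx), levels = paste0("t", 0:15))
  structure(list(
    patch_index = as.integer(idx),
    patch_label = lab,
    counts = table(lab)
  ), class = "patch_assignment")
}

#' @export
print.patch_assignment <- function(x, ...) {
  cat("<patch_assignment> neurons per patch:\n")
  print(x$counts)
  invisible(x)
}

#' Experiment configuration
#'
#' Declarative description of one end-to-end synthetic experiment:
#' stimulus protocol, population, spike generation, rate inference, model
#' and analysis settings, under a single global seed. The configuration is
#' fully serializable to YAML and its MD5 hash is recorded in every output
#' artifact.
#'
#' @param stimulus list describing the protocol. For `kind = "gratings"`:
#'   `orientations` (degrees), `spatial_freq_cpd`, `temporal_freq_hz`,
#'   `contrast`, `mean_luminance`, `duration_per_orientation_s`,
#'   `frame_rate_hz`, `frame_size`, `phase_bins`. For
#'   `kind = "natural_scan"`: `image_size`, `window`, `n_steps`, `step_px`,
#'   `frame_rate_hz`.
#' @param population list: `n_neurons`, `impairment_level`, `rf_config`.
#' @param spikes list: `doubly_stochastic_sd`.
#' @param rate_inference list: `kernel_lengthscale_s`, `kernel_variance`,
#'   `selection_threshold`.
#' @param model list: `kind` (`"mcrbm"`, `"rbm"`, `"crbm"`), `order` (crbm),
#'   `negative_phase` (mcrbm), plus any [train_config()] overrides under
#'   `train`.
#' @param analysis list: `lag_frames`, `top_states`, `label`
#'   (`"orientation_phase"`, `"phase"` or `"condition_tag"`).
#' @param evaluation list: `null_reps`.
#' @param seed global seed; all stage seeds derive from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(stimulus = list(), population = list(),
                              spikes = list(), rate_inference = list(),
                              model = list(), analysis = list(),
                              evaluation = list(), seed = 1) {
  cfg <- list(
    stimulus = utils::modifyList(list(
      kind = "gratings", orientations = seq(0, 315, by = 45),
      spatial_freq_cpd = 0.023, temporal_freq_hz = 1, contrast = 0.5,
      mean_luminance = 0.5, duration_per_orientation_s = 8,
      frame_rate_hz = 30, frame_size = 64, phase_bins = 8
    ), stimulus),
    population = utils::modifyList(list(
      n_neurons = 114, impairment_level = 0, rf_config = list()
    ), population),
    spikes = utils::modifyList(list(doubly_stochastic_sd = 0.2), spikes),
    rate_inference = utils::modifyList(list(
      kernel_lengthscale_s = 0.25, kernel_variance = 1,
      selection_threshold = 5
    ), rate_inference),
    model = utils::modifyList(list(
      kind = "mcrbm", order = 12, negative_phase = "hmc", train = list()
    ), model),
    analysis = utils::modifyList(list(
      lag_frames = 2, top_states = 3, label = "orientation_phase"
    ), analysis),
    evaluation = utils::modifyList(list(null_reps = 100), evaluation),
    seed = seed
  )
  stopifnot(cfg$model$kind %in% c("mcrbm", "rbm", "crbm"))
  structure(cfg, class = "experiment_config")
}

#' MD5 hash of an experiment configuration
#' @param config an `experiment_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

# Build the stimulus of a configured experiment.
build_config_stimulus <- function(cfg) {
  st <- cfg$stimulus
  if (identical(st$kind, "gratings")) {
    seqs <- lapply(st$orientations, function(o) {
      make_grating_sequence(
        orientation_deg = o, spatial_freq_cpd = st$spatial_freq_cpd,
        temporal_freq_hz = st$temporal_freq_hz, contrast = st$contrast,
        mean_luminance = st$mean_luminance,
        duration_s = st$duration_per_orientation_s,
        frame_rate_hz = st$frame_rate_hz, frame_size = st$frame_size,
        phase_bins = st$phase_bins,
        condition_tag = sprintf("ori_%03d", o))
    })
    concat_stimuli(seqs)
  } else if (identical(st$kind, "natural_scan")) {
    img <- brick_texture(st$image_size %||% 128, st$image_size %||% 128)
    win <- st$window %||% 64
    n_steps <- st$n_steps %||% 32
    step <- st$step_px %||% 2
    # raster scan trajectory, wrapped to stay inside the image
    max_off <- dim(img)[1] - win
    pos <- (seq_len(n_steps) - 1) * step
    traj <- cbind(row = pos %% max_off + 1, col = (pos %/% max_off * 8) %% max_off + 1)
    make_natural_scan(img, c(win, win), traj,
                      frame_rate_hz = st$frame_rate_hz %||% 30)
  } else {
    stop("unknown stimulus kind", call. = FALSE)
  }
}

# Per-sample stimulus labels used for mutual-information scoring.
config_labels <- function(cfg, stimulus) {
  lab <- stimulus$labels
  switch(cfg$analysis$label,
    orientation_phase = paste(lab$condition_tag, lab$phase_bin, sep = "|"),
    phase = as.character(lab$phase_bin),
    condition_tag = lab$condition_tag,
    stop("unknown label scheme", call. = FALSE))
}

#' Run one configured experiment end to end
#'
#' Executes the full pipeline: stimulus generation, population simulation
#' (with any configured impairment), log-Gaussian Cox spike generation,
#' LGCP rate inference, neuron selection, standardization, model training,
#' state inference, occupancy census, state-triggered averages of the top
#' states, and normalized-MI evaluation against a shuffled-label null. All
#' stage seeds derive from `config$seed`, so a rerun with the same
#' configuration reproduces every artifact byte for byte.
#'
#' @param config an [experiment_config()].
#' @param out_dir directory for CSV/TSV/JSON artifacts (`NULL` writes
#'   nothing).
#' @param keep_stimulus keep the frame stack in the returned object.
#' @return list with the per-stage results (`stimulus` (optional),
#'   `population`, `rates_inferred`, `selection`, `std`, `model`, `states`,
#'   `census`, `sta`, `mi`, `null_nmi`, `labels`, `config_hash`).
#' @export
run_experiment <- function(config, out_dir = NULL, keep_stimulus = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  hash <- config_hash(config)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[rgcmodes] ", msg)
  }
  t0 <- proc.time()[["elapsed"]]
  stage_time <- function() sprintf("%.1fs", proc.time()[["elapsed"]] - t0)

  stimulus <- build_config_stimulus(config)
  say("stimulus: %d frames (%s)", n_frames(stimulus), stage_time())

  pop <- build_population(config$population$n_neurons, seed = seed,
                          rf_config = config$population$rf_config)
  pop <- apply_impairment(pop, config$population$impairment_level)
  rates_true <- simulate_rates(pop, stimulus, seed = seed + 1L)
  spikes <- sample_spikes(rates_true, seed = seed + 2L,
                          doubly_stochastic_sd = config$spikes$doubly_stochastic_sd)
  say("simulation: %d spikes (%s)", sum(lengths(spikes$spikes)), stage_time())

  bin_w <- 1 / stimulus$frame_rate_hz
  counts <- bin_spikes(spikes, bin_w)
  rates_inf <- lgcp_fit(
    counts, bin_w,
    kernel_lengthscale_s = config$rate_inference$kernel_lengthscale_s,
    kernel_variance = config$rate_inference$kernel_variance)
  rates_inf$electrode_xy <- spikes$electrode_xy
  say("rate inference: %d neurons x %d bins (%s)",
      nrow(rates_inf$rates), ncol(rates_inf$rates), stage_time())

  sel <- select_active_neurons(rates_inf,
                               config$rate_inference$selection_threshold)
  std <- standardize_rates(sel$rates)
  x <- as_training_matrix(std)
  say("selection: kept %d / %d neurons (%s)", length(sel$report$kept_ids),
      nrow(rates_inf$rates), stage_time())

  tc_args <- utils::modifyList(list(seed = seed + 3L), config$model$train)
  tc <- do.call(train_config, tc_args)
  model <- switch(config$model$kind,
    mcrbm = train_mcrbm(x, tc, negative_phase = config$model$negative_phase),
    rbm = train_rbm(x, tc, visible_kind = "gaussian"),
    crbm = train_crbm(
      x, order = config$model$order, config = tc,
      temporal_period_s = 1 / config$stimulus$temporal_freq_hz,
      bin_width_s = bin_w))
  say("training: %s done (%s)", config$model$kind, stage_time())

  states <- infer_states(model, x)
  census <- mode_census(states)
  labels_all <- config_labels(config, stimulus)
  labels <- labels_all[states$sample_index]

  top_ids <- utils::head(census$state_id, config$analysis$top_states)
  sta <- lapply(top_ids, function(sid) {
    state_triggered_average(states, stimulus, sid,
                            lag_frames = config$analysis$lag_frames)
  })
  mi <- normalized_mi(labels, states$state_id)
  null_nmi <- nmi_permutation_null(labels, states$state_id,
                                   reps = config$evaluation$null_reps,
                                   seed = seed + 4L)
  say("evaluation: NMI %.3f (null q95 %.3f) (%s)", mi$nmi,
      as.numeric(stats::quantile(null_nmi, 0.95)), stage_time())

  result <- list(
    stimulus = if (keep_stimulus) stimulus,
    population = pop,
    spikes = spikes,
    rates_inferred = rates_inf,
    selection = sel$report,
    std = std,
    model = model,
    states = states,
    census = census,
    sta = sta,
    mi = mi,
    null_nmi = null_nmi,
    labels = labels,
    config_hash = hash
  )
  if (!is.null(out_dir)) {
    write_experiment_artifacts(result, config, out_dir, log_lines)
  }
  result
}

write_experiment_artifacts <- function(result, config, out_dir, log_lines) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_spike_trains(result$spikes, p("spikes.tsv"))
  write_rate_matrix(result$rates_inferred, p("rates.csv"))
  sel <- result$selection
  utils::write.csv(data.frame(
    neuron_id = names(sel$derivative_range),
    derivative_range_hz_per_s = as.numeric(sel$derivative_range),
    kept = names(sel$derivative_range) %in% sel$kept_ids
  ), p("selection.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(
    sample_index = result$states$sample_index,
    state_id = format(result$states$state_id, scientific = FALSE, trim = TRUE),
    label = result$labels
  ), p("states.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(result$census, p("census.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(
    nmi = result$mi$nmi,
    mi_bits = result$mi$mi_bits,
    stimulus_entropy_bits = result$mi$stimulus_entropy_bits,
    null_nmi_mean = mean(result$null_nmi),
    null_nmi_q95 = as.numeric(stats::quantile(result$null_nmi, 0.95))
  ), p("nmi.csv"), row.names = FALSE, quote = FALSE)
  sta_long <- do.call(rbind, lapply(result$sta, function(s) {
    mf <- s$mean_frame
    data.frame(id = s$id,
               row = rep(seq_len(nrow(mf)), times = ncol(mf)),
               col = rep(seq_len(ncol(mf)), each = nrow(mf)),
               value = as.vector(mf))
  }))
  utils::write.csv(sta_long, p("sta_top_states.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(
    config = unclass(config),
    config_hash = result$config_hash,
    n_neurons_kept = length(result$selection$kept_ids)
  ), p("meta.json"), auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, p("log.txt"))
  invisible(out_dir)
}

#' Impairment x spatial-frequency sweep
#'
#' Replicates the graded-impairment protocol: for every combination of
#' impairment level and grating spatial frequency, runs the full pipeline
#' with a single-orientation drifting grating and scores the stimulus-phase
#' NMI, plus the label-histogram entropy of the top-occupancy state (which
#' rises when impairment makes states pool counterphase stimuli).
#'
#' @param base_config an [experiment_config()]; its stimulus/population
#'   settings are reused with `orientations` fixed to one orientation and
#'   the phase-label scheme.
#' @param levels impairment levels to sweep.
#' @param freqs spatial frequencies (cycles/degree) to sweep.
#' @param out_dir optional artifact root (one subdirectory per run).
#' @param n_model_seeds models trained per condition; the reported NMI is
#'   the ensemble mean, which controls contrastive-divergence training
#'   variance when comparing conditions.
#' @return data frame with one row per (level, frequency): NMI, null
#'   quantiles, and top-state label entropy.
#' @export
run_impairment_sweep <- function(base_config,
                                 levels = c(0, 1, 2),
                                 freqs = c(0.011, 0.023, 0.045),
                                 out_dir = NULL, n_model_seeds = 2) {
  stopifnot(inherits(base_config, "experiment_config"))
  rows <- list()
  for (lv in levels) {
    for (fq in freqs) {
      cfg <- base_config
      cfg$stimulus$orientations <- cfg$stimulus$orientations[1L]
      cfg$stimulus$spatial_freq_cpd <- fq
      cfg$population$impairment_level <- lv
      cfg$analysis$label <- "phase"
      run_dir <- if (!is.null(out_dir)) {
        file.path(out_dir, sprintf("level%d_freq%.3f", lv, fq))
      }
      res <- run_experiment(cfg, out_dir = run_dir, keep_stimulus = FALSE)
      nmis <- res$mi$nmi
      if (n_model_seeds > 1) {
        x <- as_training_matrix(res$std)
        extra <- vapply(seq_len(n_model_seeds - 1L), function(j) {
          tc_args <- utils::modifyList(
            list(seed = cfg$seed + 3L + 1000L * j), cfg$model$train)
          tc <- do.call(train_config, tc_args)
          mj <- switch(cfg$model$kind,
            mcrbm = train_mcrbm(x, tc,
                                negative_phase = cfg$model$negative_phase),
            rbm = train_rbm(x, tc, visible_kind = "gaussian"),
            crbm = train_crbm(x, order = cfg$model$order, config = tc,
                              temporal_period_s = 1 / cfg$stimulus$temporal_freq_hz,
                              bin_width_s = 1 / cfg$stimulus$frame_rate_hz))
          sj <- infer_states(mj, x)
          normalized_mi(res$labels[match(sj$sample_index,
                                         res$states$sample_index)],
                        sj$state_id)$nmi
        }, numeric(1))
        nmis <- c(nmis, extra)
      }
      top_id <- res$census$state_id[1L]
      hist <- state_stimulus_histogram(res$states, res$labels, top_id)
      hist_entropy <- entropy_bits(rep(hist$label, hist$count))
      rows[[length(rows) + 1L]] <- data.frame(
        impairment_level = lv,
        spatial_freq_cpd = fq,
        nmi = mean(nmis),
        null_nmi_q95 = as.numeric(stats::quantile(res$null_nmi, 0.95)),
        top_state_label_entropy_bits = hist_entropy,
        n_neurons_kept = length(res$selection$kept_ids),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  out
}

#' Best-matching pure stimulus frame for a mode image
#'
#' Pearson correlation of a state/unit-triggered average against every
#' distinct frame of the stimulus, returning the best match. Frames with
#' zero pixel variance are skipped.
#'
#' @param mode_image a `mode_image`.
#' @param stimulus the `stimulus_sequence` it was computed from.
#' @return list with `frame_index`, `r` and the matching frame's label row.
#' @export
best_frame_match <- function(mode_image, stimulus) {
  v <- as.vector(mode_image$mean_frame)
  nt <- n_frames(stimulus)
  flat <- matrix(stimulus$frames, nrow = nt)
  sds <- apply(flat, 1, stats::sd)
  ok <- which(sds > 0)
  if (stats::sd(v) == 0 || !length(ok)) {
    return(list(frame_index = NA_integer_, r = NA_real_, label = NULL))
  }
  rs <- as.numeric(stats::cor(v, t(flat[ok, , drop = FALSE])))
  best <- ok[which.max(rs)]
  list(frame_index = best, r = max(rs), label = stimulus$labels[best, ])
}
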