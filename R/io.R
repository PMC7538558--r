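# Plain-text persistence for spike trains, rate matrices and tables.
# Spike trains use the 2-column tab-separated interchange format
# (neuron_id, spike_time_s), one row per spike, sorted by neuron then time,
# with a JSON sidecar carrying duration, ids and electrode coordinates.

#' Write spike trains to a tab-separated file
#'
#' @param spike_train_set a `spike_train_set`.
#' @param path output file; a `<path>.meta.json` sidecar records duration,
#'   neuron ids and electrode coordinates.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(spike_train_set, path) {
  stopifnot(inherits(spike_train_set, "spike_train_set"))
  sts <- spike_train_set
  df <- data.frame(
    neuron_id = rep.int(sts$neuron_ids, lengths(sts$spikes)),
    spike_time_s = unlist(sts$spikes, use.names = FALSE)
  )
  df <- df[order(match(df$neuron_id, sts$neuron_ids), df$spike_time_s), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    duration_s = sts$duration_s,
    neuron_ids = sts$neuron_ids,
    electrode_row = if (!is.null(sts$electrode_xy)) sts$electrode_xy[, 1],
    electrode_col = if (!is.null(sts$electrode_xy)) sts$electrode_xy[, 2]
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read spike trains written by [write_spike_trains()]
#' @param path the tab-separated spike file.
#' @return a `spike_train_set`.
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  ids <- meta$neuron_ids
  spikes <- lapply(ids, function(id) {
    sort(df$spike_time_s[df$neuron_id == id])
  })
  names(spikes) <- ids
  exy <- NULL
  if (!is.null(meta$electrode_row)) {
    exy <- cbind(row = meta$electrode_row, col = meta$electrode_col)
  }
  structure(list(spikes = spikes, duration_s = meta$duration_s,
                 electrode_xy = exy, neuron_ids = ids),
            class = "spike_train_set")
}

#' Write / read a rate matrix as CSV plus JSON sidecar
#' @param rate_matrix a [rate_matrix()].
#' @param path output CSV (neurons in rows, first column `neuron_id`).
#' @return `path` invisibly / a `rate_matrix`.
#' @export
write_rate_matrix <- function(rate_matrix, path) {
  stopifnot(inherits(rate_matrix, "rate_matrix"))
  df <- data.frame(neuron_id = rate_matrix$neuron_ids,
                   rate_matrix$rates, check.names = FALSE)
  colnames(df) <- c("neuron_id", sprintf("b%05d", seq_len(ncol(rate_matrix$rates))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(bin_width_s = rate_matrix$bin_width_s,
         time_origin_s = rate_matrix$time_origin_s),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rate_matrix
#' @export
read_rate_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  rates <- as.matrix(df[, -1, drop = FALSE])
  rate_matrix(rates, bin_width_s = meta$bin_width_s,
              neuron_ids = df$neuron_id,
              time_origin_s = meta$time_origin_s %||% 0)
}
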