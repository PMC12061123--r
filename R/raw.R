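#' Continuous multi-channel EEG recording
#'
#' Container for a continuous recording: a channels x samples matrix in uV,
#' the sampling rate, ordered channel labels and event markers (sample
#' index, trial index, condition).  Event samples must lie within the data
#' span and be sorted.
#'
#' @param data Numeric matrix, channels x samples (uV).
#' @param sfreq Sampling rate, Hz.
#' @param channel_names Character vector, one label per row of `data`.
#' @param events Data frame with columns `sample` (1-based), `trial`,
#'   `condition`; may have zero rows.
#' @param chain Character record of processing steps applied so far.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(data, sfreq, channel_names,
                          events = empty_events(), chain = character()) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_names), sfreq > 0)
  events <- as.data.frame(events)
  stopifnot(all(c("sample", "trial", "condition") %in% names(events)))
  if (nrow(events)) {
    stopifnot(all(events$sample >= 1), all(events$sample <= ncol(data)))
    events <- events[order(events$sample), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(
    list(data = data, sfreq = sfreq,
         channel_names = as.character(channel_names),
         events = events, chain = chain),
    class = "raw_recording"
  )
}

empty_events <- function() {
  data.frame(sample = integer(), trial = integer(),
             condition = character(), stringsAsFactors = FALSE)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
    nrow(x$events)
  ))
  if (length(x$chain)) cat("  chain:", paste(x$chain, collapse = " -> "), "\n")
  invisible(x)
}

#' Target-locked EEG epochs
#'
#' Container for epoched data: a trials x channels x time array, the time
#' axis in seconds relative to target onset, per-trial condition labels, and
#' a rejection log accounting for every input trial that is not retained.
#'
#' @param data Numeric array trials x channels x time (uV).
#' @param times Time axis, seconds.
#' @param sfreq Sampling rate, Hz.
#' @param channel_names Electrode labels.
#' @param labels Character vector of conditions per trial
#'   (`"congruent"`/`"incongruent"`).
#' @param trial_index Original trial indices.
#' @param baseline Baseline window `c(tmin, tmax)` in seconds if baseline
#'   correction has been applied, else `NULL`.
#' @param rejected Data frame logging dropped trials
#'   (`trial`, `reason`, `channel`, `value`).
#' @param chain Character record of processing steps.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sfreq, channel_names, labels,
                      trial_index = seq_len(dim(data)[1L]),
                      baseline = NULL, rejected = empty_rejections(),
                      chain = character()) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[2L] == length(channel_names),
            dim(data)[3L] == length(times),
            dim(data)[1L] == length(labels),
            length(trial_index) == length(labels))
  structure(
    list(data = data, times = times, sfreq = sfreq,
         channel_names = as.character(channel_names),
         labels = as.character(labels),
         trial_index = trial_index, baseline = baseline,
         rejected = rejected, chain = chain),
    class = "epoch_set"
  )
}

empty_rejections <- function() {
  data.frame(trial = integer(), reason = character(),
             channel = character(), value = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples, %.0f..%.0f ms @ %g Hz\n",
    d[1L], d[2L], d[3L], 1000 * min(x$times), 1000 * max(x$times), x$sfreq
  ))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("| rejected: %d\n", nrow(x$rejected)))
  if (!is.null(x$baseline)) {
    cat(sprintf("  baseline: %.0f..%.0f ms\n", 1000 * x$baseline[1L],
                1000 * x$baseline[2L]))
  }
  invisible(x)
}
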