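#' Spectrally shaped (1/f) Gaussian noise
#'
#' White Gaussian noise is shaped in the frequency domain with amplitude
#' proportional to `f^(-exponent/2)` (the DC bin is zeroed) and rescaled so
#' each channel has the requested standard deviation over the generated
#' stretch.
#'
#' @param n_samples Samples per channel.
#' @param n_channels Number of channels.
#' @param sfreq Sampling rate, Hz (sets the frequency axis only).
#' @param sd Target per-channel standard deviation.
#' @param exponent Spectral slope (1 gives pink noise; 0 gives white noise).
#' @return Matrix channels x samples.
#' @export
pink_noise <- function(n_samples, n_channels, sfreq, sd = 1, exponent = 1) {
  if (sd == 0) return(matrix(0, n_channels, n_samples))
  # pad to an FFT-friendly length, shape the spectrum, then truncate;
  # normalization is analytic (per-sample variance of the shaped process is
  # mean(scale^2)), so samples stay exactly Gaussian with the target sd
  n2 <- stats::nextn(n_samples)
  w <- matrix(rnorm(n2 * n_channels), n2, n_channels)
  if (exponent != 0) {
    k <- seq_len(n2) - 1L
    f <- pmin(k, n2 - k) / n2 * sfreq
    scale <- c(0, f[-1L]^(-exponent / 2))
    w <- Re(mvfft(mvfft(w) * scale, inverse = TRUE)) / n2
    w <- w / sqrt(mean(scale^2))
  }
  w <- w[seq_len(n_samples), , drop = FALSE]
  t(w) * sd
}

# Smooth ~300 ms blink transient (unit peak).
blink_waveform <- function(sfreq, dur = 0.3) {
  t <- seq(0, dur, by = 1 / sfreq)
  sin(pi * t / dur)^2
}

# Indices (0-based, relative to target onset) of template samples lying in a
# window given in ms, inclusive at both edges.  The same rule is used when
# injecting effects and when averaging windowed amplitudes, so noiseless
# round trips are exact.
window_sample_idx <- function(times, window_ms) {
  eps <- 1e-9
  which(times * 1000 >= window_ms[1] - eps & times * 1000 <= window_ms[2] + eps)
}

# Condition templates on a given time axis: shared evoked template plus the
# injected differences split +/- half between conditions.
condition_templates <- function(times, params) {
  base <- erp_template(times, params$channel_names)
  cong <- base
  incg <- base
  for (ef in params$effect_spec) {
    ch <- match(ef$electrode, params$channel_names)
    idx <- window_sample_idx(times, ef$window_ms)
    cong[ch, idx] <- cong[ch, idx] + ef$amplitude_uv / 2
    incg[ch, idx] <- incg[ch, idx] - ef$amplitude_uv / 2
  }
  list(congruent = cong, incongruent = incg)
}

#' Simulate a continuous event-marked EEG recording
#'
#' Builds one participant's continuous recording for a trial schedule: the
#' sum of (a) condition-appropriate evoked templates inserted at every
#' target onset, with the configured effect differences split +/- half
#' between congruent and incongruent trials, (b) 1/f-shaped background
#' noise on every channel, and (c) blink transients at Poisson event times
#' projected through the frontal blink topography.  Event markers encode
#' trial index and condition at the target-onset sample.
#'
#' Trial timing follows the experimental paradigm (fixation 1200 ms, prime
#' 500 ms, ISI 300 ms, target up to 2000 ms, blank 1000 ms; backward trials
#' swap prime and target).  The target presentation ends at the response:
#' actual reaction times are taken from `rt_log` when given, otherwise a
#' nominal 1000 ms display is used.
#'
#' @param schedule A [make_schedule()] object.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param rt_log Optional [simulate_rt()] log providing per-trial reaction
#'   times.
#' @return A [raw_recording()].
#' @examples
#' p <- sim_params(noise_sd = 0, blink_rate = 0)
#' raw <- simulate_eeg(make_schedule("forward", 10), p, seed = 3)
#' raw
#' @export
simulate_eeg <- function(schedule, params = sim_params(), seed = 1L,
                         rt_log = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"))
  sf <- params$sfreq
  tr <- schedule$trials
  n_trials <- nrow(tr)
  tm <- schedule$timing

  rt <- if (!is.null(rt_log)) pmin(rt_log$rt_ms, tm$target_max_ms) else
    rep(1000, n_trials)
  if (schedule$experiment == "forward") {
    pre_target <- tm$fixation_ms + tm$prime_ms + tm$isi_ms
    post_target <- tm$blank_ms
  } else {
    pre_target <- tm$fixation_ms
    post_target <- tm$isi_ms + tm$prime_ms + tm$blank_ms
  }
  durs <- pre_target + rt + post_target
  starts <- cumsum(c(0, head(durs, -1L)))
  onset_ms <- starts + pre_target
  onset_sample <- round(onset_ms / 1000 * sf) + 1L
  total <- ceiling((starts[n_trials] + durs[n_trials]) / 1000 * sf) +
    ceiling(1.2 * sf)

  seeds <- child_seeds(seed, 2L)
  data <- with_seed(seeds[1L], {
    pink_noise(total, params$n_channels, sf, params$noise_sd,
               params$noise_exponent)
  })

  # evoked templates on the post-onset grid (0 .. epoch_tmax)
  t_tpl <- seq(0L, round(params$epoch_tmax * sf)) / sf
  tpl <- condition_templates(t_tpl, params)
  for (i in seq_len(n_trials)) {
    cols <- onset_sample[i] + seq_along(t_tpl) - 1L
    keep <- cols <= total
    cond <- if (tr$congruent[i]) "congruent" else "incongruent"
    data[, cols[keep]] <- data[, cols[keep]] + tpl[[cond]][, keep]
  }

  if (params$blink_rate > 0 && params$blink_amp_uv != 0) {
    bw <- blink_waveform(sf)
    dur_s <- total / sf
    blink_t <- with_seed(seeds[2L], {
      nb <- rpois(1L, params$blink_rate * dur_s)
      sort(runif(nb, 0, dur_s - length(bw) / sf))
    })
    topo <- params$blink_amp_uv * params$blink_topography
    for (bt in blink_t) {
      cols <- round(bt * sf) + seq_along(bw)
      data[, cols] <- data[, cols] + outer(unname(topo), bw)
    }
    attr(data, "n_blinks") <- length(blink_t)
  }

  events <- data.frame(
    sample = onset_sample, trial = tr$index,
    condition = ifelse(tr$congruent, "congruent", "incongruent"),
    stringsAsFactors = FALSE
  )
  n_blinks <- attr(data, "n_blinks")
  attr(data, "n_blinks") <- NULL
  raw <- raw_recording(data, sf, params$channel_names, events,
                       chain = "simulate_eeg")
  raw$n_blinks <- n_blinks %||% 0L
  raw
}

#' Simulate target-locked epochs directly
#'
#' Epoch-level shortcut past the continuous recording: each trial's epoch is
#' the condition template plus 1/f background noise sliced from one long
#' noise stream per channel.  Blink transients are not generated on this
#' path (use [simulate_eeg()] plus the preprocessing chain for those).
#' Baseline correction is not applied; see [baseline_correct()].
#'
#' @param schedule A [make_schedule()] object.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return An [epoch_set()] spanning `params$epoch_tmin` ..
#'   `params$epoch_tmax`.
#' @export
simulate_participant_epochs <- function(schedule, params = sim_params(),
                                        seed = 1L) {
  stopifnot(inherits(schedule, "trial_schedule"))
  sf <- params$sfreq
  idx <- seq(round(params$epoch_tmin * sf), round(params$epoch_tmax * sf))
  times <- idx / sf
  nt <- length(times)
  tr <- schedule$trials
  n_trials <- nrow(tr)
  tpl <- condition_templates(times, params)

  noise <- with_seed(seed, {
    pink_noise(nt * n_trials, params$n_channels, sf, params$noise_sd,
               params$noise_exponent)
  })
  data <- array(0, c(n_trials, params$n_channels, nt))
  for (i in seq_len(n_trials)) {
    cond <- if (tr$congruent[i]) "congruent" else "incongruent"
    data[i, , ] <- tpl[[cond]] + noise[, (i - 1L) * nt + seq_len(nt)]
  }
  epoch_set(data, times, sf, params$channel_names,
            labels = ifelse(tr$congruent, "congruent", "incongruent"),
            trial_index = tr$index, chain = "simulate_participant_epochs")
}
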