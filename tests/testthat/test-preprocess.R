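sine_raw <- function(freqs, sfreq = 250, dur = 4) {
  t <- seq(0, dur, by = 1 / sfreq)
  data <- do.call(rbind, lapply(freqs, function(f) {
    if (f == 0) rep(0, length(t)) else sin(2 * pi * f * t)
  }))
  raw_recording(data, sfreq, paste0("ch", seq_along(freqs)))
}

rms <- function(x) sqrt(mean(x^2))

test_that("band-pass filter attenuates the stop band, passes the pass band, is zero-phase", {
  raw <- sine_raw(c(50, 10, 0))
  out <- bandpass_filter(raw, 0.1, 30)
  expect_lt(rms(out$data[1, ]) / rms(raw$data[1, ]), 0.05)
  expect_lt(abs(rms(out$data[2, ]) / rms(raw$data[2, ]) - 1), 0.05)
  expect_equal(out$data[3, ], raw$data[3, ])
  expect_identical(ncol(out$data), ncol(raw$data))
  # zero phase: an impulse does not move
  imp <- matrix(0, 2, 1001)
  imp[, 500] <- 1
  fi <- bandpass_filter(raw_recording(imp, 250, c("a", "b")), 1, 30)
  expect_identical(which.max(fi$data[1, ]), 500L)
  expect_error(bandpass_filter(raw, 0.1, 200), "Nyquist")
  expect_error(bandpass_filter(raw, 30, 0.1), "low < high")
})

test_that("average reference zeroes channel means and is idempotent", {
  two <- raw_recording(rbind(rep(1, 100), rep(-1, 100)), 100, c("a", "b"))
  expect_equal(rereference_average(two)$data, two$data)
  set.seed(1)
  raw <- raw_recording(matrix(rnorm(5 * 400, 3), 5, 400), 100,
                       paste0("ch", 1:5))
  ref <- rereference_average(raw)
  expect_lt(max(abs(colMeans(ref$data))), 1e-10)
  expect_equal(rereference_average(ref)$data, ref$data, tolerance = 1e-12)
  one <- raw_recording(matrix(0, 1, 10), 10, "a")
  expect_error(rereference_average(one), "2 channels")
})

test_that("ICA flags blink components via Fp1 and their removal lowers frontal variance", {
  p <- small_params(noise_sd = 8, blink_rate = 0.4)
  sch <- make_schedule("forward", 16, seed = 5)
  raw <- simulate_eeg(sch, p, seed = 7)
  fl <- rereference_average(bandpass_filter(raw, 0.1, 30))
  ica <- fit_ica(fl, seed = 1)
  flagged <- detect_blink_components(ica, fl)
  expect_gte(length(flagged), 1L)
  r <- attr(flagged, "r")
  expect_true(all(abs(r) <= 1 + 1e-12))
  expect_identical(sort(flagged), sort(which(abs(r) > 0.5)))

  fp1 <- match("Fp1", fl$channel_names)
  cleaned <- remove_components(fl, ica, flagged)
  expect_lt(var(cleaned$data[fp1, ]), var(fl$data[fp1, ]))
  # blink peaks strongly attenuated at the frontal site
  q99 <- function(x) quantile(abs(x), 0.999)
  expect_lt(q99(cleaned$data[fp1, ]) / q99(fl$data[fp1, ]), 0.5)

  # identity and annihilation
  same <- remove_components(fl, ica, integer())
  expect_lt(max(abs(same$data - fl$data)), 1e-8)
  none <- remove_components(fl, ica, seq_len(ica$n_components))
  expect_lt(max(abs(none$data - ica$row_means)), 1e-8)
  expect_error(remove_components(fl, ica, 999), "out of range")

  no_fp1 <- raw_recording(fl$data[-fp1, ], fl$sfreq,
                          fl$channel_names[-fp1])
  ica2 <- fit_ica(no_fp1, n_components = 4, seed = 1, max_iter = 20)
  expect_error(detect_blink_components(ica2, no_fp1), "Fp1")
})

test_that("component flagging follows the correlation threshold exactly", {
  # components constructed to be identical / orthogonal to the Fp1 trace
  n <- 2000
  t <- seq_len(n) / 250
  s1 <- sin(2 * pi * 3 * t)
  s2 <- cos(2 * pi * 3 * t)  # orthogonal to s1
  mix <- rbind(s1, 0.5 * s1 + 0.8 * s2, s2)
  raw <- raw_recording(mix, 250, c("Fp1", "mid", "other"))
  ica <- structure(
    list(unmixing = diag(3), mixing = diag(3), row_means = rowMeans(mix) * 0,
         n_components = 3L, channel_names = raw$channel_names),
    class = "ica_decomposition"
  )
  # sources are then the channel traces themselves
  flagged <- detect_blink_components(ica, raw, threshold = 0.5)
  r <- attr(flagged, "r")
  expect_equal(r[1], 1, tolerance = 1e-9)
  expect_lt(abs(r[3]), 0.05)
  expect_true(1L %in% flagged)
  expect_false(3L %in% flagged)
})

test_that("epoching aligns t = 0 to the event and baseline means vanish", {
  sf <- 250
  n <- 5000
  data <- matrix(5, 2, n)  # constant channels
  events <- data.frame(sample = c(1000, 2000, 4990),
                       trial = 1:3, condition = "congruent")
  raw <- raw_recording(data, sf, c("a", "b"), events)
  ep <- epoch_and_baseline(raw, tmin = -0.1, tmax = 1.0)
  # the event too close to the edge is dropped and logged
  expect_identical(dim(ep$data)[1], 2L)
  expect_identical(ep$rejected$trial, 3L)
  expect_identical(ep$rejected$reason, "epoch outside recording")
  # constant signal is annihilated by baseline correction
  expect_lt(max(abs(ep$data)), 1e-12)

  # spike 100 ms after onset appears at epoch time 0.100 s
  data2 <- matrix(0, 1, n)
  data2[1, 2000 + 25] <- 7  # 25 samples = 100 ms at 250 Hz
  raw2 <- raw_recording(data2, sf, "a",
                        data.frame(sample = 2000, trial = 1,
                                   condition = "congruent"))
  ep2 <- epoch_and_baseline(raw2, tmin = -0.1, tmax = 1.0)
  peak_t <- ep2$times[which.max(ep2$data[1, 1, ])]
  expect_equal(peak_t, 0.100, tolerance = 1e-9)

  # defining property on noisy data
  set.seed(2)
  raw3 <- raw_recording(matrix(rnorm(3 * n, 10, 4), 3, n), sf,
                        c("a", "b", "c"),
                        data.frame(sample = c(500, 1500, 3000), trial = 1:3,
                                   condition = "incongruent"))
  ep3 <- epoch_and_baseline(raw3)
  bsel <- which(ep3$times >= -0.06 - 1e-9 & ep3$times <= 0.04 + 1e-9)
  bmeans <- apply(ep3$data[, , bsel], c(1, 2), mean)
  expect_lt(max(abs(bmeans)), 1e-10)
})

test_that("peak-to-peak rejection equals an exhaustive scan and logs offenders", {
  set.seed(4)
  p <- small_params(noise_sd = 5)
  ep <- simulate_participant_epochs(make_schedule("forward", 30), p, seed = 3)
  ep$data[7, 3, 40] <- ep$data[7, 3, 40] + 250  # constructed exceedance
  kept <- reject_peak_to_peak(ep, budget_uv = 200)
  # exhaustive oracle over all trial x channel ranges
  bad_oracle <- which(apply(ep$data, 1, function(tr) {
    any(apply(tr, 1, function(v) diff(range(v))) > 200)
  }))
  expect_identical(sort(kept$rejected$trial), sort(ep$trial_index[bad_oracle]))
  expect_true(7L %in% kept$rejected$trial)
  expect_identical(dim(kept$data)[1] + nrow(kept$rejected), 30L)

  zero <- epoch_set(array(0, c(4, 2, 10)), seq(0, 0.9, 0.1), 10,
                    c("a", "b"), rep("congruent", 4))
  expect_identical(nrow(reject_peak_to_peak(zero, 200)$rejected), 0L)
})

test_that("preprocessing chain is deterministic and ordered", {
  p <- small_params(noise_sd = 6, blink_rate = 0.3)
  raw <- simulate_eeg(make_schedule("forward", 10), p, seed = 11)
  a <- preprocess_raw(raw, ica_seed = 2)
  b <- preprocess_raw(raw, ica_seed = 2)
  expect_identical(a$data, b$data)
  expect_true(any(grepl("bandpass", a$chain)))
  expect_lt(match("bandpass_filter(0.1-30 Hz)", a$chain),
            match("rereference_average", a$chain))
})
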