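test_that("participant ERPs average trials then participants, with exact SEM", {
  p <- small_params(noise_sd = 4)
  eps <- cohort_epochs(5, 24, p, seed = 2)
  erps <- participant_erps(eps)
  expect_identical(erps$n, 5L)

  # single participant, single trial per condition: ERP equals the trial
  one <- eps[[1]]
  first_c <- which(one$labels == "congruent")[1]
  first_i <- which(one$labels == "incongruent")[1]
  solo <- epoch_set(one$data[c(first_c, first_i), , , drop = FALSE],
                    one$times, one$sfreq, one$channel_names,
                    c("congruent", "incongruent"))
  es <- participant_erps(list(solo))
  expect_equal(es$cond_mean_congruent[1, , ], one$data[first_c, , ],
               tolerance = 1e-12)

  # SEM at a fixed point equals sd/sqrt(n) by brute force
  ch <- 3; tp <- 100
  vals <- vapply(seq_len(5), function(i) erps$diff[i, ch, tp], numeric(1))
  expect_equal(erps$sem_diff[ch, tp], sd(vals) / sqrt(5), tolerance = 1e-10)

  # linearity: difference of grand means = grand mean of differences
  expect_equal(erps$grand_diff,
               erps$grand_congruent - erps$grand_incongruent,
               tolerance = 1e-12)

  # participant missing a condition is excluded with a log entry
  allc <- epoch_set(one$data[one$labels == "congruent", , , drop = FALSE],
                    one$times, one$sfreq, one$channel_names,
                    rep("congruent", sum(one$labels == "congruent")))
  es2 <- participant_erps(c(eps, list(allc)))
  expect_identical(es2$n, 5L)
  expect_identical(es2$excluded, 6L)
})

test_that("noiseless grand difference equals the injected template difference", {
  p <- small_params(noise_sd = 0, blink_rate = 0)
  eps <- lapply(1:3, function(i) {
    baseline_correct(simulate_participant_epochs(
      make_schedule("forward", 16, seed = i), p, seed = i))
  })
  erps <- participant_erps(eps)
  i_p8 <- match("P8", erps$channel_names)
  in_window <- primingEEG:::window_sample_idx(erps$times, c(586, 889))
  expect_equal(unique(round(erps$grand_diff[i_p8, in_window], 10)), -1.14)
  out_window <- setdiff(seq_along(erps$times), in_window)
  expect_lt(max(abs(erps$grand_diff[i_p8, out_window])), 1e-10)
  expect_lt(max(abs(erps$grand_diff[-i_p8, ])), 1e-10)
})

test_that("running t-test matches a scalar paired t-test and handles degeneracy", {
  p <- small_params(noise_sd = 4)
  eps <- cohort_epochs(6, 20, p, seed = 4)
  erps <- participant_erps(eps)
  rt <- running_ttest(erps)
  ch <- 5; tp <- 42
  oracle <- t.test(erps$diff[, ch, tp])
  expect_equal(unname(rt$t[ch, tp]), unname(oracle$statistic),
               tolerance = 1e-10)
  expect_equal(unname(rt$p[ch, tp]), oracle$p.value, tolerance = 1e-10)
  d_vals <- erps$diff[, ch, tp]
  expect_equal(unname(rt$d[ch, tp]), mean(d_vals) / sd(d_vals),
               tolerance = 1e-10)
  expect_false(rt$corrected)

  # identical condition means everywhere: t = 0, p = 1
  zero <- erps
  zero$diff <- zero$diff * 0
  rt0 <- running_ttest(zero)
  expect_true(all(rt0$t == 0))
  expect_true(all(rt0$p == 1))

  # zero variance with nonzero mean: undefined marker, not p = 0
  const <- erps
  const$diff[] <- 1
  rtc <- running_ttest(const)
  expect_true(all(is.na(rtc$p)))
  expect_error(running_ttest(participant_erps(eps[1:2])), "3 participants")
})

test_that("longest-window selection follows constructed runs, ties and emptiness", {
  mk_rt <- function(p) {
    structure(list(p = p, t = p * 0, d = p * 0, alpha = 0.05,
                   n = 10, times = seq(0, by = 0.004,
                                       length.out = ncol(p)),
                   channel_names = rownames(p), corrected = FALSE),
              class = "running_test")
  }
  p <- matrix(0.5, 2, 20, dimnames = list(c("A", "B"), NULL))
  p["A", 3:5] <- 0.01    # run of 3
  p["B", 8:14] <- 0.01   # run of 7
  sel <- select_longest_window(mk_rt(p))
  expect_identical(sel$electrode, "B")
  expect_equal(sel$window_ms, c(7, 13) * 4, tolerance = 1e-9)
  expect_identical(sel$tie_break, "none")
  expect_identical(nrow(sel$per_electrode), 2L)

  # all p = 0.5: empty selection, not an error
  empty <- select_longest_window(mk_rt(matrix(0.5, 2, 20,
                                              dimnames = list(c("A", "B"),
                                                              NULL))))
  expect_true(empty$empty)

  # tie: earlier onset wins, then montage order
  p2 <- matrix(0.5, 2, 20, dimnames = list(c("A", "B"), NULL))
  p2["B", 2:6] <- 0.01
  p2["A", 10:14] <- 0.01
  sel2 <- select_longest_window(mk_rt(p2))
  expect_identical(sel2$electrode, "B")
  expect_identical(sel2$tie_break, "earlier onset, then montage order")

  # NA p-values break runs
  p3 <- matrix(0.5, 1, 20, dimnames = list("A", NULL))
  p3[1, 2:9] <- 0.01
  p3[1, 5] <- NA
  sel3 <- select_longest_window(mk_rt(p3))
  expect_equal(sel3$window_ms[1], 5 * 4, tolerance = 1e-9)
})

test_that("window selection is equivariant under electrode relabelling", {
  p <- small_params(noise_sd = 6)
  eps <- cohort_epochs(8, 30, p, seed = 6)
  erps <- participant_erps(eps)
  rt <- running_ttest(erps)
  sel <- select_longest_window(rt)
  perm <- rev(seq_along(rt$channel_names))
  rt2 <- rt
  rt2$p <- rt$p[perm, ]
  rt2$t <- rt$t[perm, ]
  rt2$d <- rt$d[perm, ]
  rt2$channel_names <- rt$channel_names[perm]
  rownames(rt2$p) <- rt2$channel_names
  sel2 <- select_longest_window(rt2)
  expect_identical(sel2$electrode, sel$electrode)
  expect_equal(sel2$window_ms, sel$window_ms)
})

test_that("topographic summary takes the capped median around the min-p time", {
  p <- matrix(0.5, 2, 50, dimnames = list(c("A", "B"), NULL))
  p["A", 20:30] <- 0.01
  p["A", 25] <- 0.001
  p["B", 20:30] <- seq(0.2, 0.002, length.out = 11)
  rt <- structure(list(p = p, t = p * 0, d = p * 0, alpha = 0.05, n = 10,
                       times = seq(0, by = 0.004, length.out = 50),
                       channel_names = c("A", "B"), corrected = FALSE),
                  class = "running_test")
  sel <- select_longest_window(rt)
  expect_identical(sel$electrode, "A")
  expect_equal(sel$min_p_time_ms, 24 * 4, tolerance = 1e-9)
  s <- summarize_window(rt, sel)
  # +-10 ms at 4 ms sampling = samples 23:27 (times 88..104 ms)
  nb <- which(rt$times * 1000 >= sel$min_p_time_ms - 10 - 1e-9 &
                rt$times * 1000 <= sel$min_p_time_ms + 10 + 1e-9)
  expect_equal(unname(s["A"]), min(median(p["A", nb]), 0.05), tolerance = 1e-12)
  expect_equal(unname(s["B"]), min(median(p["B", nb]), 0.05), tolerance = 1e-12)
  # capping: a flat p = 0.5 electrode reports exactly 0.05
  expect_equal(unname(summarize_window(rt, sel)["B"]) <= 0.05, TRUE)
  p2 <- p
  p2["B", ] <- 0.5
  rt2 <- rt
  rt2$p <- p2
  expect_equal(unname(summarize_window(rt2, sel)["B"]), 0.05)
  # constant p over the neighbourhood reproduces itself
  p3 <- p
  p3["B", ] <- 0.01
  rt3 <- rt
  rt3$p <- p3
  expect_equal(unname(summarize_window(rt3, sel)["B"]), 0.01)
  expect_identical(attr(s, "method"), "median")
  expect_error(summarize_window(rt, structure(list(empty = TRUE),
                                              class = "window_selection")),
               "empty")
})

test_that("windowed amplitudes equal a brute-force mean and recover injections", {
  p <- small_params(noise_sd = 3)
  eps <- cohort_epochs(6, 30, p, seed = 9)
  erps <- participant_erps(eps)
  wa <- windowed_amplitude(erps, "P8", c(586, 889))
  sel <- primingEEG:::window_sample_idx(erps$times, c(586, 889))
  i_p8 <- match("P8", erps$channel_names)
  brute <- vapply(1:6, function(i) mean(erps$diff[i, i_p8, sel]), numeric(1))
  expect_equal(wa$amplitude_uv, brute, tolerance = 1e-12)
  expect_equal(attr(wa, "mean"), mean(brute), tolerance = 1e-12)

  # parameter recovery within 2 SEM on a noisy cohort
  expect_lt(abs(attr(wa, "mean") - (-1.14)),
            2 * sd(brute) / sqrt(6) + 1e-12)

  # constant difference trace yields that constant for any window
  const <- erps
  const$diff[] <- 0.32
  expect_equal(unique(windowed_amplitude(const, "Pz",
                                         c(100, 500))$amplitude_uv), 0.32)
  expect_error(windowed_amplitude(erps, "nope", c(100, 200)), "unknown")
  expect_error(windowed_amplitude(erps, "P8", c(900, 1400)), "outside")
})
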