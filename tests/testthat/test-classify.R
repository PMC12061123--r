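make_epochs <- function(n_trials, sfreq = 250, tmin = -0.1, tmax = 1.0,
                        n_chan = 6, seed = 1) {
  idx <- seq(round(tmin * sfreq), round(tmax * sfreq))
  times <- idx / sfreq
  set.seed(seed)
  epoch_set(array(rnorm(n_trials * n_chan * length(times)),
                  c(n_trials, n_chan, length(times))),
            times, sfreq, paste0("ch", seq_len(n_chan)),
            labels = rep(c("congruent", "incongruent"),
                         length.out = n_trials))
}

test_that("decoding window slicing follows half-open sample arithmetic", {
  ep250 <- make_epochs(4, sfreq = 250)
  t250 <- extract_decoding_tensor(ep250)
  expect_identical(dim(t250$x)[3], 75L)

  ep1000 <- make_epochs(4, sfreq = 1000)
  t1000 <- extract_decoding_tensor(ep1000)
  expect_identical(dim(t1000$x)[3], 300L)
  expect_identical(t250$y, rep(c(1, 0), 2))

  # window equal to the epoch span is an identity slice
  full <- extract_decoding_tensor(ep250, c(-0.1, 1.0 + 1 / 250))
  expect_identical(dim(full$x), dim(ep250$data))
  expect_error(extract_decoding_tensor(ep250, c(0.4, 2)), "outside")
})

test_that("class balancing subsamples the majority class to the minority count", {
  y <- c(rep(1, 100), rep(0, 80))
  keep <- balance_classes(y, seed = 3)
  expect_identical(length(keep), 160L)
  expect_identical(sum(y[keep] == 1), 80L)
  expect_identical(sum(y[keep] == 0), 80L)
  expect_identical(balance_classes(y, seed = 3), keep)

  balanced <- rep(c(0, 1), 20)
  expect_identical(balance_classes(balanced, 1), seq_along(balanced))
  expect_error(balance_classes(rep(1, 10)), "both classes")
})

test_that("fold assignments partition trials with exact 50/50 class splits", {
  y <- rep(c(0, 1), each = 42)  # 42 per class: 2 dropped per class
  fold <- primingEEG:::make_cv_folds(y, 4L, seed = 2)
  expect_identical(length(attr(fold, "dropped")), 4L)
  for (f in 1:4) {
    sel <- which(!is.na(fold) & fold == f)
    expect_identical(length(sel), 20L)
    expect_identical(sum(y[sel] == 1), 10L)
  }
  # every retained trial tests exactly once
  expect_identical(sum(!is.na(fold)), 80L)
})

test_that("the CV protocol yields exactly 12 accuracies and is reproducible", {
  ep <- make_epochs(48, seed = 5)
  rep1 <- classify_participant(ep, net_spec(n_filters = 4, epochs = 2),
                               seed = 1, participant = 7,
                               experiment = "forward")
  expect_identical(length(rep1$accuracies), 12L)
  expect_identical(dim(rep1$accuracies), c(4L, 3L))
  expect_true(all(rep1$accuracies >= 0 & rep1$accuracies <= 1))
  expect_equal(rep1$summary_mean, mean(rep1$accuracies), tolerance = 1e-12)
  expect_equal(rep1$summary_median, median(rep1$accuracies),
               tolerance = 1e-12)
  expect_equal(rep1$per_seed_mean, colMeans(rep1$accuracies),
               tolerance = 1e-12)
  rep2 <- classify_participant(ep, net_spec(n_filters = 4, epochs = 2),
                               seed = 1, participant = 7,
                               experiment = "forward")
  expect_identical(rep1$accuracies, rep2$accuracies)
  expect_error(train_eval_cv(array(0, c(6, 2, 30)), rep(c(0, 1), 3)),
               "per class")
})

test_that("strongly separable trials decode far above chance", {
  p <- small_params(noise_sd = 2,
                    effect_spec = list(list(electrode = "P8",
                                            window_ms = c(400, 700),
                                            amplitude_uv = 30)))
  ep <- baseline_correct(simulate_participant_epochs(
    make_schedule("forward", 128, seed = 2), p, seed = 3))
  rep <- classify_participant(ep, net_spec(learning_rate = 1e-2,
                                           epochs = 40), seed = 1)
  expect_gt(rep$summary_mean, 0.9)
})

test_that("random search is deterministic, in-space, and internally ordered", {
  ep <- make_epochs(32, seed = 6, tmin = 0, tmax = 0.8)
  tens <- extract_decoding_tensor(ep, c(0, 0.5))
  keep <- balance_classes(tens$y, 1)
  x <- tens$x[keep, , , drop = FALSE]
  y <- tens$y[keep]
  rs1 <- suppressMessages(random_search(x, y, n_draws = 10, seed = 4,
                                        cv_seeds = 11L, epochs = 1))
  rs2 <- suppressMessages(random_search(x, y, n_draws = 10, seed = 4,
                                        cv_seeds = 11L, epochs = 1))
  expect_identical(rs1$leaderboard, rs2$leaderboard)
  lb <- rs1$leaderboard
  expect_true(all(lb$activation %in% c("relu", "softmax", "softplus",
                                       "tanh", "selu", "elu")))
  expect_true(all(lb$n_filters %in% 4:8))
  expect_true(all(lb$optimizer %in% c("adam", "sgd", "rmsprop")))
  expect_true(all(lb$learning_rate %in% c(1e-2, 1e-3, 1e-4)))
  expect_true(all(lb$loss %in% c("binary_crossentropy", "poisson",
                                 "kl_divergence")))
  expect_gte(lb$summary_mean[1], median(lb$summary_mean))
  expect_identical(rs1$best_spec$activation, lb$activation[1])
  expect_error(random_search(x, y, n_draws = 0), "at least 1")
})

test_that("mean accuracy is non-decreasing in injected effect size", {
  accs <- vapply(c(0, 8, 30), function(amp) {
    p <- small_params(noise_sd = 2,
                      effect_spec = if (amp == 0) list() else
                        list(list(electrode = "P8",
                                  window_ms = c(400, 700),
                                  amplitude_uv = amp)))
    ep <- baseline_correct(simulate_participant_epochs(
      make_schedule("forward", 64, seed = 4), p, seed = 5))
    classify_participant(ep, net_spec(learning_rate = 1e-2, epochs = 30),
                         seed = 1)$summary_mean
  }, numeric(1))
  expect_gt(accs[3], accs[1] + 0.1)
  expect_gte(accs[3] + 0.05, accs[2])  # sampling-error tolerance
})
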